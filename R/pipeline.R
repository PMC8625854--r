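# End-to-end orchestration: synthetic dataset generation, two-stage
# training, counting and evaluation. These functions are the programmatic
# interface behind the exec/stomacount command-line entry point.

writeManifest <- function(outDir, command, params) {
  tmp <- tempfile()
  saveRDS(params, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(command = command, runId = hash, params = params,
                   written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(hash)
}

paramsToList <- function(p) {
  structure(lapply(slotNames(p), function(s) slot(p, s)),
            names = slotNames(p))
}

checkOutDir <- function(outDir, overwrite) {
  if (file.exists(file.path(outDir, "manifest.json")) && !overwrite)
    stop("output directory already holds a run (manifest.json present); ",
         "use overwrite = TRUE to replace it")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{n} seeded synthetic micrographs with their red-painted
#' annotation images and truth-center CSVs, plus a parameter sidecar
#' (\code{params.yaml}) and a run manifest echoing every parameter. Reruns
#' with the same parameters produce identical files; an existing run is
#' never silently overwritten.
#'
#' @param outDir output directory.
#' @param n number of samples.
#' @param params a \linkS4class{SyntheticParams}.
#' @param overwrite replace an existing run.
#' @return Invisibly, a data.frame listing the files written.
#' @export
runSynth <- function(outDir, n, params = syntheticParams(),
                     overwrite = FALSE) {
  validObject(params)
  checkOutDir(outDir, overwrite)
  samples <- generateDataset(n, params)
  rows <- lapply(seq_along(samples), function(i) {
    base <- sprintf("sample_%03d", i)
    s <- samples[[i]]
    writeMicrograph(s@micrograph, file.path(outDir, paste0(base, ".png")))
    writeAnnotationImage(s@annotationImage,
                         file.path(outDir, paste0(base, "_annotation.png")))
    writeCentersCsv(s@truthCenters,
                    file.path(outDir, paste0(base, "_centers.csv")))
    data.frame(id = base, nStomata = nrow(centers(s@truthCenters)),
               nArtifacts = nrow(s@artifactCenters))
  })
  yaml::write_yaml(paramsToList(params), file.path(outDir, "params.yaml"))
  writeManifest(outDir, "synth", c(paramsToList(params), list(n = n)))
  invisible(do.call(rbind, rows))
}

# Stage-1 training pairs (tile pixels + quarter-resolution Gaussian target)
# from tiles carrying AnnotationSet targets.
prepareStage1Pairs <- function(tilePairs, sigmaPx = 10) {
  lapply(tilePairs, function(tp) {
    list(image = tp@imageTile@pixels,
         target = makeTargetHeatmap(tp@targetTile, sigmaPx = sigmaPx,
                                    resolutionFactor = 4L))
  })
}

#' Train the two-stage detector
#'
#' Prepares tiles and Gaussian targets, trains the stage-1 heatmap network,
#' extracts loose stage-1 candidates on the training tiles (at the proposal
#' threshold, deliberately below the detection threshold so imprint
#' artifacts and background bumps supply negative windows), labels them
#' against the truth, and trains the stage-2 window classifier.
#'
#' @param samples list of \linkS4class{SyntheticSample}, or of
#'   \code{list(micrograph = , truth = )} pairs for real annotated images
#'   (use \code{\link{extractAnnotationCenters}} on the label image first).
#' @param outDir optional directory for checkpoints, history CSVs and the
#'   run manifest.
#' @param tileShape training tile shape (default 256 x 256).
#' @param sigmaPx Gaussian target sigma in full-resolution pixels.
#' @param stage1,stage2 configurations.
#' @param proposalThreshold loose extraction threshold used only to mine
#'   stage-2 training windows.
#' @param blurSigma,threshold,minSeparationPx candidate-extraction
#'   parameters (heatmap cells).
#' @param matchRadiusPx window-labeling radius (full-resolution px).
#' @param trainFraction,seed tile split parameters.
#' @param overwrite replace an existing run in \code{outDir}.
#' @return List with \code{stage1}, \code{stage2} (trained models),
#'   \code{split} (the tile split) and \code{windowCounts}.
#' @export
runTrain <- function(samples, outDir = NULL, tileShape = c(256L, 256L),
                     sigmaPx = 10, stage1 = stage1Config(),
                     stage2 = stage2Config(), proposalThreshold = 0.15,
                     blurSigma = 2, threshold = 0.3, minSeparationPx = 8,
                     matchRadiusPx = 16, trainFraction = 0.9, seed = 1L,
                     overwrite = FALSE) {
  if (!length(samples)) stop("no training samples provided")
  pairs <- list()
  for (s in samples) {
    if (is(s, "SyntheticSample")) {
      mg <- s@micrograph; tr <- s@truthCenters
    } else {
      mg <- s$micrograph; tr <- s$truth
      if (is.null(mg) || is.null(tr))
        stop("each sample needs a micrograph and its truth annotation")
    }
    pairs <- c(pairs, tileImagePair(mg, tr, tileShape))
  }
  split <- splitDataset(pairs, trainFraction, seed)
  if (!length(split$train)) stop("training split is empty")

  s1pairs <- prepareStage1Pairs(split$train, sigmaPx)
  v1pairs <- if (length(split$test)) prepareStage1Pairs(split$test, sigmaPx)
             else NULL
  model1 <- trainStage1(buildStage1(stage1), s1pairs, v1pairs, stage1)

  mineWindows <- function(thr) {
    wsamples <- lapply(split$train, function(tp) {
      hm <- predictHeatmap(model1, tp@imageTile)
      cand <- extractCandidates(hm, blurSigma = blurSigma, threshold = thr,
                                minSeparationPx = minSeparationPx)
      list(micrograph = tp@imageTile, candidates = cand, truth = tp@targetTile)
    })
    buildTrainingWindows(wsamples, stage2@windowSize, matchRadiusPx)
  }
  windows <- mineWindows(proposalThreshold)
  labs <- vapply(windows, function(w) w$label, integer(1))
  if (!length(windows) || length(unique(labs)) < 2L) {
    # a sharply trained stage 1 may propose only true stomata at the
    # proposal threshold (and a weak one may propose nothing); mine the
    # weakest peaks too so both classes are represented, keeping the
    # deeper set no larger than the other class
    message("mining additional stage-2 windows at threshold 0.01 ",
            "(missing class at the proposal threshold)")
    deep <- mineWindows(0.01)
    dlabs <- vapply(deep, function(w) w$label, integer(1))
    for (miss in setdiff(unique(dlabs), labs)) {
      add <- deep[dlabs == miss]
      cap <- max(32L, sum(labs != miss))
      windows <- c(windows, add[seq_len(min(length(add), cap))])
    }
    labs <- vapply(windows, function(w) w$label, integer(1))
    attr(windows, "classCounts") <- c(positive = sum(labs == 1L),
                                      negative = sum(labs == 0L))
  }
  if (!length(windows))
    stop("stage 1 produced no candidate windows; cannot train stage 2")
  if (length(unique(labs)) < 2L)
    stop("stage-1 proposals contain a single class; cannot train stage 2")
  model2 <- trainStage2(buildStage2(stage2), windows, stage2)

  if (!is.null(outDir)) {
    checkOutDir(outDir, overwrite)
    saveModel(model1, file.path(outDir, "stage1"))
    saveModel(model2, file.path(outDir, "stage2"))
    writeHistoryCsv(model1@history, file.path(outDir, "stage1_history.csv"))
    writeHistoryCsv(model2@history, file.path(outDir, "stage2_history.csv"))
    writeManifest(outDir, "train",
                  list(tileShape = tileShape, sigmaPx = sigmaPx,
                       stage1 = paramsToList(stage1),
                       stage2 = paramsToList(stage2),
                       proposalThreshold = proposalThreshold,
                       blurSigma = blurSigma, threshold = threshold,
                       minSeparationPx = minSeparationPx,
                       matchRadiusPx = matchRadiusPx,
                       trainFraction = trainFraction, seed = seed))
  }
  list(stage1 = model1, stage2 = model2, split = split,
       windowCounts = attr(windows, "classCounts"))
}

# Center-crop a pixel matrix so both dimensions are multiples of f.
cropToMultiple <- function(px, f = 4L) {
  h <- nrow(px); w <- ncol(px)
  h2 <- (h %/% f) * f; w2 <- (w %/% f) * f
  if (h2 == h && w2 == w) return(list(px = px, offset = c(0L, 0L)))
  r0 <- (h - h2) %/% 2L; c0 <- (w - w2) %/% 2L
  message(sprintf("image %d x %d auto center-cropped to %d x %d (multiple of %d)",
                  h, w, h2, w2, f))
  list(px = px[(r0 + 1L):(r0 + h2), (c0 + 1L):(c0 + w2), drop = FALSE],
       offset = c(r0, c0))
}

#' Detect stomata on one micrograph (stage 1 + stage 2)
#'
#' @param stage1,stage2 trained models.
#' @param image a \linkS4class{Micrograph} (or matrix); dimensions not
#'   divisible by 4 are auto center-cropped (logged).
#' @param blurSigma,threshold,minSeparationPx extraction parameters.
#' @param cutoff stage-2 decision cutoff.
#' @return Confirmed \linkS4class{DetectionSet} (coordinates relative to the
#'   cropped image; the crop offset is recorded in the provenance).
#' @export
detectStomata <- function(stage1, stage2, image, blurSigma = 2,
                          threshold = 0.3, minSeparationPx = 8,
                          cutoff = stage2@config@decisionCutoff) {
  px <- asPixelMatrix(image)
  cr <- cropToMultiple(px, 4L)
  mg <- micrograph(cr$px, umPerPx = if (is(image, "Micrograph")) image@umPerPx
                                    else NA_real_)
  hm <- predictHeatmap(stage1, mg)
  cand <- extractCandidates(hm, blurSigma = blurSigma, threshold = threshold,
                            minSeparationPx = minSeparationPx)
  conf <- confirmDetections(stage2, mg, cand, cutoff)
  conf@provenance <- c(conf@provenance, list(cropOffset = cr$offset))
  conf
}

#' Count stomata and report densities for a set of images
#'
#' Runs the full pipeline (stage-1 heatmap, candidate extraction, stage-2
#' confirmation, unbiased counting frame) per image and reports
#' \code{image_id, side, count, area_mm2, density_per_mm2}. When the image
#' set consists of one abaxial and one adaxial image (a leaf), a
#' \code{combined} row with the per-leaf mean density is appended.
#'
#' @param stage1,stage2 trained models, or a directory containing
#'   \code{stage1.rds} / \code{stage2.rds} checkpoints (a missing checkpoint
#'   is an error naming the expected path).
#' @param images list of \linkS4class{Micrograph} objects or image paths.
#' @param umPerPx calibration applied to path inputs.
#' @param sides optional character vector (\code{"abaxial"} /
#'   \code{"adaxial"}) parallel to \code{images}.
#' @param frameMarginPx counting-frame margin (default 16 px).
#' @param outCsv optional CSV output path.
#' @param ... extraction/cutoff parameters passed to
#'   \code{\link{detectStomata}}.
#' @return The density report data.frame.
#' @export
runCount <- function(stage1, stage2, images, umPerPx = NA_real_,
                     sides = NULL, frameMarginPx = 16, outCsv = NULL, ...) {
  if (is.character(stage1) && length(stage1) == 1L && dir.exists(stage1)) {
    dirPath <- stage1
    stage1 <- loadModel(file.path(dirPath, "stage1.rds"))
    stage2 <- loadModel(file.path(dirPath, "stage2.rds"))
  }
  if (is.null(sides))
    sides <- rep(c("abaxial", "adaxial"), length.out = length(images))
  rows <- list()
  dens <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    mg <- if (is.character(im)) readMicrograph(im, umPerPx)
          else if (is(im, "Micrograph")) im
          else micrograph(as.matrix(im), umPerPx)
    if (is.na(mg@umPerPx) && !is.na(umPerPx)) mg@umPerPx <- umPerPx
    id <- if (is.character(im)) basename(im) else sprintf("image_%03d", i)
    det <- detectStomata(stage1, stage2, mg, ...)
    fr <- defaultCountingFrame(det@sourceShape, frameMarginPx, mg@umPerPx)
    cnt <- countInFrame(det, fr)
    dr <- computeDensity(cnt$count, fr, sides[i])
    dens[[i]] <- dr
    rows[[i]] <- data.frame(image_id = id, side = sides[i],
                            count = cnt$count, area_mm2 = dr@frameAreaMm2,
                            density_per_mm2 = dr@densityPerMm2)
  }
  rep <- do.call(rbind, rows)
  if (length(dens) == 2L && setequal(sides, c("abaxial", "adaxial"))) {
    comb <- combineSides(dens[[which(sides == "abaxial")]],
                         dens[[which(sides == "adaxial")]])
    rep <- rbind(rep, data.frame(image_id = "combined", side = "combined",
                                 count = comb@count,
                                 area_mm2 = comb@frameAreaMm2,
                                 density_per_mm2 = comb@densityPerMm2))
  }
  if (!is.null(outCsv)) utils::write.csv(rep, outCsv, row.names = FALSE)
  rep
}

#' Evaluate detections against ground truth
#'
#' Either computes confusion counts by center matching (give
#' \code{predicted} and \code{truth}) or takes counts directly (give
#' \code{NTP}/\code{NFP}/\code{NFN}, optionally \code{NTN}), then reports
#' precision and recall (and accuracy when \code{NTN} is available).
#' Undefined metrics (zero denominators) are flagged rather than reported
#' as numbers.
#'
#' @param predicted,truth detections and annotations (objects, matrices or
#'   CSV paths; paths are read with \code{sourceShape} taken large enough).
#' @param NTP,NFP,NFN,NTN direct confusion counts (alternative input).
#' @param matchRadiusPx matching radius for center matching.
#' @param outJson optional JSON report path.
#' @return A list with the counts, numeric metrics (or \code{NA} when
#'   undefined), formatted percentages and the matching radius.
#' @export
runEvaluate <- function(predicted = NULL, truth = NULL, NTP = NULL,
                        NFP = NULL, NFN = NULL, NTN = NA_integer_,
                        matchRadiusPx = 16, outJson = NULL) {
  if (!is.null(NTP)) {
    cc <- confusionCounts(NTP, NFP, NFN, NTN)
    matching <- NULL
  } else {
    if (is.character(predicted))
      predicted <- utils::read.csv(predicted)[, c("row", "col")]
    if (is.character(truth))
      truth <- utils::read.csv(truth)[, c("row", "col")]
    mt <- matchDetections(as.matrix(predicted), as.matrix(truth),
                          maxDistPx = matchRadiusPx)
    cc <- mt$counts
    matching <- mt$matching
  }
  p <- if (cc@NTP + cc@NFP > 0L) precision(cc) else NA_real_
  r <- if (cc@NTP + cc@NFN > 0L) recall(cc) else NA_real_
  a <- if (!is.na(cc@NTN)) accuracy(cc) else NA_real_
  rep <- list(
    counts = cc,
    precision = p, recall = r, accuracy = a,
    precisionFormatted = if (is.na(p)) "undefined (no predictions)"
                         else formatPercent(p, 1),
    recallFormatted = if (is.na(r)) "undefined (no truth objects)"
                      else formatPercent(r, 0),
    matchRadiusPx = matchRadiusPx, matching = matching)
  if (!is.null(outJson)) {
    out <- rep
    out$counts <- list(NTP = cc@NTP, NFP = cc@NFP, NTN = cc@NTN, NFN = cc@NFN)
    out$matching <- NULL
    jsonlite::write_json(out, outJson, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  rep
}
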