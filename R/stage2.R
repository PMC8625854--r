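#' Stage-2 configuration
#'
#' Configuration of the binary window classifier that verifies stage-1
#' candidates: two 3x3 convolution layers (ReLU, batch-normalized) followed
#' by two fully connected sigmoid layers ending in a single probability that
#' the window contains a stomatal complex.
#'
#' @param windowSize even window side in full-resolution pixels (default
#'   32).
#' @param filtersPerLayer filters of the two convolution layers.
#' @param denseUnits units of the two dense layers; the last must be 1.
#' @param decisionCutoff probability cutoff for confirming a candidate
#'   (default 0.5).
#' @param learningRate,batchSize,epochs Adam training hyperparameters.
#' @param classWeighting weight the binary cross-entropy inversely to class
#'   frequency (off by default).
#' @param seed RNG seed.
#' @param nConvLayers,nDenseLayers architecture descriptors (must be 2 / 2).
#' @param lossName,optimizerName \code{"bce"} and \code{"adam"}.
#' @return A \linkS4class{Stage2Config}.
#' @export
stage2Config <- function(windowSize = 32L, filtersPerLayer = c(8L, 16L),
                         denseUnits = c(64L, 1L), decisionCutoff = 0.5,
                         learningRate = 1e-3, batchSize = 32L, epochs = 15L,
                         classWeighting = FALSE, seed = 1L,
                         nConvLayers = 2L, nDenseLayers = 2L,
                         lossName = "bce", optimizerName = "adam") {
  new("Stage2Config", windowSize = as.integer(windowSize),
      nConvLayers = as.integer(nConvLayers),
      nDenseLayers = as.integer(nDenseLayers),
      filtersPerLayer = as.integer(filtersPerLayer),
      denseUnits = as.integer(denseUnits),
      decisionCutoff = decisionCutoff, lossName = lossName,
      optimizerName = optimizerName, learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      classWeighting = classWeighting, seed = as.integer(seed))
}

validateStage2Config <- function(config) {
  if (config@windowSize < 2L || config@windowSize %% 2L != 0L)
    stop("windowSize must be a positive even integer")
  if (config@nConvLayers != 2L || config@nDenseLayers != 2L)
    stop("stage-2 contract requires 2 convolution and 2 dense layers")
  if (length(config@filtersPerLayer) != 2L)
    stop("filtersPerLayer must have 2 entries")
  if (length(config@denseUnits) != 2L || config@denseUnits[2L] != 1L)
    stop("denseUnits must have 2 entries ending in 1 (a single probability)")
  invisible(TRUE)
}

#' Build the stage-2 window classifier
#'
#' @param config a \linkS4class{Stage2Config}.
#' @return An untrained \linkS4class{Stage2Model} mapping a
#'   \code{windowSize^2} single-channel patch to a probability in
#'   \eqn{[0,1]}.
#' @export
buildStage2 <- function(config = stage2Config()) {
  validateStage2Config(config)
  fl <- config@filtersPerLayer
  ws <- config@windowSize
  set.seed(config@seed)
  net <- list(
    nnLayerConv(1L, fl[1L], 3L, "relu"), nnLayerAct("relu"), nnLayerBn(fl[1L]),
    nnLayerConv(fl[1L], fl[2L], 3L, "relu"), nnLayerAct("relu"), nnLayerBn(fl[2L]),
    nnLayerFlatten(),
    nnLayerDense(ws * ws * fl[2L], config@denseUnits[1L]), nnLayerAct("sigmoid"),
    nnLayerDense(config@denseUnits[1L], 1L), nnLayerAct("sigmoid"))
  new("Stage2Model", net = net, config = config,
      history = data.frame(), trained = FALSE)
}

reflectIndex <- function(idx, n) {
  # symmetric reflection (edge pixel duplicated) onto 0..n-1
  idx <- ifelse(idx < 0L, -idx - 1L, idx)
  idx <- ifelse(idx >= n, 2L * n - 1L - idx, idx)
  idx
}

#' Crop a classifier window around a candidate center
#'
#' Cuts a \code{windowSize x windowSize} patch centered on the rounded
#' center (start index \code{round(center) - windowSize/2}, 0-based);
#' regions falling outside the image are filled by symmetric reflection.
#'
#' @param micrograph a \linkS4class{Micrograph} (or matrix).
#' @param center numeric \code{c(row, col)}, 0-based; must lie within the
#'   image.
#' @param windowSize even patch side (default 32).
#' @return \code{list(patch = <matrix>, center = <c(row, col)>, label = NA)},
#'   the window-sample structure used by the classifier.
#' @export
cropWindow <- function(micrograph, center, windowSize = 32L) {
  px <- asPixelMatrix(micrograph)
  h <- nrow(px); w <- ncol(px)
  if (center[1L] < 0 || center[1L] >= h || center[2L] < 0 || center[2L] >= w)
    stop(sprintf("center (%.1f, %.1f) lies outside the %d x %d image",
                 center[1L], center[2L], h, w))
  ws <- as.integer(windowSize)
  r0 <- as.integer(round(center[1L])) - ws %/% 2L
  c0 <- as.integer(round(center[2L])) - ws %/% 2L
  ri <- reflectIndex(r0:(r0 + ws - 1L), h)
  ci <- reflectIndex(c0:(c0 + ws - 1L), w)
  list(patch = px[ri + 1L, ci + 1L, drop = FALSE],
       center = as.numeric(center), label = NA_integer_)
}

#' Build labeled training windows from stage-1 candidates
#'
#' Crops a window around every stage-1 candidate of every image and labels
#' it 1 when the candidate lies within \code{matchRadiusPx} of a true center
#' under one-to-one matching (\code{\link{matchDetections}}), else 0 — so the
#' positive/negative counts equal the matcher's NTP and NFP at the same
#' radius.
#'
#' @param samples list of \code{list(micrograph = , candidates = , truth = )}
#'   with a \linkS4class{Micrograph}, the stage-1
#'   \linkS4class{DetectionSet} for that image and its
#'   \linkS4class{AnnotationSet}.
#' @param windowSize window side (default 32).
#' @param matchRadiusPx matching radius in full-resolution pixels (default
#'   16).
#' @return List of labeled window samples (as \code{\link{cropWindow}}, with
#'   \code{label} set); attribute \code{classCounts} reports
#'   \code{c(positive = , negative = )}.
#' @export
buildTrainingWindows <- function(samples, windowSize = 32L,
                                 matchRadiusPx = 16) {
  out <- list()
  npos <- 0L; nneg <- 0L
  for (s in samples) {
    cand <- s$candidates
    stopifnot(is(cand, "DetectionSet"))
    m <- nDetections(cand)
    if (m == 0L) next
    mt <- matchDetections(cand, s$truth, maxDistPx = matchRadiusPx)
    lab <- integer(m)
    lab[mt$matching$predIndex] <- 1L
    ce <- centers(cand)
    for (i in seq_len(m)) {
      wsmp <- cropWindow(s$micrograph, ce[i, ], windowSize)
      wsmp$label <- lab[i]
      out[[length(out) + 1L]] <- wsmp
    }
    npos <- npos + sum(lab == 1L); nneg <- nneg + sum(lab == 0L)
  }
  attr(out, "classCounts") <- c(positive = npos, negative = nneg)
  out
}

#' Train the stage-2 window classifier
#'
#' Seeded mini-batch Adam training with binary cross-entropy on labeled
#' windows. A 90/10 seeded split of the windows provides a held-out set;
#' per-epoch losses and held-out accuracy (at the config decision cutoff)
#' are recorded and the best-held-out-loss parameters are kept.
#'
#' @param model a \linkS4class{Stage2Model}.
#' @param windows non-empty list of labeled window samples (see
#'   \code{\link{buildTrainingWindows}}); both classes must be present
#'   (single-class training is degenerate and an error).
#' @param config training configuration (defaults to the model's).
#' @return The trained model; \code{model@history} has columns \code{epoch},
#'   \code{trainLoss}, \code{valLoss}, \code{valAccuracy},
#'   \code{bestValLoss}.
#' @export
trainStage2 <- function(model, windows, config = model@config) {
  stopifnot(is(model, "Stage2Model"))
  if (!length(windows)) stop("windows must be a non-empty list")
  labs <- vapply(windows, function(w) as.integer(w$label), integer(1))
  if (any(is.na(labs))) stop("all windows must be labeled")
  if (length(unique(labs)) < 2L)
    stop("degenerate training set: both classes (stoma / non-stoma) must be present")
  patches <- lapply(windows, `[[`, "patch")

  set.seed(config@seed)
  n <- length(windows)
  perm <- sample.int(n)
  nTrain <- max(1L, floor(0.9 * n))
  trIdx <- perm[seq_len(nTrain)]
  vaIdx <- perm[setdiff(seq_len(n), seq_len(nTrain))]
  if (!length(vaIdx)) vaIdx <- trIdx
  # guarantee both classes in the training part
  if (length(unique(labs[trIdx])) < 2L) {
    miss <- setdiff(unique(labs), labs[trIdx])
    swap <- vaIdx[which(labs[vaIdx] %in% miss)[1L]]
    trIdx <- c(trIdx, swap)
  }
  w <- NULL
  if (config@classWeighting) {
    pPos <- mean(labs[trIdx] == 1L)
    w <- ifelse(labs == 1L, 0.5 / pPos, 0.5 / (1 - pPos))
  }

  net <- model@net
  state <- nnAdamInit(net)
  bs <- config@batchSize
  ws <- nnMakeWorkspace(net, dim(patches[[1L]]),
                        min(bs, length(trIdx)))
  hist <- data.frame()
  bestVal <- Inf; bestNet <- net; t <- 0L
  for (ep in seq_len(config@epochs)) {
    ord <- trIdx[sample.int(length(trIdx))]
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = bs)) {
      idx <- ord[b0:min(b0 + bs - 1L, length(ord))]
      X <- nnBatchArray(patches, idx)
      y <- labs[idx]
      fw <- nnForward(net, X, training = TRUE, ws = ws)
      net <- fw$net
      ls <- nnBceLoss(fw$out, y, if (is.null(w)) NULL else w[idx])
      losses <- c(losses, ls$loss)
      bw <- nnBackward(net, fw$caches, ls$grad, ws = ws)
      t <- t + 1L
      up <- nnAdamStep(net, bw$grads, state, config@learningRate, t)
      net <- up$net; state <- up$state
    }
    vp <- stage2Probs(net, patches, vaIdx, bs)
    vl <- nnBceLoss(vp, labs[vaIdx])$loss
    va <- mean((vp >= config@decisionCutoff) == (labs[vaIdx] == 1L))
    if (vl < bestVal) { bestVal <- vl; bestNet <- net }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                   valLoss = vl, valAccuracy = va,
                                   bestValLoss = bestVal))
  }
  model@net <- bestNet
  model@config <- config
  # held-out accuracy of the checkpointed model
  vp <- stage2Probs(bestNet, patches, vaIdx, bs)
  attr(hist, "heldOutAccuracy") <-
    mean((vp >= config@decisionCutoff) == (labs[vaIdx] == 1L))
  model@history <- hist
  model@trained <- TRUE
  model
}

stage2Probs <- function(net, patches, idx, bs = 64L) {
  probs <- numeric(length(idx))
  for (b0 in seq(1L, length(idx), by = bs)) {
    sel <- idx[b0:min(b0 + bs - 1L, length(idx))]
    fw <- nnForward(net, nnBatchArray(patches, sel), training = FALSE)
    probs[b0:(b0 + length(sel) - 1L)] <- as.numeric(fw$out)
  }
  probs
}

#' Classify one or more windows
#'
#' @param model a \linkS4class{Stage2Model}.
#' @param patches list of \code{windowSize x windowSize} matrices (or a
#'   single matrix).
#' @return Numeric vector of stoma probabilities in \eqn{[0,1]}.
#' @export
predictWindowProb <- function(model, patches) {
  if (is.matrix(patches)) patches <- list(patches)
  stage2Probs(model@net, patches, seq_along(patches))
}

#' Confirm stage-1 candidates with the window classifier
#'
#' Crops a window around every candidate, classifies it, and keeps the
#' candidates whose stoma probability is at least the cutoff; kept
#' detections carry the classifier probability as their score and
#' \code{stage = "confirmed"}. Confirmation only ever removes candidates.
#'
#' @param model a trained \linkS4class{Stage2Model}.
#' @param micrograph the \linkS4class{Micrograph} the candidates refer to.
#' @param candidates a \linkS4class{DetectionSet} (stage-1 output).
#' @param cutoff decision cutoff in \eqn{[0, 1)} (0 retains everything).
#' @return A \linkS4class{DetectionSet} with \code{stage = "confirmed"},
#'   a subset of the candidates.
#' @export
confirmDetections <- function(model, micrograph, candidates,
                              cutoff = model@config@decisionCutoff) {
  stopifnot(is(model, "Stage2Model"), is(candidates, "DetectionSet"))
  if (!is.numeric(cutoff) || cutoff < 0 || cutoff >= 1)
    stop("cutoff must lie in [0, 1)")
  m <- nDetections(candidates)
  src <- candidates@sourceShape
  prov <- c(candidates@provenance, list(decisionCutoff = cutoff))
  if (m == 0L)
    return(detectionSet(matrix(numeric(0), 0, 2), numeric(0), "confirmed",
                        src, prov))
  ce <- centers(candidates)
  patches <- lapply(seq_len(m), function(i)
    cropWindow(micrograph, ce[i, ], model@config@windowSize)$patch)
  probs <- stage2Probs(model@net, patches, seq_len(m))
  keep <- probs >= cutoff
  detectionSet(ce[keep, , drop = FALSE], pmin(1, pmax(0, probs[keep])),
               "confirmed", src, prov)
}
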