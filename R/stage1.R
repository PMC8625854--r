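#' Stage-1 configuration
#'
#' Configuration of the heatmap-regression network. The architecture
#' contract is fixed: six 3x3 convolution layers (ReLU activation on the
#' first two, sigmoid on the last four) interspersed with batch
#' normalization and dropout, and two 2x2 max-pooling layers giving a total
#' downsampling factor of four; the final layer is a single-channel sigmoid
#' map. \code{\link{buildStage1}} refuses configurations that violate the
#' contract.
#'
#' @param filtersPerLayer filters per convolution layer; the last entry must
#'   be 1 (the heatmap channel).
#' @param kernelSize odd kernel size (default 3).
#' @param dropoutRate dropout rate (default 0.25).
#' @param learningRate,batchSize,epochs Adam training hyperparameters.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param nConvLayers,nPoolLayers,poolFactorTotal,activations architecture
#'   descriptors; defaults are the only values \code{\link{buildStage1}}
#'   accepts, and are exposed so invalid configurations can be constructed
#'   and rejected explicitly.
#' @param lossName,optimizerName \code{"mse"} and \code{"adam"} (the only
#'   supported values).
#' @return A \linkS4class{Stage1Config}.
#' @export
stage1Config <- function(filtersPerLayer = c(8L, 8L, 16L, 16L, 32L, 1L),
                         kernelSize = 3L, dropoutRate = 0.25,
                         learningRate = 2e-3, batchSize = 8L, epochs = 10L,
                         seed = 1L, nConvLayers = 6L, nPoolLayers = 2L,
                         poolFactorTotal = 4L,
                         activations = c("relu", "relu", "sigmoid", "sigmoid",
                                         "sigmoid", "sigmoid"),
                         lossName = "mse", optimizerName = "adam") {
  new("Stage1Config", nConvLayers = as.integer(nConvLayers),
      activations = activations, nPoolLayers = as.integer(nPoolLayers),
      poolFactorTotal = as.integer(poolFactorTotal),
      filtersPerLayer = as.integer(filtersPerLayer),
      kernelSize = as.integer(kernelSize), dropoutRate = dropoutRate,
      lossName = lossName, optimizerName = optimizerName,
      learningRate = learningRate, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), seed = as.integer(seed))
}

validateStage1Config <- function(config) {
  if (config@nConvLayers != 6L)
    stop("stage-1 contract requires exactly 6 convolution layers")
  if (config@nPoolLayers != 2L || config@poolFactorTotal != 4L)
    stop("stage-1 contract requires 2 pooling layers (total factor 4)")
  if (length(config@filtersPerLayer) != 6L)
    stop("filtersPerLayer must have one entry per convolution layer (6)")
  if (config@filtersPerLayer[6L] != 1L)
    stop("the final convolution must output a single heatmap channel")
  if (!identical(config@activations,
                 c("relu", "relu", "sigmoid", "sigmoid", "sigmoid", "sigmoid")))
    stop("activations must be ReLU for the first two layers and sigmoid for the last four")
  if (config@kernelSize %% 2L != 1L || config@kernelSize < 1L)
    stop("kernelSize must be a positive odd integer")
  if (config@kernelSize != 3L)
    stop("the convolution engine implements 3x3 kernels; kernelSize must be 3")
  if (config@dropoutRate < 0 || config@dropoutRate >= 1)
    stop("dropoutRate must lie in [0, 1)")
  invisible(TRUE)
}

#' Build the stage-1 heatmap-regression network
#'
#' Instantiates the network mapping an \code{h x w} single-channel tile to an
#' \code{(h/4) x (w/4)} single-channel heatmap in \eqn{[0,1]}. Layer order:
#' conv(ReLU)-BN-conv(ReLU)-BN-pool-conv(sig)-dropout-conv(sig)-pool-
#' conv(sig)-BN-conv(sig). Weights are initialized from the config seed.
#'
#' @param config a \linkS4class{Stage1Config}; configurations violating the
#'   6-convolution / 2-pool contract are an error.
#' @return An untrained \linkS4class{Stage1Model}.
#' @export
buildStage1 <- function(config = stage1Config()) {
  validateStage1Config(config)
  fl <- config@filtersPerLayer
  k <- config@kernelSize
  set.seed(config@seed)
  net <- list(
    nnLayerConv(1L, fl[1L], k, "relu"), nnLayerAct("relu"), nnLayerBn(fl[1L]),
    nnLayerConv(fl[1L], fl[2L], k, "relu"), nnLayerAct("relu"), nnLayerBn(fl[2L]),
    nnLayerPool(),
    nnLayerConv(fl[2L], fl[3L], k, "sigmoid"), nnLayerAct("sigmoid"),
    nnLayerDropout(config@dropoutRate),
    nnLayerConv(fl[3L], fl[4L], k, "sigmoid"), nnLayerAct("sigmoid"),
    nnLayerPool(),
    nnLayerConv(fl[4L], fl[5L], k, "sigmoid"), nnLayerAct("sigmoid"),
    nnLayerBn(fl[5L]),
    nnLayerConv(fl[5L], fl[6L], k, "sigmoid"), nnLayerAct("sigmoid"))
  # output bias at the logit of a small background rate, so the untrained
  # network starts near the mostly-empty Gaussian target
  net[[17L]]$b <- rep(-3, fl[6L])
  new("Stage1Model", net = net, config = config,
      history = data.frame(), trained = FALSE)
}

asPixelMatrix <- function(x) {
  if (is(x, "Micrograph")) x@pixels
  else if (is(x, "Heatmap")) x@values
  else as.matrix(x)
}

#' Train the stage-1 network
#'
#' Seeded mini-batch Adam training of the heatmap regression against
#' Gaussian-peak targets (mean squared error). Per-epoch training and
#' validation losses are recorded and the parameters with the best
#' validation loss are kept (checkpointing), so the returned model is the
#' best-validation checkpoint.
#'
#' @param model an (untrained or trained) \linkS4class{Stage1Model}.
#' @param trainPairs,valPairs lists of \code{list(image = , target = )} where
#'   \code{image} is an \code{h x w} tile (matrix or
#'   \linkS4class{Micrograph}) and \code{target} the matching
#'   \code{(h/4) x (w/4)} heatmap (matrix or \linkS4class{Heatmap} at
#'   resolution factor 4). A shape mismatch is an error raised before any
#'   training. \code{valPairs = NULL} falls back to checkpointing on the
#'   training loss.
#' @param config training configuration (defaults to the model's).
#' @return The model with \code{trained = TRUE}, best-validation parameters
#'   and a history data.frame (\code{epoch}, \code{trainLoss},
#'   \code{valLoss}, \code{bestValLoss}).
#' @export
trainStage1 <- function(model, trainPairs, valPairs = NULL,
                        config = model@config) {
  stopifnot(is(model, "Stage1Model"))
  if (!length(trainPairs)) stop("trainPairs must be non-empty")
  imgs <- lapply(trainPairs, function(p) asPixelMatrix(p$image))
  tgts <- lapply(trainPairs, function(p) asPixelMatrix(p$target))
  for (i in seq_along(imgs)) {
    di <- dim(imgs[[i]]); dt <- dim(tgts[[i]])
    if (!all(di %/% 4L == dt) || any(di %% 4L != 0L))
      stop(sprintf("pair %d: target shape %d x %d does not match tile %d x %d at 1/4 resolution",
                   i, dt[1L], dt[2L], di[1L], di[2L]))
  }
  if (is.null(valPairs) || !length(valPairs)) {
    vimgs <- imgs; vtgts <- tgts
  } else {
    vimgs <- lapply(valPairs, function(p) asPixelMatrix(p$image))
    vtgts <- lapply(valPairs, function(p) asPixelMatrix(p$target))
  }

  set.seed(config@seed)
  net <- model@net
  state <- nnAdamInit(net)
  bs <- config@batchSize
  n <- length(imgs)
  ws <- nnMakeWorkspace(net, dim(imgs[[1L]]), min(bs, n))
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), bestValLoss = numeric())
  bestVal <- Inf; bestNet <- net; t <- 0L
  for (ep in seq_len(config@epochs)) {
    perm <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = bs)) {
      idx <- perm[b0:min(b0 + bs - 1L, n)]
      X <- nnBatchArray(imgs, idx)
      Tg <- nnBatchArray(tgts, idx)
      fw <- nnForward(net, X, training = TRUE, ws = ws)
      net <- fw$net
      ls <- nnMseLoss(fw$out, Tg)
      losses <- c(losses, ls$loss)
      bw <- nnBackward(net, fw$caches, ls$grad, ws = ws)
      t <- t + 1L
      up <- nnAdamStep(net, bw$grads, state, config@learningRate, t)
      net <- up$net; state <- up$state
    }
    valLoss <- stage1Loss(net, vimgs, vtgts, bs, ws)
    if (valLoss < bestVal) { bestVal <- valLoss; bestNet <- net }
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = mean(losses),
                                   valLoss = valLoss, bestValLoss = bestVal))
  }
  model@net <- bestNet
  model@config <- config
  model@history <- hist
  model@trained <- TRUE
  model
}

stage1Loss <- function(net, imgs, tgts, bs, ws = NULL) {
  tot <- 0; cnt <- 0
  for (b0 in seq(1L, length(imgs), by = bs)) {
    idx <- b0:min(b0 + bs - 1L, length(imgs))
    fw <- nnForward(net, nnBatchArray(imgs, idx), training = FALSE, ws = ws)
    Tg <- nnBatchArray(tgts, idx)
    tot <- tot + sum((fw$out - Tg)^2)
    cnt <- cnt + length(Tg)
  }
  tot / cnt
}

#' Predict a stomatal-location heatmap
#'
#' Runs the stage-1 network on a micrograph tile whose dimensions are
#' divisible by 4 and returns the quarter-resolution heatmap.
#'
#' @param model a \linkS4class{Stage1Model}.
#' @param tile an \code{h x w} matrix or \linkS4class{Micrograph} with
#'   \code{h, w} divisible by 4; otherwise an error instructing to pad or
#'   crop.
#' @return A \linkS4class{Heatmap} with resolution factor 4 and values in
#'   \eqn{[0,1]}.
#' @export
predictHeatmap <- function(model, tile) {
  stopifnot(is(model, "Stage1Model"))
  px <- asPixelMatrix(tile)
  if (any(dim(px) %% 4L != 0L))
    stop(sprintf("tile shape %d x %d is not divisible by 4; pad or crop the tile first",
                 nrow(px), ncol(px)))
  X <- array(px, c(nrow(px), ncol(px), 1L, 1L))
  out <- nnForward(model@net, X, training = FALSE)$out
  vals <- pmin(pmax(matrix(out, nrow(px) %/% 4L, ncol(px) %/% 4L), 0), 1)
  heatmap2d(vals, resolutionFactor = 4L)
}

#' Extract candidate stomatal centers from a heatmap
#'
#' The candidate extractor: Gaussian-blur the heatmap, zero out
#' values below the threshold, locate local maxima, and apply greedy
#' non-maximum suppression at the minimum separation (strongest peak first,
#' ties broken by row-major order). Each surviving maximum becomes a
#' candidate detection; its heatmap-cell coordinate \code{i} is rescaled to
#' full resolution as \code{f*i + floor(f/2)} (cell-center convention, e.g.
#' \code{4i + 2} at factor 4) and its score is the blurred heatmap value.
#'
#' @param heatmap a \linkS4class{Heatmap} (any resolution factor).
#' @param blurSigma Gaussian blur sigma in heatmap cells (0 disables
#'   blurring; default 2).
#' @param threshold detection threshold in \eqn{(0,1)}; default 0.3, half the
#'   amplitude that a perfect unit peak of the default target width (sigma
#'   2.5 cells) retains after the default blur.
#' @param minSeparationPx minimum peak separation in heatmap cells (default
#'   8).
#' @return A \linkS4class{DetectionSet} with \code{stage = "candidate"}.
#' @export
extractCandidates <- function(heatmap, blurSigma = 2, threshold = 0.3,
                              minSeparationPx = 8) {
  stopifnot(is(heatmap, "Heatmap"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (minSeparationPx <= 0) stop("minSeparationPx must be positive")
  v <- heatmap@values
  f <- as.integer(heatmap@resolutionFactor)
  if (blurSigma > 0)
    v <- matrix(EBImage::gblur(v, sigma = blurSigma, boundary = "replicate"),
                nrow(v), ncol(v))
  v[v < threshold] <- 0
  pk <- localMaxima(v)
  srcShape <- dim(heatmap@values) * f
  prov <- list(blurSigma = blurSigma, threshold = threshold,
               minSeparationPx = minSeparationPx)
  if (nrow(pk) == 0L)
    return(detectionSet(matrix(numeric(0), 0, 2), numeric(0), "candidate",
                        srcShape, prov))
  ord <- order(-pk[, 3L], pk[, 1L], pk[, 2L])
  pk <- pk[ord, , drop = FALSE]
  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    sel <- which(keep)
    if (!length(sel) ||
        min(sqrt((pk[sel, 1L] - pk[i, 1L])^2 + (pk[sel, 2L] - pk[i, 2L])^2)) >=
          minSeparationPx)
      keep[i] <- TRUE
  }
  pk <- pk[keep, , drop = FALSE]
  off <- f %/% 2L
  detectionSet(cbind(f * pk[, 1L] + off, f * pk[, 2L] + off),
               scores = pmin(1, pk[, 3L]), stage = "candidate",
               sourceShape = srcShape, provenance = prov)
}

# Strict-positive local maxima (>= all 8 neighbours) of a matrix; returns a
# matrix with columns (row0, col0, value), 0-based coordinates.
localMaxima <- function(v) {
  h <- nrow(v); w <- ncol(v)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- v
  ok <- v > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & v >= p[2:(h + 1L) + dr, 2:(w + 1L) + dc]
  }
  ind <- which(ok, arr.ind = TRUE)
  cbind(ind[, 1L] - 1, ind[, 2L] - 1, v[ok])
}
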