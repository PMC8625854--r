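test_that("the stage-1 architecture contract is enforced", {
  expect_error(buildStage1(stage1Config(filtersPerLayer = c(8L, 8L, 16L, 16L, 1L),
                                        nConvLayers = 5L)),
               "6 convolution layers")
  expect_error(buildStage1(stage1Config(nPoolLayers = 3L)), "pooling")
  expect_error(buildStage1(stage1Config(activations = rep("relu", 6))),
               "sigmoid")
  expect_error(buildStage1(stage1Config(kernelSize = 4L)), "odd")
  m <- buildStage1(stage1Config())
  types <- vapply(m@net, function(l) l$type, character(1))
  expect_identical(sum(types == "conv"), 6L)
  expect_identical(sum(types == "pool"), 2L)
})

test_that("an untrained model maps a 256-tile to a bounded 64-heatmap", {
  m <- buildStage1(stage1Config(seed = 2L))
  set.seed(1)
  tile <- matrix(runif(256 * 256), 256, 256)
  hm <- predictHeatmap(m, tile)
  expect_identical(dim(heatmapValues(hm)), c(64L, 64L))
  expect_identical(resolutionFactor(hm), 4L)
  expect_gte(min(heatmapValues(hm)), 0)
  expect_lte(max(heatmapValues(hm)), 1)
  expect_error(predictHeatmap(m, matrix(0.5, 30, 32)), "divisible by 4")
})

test_that("a constant input yields a spatially near-constant heatmap", {
  m <- buildStage1(stage1Config(seed = 3L))
  hm <- predictHeatmap(m, matrix(0.5, 128, 128))
  v <- heatmapValues(hm)
  # interior cells (away from padding effects) are equal by equivariance
  inner <- v[8:25, 8:25]
  expect_lt(max(inner) - min(inner), 1e-10)
})

test_that("training records losses, checkpoints, and beats the zero baseline", {
  set.seed(41)
  ds <- generateDataset(10, syntheticParams(imageHeightPx = 64L,
                                            imageWidthPx = 64L,
                                            targetDensity = 250,
                                            minSeparationPx = 20,
                                            stomaLengthPx = 12,
                                            stomaWidthPx = 6,
                                            artifactRate = 0,
                                            noiseSd = 0.01, seed = 5L))
  pairs <- lapply(ds, function(s) list(
    image = pixels(s@micrograph),
    target = makeTargetHeatmap(s@truthCenters, 10, 4L)))
  cfg <- stage1Config(epochs = 5L, batchSize = 4L, seed = 8L)
  m <- trainStage1(buildStage1(cfg), pairs[1:8], pairs[9:10], cfg)
  h <- m@history
  expect_identical(nrow(h), 5L)
  expect_true(all(diff(h$bestValLoss) <= 0))            # monotone best-so-far
  expect_true(all(is.finite(h$trainLoss)))
  # the all-zeros predictor loss on the validation targets, computed
  # analytically from the targets themselves
  baseline <- mean(vapply(9:10, function(i)
    mean(heatmapValues(pairs[[i]]$target)^2), numeric(1)))
  expect_lt(min(h$valLoss), baseline)
})

test_that("shape mismatches are rejected before training", {
  pairs <- list(list(image = matrix(0.5, 64, 64), target = matrix(0, 8, 8)))
  m <- buildStage1(stage1Config(epochs = 1L))
  expect_error(trainStage1(m, pairs), "1/4 resolution")
})

test_that("candidate extraction follows the cell-center convention and suppresses", {
  # empty heatmap
  empty <- heatmap2d(matrix(0, 64, 64), 4L)
  expect_identical(nDetections(extractCandidates(empty)), 0L)

  # single Gaussian peak at cell (20, 30) -> full-res (82, 122)
  ann <- annotationSet(rbind(c(82, 122)), c(256, 256))
  hm <- makeTargetHeatmap(ann, sigmaPx = 10, resolutionFactor = 4L)
  cand <- extractCandidates(hm)
  expect_identical(nDetections(cand), 1L)
  expect_equal(unname(centers(cand)), rbind(c(82, 122)))
  expect_true(all(scores(cand) > 0 & scores(cand) <= 1))

  # two peaks closer than the minimum separation: one candidate, the larger
  v <- matrix(0, 64, 64)
  v[21, 31] <- 1; v[23, 33] <- 0.8
  both <- extractCandidates(heatmap2d(v, 4L), blurSigma = 0, threshold = 0.5,
                            minSeparationPx = 8)
  expect_identical(nDetections(both), 1L)
  expect_equal(unname(centers(both)), rbind(c(82, 122)))

  expect_error(extractCandidates(hm, threshold = 1.2), "between 0 and 1")
  expect_error(extractCandidates(hm, threshold = 0), "between 0 and 1")
})

test_that("extraction matches the brute-force suppression oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    ce <- cbind(sample(8:56, 5), sample(8:56, 5)) * 4 + 2
    hm <- makeTargetHeatmap(annotationSet(ce, c(256, 256)), 10, 4L)
    a <- extractCandidates(hm, blurSigma = 1, threshold = 0.2,
                           minSeparationPx = 6)
    b <- extractCandidates(hm, blurSigma = 1, threshold = 0.2,
                           minSeparationPx = 6)
    expect_identical(centers(a), centers(b))                 # idempotent
    # oracle on the same blurred/thresholded surface
    v <- matrix(EBImage::gblur(heatmapValues(hm), sigma = 1,
                               boundary = "replicate"), 64, 64)
    v[v < 0.2] <- 0
    oracle <- oracleExtract(v, 6)
    expect_identical(nDetections(a), nrow(oracle))
    got <- unname(centers(a))
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    want <- oracle[order(oracle[, 1], oracle[, 2]), 1:2, drop = FALSE] * 4 + 2
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})
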