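test_that("window cropping follows the centering and reflection conventions", {
  set.seed(51)
  px <- matrix(runif(100 * 100), 100, 100)
  mg <- micrograph(px)
  # center at the middle: start = round(50) - 16 = 34 -> rows/cols 34..65
  w <- cropWindow(mg, c(50, 50), 32L)
  expect_identical(dim(w$patch), c(32L, 32L))
  expect_identical(w$patch, px[35:66, 35:66])
  # corner center: upper-left quadrant is the reflection of the image corner
  w0 <- cropWindow(mg, c(0, 0), 32L)
  expect_identical(dim(w0$patch), c(32L, 32L))
  expect_identical(w0$patch[17:32, 17:32], px[1:16, 1:16])
  expect_identical(w0$patch[16, 17], px[1, 1])   # reflected row -1 -> row 0
  expect_identical(w0$patch[1:16, 17:32], px[16:1, 1:16])
  # constant image: constant window wherever centered
  cm <- micrograph(matrix(0.25, 50, 50))
  expect_true(all(cropWindow(cm, c(3, 48), 32L)$patch == 0.25))
  expect_error(cropWindow(mg, c(-1, 5)), "outside")
  expect_error(cropWindow(mg, c(5, 100)), "outside")
})

test_that("the stage-2 architecture contract is enforced", {
  expect_error(buildStage2(stage2Config(windowSize = 31L)), "even")
  expect_error(buildStage2(stage2Config(denseUnits = c(64L, 2L))), "single probability")
  m <- buildStage2(stage2Config())
  types <- vapply(m@net, function(l) l$type, character(1))
  expect_identical(sum(types == "conv"), 2L)
  expect_identical(sum(types == "dense"), 2L)
  # output is a single probability
  p <- predictWindowProb(m, matrix(runif(1024), 32, 32))
  expect_length(p, 1L)
  expect_true(p >= 0 && p <= 1)
})

test_that("training windows are labeled by the same matching as the evaluator", {
  s <- refSample()
  truth <- s@truthCenters
  ce <- centers(truth)
  # candidates: all truths plus all artifacts (as stage-1 might propose)
  candCenters <- rbind(ce, s@artifactCenters)
  cand <- detectionSet(candCenters, rep(0.9, nrow(candCenters)), "candidate",
                       c(1000L, 1000L))
  wins <- buildTrainingWindows(list(list(micrograph = s@micrograph,
                                         candidates = cand, truth = truth)),
                               32L, matchRadiusPx = 16)
  labs <- vapply(wins, `[[`, integer(1), "label")
  cc <- matchDetections(cand, truth, 16)$counts
  expect_identical(sum(labs == 1L), cc@NTP)
  expect_identical(sum(labs == 0L), cc@NFP)
  expect_identical(unname(attr(wins, "classCounts")),
                   c(cc@NTP, cc@NFP))
  # candidates exactly on truths -> all positive; on artifacts -> all negative
  expect_true(all(labs[seq_len(nrow(ce))] == 1L))
  expect_true(all(labs[-seq_len(nrow(ce))] == 0L))
})

test_that("the classifier separates trivially separable window classes", {
  set.seed(52)
  mkdisc <- function(bright) {
    base <- matrix(runif(32 * 32, 0.45, 0.55), 32, 32)
    d <- sqrt(outer((1:32 - 16.5)^2, (1:32 - 16.5)^2, "+"))
    base[d < 8] <- if (bright) 0.95 else 0.05
    base
  }
  wins <- c(lapply(1:30, function(i) list(patch = mkdisc(TRUE), center = c(0, 0),
                                          label = 1L)),
            lapply(1:30, function(i) list(patch = mkdisc(FALSE), center = c(0, 0),
                                          label = 0L)))
  cfg <- stage2Config(epochs = 10L, seed = 4L)
  m <- trainStage2(buildStage2(cfg), wins, cfg)
  expect_true(m@trained)
  expect_identical(attr(m@history, "heldOutAccuracy"), 1)
  # determinism
  m2 <- trainStage2(buildStage2(cfg), wins, cfg)
  expect_identical(m@history, m2@history)
})

test_that("degenerate window sets are rejected", {
  w1 <- list(list(patch = matrix(0.5, 32, 32), center = c(0, 0), label = 1L))
  m <- buildStage2(stage2Config(epochs = 1L))
  expect_error(trainStage2(m, list()), "non-empty")
  expect_error(trainStage2(m, w1), "degenerate")
})

test_that("confirmation only removes candidates and is monotone in the cutoff", {
  set.seed(53)
  s <- generateSample(tinyParams(seed = 14L))
  cand <- detectionSet(rbind(centers(s@truthCenters), s@artifactCenters),
                       rep(0.5, nrow(centers(s@truthCenters)) +
                             nrow(s@artifactCenters)),
                       "candidate", c(256L, 256L))
  m <- buildStage2(stage2Config(seed = 5L))     # untrained net still scores
  probs <- predictWindowProb(m, lapply(seq_len(nDetections(cand)), function(i)
    cropWindow(s@micrograph, centers(cand)[i, ], 32L)$patch))
  counts <- vapply(c(0, 0.3, 0.6, 0.9), function(cut)
    nDetections(confirmDetections(m, s@micrograph, cand, cut)), integer(1))
  expect_identical(counts[1], nDetections(cand))          # cutoff 0 keeps all
  expect_true(all(diff(counts) <= 0))                     # monotone
  conf <- confirmDetections(m, s@micrograph, cand, 0.3)
  expect_identical(detectionStage(conf), "confirmed")
  # confirmed subset of candidates as point sets
  expect_true(all(apply(centers(conf), 1, function(r)
    any(centers(cand)[, 1] == r[1] & centers(cand)[, 2] == r[2]))))
  expect_error(confirmDetections(m, s@micrograph, cand, 1), "cutoff")
  expect_error(confirmDetections(m, s@micrograph, cand, -0.1), "cutoff")
  # empty candidates stay empty
  e <- detectionSet(matrix(numeric(0), 0, 2), numeric(0), "candidate",
                    c(256L, 256L))
  expect_identical(nDetections(confirmDetections(m, s@micrograph, e, 0.5)), 0L)
})
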