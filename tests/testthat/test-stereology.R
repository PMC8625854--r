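test_that("edge rules: top/right count, bottom/left and their corners do not", {
  fr <- countingFrame(10, 20, 110, 220)
  pts <- rbind(
    inside      = c(50, 50),
    topEdge     = c(10, 100),
    rightEdge   = c(60, 220),
    topRight    = c(10, 220),
    bottomEdge  = c(110, 100),
    leftEdge    = c(60, 20),
    topLeft     = c(10, 20),
    bottomLeft  = c(110, 20),
    bottomRight = c(110, 220))
  res <- countInFrame(pts, fr)
  expect_identical(res$count, 4L)
  expect_identical(sort(rownames(pts)[res$counted]),
                   sort(c("inside", "topEdge", "rightEdge", "topRight")))
})

test_that("frames tiling the plane count every point exactly once", {
  set.seed(10)
  frames <- list()
  for (i in 0:3) for (j in 0:3)
    frames[[length(frames) + 1]] <- countingFrame(i * 25, j * 25,
                                                  (i + 1) * 25, (j + 1) * 25)
  for (rep in 1:5) {
    pts <- cbind(runif(2000, 0, 100), runif(2000, 0, 100))
    # include awkward points exactly on the grid lines
    pts <- rbind(pts, cbind(rep(seq(0, 100, 25), each = 5),
                            rep(seq(0, 100, 25), times = 5)))
    perFrame <- vapply(frames, function(f) countInFrame(pts, f)$count, integer(1))
    # snapped points strictly inside [0,100)^2 must be counted exactly once
    rs <- round(2 * pts[, 1]) / 2; cs <- round(2 * pts[, 2]) / 2
    inRegion <- rs < 100 & cs < 100 & rs >= 0 & cs >= 0
    # left column edge (c = 0) and top row edge (r = 0) of the region lie on
    # exclusionary/inclusionary borders of edge frames; count membership per point
    hits <- integer(nrow(pts))
    for (f in frames) hits <- hits + seq_len(nrow(pts)) %in% countInFrame(pts, f)$counted
    expect_true(all(hits <= 1))
    inInterior <- rs > 0 & rs < 100 & cs > 0 & cs < 100
    expect_true(all(hits[inInterior] == 1))
    expect_identical(sum(perFrame), sum(hits))
  }
})

test_that("density arithmetic is exact and splitting frames is consistent", {
  fr <- countingFrame(0, 0, 1000, 1000, umPerPx = 1)
  d <- computeDensity(35, fr, "abaxial")
  expect_identical(d@densityPerMm2, 35)
  expect_identical(computeDensity(0, fr, "adaxial")@densityPerMm2, 0)
  frHalf <- countingFrame(0, 0, 1000, 500, umPerPx = 1)
  expect_identical(computeDensity(18, frHalf, "abaxial")@densityPerMm2, 36)
  expect_error(computeDensity(-1, fr), "non-negative")
  expect_error(computeDensity(3, countingFrame(0, 0, 10, 10)), "calibration")

  # counts and areas add over an exact 2x2 tiling of the frame
  set.seed(11)
  pts <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
  whole <- countInFrame(pts, fr)$count
  subs <- 0L
  for (i in 0:1) for (j in 0:1)
    subs <- subs + countInFrame(pts, countingFrame(i * 500, j * 500,
                                                   (i + 1) * 500,
                                                   (j + 1) * 500))$count
  expect_identical(subs, whole)
})

test_that("combineSides averages densities and refuses mixed calibrations", {
  fr <- countingFrame(0, 0, 1000, 1000, umPerPx = 1)
  ab <- computeDensity(30, fr, "abaxial")
  ad <- computeDensity(40, fr, "adaxial")
  comb <- combineSides(ab, ad)
  expect_identical(comb@densityPerMm2, 35)
  expect_identical(comb@side, "combined")
  expect_identical(combineSides(ab, computeDensity(30, fr, "adaxial"))@densityPerMm2, 30)
  fr2 <- countingFrame(0, 0, 1000, 1000, umPerPx = 2)
  expect_error(combineSides(ab, computeDensity(40, fr2, "adaxial")),
               "mixed calibrations")
  expect_error(combineSides(ad, ab), "abaxial and an adaxial")
})

test_that("uniformly random frames from a tiling estimate the planted density without bias", {
  # frames drawn uniformly from an exact tiling of the field are the
  # unbiased stereological design: each stoma has equal probability of
  # being sampled, so E[count / area] equals the planted density
  ds <- generateDataset(5, syntheticParams(seed = 21L))
  set.seed(12)
  nFrames <- 50
  dens <- numeric(nFrames)
  for (k in seq_len(nFrames)) {
    s <- ds[[sample.int(5, 1)]]
    i <- sample(0:3, 1); j <- sample(0:3, 1)
    fr <- countingFrame(i * 250, j * 250, (i + 1) * 250, (j + 1) * 250,
                        umPerPx = 1)
    dens[k] <- computeDensity(countInFrame(s@truthCenters, fr)$count,
                              fr)@densityPerMm2
  }
  se <- sd(dens) / sqrt(nFrames)
  expect_lt(abs(mean(dens) - 35), 3 * se + 1e-9)
})

test_that("a frame larger than the image is rejected", {
  det <- detectionSet(rbind(c(5, 5)), 0.9, "confirmed", c(100, 100))
  expect_error(countInFrame(det, countingFrame(0, 0, 200, 100)), "beyond")
  expect_silent(countInFrame(det, countingFrame(0, 0, 100, 100)))
})
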