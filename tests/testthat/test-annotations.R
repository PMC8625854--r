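test_that("red-square and irregular-blob centroids are exact", {
  img <- array(0.4, c(40, 60, 3))
  img[11:15, 21:25, 1] <- 1; img[11:15, 21:25, 2:3] <- 0   # 5x5 at rows 10-14
  ann <- extractAnnotationCenters(img)
  expect_equal(centers(ann), matrix(c(12, 22), 1, 2,
               dimnames = list(NULL, c("row", "col"))))

  # two irregular blobs vs brute-force per-blob means
  img2 <- array(0.4, c(50, 50, 3))
  blob1 <- rbind(c(5, 5), c(5, 6), c(6, 5), c(7, 6), c(6, 6))
  blob2 <- rbind(c(30, 40), c(31, 41), c(32, 40), c(30, 41))  # diagonal touches
  pts <- rbind(blob1, blob2)
  for (k in seq_len(nrow(pts))) {
    img2[pts[k, 1] + 1, pts[k, 2] + 1, 1] <- 1
    img2[pts[k, 1] + 1, pts[k, 2] + 1, 2:3] <- 0
  }
  ann2 <- extractAnnotationCenters(img2)
  got <- centers(ann2)[order(centers(ann2)[, 1]), ]
  expect_equal(unname(got), rbind(colMeans(blob1), colMeans(blob2)))
})

test_that("no red pixels gives an empty set; non-RGB input errors", {
  img <- array(0.7, c(20, 20, 3))
  expect_identical(nrow(centers(extractAnnotationCenters(img))), 0L)
  expect_error(extractAnnotationCenters(matrix(0.5, 10, 10)), "RGB")
})

test_that("red tolerance admits near-red paint but not reddish tissue", {
  img <- array(0.5, c(20, 20, 3))
  img[5:7, 5:7, 1] <- 250 / 255; img[5:7, 5:7, 2] <- 5 / 255
  img[5:7, 5:7, 3] <- 0                                   # re-encoded paint
  img[15, 15, 1] <- 0.8; img[15, 15, 2] <- 0.3; img[15, 15, 3] <- 0.3
  ann <- extractAnnotationCenters(img, redTolerance = 10)
  expect_identical(nrow(centers(ann)), 1L)
})

test_that("target heatmap peaks are exactly 1 and combine by maximum", {
  ann <- annotationSet(rbind(c(50, 50)), c(100, 100))
  hm <- makeTargetHeatmap(ann, sigmaPx = 10)
  v <- heatmapValues(hm)
  expect_identical(v[51, 51], 1)
  expect_true(all(v >= 0 & v <= 1))
  # analytic value away from the peak
  expect_equal(v[51, 61], exp(-100 / 200), tolerance = 1e-12)

  expect_true(all(heatmapValues(makeTargetHeatmap(
    annotationSet(matrix(numeric(0), 0, 2), c(30, 30)), 10)) == 0))

  # two centers 1 px apart: max-combination keeps the peak at 1, not 2
  ann2 <- annotationSet(rbind(c(20, 20), c(20, 21)), c(64, 64))
  v2 <- heatmapValues(makeTargetHeatmap(ann2, sigmaPx = 10))
  expect_lte(max(v2), 1)
  expect_identical(v2[21, 21], 1)
  expect_identical(v2[21, 22], 1)
})

test_that("heatmap is invariant to center order and round-trips centers", {
  set.seed(3)
  ce <- cbind(sample(30:220, 6) + runif(6, -0.4, 0.4),
              sample(30:220, 6) + runif(6, -0.4, 0.4))
  a <- makeTargetHeatmap(annotationSet(ce, c(256, 256)), 10)
  b <- makeTargetHeatmap(annotationSet(ce[sample(6), ], c(256, 256)), 10)
  expect_identical(heatmapValues(a), heatmapValues(b))
  # noise-free extraction recovers every center within 1 px
  cand <- extractCandidates(a, blurSigma = 0, threshold = 0.5,
                            minSeparationPx = 8)
  expect_identical(nDetections(cand), 6L)
  mt <- matchDetections(cand, annotationSet(ce, c(256, 256)), maxDistPx = 1)
  expect_identical(mt$counts@NTP, 6L)
})

test_that("quarter-resolution targets follow the cell-center convention", {
  ann <- annotationSet(rbind(c(82, 122)), c(256, 256))
  hm <- makeTargetHeatmap(ann, sigmaPx = 10, resolutionFactor = 4L)
  expect_identical(dim(heatmapValues(hm)), c(64L, 64L))
  # source (82, 122) is cell (20, 30): 4*20+2 = 82
  expect_identical(heatmapValues(hm)[21, 31], 1)
})

test_that("tiling partitions the image and stitches back bit-exactly", {
  set.seed(4)
  m <- micrograph(matrix(round(runif(120 * 90) * 255) / 255, 120, 90))
  tiles <- tileImagePair(m, NULL, c(60, 45))
  expect_length(tiles, 4L)
  origins <- do.call(rbind, lapply(tiles, function(t) t@origin))
  expect_identical(nrow(unique(origins)), 4L)      # disjoint by construction
  expect_identical(pixels(stitchTiles(tiles)), pixels(m))

  # identity tiling
  one <- tileImagePair(m, NULL, c(120, 90))
  expect_length(one, 1L)
  expect_identical(pixels(one[[1]]@imageTile), pixels(m))

  expect_error(tileImagePair(m, NULL, c(200, 90)), "exceeds")
})

test_that("center-crop tiling drops margins symmetrically and keeps targets aligned", {
  set.seed(5)
  px <- matrix(runif(100 * 70), 100, 70)
  hm <- heatmap2d(matrix(runif(100 * 70), 100, 70), 1L)
  tiles <- tileImagePair(micrograph(px), hm, c(32, 32))
  expect_length(tiles, 3L * 2L)                    # 96 x 64 crop
  # stitched image equals the center crop
  got <- pixels(stitchTiles(tiles))
  expect_identical(got, px[3:98, 4:67])
  # target tiles align with image tiles
  t1 <- tiles[[1]]
  expect_identical(heatmapValues(t1@targetTile),
                   heatmapValues(hm)[3:34, 4:35])

  # AnnotationSet targets are translated into tile coordinates
  ann <- annotationSet(rbind(c(10, 10), c(50, 40)), c(100, 70))
  tA <- tileImagePair(micrograph(px), ann, c(32, 32))
  allCe <- do.call(rbind, lapply(tA, function(t) {
    ce <- centers(t@targetTile)
    if (nrow(ce)) cbind(ce[, 1] + t@origin[1] + 2, ce[, 2] + t@origin[2] + 3)
    else NULL
  }))
  expect_equal(unname(allCe[order(allCe[, 1]), ]),
               rbind(c(10, 10), c(50, 40)))
})

test_that("dataset split gives floor(n * fraction) and is seed-reproducible", {
  pairs <- as.list(seq_len(10))
  sp <- splitDataset(pairs, 0.9, seed = 1)
  expect_length(sp$train, 9L); expect_length(sp$test, 1L)
  expect_length(intersect(unlist(sp$train), unlist(sp$test)), 0L)

  sp2 <- splitDataset(as.list(seq_len(1552)), 0.9, seed = 42)
  expect_length(sp2$train, 1396L)
  expect_length(sp2$test, 156L)

  a <- splitDataset(pairs, 0.7, seed = 99)
  b <- splitDataset(pairs, 0.7, seed = 99)
  expect_identical(unlist(a$train), unlist(b$train))

  expect_error(splitDataset(pairs, 1.0), "strictly between")
  expect_error(splitDataset(pairs, 0), "strictly between")
  expect_error(splitDataset(list(), 0.5), "non-empty")
})
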