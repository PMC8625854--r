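test_that("exact predictions give perfect counts; empty predictions give NFN", {
  truth <- annotationSet(rbind(c(10, 10), c(40, 40), c(70, 20)), c(100, 100))
  mt <- matchDetections(centers(truth), truth, maxDistPx = 4)
  expect_identical(mt$counts@NTP, 3L)
  expect_identical(mt$counts@NFP, 0L)
  expect_identical(mt$counts@NFN, 0L)

  mt0 <- matchDetections(matrix(numeric(0), 0, 2), truth, maxDistPx = 4)
  expect_identical(mt0$counts@NTP, 0L)
  expect_identical(mt0$counts@NFP, 0L)
  expect_identical(mt0$counts@NFN, 3L)
  expect_error(matchDetections(centers(truth), truth, maxDistPx = 0), "positive")
})

test_that("counts are conserved and invariant to prediction order", {
  set.seed(20)
  for (rep in 1:25) {
    m <- sample(0:8, 1); n <- sample(0:8, 1)
    P <- cbind(runif(m, 0, 50), runif(m, 0, 50))
    Tr <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    mt <- matchDetections(P, Tr, maxDistPx = 10)
    expect_identical(mt$counts@NTP + mt$counts@NFP, m)
    expect_identical(mt$counts@NTP + mt$counts@NFN, n)
    if (m > 1) {
      perm <- sample(m)
      mt2 <- matchDetections(P[perm, , drop = FALSE], Tr, maxDistPx = 10)
      expect_identical(mt2$counts@NTP, mt$counts@NTP)
    }
  }
})

test_that("matching equals the exhaustive optimal-assignment oracle", {
  set.seed(21)
  for (rep in 1:60) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    P <- cbind(runif(m, 0, 30), runif(m, 0, 30))
    Tr <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    radius <- runif(1, 5, 20)
    mt <- matchDetections(P, Tr, maxDistPx = radius)
    oracle <- stomaCount:::matchOracle(P, Tr, radius)
    expect_identical(mt$counts@NTP, oracle$NTP)
  }
})

test_that("greedy matching can undercount where the optimum needs foresight", {
  # prediction B is closest to truth 1 but is the only admissible partner of
  # nothing: greedy pairs (B, t1) and strands A; the optimum matches both
  P <- rbind(A = c(0, 0), B = c(0, 3))
  Tr <- rbind(t1 = c(0, 4), t2 = c(0, 7))
  greedy <- matchDetections(P, Tr, maxDistPx = 4.5, method = "greedy")
  maxm <- matchDetections(P, Tr, maxDistPx = 4.5, method = "max")
  expect_identical(greedy$counts@NTP, 1L)
  expect_identical(maxm$counts@NTP, 2L)
  expect_identical(stomaCount:::matchOracle(P, Tr, 4.5)$NTP, 2L)
})

test_that("precision and recall reproduce the published worked example", {
  cc <- confusionCounts(NTP = 1332L, NFP = 25L, NFN = 55L)
  expect_equal(precision(cc), 1332 / 1357, tolerance = 1e-12)
  expect_equal(recall(cc), 1332 / 1387, tolerance = 1e-12)
  expect_identical(formatPercent(precision(cc), 1), "98.1%")
  expect_identical(formatPercent(recall(cc), 0), "96%")
})

test_that("metric boundary values and undefined denominators behave", {
  expect_identical(precision(confusionCounts(5L, 0L, 3L)), 1)
  expect_identical(precision(confusionCounts(0L, 4L, 0L)), 0)
  expect_identical(recall(confusionCounts(5L, 2L, 0L)), 1)
  expect_identical(recall(confusionCounts(0L, 0L, 4L)), 0)
  expect_error(precision(confusionCounts(0L, 0L, 3L)), "undefined")
  expect_error(recall(confusionCounts(0L, 3L, 0L)), "undefined")
})

test_that("accuracy needs NTN, matches direct enumeration, and exposes the audit formula", {
  expect_identical(accuracy(confusionCounts(5L, 0L, 0L, NTN = 5L)), 1)
  expect_identical(accuracy(confusionCounts(3L, 3L, 3L, NTN = 3L)), 0.5)
  expect_error(accuracy(confusionCounts(5L, 1L, 1L)), "precision and recall")

  # agreement with direct enumeration on a labeled window benchmark
  set.seed(22)
  labels <- rbinom(200, 1, 0.5)
  predicted <- ifelse(runif(200) < 0.9, labels, 1 - labels)
  cc <- confusionCounts(NTP = sum(predicted == 1 & labels == 1),
                        NFP = sum(predicted == 1 & labels == 0),
                        NFN = sum(predicted == 0 & labels == 1),
                        NTN = sum(predicted == 0 & labels == 0))
  expect_identical(accuracy(cc), mean(predicted == labels))

  # the printed-formula variant swaps NTN for NFN in the numerator
  cc2 <- confusionCounts(NTP = 10L, NFP = 2L, NFN = 4L, NTN = 8L)
  expect_identical(accuracy(cc2, printedFormula = TRUE), 14 / 24)
})
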