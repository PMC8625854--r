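# Analytic gradients of every layer type are checked against central finite
# differences through a small conv/bn/pool stack and a conv/dense stack.

numGrad <- function(net, lossFn, i, p, k, eps = 1e-6) {
  n2 <- net; n2[[i]][[p]][k] <- n2[[i]][[p]][k] + eps; lp <- lossFn(n2)
  n2[[i]][[p]][k] <- n2[[i]][[p]][k] - 2 * eps; lm <- lossFn(n2)
  (lp - lm) / (2 * eps)
}

checkNetGrads <- function(net, X, lossAt, tol = 1e-5) {
  set.seed(99)
  fw <- nnForward(net, X, training = TRUE)
  ls <- lossAt(fw$out)
  bw <- nnBackward(net, fw$caches, ls$grad)
  lossFn <- function(n) { set.seed(99); lossAt(nnForward(n, X, training = TRUE)$out)$loss }
  worst <- 0
  for (i in seq_along(net)) {
    g <- bw$grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      for (k in sample(length(net[[i]][[p]]), min(5, length(net[[i]][[p]])))) {
        num <- numGrad(net, lossFn, i, p, k)
        an <- g[[p]][k]
        worst <- max(worst, abs(num - an) / max(1e-6, abs(num) + abs(an)))
      }
    }
  }
  worst
}

test_that("conv/bn/pool gradients match finite differences", {
  set.seed(31)
  net <- list(nnLayerConv(1L, 3L, 3L, "relu"), nnLayerAct("relu"),
              nnLayerBn(3L), nnLayerConv(3L, 2L, 3L, "sigmoid"),
              nnLayerAct("sigmoid"), nnLayerPool(),
              nnLayerConv(2L, 1L, 3L, "sigmoid"), nnLayerAct("sigmoid"))
  X <- array(runif(10 * 8 * 2), c(10L, 8L, 2L, 1L))
  Tg <- array(runif(5 * 4 * 2), c(5L, 4L, 2L, 1L))
  worst <- checkNetGrads(net, X, function(out) nnMseLoss(out, Tg))
  expect_lt(worst, 1e-5)
})

test_that("dense/flatten/dropout gradients match finite differences (BCE)", {
  set.seed(32)
  net <- list(nnLayerConv(1L, 2L, 3L, "relu"), nnLayerAct("relu"),
              nnLayerBn(2L), nnLayerDropout(0.3), nnLayerFlatten(),
              nnLayerDense(8L * 8L * 2L, 5L), nnLayerAct("sigmoid"),
              nnLayerDense(5L, 1L), nnLayerAct("sigmoid"))
  X <- array(runif(8 * 8 * 4), c(8L, 8L, 4L, 1L))
  y <- c(1, 0, 1, 0)
  worst <- checkNetGrads(net, X, function(out) nnBceLoss(out, y))
  expect_lt(worst, 1e-5)
})

test_that("the compiled patch matrix agrees with direct convolution", {
  set.seed(33)
  X <- array(rnorm(7 * 6 * 2 * 3), c(7L, 6L, 2L, 3L))
  W <- array(rnorm(3 * 3 * 3 * 2), c(3L, 3L, 3L, 2L))  # k x k x Cin x Cout
  # direct same-padding convolution (correlation) oracle
  direct <- array(0, c(7L, 6L, 2L, 2L))
  for (o in 1:2) for (b in 1:2) for (r in 1:7) for (c in 1:6) {
    acc <- 0
    for (dr in -1:1) for (dc in -1:1) for (ci in 1:3) {
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= 7 && cc >= 1 && cc <= 6)
        acc <- acc + X[rr, cc, b, ci] * W[dr + 2, dc + 2, ci, o]
    }
    direct[r, c, b, o] <- acc
  }
  # weight matrix rows: offset block-major (dc outer, dr inner), channel within
  Wm <- matrix(0, 27, 2)
  rowIdx <- 1L
  for (dc in 1:3) for (dr in 1:3) for (ci in 1:3) {
    Wm[rowIdx, ] <- W[dr, dc, ci, ]
    rowIdx <- rowIdx + 1L
  }
  M <- stomaCount:::im2col_nhwc(X, 7L, 6L, 2L, 3L, 3L)
  got <- array(M %*% Wm, c(7L, 6L, 2L, 2L))
  expect_equal(got, direct, tolerance = 1e-12)
})

test_that("Adam training is deterministic under a fixed seed", {
  set.seed(34)
  mkdata <- function() {
    imgs <- lapply(1:8, function(i) matrix(runif(16 * 16), 16, 16))
    tgts <- lapply(1:8, function(i) matrix(runif(4 * 4) * 0.1, 4, 4))
    list(imgs = imgs, tgts = tgts)
  }
  d <- mkdata()
  pairs <- lapply(1:8, function(i) list(image = d$imgs[[i]], target = d$tgts[[i]]))
  cfg <- stage1Config(epochs = 2L, batchSize = 4L, seed = 11L)
  m1 <- trainStage1(buildStage1(cfg), pairs, pairs[1:2], cfg)
  m2 <- trainStage1(buildStage1(cfg), pairs, pairs[1:2], cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@net, m2@net)
})
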