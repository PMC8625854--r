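# Minimal CNN engine used by both detector stages.
#
# Activations are 4-D arrays laid out (H, W, B, C); after a flatten layer
# they become (B x features) matrices. Convolutions are computed as im2col
# patch matrices multiplied through BLAS. All randomness (initialization,
# shuffling, dropout) goes through R's RNG, so a set.seed() at the training
# entry point makes runs bit-reproducible.

nnLayerConv <- function(cin, cout, k = 3L, act = c("relu", "sigmoid")) {
  act <- match.arg(act)
  fanIn <- k * k * cin
  sd <- if (act == "relu") sqrt(2 / fanIn) else sqrt(2 / (fanIn + cout))
  list(type = "conv", k = as.integer(k), cin = cin, cout = cout,
       W = matrix(stats::rnorm(fanIn * cout, sd = sd), fanIn, cout),
       b = numeric(cout))
}

nnLayerAct <- function(kind) list(type = kind)  # "relu" or "sigmoid"

nnLayerBn <- function(c, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c), momentum = momentum, eps = eps)
}

nnLayerPool <- function() list(type = "pool")

nnLayerDropout <- function(rate) list(type = "dropout", rate = rate)

nnLayerFlatten <- function() list(type = "flatten")

nnLayerDense <- function(fin, fout) {
  sd <- sqrt(2 / (fin + fout))
  list(type = "dense",
       W = matrix(stats::rnorm(fin * fout, sd = sd), fin, fout),
       b = numeric(fout))
}

eachCol <- function(m, v) m + rep(v, each = nrow(m))

# Preallocated per-conv-layer im2col workspaces, so the big patch matrices
# are allocated once per training run instead of once per batch. The same
# buffer doubles as the backward-pass dM scratch (dW is taken from it first).
nnMakeWorkspace <- function(net, inputShape, batchSize) {
  h <- inputShape[1L]; w <- inputShape[2L]
  ws <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ly$type == "conv") {
      ws[[i]] <- list(M = matrix(0, h * w * batchSize, ly$k^2 * ly$cin))
    } else if (ly$type == "pool") {
      h <- h %/% 2L; w <- w %/% 2L
    } else if (ly$type == "flatten") break
  }
  ws
}

# ---- forward ----

nnForward <- function(net, X, training = FALSE, ws = NULL) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ly$type == "conv") {
      d <- dim(X)
      n <- d[1L] * d[2L] * d[3L]
      wsl <- if (!is.null(ws)) ws[[i]] else NULL
      if (!is.null(wsl) && nrow(wsl$M) == n) {
        im2col_into(X, wsl$M, d[1L], d[2L], d[3L], d[4L], ly$k)
        M <- wsl$M
      } else {
        M <- im2col_nhwc(X, d[1L], d[2L], d[3L], d[4L], ly$k)
      }
      Y <- M %*% ly$W
      dim(Y) <- c(d[1L], d[2L], d[3L], ly$cout)
      add_bias_cols(Y, ly$b)
      caches[[i]] <- list(M = M, dims = d)
      X <- Y
    } else if (ly$type == "relu") {
      X <- relu_fwd(X)
      caches[[i]] <- X
    } else if (ly$type == "sigmoid") {
      X <- sigmoid_fwd(X)
      caches[[i]] <- X
    } else if (ly$type == "bn") {
      d <- dim(X); C <- d[length(d)]
      res <- bn_fwd(X, C, ly$gamma, ly$beta, ly$rm, ly$rv,
                    useGiven = !training, eps = ly$eps)
      if (training) {
        net[[i]]$rm <- ly$momentum * ly$rm + (1 - ly$momentum) * res$mu
        net[[i]]$rv <- ly$momentum * ly$rv + (1 - ly$momentum) * res$var
      }
      caches[[i]] <- list(xhat = res$xhat, var = res$var, dims = d)
      X <- res$y
    } else if (ly$type == "pool") {
      d <- dim(X)
      res <- pool_fwd(X, d[1L], d[2L], d[3L], d[4L])
      caches[[i]] <- list(arg = res$arg, dims = d)
      X <- res$y
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- array(as.numeric(stats::runif(length(X)) >= ly$rate), dim(X)) /
          (1 - ly$rate)
        caches[[i]] <- mask
        X <- X * mask
      } else caches[[i]] <- NULL
    } else if (ly$type == "flatten") {
      d <- dim(X)
      caches[[i]] <- d
      X <- t(matrix(aperm(X, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L]))
    } else if (ly$type == "dense") {
      caches[[i]] <- X
      X <- eachCol(X %*% ly$W, ly$b)
    } else stop("unknown layer type: ", ly$type)
  }
  list(out = X, caches = caches, net = net)
}

# ---- backward ----

nnBackward <- function(net, caches, dOut, ws = NULL) {
  grads <- vector("list", length(net))
  dX <- dOut
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    if (ly$type == "conv") {
      ca <- caches[[i]]
      d <- ca$dims
      n <- d[1L] * d[2L] * d[3L]
      dim(dX) <- c(n, ly$cout)
      grads[[i]] <- list(W = crossprod(ca$M, dX), b = colSums(dX))
      if (i == 1L) { dX <- NULL; next }   # input gradient never used
      wsl <- if (!is.null(ws)) ws[[i]] else NULL
      if (!is.null(wsl) && nrow(wsl$M) == n) {
        gemm_nt_into(dX, ly$W, wsl$M)     # reuse M: dW already extracted
        dM <- wsl$M
      } else {
        dM <- dX %*% t(ly$W)
      }
      dX <- col2im_nhwc(dM, d[1L], d[2L], d[3L], d[4L], ly$k)
    } else if (ly$type == "relu") {
      relu_bwd_ip(dX, caches[[i]])
    } else if (ly$type == "sigmoid") {
      sigmoid_bwd_ip(dX, caches[[i]])
    } else if (ly$type == "bn") {
      ca <- caches[[i]]
      C <- ca$dims[length(ca$dims)]
      res <- bn_bwd(dX, ca$xhat, C, ly$gamma, ca$var, ly$eps)
      grads[[i]] <- list(gamma = res$gamma, beta = res$beta)
      dX <- res$dX
    } else if (ly$type == "pool") {
      ca <- caches[[i]]
      d <- ca$dims
      dX <- pool_bwd(dX, ca$arg, d[1L], d[2L], d[3L], d[4L])
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) dX <- dX * caches[[i]]
    } else if (ly$type == "flatten") {
      d <- caches[[i]]
      dX <- aperm(array(t(dX), c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
    } else if (ly$type == "dense") {
      Xin <- caches[[i]]
      grads[[i]] <- list(W = crossprod(Xin, dX), b = colSums(dX))
      dX <- dX %*% t(ly$W)
    }
  }
  list(grads = grads, dX = dX)
}

# ---- losses ----

nnMseLoss <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d * d), grad = 2 * d / length(d))
}

nnBceLoss <- function(pred, y, w = NULL) {
  p <- pmin(1 - 1e-7, pmax(1e-7, pred))
  if (is.null(w)) w <- rep(1, length(y))
  sw <- sum(w)
  grad <- w * (-(y / p) + (1 - y) / (1 - p)) / sw
  if (!is.null(dim(pred))) dim(grad) <- dim(pred)
  list(loss = -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sw, grad = grad)
}

# ---- Adam ----

nnAdamInit <- function(net) {
  lapply(net, function(ly) {
    nm <- intersect(names(ly), c("W", "b", "gamma", "beta"))
    if (!length(nm)) return(NULL)
    st <- lapply(nm, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    names(st) <- nm
    st
  })
}

nnAdamStep <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (i in seq_along(net)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      net[[i]][[p]] <- net[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# Collect inputs (list of H x W matrices) into an (H, W, B, 1) batch array.
nnBatchArray <- function(mats, idx) {
  h <- nrow(mats[[idx[1L]]]); w <- ncol(mats[[idx[1L]]])
  X <- array(0, c(h, w, length(idx), 1L))
  for (j in seq_along(idx)) X[, , j, 1L] <- mats[[idx[j]]]
  X
}
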