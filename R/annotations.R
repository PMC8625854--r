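#' Extract stomatal centers from a red-painted annotation image
#'
#' Pixels within \code{redTolerance} per channel of pure red \code{#FF0000}
#' form a binary mask; its 8-connected components are reduced to their pixel
#' centroids, one center per painted complex. An image without red pixels
#' yields an empty center set (not an error).
#'
#' @param annotationImage an H x W x 3 array with channels in \eqn{[0,1]}
#'   (as returned by \code{\link{readAnnotationImage}} or carried by a
#'   \linkS4class{SyntheticSample}).
#' @param redTolerance per-channel tolerance on the 0--255 scale (default 10,
#'   wide enough to survive re-encoding of hand-painted labels while
#'   excluding reddish tissue).
#' @return An \linkS4class{AnnotationSet} of 0-based centroid coordinates.
#' @examples
#' img <- array(0.5, c(30, 30, 3))
#' img[11:15, 21:25, 1] <- 1; img[11:15, 21:25, 2:3] <- 0
#' centers(extractAnnotationCenters(img))  # centroid (12, 22)
#' @export
extractAnnotationCenters <- function(annotationImage, redTolerance = 10) {
  d <- dim(annotationImage)
  if (length(d) != 3L || d[3L] != 3L)
    stop("annotationImage must be an RGB (H x W x 3) array")
  tol <- redTolerance / 255 + 1e-9
  mask <- annotationImage[, , 1L] >= 1 - tol &
          annotationImage[, , 2L] <= tol &
          annotationImage[, , 3L] <= tol
  sh <- d[1:2]
  if (!any(mask)) return(annotationSet(matrix(numeric(0), 0, 2), sh))
  lab <- labelComponents8(mask)
  ind <- which(mask, arr.ind = TRUE)
  lb <- lab[mask]
  cr <- rowsum(ind[, 1L] - 1, lb) / as.vector(table(lb))
  cc <- rowsum(ind[, 2L] - 1, lb) / as.vector(table(lb))
  annotationSet(cbind(as.vector(cr), as.vector(cc)), sh)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a union-find pass.
labelComponents8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]       # \ diagonal neighbours
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]       # / diagonal neighbours
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Build a Gaussian-peak target heatmap from center annotations
#'
#' Replaces each annotated center by a two-dimensional Gaussian peak:
#' \deqn{v(p) = \max_c \exp(-\|p - c\|^2 / (2\sigma^2)),}
#' combined across centers by the per-pixel \emph{maximum} so the target
#' stays in \eqn{[0,1]} even when peaks overlap. The heatmap cell nearest
#' each center is set to exactly 1. Targets can be generated directly at a
#' reduced resolution (\code{resolutionFactor} source pixels per cell, sigma
#' scaled accordingly), matching the stage-1 output grid without resampling.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param sigmaPx Gaussian standard deviation in full-resolution pixels
#'   (default 10, about half a guard-cell-complex width at the synthetic
#'   scale).
#' @param resolutionFactor source pixels per heatmap cell (1 for
#'   full-resolution targets, 4 for stage-1 training targets).
#' @return A \linkS4class{Heatmap} whose shape is the source shape divided by
#'   \code{resolutionFactor} (floor).
#' @examples
#' ann <- annotationSet(rbind(c(50, 50)), c(100, 100))
#' hm <- makeTargetHeatmap(ann, sigmaPx = 10)
#' heatmapValues(hm)[51, 51]  # exactly 1 at the center
#' @export
makeTargetHeatmap <- function(ann, sigmaPx = 10, resolutionFactor = 1L) {
  stopifnot(is(ann, "AnnotationSet"))
  if (sigmaPx <= 0) stop("sigmaPx must be > 0")
  f <- as.integer(resolutionFactor)
  sh <- ann@sourceShape
  hh <- sh[1L] %/% f; ww <- sh[2L] %/% f
  vals <- matrix(0, hh, ww)
  ce <- ann@centers
  if (nrow(ce) > 0L) {
    off <- f %/% 2L                      # cell i represents source f*i + off
    sc <- sigmaPx / f
    reach <- ceiling(4 * sc)
    for (k in seq_len(nrow(ce))) {
      cr <- (ce[k, 1L] - off) / f        # center in cell coordinates
      cc <- (ce[k, 2L] - off) / f
      r0 <- max(0L, floor(cr - reach)); r1 <- min(hh - 1L, ceiling(cr + reach))
      c0 <- max(0L, floor(cc - reach)); c1 <- min(ww - 1L, ceiling(cc + reach))
      if (r0 > r1 || c0 > c1) next
      g <- exp(-(outer((r0:r1 - cr)^2, (c0:c1 - cc)^2, "+")) / (2 * sc^2))
      sub <- vals[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE]
      vals[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L)] <- pmax(sub, g)
      pr <- round(cr); pc <- round(cc)   # peak cell clamped to exactly 1
      if (pr >= 0 && pr < hh && pc >= 0 && pc < ww)
        vals[pr + 1L, pc + 1L] <- 1
    }
  }
  heatmap2d(vals, resolutionFactor = f)
}

#' Cut a micrograph / target pair into disjoint training tiles
#'
#' Tiles the image (and its target) into a row-major grid of disjoint
#' \code{tileShape} tiles that exactly partition the source. Images whose
#' dimensions are not tile multiples are first center-cropped to the largest
#' multiple; tile origins are relative to the cropped source, so stitching
#' the tiles (\code{\link{stitchTiles}}) reconstructs it bit-exactly.
#'
#' @param image a \linkS4class{Micrograph}.
#' @param target the matching full-resolution \linkS4class{Heatmap}
#'   (resolution factor 1), an \linkS4class{AnnotationSet}, or \code{NULL}
#'   for prediction-time tiling.
#' @param tileShape integer \code{c(h, w)}; must not exceed the image.
#' @return A row-major list of \linkS4class{TilePair}.
#' @examples
#' m <- micrograph(matrix(runif(120 * 90), 120, 90))
#' tiles <- tileImagePair(m, NULL, c(60, 45))  # 2 x 2 grid
#' @export
tileImagePair <- function(image, target = NULL, tileShape) {
  stopifnot(is(image, "Micrograph"))
  th <- as.integer(tileShape[1L]); tw <- as.integer(tileShape[2L])
  px <- image@pixels
  h <- nrow(px); w <- ncol(px)
  if (th > h || tw > w)
    stop(sprintf("tile shape %d x %d exceeds image %d x %d", th, tw, h, w))
  if (th < 1L || tw < 1L) stop("tile shape must be positive")
  nr <- h %/% th; nc <- w %/% tw
  r0 <- (h - nr * th) %/% 2L             # center-crop offset (0-based)
  c0 <- (w - nc * tw) %/% 2L
  hv <- NULL
  if (is(target, "Heatmap")) {
    if (target@resolutionFactor != 1L)
      stop("tiling expects a full-resolution (factor 1) target heatmap")
    if (!all(dim(target@values) == c(h, w)))
      stop("target heatmap shape must match the image")
    hv <- target@values
  } else if (!is.null(target) && !is(target, "AnnotationSet")) {
    stop("target must be a Heatmap, an AnnotationSet, or NULL")
  }
  out <- vector("list", nr * nc)
  idx <- 1L
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nc) - 1L) {
      rows <- (r0 + i * th + 1L):(r0 + (i + 1L) * th)
      cols <- (c0 + j * tw + 1L):(c0 + (j + 1L) * tw)
      tileImg <- micrograph(px[rows, cols, drop = FALSE],
                            umPerPx = image@umPerPx)
      tgt <- NULL
      if (!is.null(hv)) {
        tgt <- heatmap2d(hv[rows, cols, drop = FALSE], 1L)
      } else if (is(target, "AnnotationSet")) {
        ce <- target@centers
        sel <- ce[, 1L] >= r0 + i * th & ce[, 1L] < r0 + (i + 1L) * th &
               ce[, 2L] >= c0 + j * tw & ce[, 2L] < c0 + (j + 1L) * tw
        loc <- ce[sel, , drop = FALSE]
        loc[, 1L] <- loc[, 1L] - (r0 + i * th)
        loc[, 2L] <- loc[, 2L] - (c0 + j * tw)
        tgt <- annotationSet(loc, c(th, tw))
      }
      out[[idx]] <- new("TilePair", imageTile = tileImg, targetTile = tgt,
                        origin = c(i * th, j * tw), tileShape = c(th, tw))
      idx <- idx + 1L
    }
  }
  out
}

#' Stitch tiles back into the (cropped) source image
#'
#' @param pairs list of \linkS4class{TilePair} produced by
#'   \code{\link{tileImagePair}}.
#' @return A \linkS4class{Micrograph} equal, pixel for pixel, to the
#'   center-cropped source the tiles were cut from.
#' @export
stitchTiles <- function(pairs) {
  stopifnot(length(pairs) > 0L)
  orig <- do.call(rbind, lapply(pairs, function(p) p@origin))
  shp <- pairs[[1L]]@tileShape
  h <- max(orig[, 1L]) + shp[1L]; w <- max(orig[, 2L]) + shp[2L]
  out <- matrix(NA_real_, h, w)
  for (p in pairs) {
    out[(p@origin[1L] + 1L):(p@origin[1L] + p@tileShape[1L]),
        (p@origin[2L] + 1L):(p@origin[2L] + p@tileShape[2L])] <-
      p@imageTile@pixels
  }
  micrograph(out, umPerPx = pairs[[1L]]@imageTile@umPerPx)
}

#' Split tile pairs into training and test sets
#'
#' Seeded permutation split: \code{floor(n * trainFraction)} items go to
#' training and the remainder to test; no item appears in both. (1552 pairs
#' at fraction 0.9 give the canonical 1396 / 156 partition.)
#'
#' @param pairs non-empty list (typically of \linkS4class{TilePair}).
#' @param trainFraction fraction in the open interval (0, 1).
#' @param seed integer seed making the partition reproducible.
#' @return \code{list(train = ..., test = ...)}.
#' @export
splitDataset <- function(pairs, trainFraction = 0.9, seed = 1L) {
  n <- length(pairs)
  if (n < 1L) stop("pairs must be a non-empty list")
  if (!is.numeric(trainFraction) || trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nTrain <- floor(n * trainFraction)
  list(train = pairs[perm[seq_len(nTrain)]],
       test = pairs[perm[setdiff(seq_len(n), seq_len(nTrain))]])
}
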