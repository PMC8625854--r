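#' Synthetic micrograph generator parameters
#'
#' Builds the parameter set for the seeded synthetic epidermal-micrograph
#' benchmark. The defaults define the package's reference study conditions:
#' a 1000 x 1000 px field at 1 um/px (exactly 1 mm^2, so density arithmetic
#' is transparent), 35 stomata mm^-2 (the magnitude measured on barley
#' epidermis), dumbbell-shaped stomatal complexes about 24 x 12 px, ten
#' distractor artifacts (bright bubble rings and dark thorn-cell spikes) per
#' mm^2, and mild additive noise.
#'
#' @param imageHeightPx,imageWidthPx image size in pixels.
#' @param umPerPx micrometres per pixel.
#' @param targetDensity planted stomatal density (stomata mm^-2).
#' @param minSeparationPx minimum distance between planted stomatal centers.
#' @param stomaLengthPx,stomaWidthPx stomatal-complex length and width in px
#'   (length >= width).
#' @param artifactRate distractor artifacts per mm^2.
#' @param noiseSd standard deviation of additive Gaussian intensity noise
#'   (intensity units, image range is \eqn{[0,1]}).
#' @param seed integer seed; the whole sample is a deterministic function of
#'   the parameter set.
#' @return A validated \linkS4class{SyntheticParams}.
#' @examples
#' p <- syntheticParams(imageHeightPx = 256, imageWidthPx = 256, seed = 7)
#' s <- generateSample(p)
#' @export
syntheticParams <- function(imageHeightPx = 1000L, imageWidthPx = 1000L,
                            umPerPx = 1.0, targetDensity = 35,
                            minSeparationPx = 48, stomaLengthPx = 24,
                            stomaWidthPx = 12, artifactRate = 10,
                            noiseSd = 0.03, seed = 1L) {
  new("SyntheticParams",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      umPerPx = as.numeric(umPerPx),
      targetDensity = as.numeric(targetDensity),
      minSeparationPx = as.numeric(minSeparationPx),
      stomaLengthPx = as.numeric(stomaLengthPx),
      stomaWidthPx = as.numeric(stomaWidthPx),
      artifactRate = as.numeric(artifactRate),
      noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# Area of the image in mm^2 under the given calibration.
frameAreaMm2 <- function(hPx, wPx, umPerPx) hPx * wPx * umPerPx^2 / 1e6

# Hexagonal-packing bound on the number of points with pairwise distance
# >= d that fit in an area A: at most 2/sqrt(3) * A / d^2.
packingBound <- function(areaPx2, dPx) floor(2 / sqrt(3) * areaPx2 / dPx^2)

# Rejection-sample n points in [lo1, hi1] x [lo2, hi2] (integer positions)
# with pairwise distance >= minSep and distance >= minSep from `avoid`.
# Hard cap of 10000 attempts per point.
samplePoints <- function(n, lo, hi, minSep, avoid = NULL, what = "point") {
  pts <- matrix(numeric(0), 0, 2)
  if (n == 0L) return(pts)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(10000L)) {
      cand <- c(sample(lo[1L]:hi[1L], 1L), sample(lo[2L]:hi[2L], 1L))
      ok <- TRUE
      if (nrow(pts) > 0L &&
          min(sqrt((pts[, 1L] - cand[1L])^2 + (pts[, 2L] - cand[2L])^2)) < minSep)
        ok <- FALSE
      if (ok && !is.null(avoid) && nrow(avoid) > 0L &&
          min(sqrt((avoid[, 1L] - cand[1L])^2 + (avoid[, 2L] - cand[2L])^2)) < minSep)
        ok <- FALSE
      if (ok) { pts <- rbind(pts, cand); placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("rejection sampling failed after 10000 attempts while placing %s %d of %d",
                   what, k, n))
  }
  unname(pts)
}

# Smooth low-frequency field: coarse white noise bilinearly upsampled.
lowFreqField <- function(h, w, spacing = 64) {
  ch <- max(2L, ceiling(h / spacing) + 1L)
  cw <- max(2L, ceiling(w / spacing) + 1L)
  coarse <- matrix(stats::rnorm(ch * cw), ch, cw)
  up <- EBImage::resize(coarse, w = h, h = w)  # EBImage dim1 = our rows
  matrix(up, h, w)
}

# Render one dumbbell-shaped stomatal complex into `img` (modified in the
# caller via returned patch). Returns list(img, mask) where mask marks the
# complex footprint used for red annotation painting.
renderStoma <- function(img, mask, r, c, lenPx, widPx, theta, depth = 0.35) {
  h <- nrow(img); w <- ncol(img)
  a <- lenPx / 2                  # semi-axis along the leaf axis
  bw <- widPx / 4                 # lobe semi-axis across the axis
  off <- widPx / 4 + 1            # lobe center offset from the pore line
  s <- ceiling(a + widPx / 2 + 3)
  rr <- max(0L, floor(r - s)):min(h - 1L, ceiling(r + s))
  cc <- max(0L, floor(c - s)):min(w - 1L, ceiling(c + s))
  dr <- outer(rr - r, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c)
  u <- dc * cos(theta) + dr * sin(theta)   # along the long axis
  v <- -dc * sin(theta) + dr * cos(theta)  # across the long axis
  q1 <- (u / a)^2 + ((v - off) / bw)^2
  q2 <- (u / a)^2 + ((v + off) / bw)^2
  patch <- img[rr + 1L, cc + 1L, drop = FALSE]
  patch <- patch - depth * pmax(0, 1 - pmin(q1, q2))      # dark guard-cell pair
  pore <- abs(v) <= 1 & abs(u) <= 0.7 * a                 # 2-px bright pore line
  patch[pore] <- patch[pore] + 0.2
  img[rr + 1L, cc + 1L] <- patch
  foot <- (u / (a + 1))^2 + (v / (widPx / 2 + 1))^2 <= 1  # whole-complex footprint
  mk <- mask[rr + 1L, cc + 1L, drop = FALSE]
  mask[rr + 1L, cc + 1L] <- mk | foot
  list(img = img, mask = mask)
}

renderBubble <- function(img, r, c, radius, height = 0.18) {
  h <- nrow(img); w <- ncol(img)
  s <- ceiling(radius + 3)
  rr <- max(0L, floor(r - s)):min(h - 1L, ceiling(r + s))
  cc <- max(0L, floor(c - s)):min(w - 1L, ceiling(c + s))
  d <- sqrt(outer((rr - r)^2, rep(1, length(cc))) +
            outer(rep(1, length(rr)), (cc - c)^2))
  ring <- abs(d - radius) <= 1.5
  patch <- img[rr + 1L, cc + 1L, drop = FALSE]
  patch[ring] <- patch[ring] + height
  img[rr + 1L, cc + 1L] <- patch
  img
}

renderThorn <- function(img, r, c, len, phi, depth = 0.3) {
  h <- nrow(img); w <- ncol(img)
  s <- ceiling(len / 2 + 2)
  rr <- max(0L, floor(r - s)):min(h - 1L, ceiling(r + s))
  cc <- max(0L, floor(c - s)):min(w - 1L, ceiling(c + s))
  dr <- outer(rr - r, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c)
  u <- dc * cos(phi) + dr * sin(phi)
  v <- -dc * sin(phi) + dr * cos(phi)
  spike <- abs(v) <= 1 & abs(u) <= len / 2
  patch <- img[rr + 1L, cc + 1L, drop = FALSE]
  patch[spike] <- patch[spike] - depth * (1 - abs(u[spike]) / (len / 2))
  img[rr + 1L, cc + 1L] <- patch
  img
}

#' Generate one synthetic epidermal micrograph with ground truth
#'
#' Produces a seeded, bit-reproducible synthetic micrograph: an elongated
#' pavement-cell background (ridge texture along the leaf axis plus smooth
#' low-frequency shading), dumbbell-shaped stomatal complexes (two darker
#' guard-cell lobes split by a 2-px bright pore line) placed by rejection
#' sampling at the target density, distractor artifacts (bright bubble rings
#' and dark thorn-cell spikes) that are \emph{not} listed as truth, additive
#' Gaussian noise, and 8-bit quantization. The matching annotation image
#' paints each complex footprint in pure red \code{#FF0000} over the
#' micrograph, and the exact planted centers are returned as truth.
#'
#' The number of planted stomata is exactly
#' \code{round(targetDensity * area_mm2)}; an error naming the hexagonal
#' packing bound is raised when that many points cannot respect
#' \code{minSeparationPx}.
#'
#' @param params a \linkS4class{SyntheticParams}.
#' @return A \linkS4class{SyntheticSample}.
#' @examples
#' s <- generateSample(syntheticParams(imageHeightPx = 256,
#'                                     imageWidthPx = 256, seed = 1))
#' nrow(centers(s@truthCenters))
#' @export
generateSample <- function(params) {
  stopifnot(is(params, "SyntheticParams"))
  validObject(params)
  h <- params@imageHeightPx; w <- params@imageWidthPx
  area <- frameAreaMm2(h, w, params@umPerPx)
  nStomata <- round(params@targetDensity * area)
  margin <- ceiling(params@stomaLengthPx)
  if (h - 1L - 2L * margin < 1L || w - 1L - 2L * margin < 1L)
    stop("image too small for the stoma placement margin")
  usable <- (h - 2 * margin) * (w - 2 * margin)
  bound <- packingBound(usable, params@minSeparationPx)
  if (nStomata > bound)
    stop(sprintf(paste0("infeasible: %d stomata requested but at most %d points ",
                        "with pairwise separation %.1f px fit the %.3g px^2 ",
                        "placement area (hexagonal packing bound)"),
                 nStomata, bound, params@minSeparationPx, usable))

  set.seed(params@seed)
  # pavement-cell background: base + smooth shading + elongated ridges
  img <- matrix(0.72, h, w)
  img <- img + 0.05 * lowFreqField(h, w)
  phase <- 3 * lowFreqField(h, w, spacing = 96)
  ridgePeriod <- 18
  rows0 <- matrix(0:(h - 1L), h, w)
  img <- img + 0.035 * sin(2 * pi * rows0 / ridgePeriod + phase)

  truth <- samplePoints(nStomata, lo = c(margin, margin),
                        hi = c(h - 1L - margin, w - 1L - margin),
                        minSep = params@minSeparationPx, what = "stoma")
  mask <- matrix(FALSE, h, w)
  if (nStomata > 0L) {
    thetas <- stats::runif(nStomata, -0.15, 0.15)
    for (k in seq_len(nStomata)) {
      res <- renderStoma(img, mask, truth[k, 1L], truth[k, 2L],
                         params@stomaLengthPx, params@stomaWidthPx, thetas[k])
      img <- res$img; mask <- res$mask
    }
  }

  nArt <- round(params@artifactRate * area)
  artMargin <- 12L
  art <- if (nArt > 0L && h > 2L * artMargin && w > 2L * artMargin) {
    samplePoints(nArt, lo = c(artMargin, artMargin),
                 hi = c(h - 1L - artMargin, w - 1L - artMargin),
                 minSep = params@minSeparationPx, avoid = truth,
                 what = "artifact")
  } else matrix(numeric(0), 0, 2)
  if (nrow(art) > 0L) {
    for (k in seq_len(nrow(art))) {
      if (k %% 2L == 1L) {
        img <- renderBubble(img, art[k, 1L], art[k, 2L],
                            radius = stats::runif(1, 6, 12))
      } else {
        img <- renderThorn(img, art[k, 1L], art[k, 2L],
                           len = stats::runif(1, 20, 40),
                           phi = stats::runif(1, 0, pi))
      }
    }
  }

  if (params@noiseSd > 0)
    img <- img + matrix(stats::rnorm(h * w, sd = params@noiseSd), h, w)
  img <- round(pmin(pmax(img, 0), 1) * 255) / 255   # clip + 8-bit quantization

  annot <- array(img, dim = c(h, w, 3))
  annot[, , 1][mask] <- 1
  annot[, , 2][mask] <- 0
  annot[, , 3][mask] <- 0

  new("SyntheticSample",
      micrograph = micrograph(img, umPerPx = params@umPerPx),
      annotationImage = annot,
      truthCenters = annotationSet(truth, sourceShape = c(h, w)),
      artifactCenters = art)
}

#' Generate a reproducible synthetic dataset
#'
#' Generates \code{n} samples whose per-sample seeds are derived
#' deterministically from the master seed in \code{params}, so the whole
#' dataset is a pure function of \code{(n, params)}.
#'
#' @param n number of samples (>= 1).
#' @param params a \linkS4class{SyntheticParams}; \code{params@seed} is the
#'   master seed.
#' @return A list of \linkS4class{SyntheticSample}.
#' @export
generateDataset <- function(n, params) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  lapply(seq_len(n), function(i) {
    p <- params
    p@seed <- deriveSeed(params@seed, i)
    generateSample(p)
  })
}

# Derived per-item seed, kept inside 32-bit integer range and distinct for
# i = 1..n at any master seed.
deriveSeed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1000003 + 1) * 1009 + i * 99991) %% 2147483647)
}
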