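#' Construct an unbiased counting frame
#'
#' The frame's top and right borders are inclusionary, its bottom and left
#' borders exclusionary (with the exclusionary lines conceptually extended
#' beyond the frame — left upward, right downward — which for center-point
#' counting reduces to the corner rule: a center on a corner touching an
#' exclusionary border is not counted). Under this rule a set of adjacent
#' frames tiling a region counts every center exactly once.
#'
#' @param top,left,bottom,right frame borders in pixel coordinates
#'   (\code{bottom > top}, \code{right > left}).
#' @param umPerPx calibration, needed only for densities.
#' @return A \linkS4class{CountingFrame}.
#' @export
countingFrame <- function(top, left, bottom, right, umPerPx = NA_real_) {
  new("CountingFrame", top = as.numeric(top), left = as.numeric(left),
      bottom = as.numeric(bottom), right = as.numeric(right),
      umPerPx = as.numeric(umPerPx))
}

#' Default frame for a tile: the image minus a margin
#'
#' @param sourceShape integer \code{c(height, width)}.
#' @param marginPx margin in pixels (default 16, so detections whose
#'   classifier windows were dominated by border padding are not counted).
#' @param umPerPx calibration.
#' @return A \linkS4class{CountingFrame}.
#' @export
defaultCountingFrame <- function(sourceShape, marginPx = 16,
                                 umPerPx = NA_real_) {
  countingFrame(top = marginPx, left = marginPx,
                bottom = sourceShape[1L] - marginPx,
                right = sourceShape[2L] - marginPx, umPerPx = umPerPx)
}

extractCentersMatrix <- function(x) {
  if (is(x, "DetectionSet") || is(x, "AnnotationSet")) centers(x)
  else {
    m <- as.matrix(x)
    if (length(m) == 0L) matrix(numeric(0), 0, 2) else m
  }
}

#' Count detections inside an unbiased counting frame
#'
#' A center \code{(r, c)} (snapped to the nearest 0.5 px so that border
#' incidence is well defined for continuous coordinates) is counted iff it
#' is strictly inside the frame, or on the inclusionary top border (top-left
#' corner excluded, top-right corner included), or on the inclusionary right
#' border (bottom-right corner excluded). Centers on the exclusionary
#' bottom/left borders are never counted. Summed over frames tiling a
#' region, every center is counted exactly once.
#'
#' @param detections a \linkS4class{DetectionSet},
#'   \linkS4class{AnnotationSet} or \code{(row, col)} matrix, in the frame's
#'   coordinate system.
#' @param frame a \linkS4class{CountingFrame}. When the detections carry a
#'   source shape, a frame extending beyond the image is an error.
#' @return \code{list(count = <integer>, counted = <indices>, centers =
#'   <matrix of counted centers>)}.
#' @examples
#' fr <- countingFrame(0, 0, 100, 100)
#' countInFrame(rbind(c(50, 50), c(0, 0), c(0, 100)), fr)$count  # 2
#' @export
countInFrame <- function(detections, frame) {
  stopifnot(is(frame, "CountingFrame"))
  validObject(frame)
  if (is(detections, "DetectionSet") || is(detections, "AnnotationSet")) {
    sh <- detections@sourceShape
    if (frame@bottom > sh[1L] || frame@right > sh[2L])
      stop(sprintf("frame [%g,%g) x [%g,%g) extends beyond the %d x %d image",
                   frame@top, frame@bottom, frame@left, frame@right,
                   sh[1L], sh[2L]))
  }
  ce <- extractCentersMatrix(detections)
  if (nrow(ce) == 0L)
    return(list(count = 0L, counted = integer(0),
                centers = matrix(numeric(0), 0, 2)))
  r <- round(2 * ce[, 1L]) / 2          # snap to nearest 0.5 px
  c <- round(2 * ce[, 2L]) / 2
  interior <- r > frame@top & r < frame@bottom &
              c > frame@left & c < frame@right
  onTop <- r == frame@top & c > frame@left & c <= frame@right
  onRight <- c == frame@right & r >= frame@top & r < frame@bottom
  counted <- which(interior | onTop | onRight)
  list(count = length(counted), counted = counted,
       centers = ce[counted, , drop = FALSE])
}

#' Convert a frame count to stomatal density
#'
#' @param count non-negative stomata count.
#' @param frame the \linkS4class{CountingFrame} the count was taken in; must
#'   carry a calibration (a frame without one has no physical area).
#' @param side \code{"abaxial"}, \code{"adaxial"} or \code{"combined"}.
#' @return A \linkS4class{DensityResult} with
#'   \code{densityPerMm2 = count / frameAreaMm2} exactly.
#' @examples
#' fr <- countingFrame(0, 0, 1000, 1000, umPerPx = 1)
#' computeDensity(35, fr, "abaxial")   # 35 stomata mm^-2
#' @export
computeDensity <- function(count, frame, side = "abaxial") {
  stopifnot(is(frame, "CountingFrame"))
  if (!is.numeric(count) || count < 0) stop("count must be non-negative")
  if (is.na(frame@umPerPx) || frame@umPerPx <= 0)
    stop("frame has zero physical area: a positive umPerPx calibration is required")
  area <- (frame@bottom - frame@top) * (frame@right - frame@left) *
    frame@umPerPx^2 / 1e6
  if (area <= 0) stop("frame has zero area")
  new("DensityResult", count = as.numeric(count), frameAreaMm2 = area,
      densityPerMm2 = count / area, side = side, umPerPx = frame@umPerPx)
}

#' Combine abaxial and adaxial densities into a per-leaf value
#'
#' The per-leaf stomatal density is the arithmetic mean of the densities of
#' the two leaf sides.
#'
#' @param abaxial,adaxial \linkS4class{DensityResult} objects for the lower
#'   and upper leaf side; mixing results computed under different
#'   calibrations is an error.
#' @return A \linkS4class{DensityResult} with \code{side = "combined"},
#'   pooled counts/areas and the mean density.
#' @export
combineSides <- function(abaxial, adaxial) {
  stopifnot(is(abaxial, "DensityResult"), is(adaxial, "DensityResult"))
  if (abaxial@side != "abaxial" || adaxial@side != "adaxial")
    stop("arguments must be an abaxial and an adaxial DensityResult")
  ua <- abaxial@umPerPx; ud <- adaxial@umPerPx
  if (!isTRUE(all.equal(ua, ud)))
    stop(sprintf("mixed calibrations: %.4g vs %.4g um/px", ua, ud))
  new("DensityResult", count = abaxial@count + adaxial@count,
      frameAreaMm2 = abaxial@frameAreaMm2 + adaxial@frameAreaMm2,
      densityPerMm2 = (abaxial@densityPerMm2 + adaxial@densityPerMm2) / 2,
      side = "combined", umPerPx = ua)
}
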