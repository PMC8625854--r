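#' Construct a Micrograph
#'
#' @param pixels numeric matrix of intensities. Values outside \eqn{[0,1]}
#'   are an error; use \code{rescale = TRUE} to min-max rescale arbitrary
#'   input (e.g. raw 8-bit counts).
#' @param umPerPx calibration in micrometres per pixel (\code{NA} if
#'   unknown).
#' @param rescale rescale input linearly to \eqn{[0,1]} first.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' m <- micrograph(matrix(runif(100), 10, 10), umPerPx = 1)
#' @export
micrograph <- function(pixels, umPerPx = NA_real_, rescale = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (rescale) {
    rng <- range(pixels)
    pixels <- if (rng[2L] > rng[1L]) (pixels - rng[1L]) / (rng[2L] - rng[1L])
              else pixels * 0
  }
  new("Micrograph", pixels = pixels, umPerPx = as.numeric(umPerPx))
}

#' Construct an AnnotationSet
#'
#' @param centers numeric matrix (or two-column data.frame) of 0-based
#'   \code{(row, col)} coordinates.
#' @param sourceShape integer \code{c(height, width)} of the annotated image.
#' @return An \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(centers, sourceShape) {
  centers <- as.matrix(centers)
  if (length(centers) == 0L)
    centers <- matrix(numeric(0), 0, 2)
  storage.mode(centers) <- "double"
  colnames(centers) <- c("row", "col")
  new("AnnotationSet", centers = centers,
      sourceShape = as.integer(sourceShape))
}

#' Construct a Heatmap
#'
#' @param values numeric matrix in \eqn{[0,1]}.
#' @param resolutionFactor source pixels per heatmap cell.
#' @return A \linkS4class{Heatmap}.
#' @export
heatmap2d <- function(values, resolutionFactor = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("Heatmap", values = values,
      resolutionFactor = as.integer(resolutionFactor))
}

#' Construct a DetectionSet
#'
#' @param centers numeric matrix of 0-based \code{(row, col)} full-resolution
#'   coordinates.
#' @param scores numeric vector in \eqn{[0,1]}.
#' @param stage \code{"candidate"} or \code{"confirmed"}.
#' @param sourceShape integer \code{c(height, width)}.
#' @param provenance list of model/parameter identifiers.
#' @return A \linkS4class{DetectionSet}.
#' @export
detectionSet <- function(centers, scores, stage = "candidate", sourceShape,
                         provenance = list()) {
  centers <- as.matrix(centers)
  if (length(centers) == 0L) centers <- matrix(numeric(0), 0, 2)
  storage.mode(centers) <- "double"
  colnames(centers) <- c("row", "col")
  new("DetectionSet", centers = centers, scores = as.numeric(scores),
      stage = stage, sourceShape = as.integer(sourceShape),
      provenance = provenance)
}

#' Construct confusion counts
#'
#' @param NTP,NFP,NFN non-negative integer counts.
#' @param NTN non-negative integer count, or \code{NA} (detection mode,
#'   where true negatives are undefined).
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(NTP, NFP, NFN, NTN = NA_integer_) {
  new("ConfusionCounts", NTP = as.integer(NTP), NFP = as.integer(NFP),
      NTN = as.integer(NTN), NFN = as.integer(NFN))
}
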