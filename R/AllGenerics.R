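#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: \code{pixels} and
#' \code{umPerPx} for \linkS4class{Micrograph}, \code{centers} for
#' \linkS4class{AnnotationSet} / \linkS4class{DetectionSet},
#' \code{heatmapValues} and \code{resolutionFactor} for
#' \linkS4class{Heatmap}, \code{scores}, \code{detectionStage} and
#' \code{nDetections} for \linkS4class{DetectionSet}.
#'
#' @param object an object of the documented class.
#' @return The slot contents (matrices, numeric vectors or scalars).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("umPerPx", function(object) standardGeneric("umPerPx"))
#' @rdname accessors
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))
#' @rdname accessors
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))
#' @rdname accessors
#' @export
setGeneric("resolutionFactor",
           function(object) standardGeneric("resolutionFactor"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("detectionStage", function(object) standardGeneric("detectionStage"))
#' @rdname accessors
#' @export
setGeneric("nDetections", function(object) standardGeneric("nDetections"))

#' Precision, recall and accuracy of confusion counts
#'
#' The detection metrics derived from \linkS4class{ConfusionCounts}:
#' precision \eqn{P = NTP / (NTP + NFP)}, recall \eqn{R = NTP / (NTP + NFN)}
#' and accuracy \eqn{Ac = (NTP + NTN) / (NTP + NFP + NTN + NFN)}. Accuracy
#' requires \code{NTN} and is therefore defined only for window
#' classification; calling it on detection-mode counts (where \code{NTN} is
#' \code{NA}) is an error directing the user to precision/recall.
#'
#' @param object a \linkS4class{ConfusionCounts}.
#' @param ... further arguments; \code{accuracy} accepts
#'   \code{printedFormula = FALSE}, which when \code{TRUE} uses the
#'   alternative numerator \eqn{NTP + NFN} (available for audit only).
#' @return A number in \eqn{[0, 1]}. A zero denominator is an explicit error
#'   (the metric is undefined), never \code{NaN}.
#' @examples
#' cc <- confusionCounts(NTP = 1332L, NFP = 25L, NFN = 55L)
#' precision(cc)   # 0.98157...
#' recall(cc)      # 0.96034...
#' @name detection-metrics
NULL

#' @rdname detection-metrics
#' @export
setGeneric("precision", function(object, ...) standardGeneric("precision"))
#' @rdname detection-metrics
#' @export
setGeneric("recall", function(object, ...) standardGeneric("recall"))
#' @rdname detection-metrics
#' @export
setGeneric("accuracy", function(object, ...) standardGeneric("accuracy"))

# ---- accessor methods ----

#' @rdname accessors
#' @export
setMethod("pixels", "Micrograph", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("umPerPx", "Micrograph", function(object) object@umPerPx)
#' @rdname accessors
#' @export
setMethod("umPerPx", "CountingFrame", function(object) object@umPerPx)
#' @rdname accessors
#' @export
setMethod("centers", "AnnotationSet", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("centers", "DetectionSet", function(object) object@centers)
#' @rdname accessors
#' @export
setMethod("heatmapValues", "Heatmap", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("resolutionFactor", "Heatmap", function(object) object@resolutionFactor)
#' @rdname accessors
#' @export
setMethod("scores", "DetectionSet", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("detectionStage", "DetectionSet", function(object) object@stage)
#' @rdname accessors
#' @export
setMethod("nDetections", "DetectionSet", function(object) nrow(object@centers))

# ---- show methods ----

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cal <- if (is.na(object@umPerPx)) "uncalibrated"
         else sprintf("%.4g um/px", object@umPerPx)
  cat(sprintf("Micrograph: %d x %d px, %s, intensity [%.3f, %.3f]\n",
              d[1L], d[2L], cal, min(object@pixels), max(object@pixels)))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d centers on a %d x %d image\n",
              nrow(object@centers), object@sourceShape[1L],
              object@sourceShape[2L]))
})

setMethod("show", "Heatmap", function(object) {
  d <- dim(object@values)
  cat(sprintf("Heatmap: %d x %d cells (resolution factor %d), max %.3f\n",
              d[1L], d[2L], object@resolutionFactor, max(object@values)))
})

setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet: %d %s detections on a %d x %d image\n",
              nrow(object@centers), object@stage, object@sourceShape[1L],
              object@sourceShape[2L]))
})

setMethod("show", "CountingFrame", function(object) {
  cat(sprintf(
    "CountingFrame: rows [%g, %g), cols [%g, %g); inclusion top/right, exclusion bottom/left\n",
    object@top, object@bottom, object@left, object@right))
})

setMethod("show", "DensityResult", function(object) {
  cat(sprintf("DensityResult (%s): %g stomata in %.4g mm^2 = %.3g mm^-2\n",
              object@side, object@count, object@frameAreaMm2,
              object@densityPerMm2))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: NTP=%d NFP=%d NTN=%s NFN=%d\n",
              object@NTP, object@NFP,
              if (is.na(object@NTN)) "NA" else object@NTN, object@NFN))
})

setMethod("show", "SyntheticSample", function(object) {
  cat(sprintf("SyntheticSample: %d x %d px, %d stomata, %d artifacts\n",
              nrow(object@micrograph@pixels), ncol(object@micrograph@pixels),
              nrow(object@truthCenters@centers), nrow(object@artifactCenters)))
})

setMethod("show", "Stage1Model", function(object) {
  cat(sprintf("Stage1Model (heatmap regression): %s, %d conv layers, filters %s\n",
              if (object@trained) "trained" else "untrained",
              object@config@nConvLayers,
              paste(object@config@filtersPerLayer, collapse = "-")))
})

setMethod("show", "Stage2Model", function(object) {
  cat(sprintf("Stage2Model (window classifier): %s, window %d px\n",
              if (object@trained) "trained" else "untrained",
              object@config@windowSize))
})
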