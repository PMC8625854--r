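# File I/O: PNG/TIFF images via EBImage, float TIFF heatmaps via the tiff
# package, center/detection tables as CSV, model checkpoints as RDS with a
# JSON architecture sidecar.
#
# Image matrices in this package are [row, col]; image files store the first
# axis horizontally, so reading/writing transposes.

#' Read a micrograph from PNG or TIFF
#'
#' Multi-channel images are converted to intensity by channel averaging.
#'
#' @param path image file path.
#' @param umPerPx calibration to attach (micrometres per pixel).
#' @return A \linkS4class{Micrograph}.
#' @export
readMicrograph <- function(path, umPerPx = NA_real_) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) == 3L) {
    nc <- min(3L, dim(a)[3L])
    a <- Reduce(`+`, lapply(seq_len(nc), function(k) a[, , k])) / nc
  }
  micrograph(t(a), umPerPx = umPerPx)
}

#' Read a red-painted annotation image
#'
#' @param path PNG/TIFF path of an RGB image.
#' @return An H x W x 3 array in \eqn{[0,1]} (rows x cols x channel), ready
#'   for \code{\link{extractAnnotationCenters}}. A grayscale file is an
#'   error.
#' @export
readAnnotationImage <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) != 3L || dim(a)[3L] < 3L)
    stop("annotation image must be RGB: ", path)
  aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
}

#' Write a micrograph (8-bit grayscale PNG)
#'
#' @param object a \linkS4class{Micrograph} or matrix in \eqn{[0,1]}.
#' @param path output path ending in .png or .tif/.tiff.
#' @export
writeMicrograph <- function(object, path) {
  px <- asPixelMatrix(object)
  EBImage::writeImage(t(px), path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an annotation image (8-bit RGB PNG)
#'
#' @param annotationImage H x W x 3 array in \eqn{[0,1]}.
#' @param path output path.
#' @export
writeAnnotationImage <- function(annotationImage, path) {
  img <- EBImage::Image(aperm(annotationImage, c(2L, 1L, 3L)),
                        colormode = "Color")
  EBImage::writeImage(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read/write center coordinate tables
#'
#' CSV with header \code{row,col}; 0-based pixel coordinates.
#'
#' @param object an \linkS4class{AnnotationSet} (or matrix) to write.
#' @param path CSV path.
#' @param sourceShape image shape to attach when reading.
#' @return \code{readCentersCsv} returns an \linkS4class{AnnotationSet}.
#' @name centers-io
NULL

#' @rdname centers-io
#' @export
writeCentersCsv <- function(object, path) {
  ce <- extractCentersMatrix(object)
  df <- data.frame(row = ce[, 1L], col = ce[, 2L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname centers-io
#' @export
readCentersCsv <- function(path, sourceShape) {
  df <- utils::read.csv(path)
  annotationSet(as.matrix(df[, c("row", "col")]), sourceShape)
}

#' Write detections as CSV (\code{row,col,score,stage})
#'
#' @param detections a \linkS4class{DetectionSet}.
#' @param path CSV path.
#' @export
writeDetectionsCsv <- function(detections, path) {
  ce <- centers(detections)
  df <- data.frame(row = ce[, 1L], col = ce[, 2L],
                   score = scores(detections),
                   stage = detectionStage(detections))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read detections from CSV
#'
#' @param path CSV written by \code{\link{writeDetectionsCsv}}.
#' @param sourceShape image shape.
#' @return A \linkS4class{DetectionSet}.
#' @export
readDetectionsCsv <- function(path, sourceShape) {
  df <- utils::read.csv(path)
  stage <- if (nrow(df)) as.character(df$stage[1L]) else "candidate"
  detectionSet(as.matrix(df[, c("row", "col")]), df$score, stage, sourceShape)
}

#' Write/read a heatmap as 32-bit float TIFF
#'
#' @param heatmap a \linkS4class{Heatmap} to write.
#' @param path TIFF path.
#' @param resolutionFactor factor to attach when reading.
#' @name heatmap-io
NULL

#' @rdname heatmap-io
#' @export
writeHeatmapTiff <- function(heatmap, path) {
  tiff::writeTIFF(t(heatmap@values), path, bits.per.sample = 32L,
                  reduce = TRUE)
  invisible(path)
}

#' @rdname heatmap-io
#' @export
readHeatmapTiff <- function(path, resolutionFactor = 1L) {
  v <- tiff::readTIFF(path)
  heatmap2d(t(v), resolutionFactor = resolutionFactor)
}

#' Save / load a model checkpoint
#'
#' Writes the model object as RDS next to a human-readable JSON sidecar
#' describing the architecture and training configuration.
#'
#' @param model a \linkS4class{Stage1Model} or \linkS4class{Stage2Model}.
#' @param path checkpoint path (an \code{.rds} suffix is added if missing);
#'   the sidecar replaces it with \code{.json}.
#' @return \code{loadModel} returns the model.
#' @name model-io
NULL

#' @rdname model-io
#' @export
saveModel <- function(model, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(model, path)
  cfg <- model@config
  desc <- list(
    class = class(model)[1L],
    trained = model@trained,
    layers = vapply(model@net, function(l) l$type, character(1)),
    config = as.list(structure(lapply(slotNames(cfg), function(s) slot(cfg, s)),
                               names = slotNames(cfg))))
  jsonlite::write_json(desc, sub("\\.rds$", ".json", path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname model-io
#' @export
loadModel <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  if (!file.exists(path)) stop("missing model checkpoint: ", path)
  readRDS(path)
}

#' Write a training history as CSV
#'
#' @param history the \code{history} data.frame of a trained model.
#' @param path CSV path.
#' @export
writeHistoryCsv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
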