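#' @import methods
NULL

# Coordinate convention used throughout the package: image positions are
# 0-based (row, col) doubles; pixel (i, j) of an H x W image occupies
# [i, i+1) x [j, j+1) with i in 0..H-1.  Heatmap cell (i, j) at resolution
# factor f covers source pixels [i*f, (i+1)*f) x [j*f, (j+1)*f); its
# representative full-resolution coordinate is f*i + floor(f/2).

#' Calibrated epidermal micrograph
#'
#' A single-channel intensity image of a leaf epidermal imprint, with an
#' optional pixel calibration. Intensities are stored normalized to
#' \eqn{[0, 1]}.
#'
#' @slot pixels numeric matrix of intensities in \eqn{[0,1]}; rows are image
#'   rows, columns image columns.
#' @slot umPerPx micrometres per pixel (scalar), or \code{NA_real_} when no
#'   calibration is available. A calibration is required only when densities
#'   are computed.
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", umPerPx = "numeric"),
  prototype(pixels = matrix(0, 1, 1), umPerPx = NA_real_),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L) return("image must be non-empty")
    rng <- range(p)
    if (is.na(rng[1L])) return("pixels contain NA")
    if (rng[1L] < 0 || rng[2L] > 1) return("pixel values must lie in [0, 1]")
    if (length(object@umPerPx) != 1L)
      return("umPerPx must be a scalar (possibly NA)")
    if (!is.na(object@umPerPx) && object@umPerPx <= 0)
      return("umPerPx must be > 0")
    TRUE
  })

#' Ground-truth stomatal center set
#'
#' Center coordinates of the stomatal complexes of one micrograph, usually
#' derived from a red-painted annotation image.
#'
#' @slot centers numeric matrix with columns \code{row}, \code{col};
#'   0-based pixel coordinates (may be fractional centroids).
#' @slot sourceShape integer vector \code{c(height, width)} of the image the
#'   centers refer to.
#' @export
setClass("AnnotationSet",
  representation(centers = "matrix", sourceShape = "integer"),
  prototype(centers = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("row", "col"))),
            sourceShape = c(1L, 1L)),
  validity = function(object) {
    ce <- object@centers
    if (ncol(ce) != 2L) return("centers must have two columns (row, col)")
    sh <- object@sourceShape
    if (length(sh) != 2L || any(sh < 1L)) return("bad sourceShape")
    if (nrow(ce) > 0L) {
      if (any(!is.finite(ce))) return("centers must be finite")
      if (any(ce[, 1L] < 0) || any(ce[, 1L] >= sh[1L]) ||
          any(ce[, 2L] < 0) || any(ce[, 2L] >= sh[2L]))
        return("centers must lie within [0, height) x [0, width)")
      if (nrow(ce) > 1L) {
        d <- as.matrix(stats::dist(ce))
        diag(d) <- Inf
        if (min(d) < 0.5) return("duplicate centers (within 0.5 px)")
      }
    }
    TRUE
  })

#' Stomata-presence heatmap
#'
#' Per-pixel (or per-cell, at reduced resolution) stomata-presence surface in
#' \eqn{[0,1]}. Serves both as the Gaussian-peak training target and as the
#' stage-1 network output.
#'
#' @slot values numeric matrix in \eqn{[0,1]}.
#' @slot resolutionFactor source pixels per heatmap cell (1 for full-resolution
#'   training targets, 4 for stage-1 outputs).
#' @export
setClass("Heatmap",
  representation(values = "matrix", resolutionFactor = "integer"),
  prototype(values = matrix(0, 1, 1), resolutionFactor = 1L),
  validity = function(object) {
    v <- object@values
    if (any(!is.finite(v))) return("heatmap values must be finite")
    if (min(v) < 0 || max(v) > 1) return("heatmap values must lie in [0, 1]")
    if (length(object@resolutionFactor) != 1L || object@resolutionFactor < 1L)
      return("resolutionFactor must be a positive integer")
    TRUE
  })

#' Detected stomatal centers
#'
#' Candidate (stage-1) or confirmed (stage-2) stomatal-center detections in
#' full-resolution pixel coordinates, each with a score in \eqn{[0,1]}.
#'
#' @slot centers numeric matrix with columns \code{row}, \code{col} (0-based,
#'   full-resolution coordinates).
#' @slot scores numeric vector in \eqn{[0,1]}, one per detection.
#' @slot stage \code{"candidate"} or \code{"confirmed"}.
#' @slot sourceShape integer \code{c(height, width)} of the source micrograph.
#' @slot provenance list of identifiers/parameters of the producing model.
#' @export
setClass("DetectionSet",
  representation(centers = "matrix", scores = "numeric", stage = "character",
                 sourceShape = "integer", provenance = "list"),
  prototype(centers = matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("row", "col"))),
            scores = numeric(0), stage = "candidate",
            sourceShape = c(1L, 1L), provenance = list()),
  validity = function(object) {
    if (ncol(object@centers) != 2L) return("centers must have two columns")
    if (length(object@scores) != nrow(object@centers))
      return("scores length must match number of detections")
    if (length(object@scores) && (min(object@scores) < 0 || max(object@scores) > 1))
      return("scores must lie in [0, 1]")
    if (!object@stage %in% c("candidate", "confirmed"))
      return("stage must be 'candidate' or 'confirmed'")
    sh <- object@sourceShape
    ce <- object@centers
    if (nrow(ce) > 0L &&
        (any(ce[, 1L] < 0) || any(ce[, 1L] >= sh[1L]) ||
         any(ce[, 2L] < 0) || any(ce[, 2L] >= sh[2L])))
      return("detection centers must lie within the source image")
    TRUE
  })

#' Unbiased counting frame
#'
#' Stereological sampling rectangle with inclusionary top/right borders and
#' exclusionary bottom/left borders. A center on an inclusionary border is
#' counted; a center on an exclusionary border (or on a corner touching an
#' exclusionary border) is not, so that adjacent frames tiling a region count
#' every object exactly once.
#'
#' @slot top,left,bottom,right frame border coordinates in pixels
#'   (\code{bottom > top}, \code{right > left}).
#' @slot umPerPx micrometres per pixel, or \code{NA_real_} if only counts (not
#'   densities) are needed.
#' @export
setClass("CountingFrame",
  representation(top = "numeric", left = "numeric", bottom = "numeric",
                 right = "numeric", umPerPx = "numeric"),
  prototype(top = 0, left = 0, bottom = 1, right = 1, umPerPx = NA_real_),
  validity = function(object) {
    for (s in c("top", "left", "bottom", "right"))
      if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
        return(sprintf("%s must be a finite scalar", s))
    if (object@bottom <= object@top) return("bottom must exceed top")
    if (object@right <= object@left) return("right must exceed left")
    if (object@top < 0 || object@left < 0)
      return("frame must not extend to negative coordinates")
    if (!is.na(object@umPerPx) && object@umPerPx <= 0)
      return("umPerPx must be > 0")
    TRUE
  })

#' Stomatal density result
#'
#' A stereological count and the derived stomatal density (pores per square
#' millimetre) for one leaf side, or the per-leaf combination of both sides.
#'
#' @slot count number of stomatal centers counted in the frame.
#' @slot frameAreaMm2 frame area in mm^2.
#' @slot densityPerMm2 \code{count / frameAreaMm2}.
#' @slot side \code{"abaxial"}, \code{"adaxial"} or \code{"combined"}.
#' @slot umPerPx the calibration the result was computed with (used to refuse
#'   combining results with mixed calibrations).
#' @export
setClass("DensityResult",
  representation(count = "numeric", frameAreaMm2 = "numeric",
                 densityPerMm2 = "numeric", side = "character",
                 umPerPx = "numeric"),
  prototype(count = 0, frameAreaMm2 = 1, densityPerMm2 = 0, side = "combined",
            umPerPx = NA_real_),
  validity = function(object) {
    if (object@count < 0) return("count must be non-negative")
    if (object@frameAreaMm2 <= 0) return("frame area must be positive")
    if (!object@side %in% c("abaxial", "adaxial", "combined"))
      return("side must be abaxial, adaxial or combined")
    TRUE
  })

#' Confusion counts for detection or window classification
#'
#' True/false positive/negative counts. \code{NTN} is defined only for window
#' classification (a "true negative" has no meaning for whole-image center
#' detection) and is \code{NA} in detection mode.
#'
#' @slot NTP,NFP,NFN non-negative integer counts.
#' @slot NTN non-negative integer count, or \code{NA_integer_} in detection
#'   mode.
#' @export
setClass("ConfusionCounts",
  representation(NTP = "integer", NFP = "integer", NTN = "integer",
                 NFN = "integer"),
  prototype(NTP = 0L, NFP = 0L, NTN = NA_integer_, NFN = 0L),
  validity = function(object) {
    for (s in c("NTP", "NFP", "NFN")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v < 0L)
        return(sprintf("%s must be a non-negative integer", s))
    }
    if (length(object@NTN) != 1L || (!is.na(object@NTN) && object@NTN < 0L))
      return("NTN must be NA or a non-negative integer")
    TRUE
  })

#' Synthetic micrograph generator parameters
#'
#' Study conditions for the seeded synthetic benchmark: image geometry and
#' calibration, target stomatal density, stomatal-complex geometry, artifact
#' rate and imaging noise. Defaults give a 1000 x 1000 px field at 1 um/px
#' (exactly 1 mm^2) planted at 35 stomata per mm^2, the magnitude typical of
#' barley epidermis.
#'
#' @slot imageHeightPx,imageWidthPx image size in pixels.
#' @slot umPerPx calibration (micrometres per pixel).
#' @slot targetDensity planted stomatal density, stomata per mm^2.
#' @slot minSeparationPx minimum center-to-center distance between planted
#'   stomata.
#' @slot stomaLengthPx,stomaWidthPx complex length/width in px (length >=
#'   width).
#' @slot artifactRate non-stomatal distractors (bubbles, thorn cells) per
#'   mm^2.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticParams",
  representation(imageHeightPx = "integer", imageWidthPx = "integer",
                 umPerPx = "numeric", targetDensity = "numeric",
                 minSeparationPx = "numeric", stomaLengthPx = "numeric",
                 stomaWidthPx = "numeric", artifactRate = "numeric",
                 noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@imageHeightPx < 1L || object@imageWidthPx < 1L)
      return("image dimensions must be positive")
    if (object@umPerPx <= 0) return("umPerPx must be > 0")
    if (object@targetDensity < 0) return("targetDensity must be >= 0")
    if (object@minSeparationPx <= 0) return("minSeparationPx must be > 0")
    if (object@stomaLengthPx <= 0 || object@stomaWidthPx <= 0)
      return("stoma dimensions must be positive")
    if (object@stomaLengthPx < object@stomaWidthPx)
      return("stomaLengthPx must be >= stomaWidthPx")
    if (object@artifactRate < 0) return("artifactRate must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' One synthetic micrograph with ground truth
#'
#' @slot micrograph the generated \linkS4class{Micrograph}.
#' @slot annotationImage H x W x 3 array equal to the micrograph in all three
#'   channels except where stomatal complexes are painted pure red
#'   (\code{#FF0000}).
#' @slot truthCenters \linkS4class{AnnotationSet} of planted stomatal centers.
#' @slot artifactCenters numeric matrix (\code{row}, \code{col}) of planted
#'   distractor centers (never listed as truth).
#' @export
setClass("SyntheticSample",
  representation(micrograph = "Micrograph", annotationImage = "array",
                 truthCenters = "AnnotationSet", artifactCenters = "matrix"),
  validity = function(object) {
    d <- dim(object@annotationImage)
    if (length(d) != 3L || d[3L] != 3L)
      return("annotationImage must be an H x W x 3 array")
    if (!all(d[1:2] == dim(object@micrograph@pixels)))
      return("annotationImage size must match the micrograph")
    TRUE
  })

#' One image/target training tile
#'
#' A disjoint tile cut from a micrograph together with the matching piece of
#' its training target, and the tile's origin in source coordinates.
#'
#' @slot imageTile \linkS4class{Micrograph} tile.
#' @slot targetTile matching \linkS4class{Heatmap} or
#'   \linkS4class{AnnotationSet} tile (or \code{NULL} for prediction-time
#'   tiling).
#' @slot origin integer \code{c(rowOffset, colOffset)} of the tile's top-left
#'   pixel in the (cropped) source, 0-based.
#' @slot tileShape integer \code{c(h, w)}.
#' @export
setClass("TilePair",
  representation(imageTile = "Micrograph", targetTile = "ANY",
                 origin = "integer", tileShape = "integer"))

#' Stage-1 network configuration
#'
#' Architecture and training hyperparameters of the heatmap-regression
#' network: six 3x3 convolution layers (ReLU on the first two, sigmoid on the
#' last four) interspersed with batch-normalization and dropout, and two 2x2
#' max-pooling layers for a total downsampling factor of four. The final
#' layer is a single-channel sigmoid map.
#'
#' @slot nConvLayers,nPoolLayers,poolFactorTotal architecture contract
#'   (6 / 2 / 4).
#' @slot activations per-conv-layer activation names.
#' @slot filtersPerLayer filters per convolution layer (last must be 1).
#' @slot kernelSize odd convolution kernel size.
#' @slot dropoutRate dropout rate in \eqn{[0,1)}.
#' @slot lossName,optimizerName training loss/optimizer identifiers.
#' @slot learningRate,batchSize,epochs training hyperparameters.
#' @slot seed integer RNG seed controlling initialization, shuffling and
#'   dropout.
#' @export
setClass("Stage1Config",
  representation(nConvLayers = "integer", activations = "character",
                 nPoolLayers = "integer", poolFactorTotal = "integer",
                 filtersPerLayer = "integer", kernelSize = "integer",
                 dropoutRate = "numeric", lossName = "character",
                 optimizerName = "character", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer"))

#' Stage-2 window-classifier configuration
#'
#' Architecture and training hyperparameters of the binary window classifier:
#' two 3x3 convolution layers (ReLU, batch-normalized) followed by two fully
#' connected sigmoid layers ending in a single probability in \eqn{[0,1]}.
#'
#' @slot windowSize even window side length in full-resolution pixels
#'   (default 32).
#' @slot nConvLayers,nDenseLayers architecture contract (2 / 2).
#' @slot filtersPerLayer filters per convolution layer.
#' @slot denseUnits units of the two dense layers (last must be 1).
#' @slot decisionCutoff classification cutoff in \eqn{(0,1)}.
#' @slot lossName,optimizerName,learningRate,batchSize,epochs training
#'   hyperparameters.
#' @slot classWeighting weight positives/negatives inversely to class
#'   frequency.
#' @slot seed integer RNG seed.
#' @export
setClass("Stage2Config",
  representation(windowSize = "integer", nConvLayers = "integer",
                 nDenseLayers = "integer", filtersPerLayer = "integer",
                 denseUnits = "integer", decisionCutoff = "numeric",
                 lossName = "character", optimizerName = "character",
                 learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", classWeighting = "logical",
                 seed = "integer"))

#' Trained (or initialized) stage-1 / stage-2 model handle
#'
#' Wraps the network parameter list, its configuration and, after training,
#' the per-epoch loss history and best-validation checkpoint.
#'
#' @slot net list of layer parameter tensors (internal format).
#' @slot config the \linkS4class{Stage1Config} or \linkS4class{Stage2Config}.
#' @slot history data.frame with one row per epoch (losses; accuracy for the
#'   window classifier).
#' @slot trained logical.
#' @name CnnModel-classes
NULL

#' @rdname CnnModel-classes
#' @export
setClass("Stage1Model",
  representation(net = "list", config = "Stage1Config", history = "data.frame",
                 trained = "logical"),
  prototype(trained = FALSE))

#' @rdname CnnModel-classes
#' @export
setClass("Stage2Model",
  representation(net = "list", config = "Stage2Config", history = "data.frame",
                 trained = "logical"),
  prototype(trained = FALSE))
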