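#' Match predicted detections to ground-truth centers
#'
#' One-to-one matching of predicted centers to true centers, where a pair is
#' admissible only if their distance is at most \code{maxDistPx}. The
#' default method computes a \emph{maximum-cardinality} matching on the
#' admissible-pair graph, so the true-positive count always equals the
#' optimum an exhaustive assignment oracle would find (greedy nearest-first
#' matching, available as \code{method = "greedy"} for audit, can undercount
#' when a prediction "steals" the only admissible truth of another).
#' Matched predictions are true positives, unmatched predictions false
#' positives, unmatched truths false negatives; true negatives are undefined
#' for detection and reported as \code{NA}.
#'
#' @param predicted a \linkS4class{DetectionSet} (or a \code{(row, col)}
#'   matrix).
#' @param truth an \linkS4class{AnnotationSet} (or a \code{(row, col)}
#'   matrix).
#' @param maxDistPx positive matching radius in pixels.
#' @param method \code{"max"} (maximum-cardinality, default) or
#'   \code{"greedy"} (nearest-admissible-pair first, ties broken by distance
#'   then row-major order).
#' @return \code{list(counts = <ConfusionCounts>, matching = <data.frame>)},
#'   the matching having columns \code{predIndex}, \code{truthIndex},
#'   \code{distPx}.
#' @examples
#' truth <- annotationSet(rbind(c(10, 10), c(40, 40)), c(64, 64))
#' pred <- rbind(c(11, 10), c(39, 41), c(60, 5))
#' matchDetections(pred, truth, maxDistPx = 8)$counts
#' @export
matchDetections <- function(predicted, truth, maxDistPx,
                            method = c("max", "greedy")) {
  method <- match.arg(method)
  if (!is.numeric(maxDistPx) || maxDistPx <= 0)
    stop("maxDistPx must be positive")
  P <- if (is(predicted, "DetectionSet")) centers(predicted) else as.matrix(predicted)
  Tr <- if (is(truth, "AnnotationSet")) centers(truth) else as.matrix(truth)
  if (length(P) == 0L) P <- matrix(numeric(0), 0, 2)
  if (length(Tr) == 0L) Tr <- matrix(numeric(0), 0, 2)
  m <- nrow(P); n <- nrow(Tr)
  emptyMatch <- data.frame(predIndex = integer(), truthIndex = integer(),
                           distPx = numeric())
  if (m == 0L || n == 0L)
    return(list(counts = confusionCounts(0L, m, n), matching = emptyMatch))

  D <- sqrt(outer(P[, 1L], Tr[, 1L], "-")^2 + outer(P[, 2L], Tr[, 2L], "-")^2)
  adm <- which(D <= maxDistPx, arr.ind = TRUE)
  if (nrow(adm) == 0L)
    return(list(counts = confusionCounts(0L, m, n), matching = emptyMatch))

  if (method == "greedy") {
    dd <- D[adm]
    ord <- order(dd, adm[, 1L], adm[, 2L])
    usedP <- logical(m); usedT <- logical(n)
    mp <- integer(0); mt <- integer(0)
    for (k in ord) {
      i <- adm[k, 1L]; j <- adm[k, 2L]
      if (!usedP[i] && !usedT[j]) {
        usedP[i] <- TRUE; usedT[j] <- TRUE
        mp <- c(mp, i); mt <- c(mt, j)
      }
    }
  } else {
    g <- igraph::make_bipartite_graph(
      types = c(rep(FALSE, m), rep(TRUE, n)),
      edges = as.vector(t(cbind(adm[, 1L], m + adm[, 2L]))))
    mb <- igraph::max_bipartite_match(g)
    mv <- mb$matching[seq_len(m)]
    mp <- which(!is.na(mv))
    mt <- as.integer(mv[mp]) - m
  }
  matching <- data.frame(predIndex = mp, truthIndex = mt,
                         distPx = D[cbind(mp, mt)])
  matching <- matching[order(matching$predIndex), , drop = FALSE]
  rownames(matching) <- NULL
  ntp <- nrow(matching)
  list(counts = confusionCounts(NTP = ntp, NFP = m - ntp, NFN = n - ntp),
       matching = matching)
}

# Exhaustive optimal-assignment oracle for small instances: maximizes the
# number of admissible one-to-one pairs (and among those, minimizes total
# distance). Used by the test suite as an independent check.
matchOracle <- function(P, Tr, maxDistPx) {
  m <- nrow(P); n <- nrow(Tr)
  if (m == 0L || n == 0L) return(list(NTP = 0L, totalDist = 0))
  D <- sqrt(outer(P[, 1L], Tr[, 1L], "-")^2 + outer(P[, 2L], Tr[, 2L], "-")^2)
  best <- list(NTP = 0L, totalDist = 0, count = 1L)
  assignRec <- function(i, usedT, ntp, dist) {
    if (i > m) {
      if (ntp > best$NTP ||
          (ntp == best$NTP && dist < best$totalDist - 1e-12)) {
        best <<- list(NTP = ntp, totalDist = dist, count = 1L)
      } else if (ntp == best$NTP && abs(dist - best$totalDist) <= 1e-12) {
        best$count <<- best$count + 1L
      }
      return(invisible())
    }
    assignRec(i + 1L, usedT, ntp, dist)        # prediction i unmatched
    for (j in seq_len(n)) {
      if (!usedT[j] && D[i, j] <= maxDistPx) {
        usedT[j] <- TRUE
        assignRec(i + 1L, usedT, ntp + 1L, dist + D[i, j])
        usedT[j] <- FALSE
      }
    }
  }
  assignRec(1L, logical(n), 0L, 0)
  best
}

checkDenominator <- function(num, den, what, hint = NULL) {
  if (den <= 0L)
    stop(what, " is undefined: zero denominator",
         if (!is.null(hint)) paste0(" (", hint, ")"))
  num / den
}

#' @rdname detection-metrics
#' @export
setMethod("precision", "ConfusionCounts", function(object, ...) {
  checkDenominator(object@NTP, object@NTP + object@NFP, "precision")
})

#' @rdname detection-metrics
#' @export
setMethod("recall", "ConfusionCounts", function(object, ...) {
  checkDenominator(object@NTP, object@NTP + object@NFN, "recall")
})

#' @rdname detection-metrics
#' @export
setMethod("accuracy", "ConfusionCounts",
          function(object, printedFormula = FALSE, ...) {
  if (is.na(object@NTN))
    stop("accuracy requires true-negative counts (window classification); ",
         "for detection matching use precision and recall instead")
  num <- if (printedFormula) object@NTP + object@NFN else object@NTP + object@NTN
  checkDenominator(num, object@NTP + object@NFP + object@NTN + object@NFN,
                   "accuracy")
})

#' Format a metric as a percentage string
#'
#' Truncates (never rounds up) to the requested precision, so a detector
#' metric is never overstated: a precision of 0.98158 prints as
#' \code{"98.1\%"}, a recall of 0.96034 as \code{"96\%"}.
#'
#' @param x metric value in \eqn{[0,1]}.
#' @param digits decimal places of the percentage.
#' @return Character scalar.
#' @export
formatPercent <- function(x, digits = 1) {
  v <- floor(100 * x * 10^digits + 1e-9) / 10^digits
  paste0(formatC(v, format = "f", digits = digits), "%")
}
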