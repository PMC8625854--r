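# Shared fixtures: small parameter sets and a cached tiny synthetic sample
# so several test files can reuse the same generated data.

tinyParams <- function(seed = 1L, ...) {
  syntheticParams(imageHeightPx = 256L, imageWidthPx = 256L, seed = seed, ...)
}

# memoized 1 mm^2 reference sample (1000 x 1000 px at 1 um/px)
refSample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateSample(syntheticParams(seed = 7L))
    cache
  }
})

# brute-force local maxima + greedy suppression oracle for heatmaps
oracleExtract <- function(v, minSep) {
  h <- nrow(v); w <- ncol(v)
  peaks <- NULL
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (v[i, j] <= 0) next
    nb <- v[max(1, i - 1):min(h, i + 1), max(1, j - 1):min(w, j + 1)]
    if (v[i, j] >= max(nb)) peaks <- rbind(peaks, c(i - 1, j - 1, v[i, j]))
  }
  if (is.null(peaks)) return(matrix(numeric(0), 0, 3))
  peaks <- peaks[order(-peaks[, 3], peaks[, 1], peaks[, 2]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 3)
  for (k in seq_len(nrow(peaks))) {
    if (nrow(kept) == 0 ||
        min(sqrt((kept[, 1] - peaks[k, 1])^2 + (kept[, 2] - peaks[k, 2])^2)) >= minSep)
      kept <- rbind(kept, peaks[k, ])
  }
  kept
}
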