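## Segment extraction and complexity indices: approximate and sample entropy,
## Hjorth mobility/complexity, Katz fractal dimension, standard deviation.

#' Extract fixed-duration segments from an SKNA series
#'
#' Task segments start at their event start; baseline segments are taken from
#' the middle portion of the baseline span (a 10 s window in a 120 s baseline
#' covers 55-65 s), avoiding transitional effects at either end.
#'
#' @param skna an \code{SknaSeries}.
#' @param events annotation data.frame (\code{condition}, \code{start_s},
#'   \code{end_s}, optional \code{vas}, \code{das}).
#' @param durationS segment duration in seconds (5 s gives 20000 samples at
#'   4 kHz; 20 s gives 80000).
#' @param baselineRule \code{"mid"} (centered in the annotated baseline span)
#'   or \code{"start"}.
#' @param baselineLabel label identifying baseline events, default
#'   \code{"baseline"}.
#' @param subjectId subject identifier for the produced segments (taken from
#'   the series provenance when absent).
#' @return list of \code{Segment} objects.
#' @export
extractSegments <- function(skna, events, durationS,
                            baselineRule = c("mid", "start"),
                            baselineLabel = "baseline", subjectId = NULL) {
  stopifnot(is(skna, "SknaSeries"))
  baselineRule <- match.arg(baselineRule)
  fs <- skna@fs
  n <- length(skna@values)
  nSeg <- round(durationS * fs)
  if (is.null(subjectId))
    subjectId <- if (!is.null(skna@provenance$subjectId))
      skna@provenance$subjectId else "S1"
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    isBase <- identical(as.character(ev$condition), baselineLabel)
    start <- if (isBase && baselineRule == "mid")
      (ev$start_s + ev$end_s) / 2 - durationS / 2 else ev$start_s
    i0 <- floor(start * fs) + 1
    i1 <- i0 + nSeg - 1
    if (i0 < 1 || i1 > n)
      stop(sprintf("event %d (%s) exceeds the series bounds", i, ev$condition))
    out[[length(out) + 1]] <- new("Segment",
      values = skna@values[i0:i1], fs = fs, subjectId = as.character(subjectId),
      condition = as.character(ev$condition), signal = skna@kind,
      segmentId = sprintf("%s.%s.%02d", subjectId, ev$condition, i),
      vas = if ("vas" %in% names(ev)) as.numeric(ev$vas) else NA_real_,
      das = if ("das" %in% names(ev)) as.numeric(ev$das) else NA_real_)
  }
  out
}

.entropyTol <- function(x, rCoeff, r) {
  if (!is.null(r)) return(r)
  rCoeff * sd(x)
}

#' Approximate entropy
#'
#' Negative log conditional probability that sequences of length \code{m}
#' that match within tolerance \code{r} still match at length \code{m + 1};
#' smaller values indicate more regular signals. Template comparison uses the
#' Chebyshev distance and includes self-matches. A constant segment returns 0
#' with attribute \code{degenerate = TRUE}.
#'
#' @param x numeric sample vector.
#' @param m embedding dimension, default 2.
#' @param rCoeff tolerance as a multiple of \code{sd(x)}, default 0.2.
#' @param r absolute tolerance override (bypasses \code{rCoeff}).
#' @return approximate entropy value.
#' @export
apEn <- function(x, m = 2, rCoeff = 0.2, r = NULL) {
  .assertFiniteNumeric(x)
  if (m < 1) stop("m must be >= 1")
  if (length(x) <= m + 1) stop("series too short for the requested embedding")
  if (sd(x) == 0 && is.null(r)) return(structure(0, degenerate = TRUE))
  apen_cpp(as.numeric(x), as.integer(m), .entropyTol(x, rCoeff, r))
}

#' Sample entropy
#'
#' \code{-log(A/B)} where \code{B} counts m-length template pairs within
#' tolerance and \code{A} those still within tolerance at length
#' \code{m + 1}; self-matches are excluded, so the value is non-negative
#' whenever defined. If no pairs match (\code{B = 0}) or no extended pairs
#' match (\code{A = 0}) the result is \code{NA} with attribute
#' \code{reason}.
#'
#' @inheritParams apEn
#' @return sample entropy value, or flagged \code{NA} when undefined.
#' @export
sampEn <- function(x, m = 2, rCoeff = 0.2, r = NULL) {
  .assertFiniteNumeric(x)
  if (m < 1) stop("m must be >= 1")
  if (length(x) <= m + 1) stop("series too short for the requested embedding")
  if (sd(x) == 0 && is.null(r)) return(structure(NA_real_, reason = "degenerate"))
  ab <- sampen_counts_cpp(as.numeric(x), as.integer(m), .entropyTol(x, rCoeff, r))
  if (ab[2] == 0) return(structure(NA_real_, reason = "no m-matches"))
  if (ab[1] == 0) return(structure(NA_real_, reason = "no (m+1)-matches"))
  -log(ab[1] / ab[2])
}

#' Hjorth mobility and complexity
#'
#' Mobility is \code{sqrt(var(diff(x)) / var(x))}; complexity is the mobility
#' of the first difference divided by the mobility of the signal. The
#' derivative is the unscaled first difference, so both parameters are
#' dimensionless and invariant to amplitude scaling. Activity (the variance)
#' is returned in the moments but not treated as a separate index, being
#' redundant with the standard deviation.
#'
#' @param x numeric sample vector of length >= 3.
#' @return list with \code{mobility}, \code{complexity} and \code{moments}
#'   (variances of the signal and its first and second differences).
#' @export
hjorthParams <- function(x) {
  .assertFiniteNumeric(x)
  if (length(x) < 3) stop("need at least 3 samples")
  d1 <- diff(x)
  d2 <- diff(d1)
  v0 <- var(x); v1 <- var(d1); v2 <- var(d2)
  if (v0 == 0 || v1 == 0)
    return(list(mobility = NA_real_, complexity = NA_real_,
                moments = c(var_x = v0, var_dx = v1, var_ddx = v2)))
  list(mobility = sqrt(v1 / v0), complexity = sqrt(v2 / v1) / sqrt(v1 / v0),
       moments = c(var_x = v0, var_dx = v1, var_ddx = v2))
}

#' Katz fractal dimension
#'
#' The waveform is treated as a planar curve with unit abscissa spacing:
#' \code{KFD = log10(n) / (log10(d / L) + log10(n))} with \code{L} the total
#' curve length, \code{d} the maximum distance from the first point, and
#' \code{n} the number of steps (\code{length(x) - 1}; set
#' \code{nDefinition = "points"} to use the point count instead — for long
#' segments the two differ negligibly). A straight line gives exactly 1
#' regardless of slope — including a constant trace, which is a zero-slope
#' line; because the abscissa always advances one unit per step, the curve
#' length can never vanish. Lower values indicate smoother, more linear
#' signals.
#'
#' @param x numeric sample vector of length >= 2.
#' @param nDefinition \code{"steps"} (default) or \code{"points"}.
#' @return the fractal dimension.
#' @export
katzFd <- function(x, nDefinition = c("steps", "points")) {
  .assertFiniteNumeric(x)
  nDefinition <- match.arg(nDefinition)
  N <- length(x)
  if (N < 2) stop("need at least 2 samples")
  steps <- N - 1
  L <- sum(sqrt(1 + diff(x)^2))
  d <- sqrt(max((seq_len(N) - 1)^2 + (x - x[1])^2))
  n <- if (nDefinition == "steps") steps else N
  log10(n) / (log10(d / L) + log10(n))
}

#' Segment standard deviation
#'
#' Sample standard deviation (n - 1 denominator) of a segment, computed
#' independently per segment without cross-subject normalization.
#'
#' @param x numeric sample vector of length >= 2.
#' @return the standard deviation.
#' @export
segmentSd <- function(x) {
  .assertFiniteNumeric(x)
  if (length(x) < 2) stop("need at least 2 samples")
  sd(x)
}

#' Entropy parameter grids
#'
#' \code{entropyGrid()} is the default single setting (m = 2,
#' r = 0.2 x SD); \code{sensitivityGrid()} is the 2 x 3 sensitivity grid
#' m in \{2, 3\}, r in \{0.15, 0.20, 0.25\} x SD.
#'
#' @return data.frame with columns \code{m} and \code{r_coeff}.
#' @export
entropyGrid <- function() data.frame(m = 2L, r_coeff = 0.2)

#' @rdname entropyGrid
#' @export
sensitivityGrid <- function()
  expand.grid(m = c(2L, 3L), r_coeff = c(0.15, 0.20, 0.25),
              KEEP.OUT.ATTRS = FALSE)

.indexNames <- c("ApEn", "SampEn", "Mobility", "Complexity", "KFD", "SD")

#' Compute the complexity feature table
#'
#' All six indices per segment; ApEn and SampEn are computed for every
#' \code{(m, r_coeff)} entry of the grid, the remaining indices once per
#' segment (their grid columns are NA). Pain and anxiety groups are derived
#' from the segment VAS / DAS annotations.
#'
#' @param segments list of \code{Segment} objects (uniform duration).
#' @param grid entropy parameter grid, default \code{entropyGrid()}.
#' @param indices subset of \code{c("ApEn", "SampEn", "Mobility",
#'   "Complexity", "KFD", "SD")} to compute, default all.
#' @return tidy data.frame with columns \code{subject_id, condition,
#'   pain_group, anxiety_group, segment_id, signal, index, m, r_coeff,
#'   value}.
#' @export
computeFeatures <- function(segments, grid = entropyGrid(),
                            indices = .indexNames) {
  if (is(segments, "Segment")) segments <- list(segments)
  if (!length(segments)) stop("no segments supplied")
  indices <- match.arg(indices, .indexNames, several.ok = TRUE)
  lens <- vapply(segments, function(s) length(s@values), integer(1))
  if (length(unique(lens)) != 1L)
    stop("segments must have a uniform duration within a comparison")
  rows <- vector("list", 0L)
  for (seg in segments) {
    x <- seg@values
    base <- data.frame(subject_id = seg@subjectId, condition = seg@condition,
                       pain_group = if (is.na(seg@vas)) NA_character_
                                    else as.character(assignPainGroup(seg@vas)),
                       anxiety_group = if (is.na(seg@das)) NA_character_
                                       else as.character(assignAnxietyGroup(seg@das)),
                       segment_id = seg@segmentId, signal = seg@signal,
                       vas = seg@vas, das = seg@das,
                       stringsAsFactors = FALSE)
    addRow <- function(index, m, r_coeff, value) {
      r <- base
      r$index <- index; r$m <- m; r$r_coeff <- r_coeff
      r$value <- as.numeric(value)
      rows[[length(rows) + 1L]] <<- r
    }
    hj <- if (any(c("Mobility", "Complexity") %in% indices)) hjorthParams(x)
    for (idx in indices) {
      switch(idx,
        ApEn = for (g in seq_len(nrow(grid)))
          addRow("ApEn", grid$m[g], grid$r_coeff[g],
                 apEn(x, grid$m[g], grid$r_coeff[g])),
        SampEn = for (g in seq_len(nrow(grid)))
          addRow("SampEn", grid$m[g], grid$r_coeff[g],
                 sampEn(x, grid$m[g], grid$r_coeff[g])),
        Mobility = addRow("Mobility", NA, NA, hj$mobility),
        Complexity = addRow("Complexity", NA, NA, hj$complexity),
        KFD = addRow("KFD", NA, NA, katzFd(x)),
        SD = addRow("SD", NA, NA, segmentSd(x)))
    }
  }
  do.call(rbind, rows)
}

#' Write a feature table as tidy CSV
#'
#' @param features data.frame from \code{\link{computeFeatures}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
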