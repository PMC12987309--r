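## SKNA representations: integrated SKNA (neuECG) and time-varying SKNA
## (VFCDM reconstruction + Hilbert envelope).

#' Centered moving average with reflection padding
#'
#' Window of \code{round(windowS * fs)} samples centered on each output
#' sample (for even windows the extra sample falls on the trailing side);
#' edges are handled by symmetric reflection so output length equals input
#' length.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param windowS window length in seconds, default 0.1 (100 ms).
#' @return smoothed vector, same length as \code{x}.
#' @export
movingAverage <- function(x, fs, windowS = 0.1) {
  .assertFiniteNumeric(x)
  W <- round(windowS * fs)
  if (W < 1) stop("window must span at least one sample")
  if (W > length(x)) stop("window longer than the signal")
  if (W == 1) return(x)
  l <- (W - 1) %/% 2
  r <- W - 1 - l
  xe <- c(x[l:1], x, x[length(x):(length(x) - r + 1)])
  cs <- cumsum(c(0, xe))
  (cs[(W + 1):(W + length(x))] - cs[1:length(x)]) / W
}

#' @rdname computeIskna
#' @export
setMethod("computeIskna", "numeric", function(x, fs, band = c(500, 1000),
                                              windowS = 0.1,
                                              stopbandAtten = 60,
                                              transitionWidth = 50) {
  if (fs < 2 * band[2]) stop("fs must be at least twice the upper band edge")
  if (all(x == 0)) {
    filt <- NULL
    y <- x
  } else {
    filt <- .designFirCached("bandpass", band, fs, stopbandAtten, transitionWidth)
    y <- zeroPhaseFilter(x, filt)
  }
  env <- movingAverage(abs(y), fs, windowS)
  new("SknaSeries", values = env, fs = fs, kind = "iSKNA",
      provenance = list(band = band, windowS = windowS,
                        stopbandAtten = stopbandAtten,
                        ntaps = if (is.null(filt)) 0L else length(filt@taps)))
})

#' @rdname computeIskna
#' @export
setMethod("computeIskna", "EcgRecording", function(x, ...) {
  s <- computeIskna(x@samples, fs = x@fs, ...)
  s@provenance$subjectId <- x@subjectId
  s
})

## Low-pass prototype for the demodulation stages: windowed-sinc (Hamming)
## with half-amplitude response at the cutoff, so adjacent channels sum to
## ~1 across their shared transition band. Odd length (even order).
.cdmLowpass <- function(cutoff, fs, ntaps = NULL) {
  if (is.null(ntaps)) ntaps <- 2 * ceiling(2 * fs / cutoff) + 1
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- (ntaps - 1) / 2
  k <- -m:m
  h <- 2 * cutoff / fs * sinc(2 * cutoff * k / fs)
  w <- 0.54 + 0.46 * cos(pi * k / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))

#' Variable frequency complex demodulation (VFCDM)
#'
#' Two-stage time-frequency decomposition. Stage one demodulates the signal
#' at fixed center frequencies spaced \code{spacing} Hz apart and low-pass
#' filters at \code{spacing/2}, yielding complex analytic subband components
#' whose real parts sum back to the band-limited input. Stage two
#' re-demodulates each subband along its smoothed dominant instantaneous
#' frequency with a narrower low-pass, sharpening the time-frequency
#' localization while preserving the reconstruction.
#'
#' @param x numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param spacing center-frequency spacing in Hz, default 160.
#' @param firstBw first-stage low-pass bandwidth in Hz, default
#'   \code{spacing/2}.
#' @param secondBw second-stage low-pass bandwidth in Hz, default
#'   \code{0.75 * spacing}: wide enough that re-demodulating a subband along
#'   its wandering frequency track retains the subband content (so the
#'   component sum still reconstructs the input), while the variable-
#'   frequency tracking itself provides the time-frequency sharpening.
#' @param twoStage run the variable-frequency refinement stage, default TRUE.
#' @param ifSmoothS smoothing window (s) for the instantaneous-frequency
#'   track, default 0.05.
#' @return a \code{TFDecomposition} with one complex analytic component per
#'   center frequency \code{spacing, 2*spacing, ...} below Nyquist.
#' @export
vfcdmDecompose <- function(x, fs, spacing = 160, firstBw = spacing / 2,
                           secondBw = 0.75 * spacing, twoStage = TRUE,
                           ifSmoothS = 0.05) {
  .assertFiniteNumeric(x)
  if (spacing <= 0 || spacing >= fs / 2) stop("spacing must lie in (0, fs/2)")
  if (length(x) < 10 * fs / spacing)
    stop("signal too short for the requested component spacing")
  centers <- spacing * seq_len(floor((fs / 2 - firstBw) / spacing))
  n <- length(x)
  t <- (0:(n - 1)) / fs
  lp1 <- .cdmLowpass(firstBw, fs)
  comps <- matrix(0i, nrow = n, ncol = length(centers))
  for (k in seq_along(centers)) {
    fc <- centers[k]
    z <- x * exp(-2i * pi * fc * t)
    lpz <- .firZeroPhaseSinglePass(lp1, z)
    comps[, k] <- 2 * lpz * exp(2i * pi * fc * t)
  }
  if (twoStage && any(x != 0)) {
    lp2 <- .cdmLowpass(secondBw, fs)
    wIF <- max(1, round(ifSmoothS * fs))
    for (k in seq_along(centers)) {
      ck <- comps[, k]
      ph <- Arg(ck)
      inst <- c(diff(unwrapPhase(ph)), 0) * fs / (2 * pi)
      inst <- movingAverage(inst, fs, wIF / fs)
      inst <- pmin(pmax(inst, centers[k] - firstBw), centers[k] + firstBw)
      phi <- 2 * pi * cumsum(inst) / fs
      ## re-demodulate the analytic subband along its own frequency track
      z <- ck * exp(-1i * phi)
      lpz <- .firZeroPhaseSinglePass(lp2, z)
      comps[, k] <- lpz * exp(1i * phi)
    }
  }
  new("TFDecomposition", centerFreqs = centers, components = comps, fs = fs,
      lpfBandwidth = firstBw)
}

#' Unwrap a phase sequence
#'
#' @param p phase angles in radians.
#' @return unwrapped phases (jumps larger than pi removed).
#' @export
unwrapPhase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

#' Reconstruct a signal from a VFCDM decomposition
#'
#' Sums the real parts of the components whose center frequency falls inside
#' \code{band} (inclusive); with \code{band = NULL} all components are used.
#'
#' @param decomp a \code{TFDecomposition}.
#' @param band optional numeric \code{c(low, high)} in Hz.
#' @return numeric vector, same length as the decomposed signal.
#' @export
reconstructSignal <- function(decomp, band = NULL) {
  stopifnot(is(decomp, "TFDecomposition"))
  sel <- if (is.null(band)) seq_along(decomp@centerFreqs)
         else which(decomp@centerFreqs >= band[1] & decomp@centerFreqs <= band[2])
  if (!length(sel)) stop("no components inside the requested band")
  rowSums(Re(decomp@components[, sel, drop = FALSE]))
}

#' @rdname computeTvskna
#' @export
setMethod("computeTvskna", "numeric", function(x, fs, band = c(160, 1120),
                                               highpass = 150, windowS = 0.1,
                                               spacing = 160, ...) {
  if (fs < 2 * band[2]) stop("fs must be at least twice the upper band edge")
  if (all(x == 0)) {
    env <- x
    ncomp <- 0L
  } else {
    hp <- .designFirCached("highpass", highpass, fs, stopbandAtten = 60,
                    transitionWidth = 50)
    xh <- zeroPhaseFilter(x, hp)
    dec <- vfcdmDecompose(xh, fs, spacing = spacing, ...)
    rec <- reconstructSignal(dec, band = band)
    env <- Mod(analyticSignal(rec))
    ncomp <- sum(dec@centerFreqs >= band[1] & dec@centerFreqs <= band[2])
  }
  env <- movingAverage(env, fs, windowS)
  new("SknaSeries", values = env, fs = fs, kind = "TVSKNA",
      provenance = list(band = band, highpass = highpass, windowS = windowS,
                        spacing = spacing, nComponents = ncomp))
})

#' @rdname computeTvskna
#' @export
setMethod("computeTvskna", "EcgRecording", function(x, ...) {
  s <- computeTvskna(x@samples, fs = x@fs, ...)
  s@provenance$subjectId <- x@subjectId
  s
})
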