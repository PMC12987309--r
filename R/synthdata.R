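## Synthetic recordings with the statistical structure the analysis assumes:
## template-train ECG, Poisson bursts of band-limited noise in the SKNA band,
## per-subject log-normal amplitude intercepts, interference tones.

#' Construct burst-process parameters
#'
#' @param burstRate burst arrivals per second, default 0.5.
#' @param burstDurationMean mean burst duration in seconds, default 0.35.
#' @param burstAmplitude burst envelope peak amplitude in microvolts,
#'   default 6.
#' @param bandLow,bandHigh carrier band in Hz, defaults 150 and 1000 (the
#'   SKNA band).
#' @param backgroundNoiseSd background band-limited noise SD in microvolts,
#'   default 1.
#' @return a \code{BurstParams} object.
#' @export
burstParams <- function(burstRate = 0.5, burstDurationMean = 0.35,
                        burstAmplitude = 6, bandLow = 150, bandHigh = 1000,
                        backgroundNoiseSd = 1) {
  new("BurstParams", burstRate = burstRate,
      burstDurationMean = burstDurationMean, burstAmplitude = burstAmplitude,
      bandLow = bandLow, bandHigh = bandHigh,
      backgroundNoiseSd = backgroundNoiseSd)
}

## One idealized P-QRS-T beat as a sum of Gaussians, evaluated at time tt
## (seconds) relative to beat onset, for a beat of length rr seconds.
## Smooth components only, so spectral energy stays well below 150 Hz.
.ecgBeat <- function(tt, rr) {
  ## center (fraction of beat), width (s), amplitude (uV)
  waves <- list(P = c(0.18, 0.025, 120), Q = c(0.295, 0.008, -150),
                R = c(0.32, 0.010, 1000), S = c(0.345, 0.008, -250),
                T = c(0.55, 0.060, 300))
  y <- numeric(length(tt))
  for (w in waves) y <- y + w[3] * exp(-0.5 * ((tt - w[1] * rr) / w[2])^2)
  y
}

#' Simulate a template-train ECG
#'
#' Repeating P-QRS-T morphology (sum of Gaussians) with small cycle-length
#' jitter. Dominant spectral energy lies below 150 Hz, so the SKNA filters
#' must be able to remove it.
#'
#' @param duration duration in seconds.
#' @param fs sampling rate in Hz (>= 2000).
#' @param heartRate heart rate in bpm (30-200).
#' @param seed optional integer seed; identical seeds give identical output.
#' @param jitterSd relative SD of per-cycle length jitter, default 0.02.
#' @return numeric vector of \code{duration * fs} samples (microvolts).
#' @examples
#' ecg <- simulateEcg(10, 10000, heartRate = 60, seed = 1)
#' length(ecg)   # 100000
#' @export
simulateEcg <- function(duration, fs, heartRate = 70, seed = NULL,
                        jitterSd = 0.02) {
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (fs < 2000) stop("fs must be >= 2000 Hz")
  if (heartRate < 30 || heartRate > 200) stop("heartRate must be in [30, 200] bpm")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration * fs)
  rrMean <- 60 / heartRate
  nBeats <- ceiling(duration / rrMean) + 2
  rr <- rrMean * pmax(0.7, 1 + jitterSd * rnorm(nBeats))
  onsets <- cumsum(c(0, rr[-nBeats]))
  y <- numeric(n)
  tAll <- (0:(n - 1)) / fs
  for (b in seq_len(nBeats)) {
    i0 <- floor(onsets[b] * fs) + 1
    i1 <- min(n, ceiling((onsets[b] + rr[b]) * fs))
    if (i0 > n) break
    idx <- i0:i1
    y[idx] <- y[idx] + .ecgBeat(tAll[idx] - onsets[b], rr[b])
  }
  y
}

## Band-limited unit-variance Gaussian noise (Kaiser FIR bandpass,
## delay-compensated single pass; normalized to SD 1).
.bandNoise <- function(n, fs, bandLow, bandHigh) {
  w <- rnorm(n)
  bp <- .designFirCached("bandpass", c(bandLow, bandHigh), fs,
                         stopbandAtten = 60,
                         transitionWidth = min(25, bandLow / 4))
  y <- .firZeroPhaseSinglePass(bp@taps, w)
  y / sd(y)
}

#' Simulate a sympathetic burst process
#'
#' Homogeneous-Poisson burst arrivals; the burst component is a continuous
#' band-limited Gaussian carrier multiplied by the sum of per-burst Hann
#' envelopes (unit peak, gamma-distributed durations) and scaled by
#' \code{params@burstAmplitude}; stationary band-limited background noise is
#' added on top. At a fixed seed the burst contribution scales exactly
#' linearly with the amplitude.
#'
#' @param duration duration in seconds.
#' @param fs sampling rate in Hz.
#' @param params a \code{BurstParams} object.
#' @param seed optional integer seed.
#' @return numeric vector of \code{duration * fs} samples (microvolts) with
#'   attribute \code{"burstOnsets"} (seconds).
#' @export
simulateBursts <- function(duration, fs, params, seed = NULL) {
  stopifnot(is(params, "BurstParams"))
  validObject(params)
  if (duration <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (params@bandHigh >= fs / 2) stop("carrier band exceeds Nyquist")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration * fs)
  out <- numeric(n)
  onsets <- numeric(0)
  if (params@burstRate > 0 && params@burstAmplitude > 0) {
    nb <- rpois(1, params@burstRate * duration)
    if (nb > 0) {
      starts <- sort(runif(nb, 0, duration))
      durs <- params@burstDurationMean * stats::rgamma(nb, shape = 4, rate = 4)
      durs <- pmax(durs, 20 / fs)
      E <- numeric(n)
      for (b in seq_len(nb)) {
        i0 <- floor(starts[b] * fs) + 1
        len <- max(3L, round(durs[b] * fs))
        i1 <- min(n, i0 + len - 1)
        if (i0 > n) next
        env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
        E[i0:i1] <- E[i0:i1] + env[seq_len(i1 - i0 + 1)]
      }
      carrier <- .bandNoise(n, fs, params@bandLow, params@bandHigh)
      out <- out + params@burstAmplitude * E * carrier
      onsets <- starts
    }
  }
  if (params@backgroundNoiseSd > 0) {
    out <- out + params@backgroundNoiseSd * .bandNoise(n, fs, params@bandLow,
                                                       params@bandHigh)
  }
  attr(out, "burstOnsets") <- onsets
  out
}

#' Simulate one annotated ECG recording
#'
#' Sum of a template-train ECG, a subject-scaled burst process and pure
#' interference tones, with non-overlapping task-event annotations.
#'
#' @param duration duration in seconds.
#' @param fs sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param events data.frame with columns \code{condition}, \code{start_s},
#'   \code{end_s} and optionally \code{vas}, \code{das}; events must not
#'   overlap.
#' @param burst a \code{BurstParams} object (already scaled for this subject
#'   and condition), or NULL for no bursts.
#' @param interferenceTones data.frame with columns \code{freq} (Hz) and
#'   \code{amplitude} (uV), or NULL.
#' @param heartRate heart rate in bpm.
#' @param seed optional integer seed.
#' @return an \code{EcgRecording}.
#' @export
simulateRecording <- function(duration, fs, subjectId = "S1",
                              events = data.frame(condition = character(),
                                                  start_s = numeric(),
                                                  end_s = numeric()),
                              burst = burstParams(), interferenceTones = NULL,
                              heartRate = 70, seed = NULL) {
  ok <- .validEvents(events, duration)
  if (!isTRUE(ok)) stop(ok)
  if (nrow(events) > 1) {
    ev <- events[order(events$start_s), ]
    if (any(ev$start_s[-1] < ev$end_s[-nrow(ev)] - 1e-9))
      stop("annotated events must not overlap")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- simulateEcg(duration, fs, heartRate = heartRate)
  if (!is.null(burst) && (burst@burstRate > 0 || burst@backgroundNoiseSd > 0))
    x <- x + as.numeric(simulateBursts(duration, fs, burst))
  if (!is.null(interferenceTones) && nrow(interferenceTones)) {
    t <- (0:(length(x) - 1)) / fs
    for (i in seq_len(nrow(interferenceTones)))
      x <- x + interferenceTones$amplitude[i] *
        sin(2 * pi * interferenceTones$freq[i] * t)
  }
  new("EcgRecording", samples = x, fs = fs, subjectId = as.character(subjectId),
      events = events)
}

#' Construct a synthetic study configuration
#'
#' The default layout mirrors a two-condition activation study: a no-pain
#' baseline (VAS fixed at 0) and a sympathetic-activation condition with
#' raised burst amplitude and rate and pain ratings drawn from a categorical
#' VAS distribution.
#'
#' @param nSubjects number of subjects, default 20.
#' @param conditions data.frame with columns \code{label},
#'   \code{amplitude_gain}, \code{rate_gain} and list-column \code{vas_probs}
#'   (length-11 probability vectors over VAS 0..10, or NULL).
#' @param segmentsPerCondition integer vector or list (one vector per
#'   condition) of per-subject segment counts; default 1 baseline and 3 task
#'   segments per subject.
#' @param segmentDuration segment duration in seconds, default 5.
#' @param subjectInterceptSd SD of the per-subject log-amplitude intercept,
#'   default 0.3.
#' @param interferenceTones data.frame (\code{freq}, \code{amplitude}) of
#'   tones added to every recording; default none.
#' @param fs acquisition sampling rate in Hz, default 10000.
#' @param heartRate heart rate in bpm, default 70.
#' @param burst baseline \code{BurstParams}.
#' @param gapDuration gap between task events in seconds, default 1.
#' @param seed integer seed, default 1.
#' @return a \code{StudyConfig}.
#' @export
studyConfig <- function(nSubjects = 20,
                        conditions = NULL,
                        segmentsPerCondition = NULL,
                        segmentDuration = 5,
                        subjectInterceptSd = 0.3,
                        interferenceTones = NULL,
                        fs = 10000, heartRate = 70,
                        burst = burstParams(),
                        gapDuration = 1, seed = 1) {
  if (is.null(conditions)) {
    conditions <- data.frame(label = c("baseline", "activation"),
                             amplitude_gain = c(1, 2.5),
                             rate_gain = c(1, 2))
    conditions$vas_probs <- list(
      c(1, rep(0, 10)),                                   # baseline: VAS 0
      c(0, 0, 0.05, 0.1, 0.2, 0.25, 0.2, 0.1, 0.06, 0.03, 0.01))
  }
  if (!"vas_probs" %in% names(conditions)) conditions$vas_probs <-
    rep(list(NULL), nrow(conditions))
  if (is.null(segmentsPerCondition))
    segmentsPerCondition <- ifelse(conditions$label == "baseline", 1L, 3L)
  if (!is.list(segmentsPerCondition))
    segmentsPerCondition <- as.list(segmentsPerCondition)
  if (is.null(interferenceTones))
    interferenceTones <- data.frame(freq = numeric(), amplitude = numeric())
  cfg <- new("StudyConfig", nSubjects = nSubjects, conditions = conditions,
             segmentsPerCondition = segmentsPerCondition,
             segmentDuration = segmentDuration,
             subjectInterceptSd = subjectInterceptSd,
             interferenceTones = interferenceTones, fs = fs,
             heartRate = heartRate, burst = burst, gapDuration = gapDuration,
             seed = seed)
  validObject(cfg)
  cfg
}

#' Canned study layouts for common activation protocols
#'
#' \code{"vm"}: 22 subjects, one 20 s baseline segment each and 90 task
#' segments total (4 per subject plus one extra for the first two subjects).
#' \code{"tg"}: 22 subjects, 5 s segments, baseline plus a low- and a
#' high-pain grill condition.
#'
#' @param layout \code{"vm"} or \code{"tg"}.
#' @param ... overrides passed on to \code{\link{studyConfig}}.
#' @return a \code{StudyConfig}.
#' @export
defaultStudyConfig <- function(layout = c("vm", "tg"), ...) {
  layout <- match.arg(layout)
  if (layout == "vm") {
    conditions <- data.frame(label = c("baseline", "VM"),
                             amplitude_gain = c(1, 2.5),
                             rate_gain = c(1, 2))
    conditions$vas_probs <- list(c(1, rep(0, 10)), NULL)
    perSubj <- c(rep(5L, 2), rep(4L, 20))        # 90 task segments over 22
    studyConfig(nSubjects = 22, conditions = conditions,
                segmentsPerCondition = list(rep(1L, 22), perSubj),
                segmentDuration = 20, ...)
  } else {
    conditions <- data.frame(label = c("baseline", "TG_low", "TG_high"),
                             amplitude_gain = c(1, 1.8, 2.5),
                             rate_gain = c(1, 1.5, 2))
    conditions$vas_probs <- list(
      c(1, rep(0, 10)),
      c(0, 0.05, 0.15, 0.2, 0.3, 0.2, 0.1, 0, 0, 0, 0),
      c(0, 0, 0, 0, 0.1, 0.15, 0.2, 0.25, 0.15, 0.1, 0.05))
    studyConfig(nSubjects = 22, conditions = conditions,
                segmentsPerCondition = c(1L, 3L, 3L),
                segmentDuration = 5, ...)
  }
}

.perSubjectCounts <- function(config, condIdx) {
  v <- config@segmentsPerCondition[[condIdx]]
  as.integer(rep_len(v, config@nSubjects))
}

#' Simulate a complete multi-subject study
#'
#' One recording per subject and condition. Task recordings contain
#' \code{segmentsPerCondition} annotated events of \code{segmentDuration}
#' seconds separated by \code{gapDuration}; baseline recordings are extended
#' so the mid-portion rule for baseline extraction applies. Per-subject
#' multiplicative amplitude intercepts are drawn log-normally
#' (\code{meanlog = 0}, \code{sdlog = subjectInterceptSd}); the truth slot
#' records gains, intercepts and seed, and the whole study is exactly
#' reproducible from (config, seed).
#'
#' @param config a \code{StudyConfig}.
#' @return a \code{SimulatedStudy}.
#' @export
simulateStudy <- function(config) {
  stopifnot(is(config, "StudyConfig"))
  validObject(config)
  set.seed(as.integer(config@seed))
  nS <- config@nSubjects
  intercepts <- if (config@subjectInterceptSd > 0)
    rlnorm(nS, 0, config@subjectInterceptSd) else rep(1, nS)
  names(intercepts) <- sprintf("S%02d", seq_len(nS))
  recs <- list()
  das <- round(runif(nS, 4, 20))          # per-subject anxiety score
  segDur <- config@segmentDuration
  gap <- config@gapDuration
  recSeeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                nS * nrow(config@conditions)),
                     nrow = nS)
  for (s in seq_len(nS)) {
    sid <- names(intercepts)[s]
    for (ci in seq_len(nrow(config@conditions))) {
      cond <- config@conditions$label[ci]
      nSeg <- .perSubjectCounts(config, ci)[s]
      if (nSeg < 1) next
      isBaseline <- cond == "baseline"
      lead <- if (isBaseline) segDur else gap   # pre-roll before first event
      starts <- lead + (seq_len(nSeg) - 1) * (segDur + gap)
      dur <- max(starts) + segDur + lead
      probs <- config@conditions$vas_probs[[ci]]
      vas <- if (is.null(probs)) rep(NA_real_, nSeg)
             else sample(0:10, nSeg, replace = TRUE, prob = probs)
      ev <- data.frame(condition = cond, start_s = starts,
                       end_s = starts + segDur, vas = vas, das = das[s])
      bp <- config@burst
      bp@burstAmplitude <- bp@burstAmplitude *
        config@conditions$amplitude_gain[ci] * intercepts[s]
      bp@burstRate <- bp@burstRate * config@conditions$rate_gain[ci]
      recs[[sprintf("%s.%s", sid, cond)]] <-
        simulateRecording(dur, config@fs, subjectId = sid, events = ev,
                          burst = bp,
                          interferenceTones = config@interferenceTones,
                          heartRate = config@heartRate,
                          seed = recSeeds[s, ci])
    }
  }
  truth <- list(conditionGains = config@conditions[, c("label", "amplitude_gain",
                                                       "rate_gain")],
                subjectIntercepts = intercepts, das = das,
                seed = config@seed)
  new("SimulatedStudy", recordings = recs, truth = truth, config = config)
}

#' Write / read a recording as CSV
#'
#' Two-column CSV (\code{time_s}, \code{ecg_uv}); annotations go to a
#' side-car CSV (\code{subject_id, condition, start_s, end_s, vas, das}).
#'
#' @param rec an \code{EcgRecording}.
#' @param path CSV path for the signal.
#' @param annotationPath optional side-car CSV path for the events.
#' @return \code{writeRecordingCsv}: \code{path}, invisibly.
#' @export
writeRecordingCsv <- function(rec, path, annotationPath = NULL) {
  stopifnot(is(rec, "EcgRecording"))
  df <- data.frame(time_s = (seq_along(rec@samples) - 1) / rec@fs,
                   ecg_uv = rec@samples)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(annotationPath)) {
    ev <- rec@events
    ev$subject_id <- rec@subjectId
    cols <- intersect(c("subject_id", "condition", "start_s", "end_s",
                        "vas", "das"), names(ev))
    write.csv(ev[, cols], annotationPath, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeRecordingCsv
#' @param path CSV path written by \code{writeRecordingCsv}.
#' @param subjectId subject identifier to attach on read.
#' @return \code{readRecordingCsv}: an \code{EcgRecording}.
#' @export
readRecordingCsv <- function(path, annotationPath = NULL, subjectId = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "ecg_uv") %in% names(df)))
    stop("recording CSV must have columns time_s, ecg_uv: ", path)
  fs <- round(1 / median(diff(df$time_s)))
  ev <- data.frame(condition = character(), start_s = numeric(),
                   end_s = numeric())
  sid <- if (is.null(subjectId)) "S1" else subjectId
  if (!is.null(annotationPath)) {
    ann <- read.csv(annotationPath)
    if ("subject_id" %in% names(ann) && is.null(subjectId))
      sid <- as.character(ann$subject_id[1])
    ev <- ann[, setdiff(names(ann), "subject_id"), drop = FALSE]
  }
  new("EcgRecording", samples = df$ecg_uv, fs = fs, subjectId = sid,
      events = ev)
}
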