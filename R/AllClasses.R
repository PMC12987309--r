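#' @import methods
#' @importFrom stats sd var median rnorm runif rpois rlnorm fft filter aov
#'   p.adjust pnorm qnorm qt pt anova lm coef convolve nextn rbinom quantile
#'   predict spec.pgram approx
#' @importFrom utils head tail read.csv write.csv modifyList
#' @useDynLib sknatools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Central containers. Events travel as a plain data.frame with columns
## condition, start_s, end_s, vas, das (vas/das may be NA).

.validEvents <- function(events, duration = NULL) {
  need <- c("condition", "start_s", "end_s")
  if (!is.data.frame(events)) return("events must be a data.frame")
  if (!all(need %in% names(events)))
    return(sprintf("events must have columns %s", paste(need, collapse = ", ")))
  if (nrow(events)) {
    if (any(events$start_s >= events$end_s)) return("event start_s must be < end_s")
    if (!is.null(duration) &&
        (any(events$start_s < 0) || any(events$end_s > duration + 1e-9)))
      return("events must lie within [0, duration]")
    if ("vas" %in% names(events)) {
      v <- events$vas[!is.na(events$vas)]
      if (length(v) && (any(v < 0) || any(v > 10))) return("vas must be in [0, 10]")
    }
    if ("das" %in% names(events)) {
      d <- events$das[!is.na(events$das)]
      if (length(d) && (any(d < 4) || any(d > 20))) return("das must be in [4, 20]")
    }
  }
  TRUE
}

#' EcgRecording: a raw single-channel ECG trace
#'
#' Holds a microvolt-scale sample vector, its sampling rate, the subject
#' identifier and task-event annotations (condition label, start/end time,
#' optional VAS pain and DAS anxiety scores).
#'
#' @slot samples numeric vector of samples in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot events data.frame with columns \code{condition}, \code{start_s},
#'   \code{end_s} and optionally \code{vas} (0-10) and \code{das} (4-20).
#' @exportClass EcgRecording
setClass("EcgRecording",
  representation(samples = "numeric", fs = "numeric",
                 subjectId = "character", events = "data.frame"),
  validity = function(object) {
    if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a single positive number")
    if (any(!is.finite(object@samples))) return("all samples must be finite")
    .validEvents(object@events, duration = length(object@samples) / object@fs)
  })

#' SknaSeries: an extracted SKNA envelope
#'
#' Non-negative envelope time series derived from one recording, either the
#' integrated SKNA (neuECG; 500-1000 Hz) or the time-varying SKNA
#' (VFCDM-reconstructed 160-1120 Hz Hilbert amplitude), both smoothed with a
#' 100 ms moving average.
#'
#' @slot values numeric envelope, microvolt scale, same length as the input.
#' @slot fs sampling rate in Hz.
#' @slot kind \code{"iSKNA"} or \code{"TVSKNA"}.
#' @slot provenance named list of processing parameters.
#' @exportClass SknaSeries
setClass("SknaSeries",
  representation(values = "numeric", fs = "numeric",
                 kind = "character", provenance = "list"),
  validity = function(object) {
    if (!object@kind %in% c("iSKNA", "TVSKNA")) return("kind must be iSKNA or TVSKNA")
    if (length(object@fs) != 1L || object@fs <= 0) return("fs must be positive")
    if (any(object@values < -1e-9, na.rm = TRUE)) return("values must be non-negative")
    TRUE
  })

#' TFDecomposition: VFCDM time-frequency decomposition
#'
#' Complex analytic components at fixed center-frequency spacing produced by
#' variable frequency complex demodulation. Summing the real parts of the
#' components reconstructs the band-limited input.
#'
#' @slot centerFreqs center frequencies in Hz (strictly increasing).
#' @slot components complex matrix, one column per center frequency.
#' @slot fs sampling rate in Hz.
#' @slot lpfBandwidth first-stage low-pass bandwidth in Hz.
#' @exportClass TFDecomposition
setClass("TFDecomposition",
  representation(centerFreqs = "numeric", components = "matrix",
                 fs = "numeric", lpfBandwidth = "numeric"),
  validity = function(object) {
    cf <- object@centerFreqs
    if (length(cf) && any(diff(cf) <= 0)) return("centerFreqs must be strictly increasing")
    if (length(cf) && any(cf >= object@fs / 2)) return("centerFreqs must be below Nyquist")
    if (ncol(object@components) != length(cf))
      return("one component column per center frequency")
    TRUE
  })

#' Segment: a fixed-duration condition-labelled SKNA excerpt
#'
#' The unit of analysis: a fixed-length excerpt of a processed SKNA series
#' with its subject, condition and (optional) VAS / DAS annotations.
#'
#' @slot values numeric sample vector.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot condition condition label.
#' @slot signal signal kind, \code{"iSKNA"} or \code{"TVSKNA"}.
#' @slot segmentId segment identifier, unique within a study.
#' @slot vas VAS pain score 0-10, or NA.
#' @slot das DAS anxiety score 4-20, or NA.
#' @exportClass Segment
setClass("Segment",
  representation(values = "numeric", fs = "numeric", subjectId = "character",
                 condition = "character", signal = "character",
                 segmentId = "character", vas = "numeric", das = "numeric"),
  prototype(vas = NA_real_, das = NA_real_),
  validity = function(object) {
    if (length(object@fs) != 1L || object@fs <= 0) return("fs must be positive")
    if (!length(object@values)) return("segment must be non-empty")
    TRUE
  })

#' BurstParams: parameters of the synthetic sympathetic burst process
#'
#' Describes a homogeneous-Poisson train of band-limited noise bursts riding
#' on stationary band-limited background noise, emulating intermittent
#' postganglionic sympathetic discharges in the 150-1000 Hz SKNA band.
#'
#' @slot burstRate burst arrivals per second (Poisson rate).
#' @slot burstDurationMean mean burst duration in seconds.
#' @slot burstAmplitude envelope peak amplitude in microvolts.
#' @slot bandLow,bandHigh carrier band edges in Hz.
#' @slot backgroundNoiseSd standard deviation of the background noise (uV).
#' @exportClass BurstParams
setClass("BurstParams",
  representation(burstRate = "numeric", burstDurationMean = "numeric",
                 burstAmplitude = "numeric", bandLow = "numeric",
                 bandHigh = "numeric", backgroundNoiseSd = "numeric"),
  validity = function(object) {
    if (object@burstRate < 0) return("burstRate must be >= 0")
    if (object@burstDurationMean < 0 || object@burstAmplitude < 0 ||
        object@backgroundNoiseSd < 0)
      return("durations and amplitudes must be >= 0")
    if (!(object@bandLow > 0 && object@bandHigh > object@bandLow))
      return("need 0 < bandLow < bandHigh")
    TRUE
  })

#' StudyConfig: layout of a synthetic multi-subject study
#'
#' @slot nSubjects number of subjects (>= 2 for any mixed-model analysis).
#' @slot conditions data.frame with columns \code{label},
#'   \code{amplitude_gain}, \code{rate_gain} and a list-column \code{vas_probs}
#'   (probabilities over VAS 0..10; may be NULL for conditions without pain
#'   ratings).
#' @slot segmentsPerCondition integer vector (recycled over subjects) or a
#'   list, one integer vector per condition, giving per-subject segment counts.
#' @slot segmentDuration segment duration in seconds.
#' @slot subjectInterceptSd SD of the log-normal per-subject amplitude factor
#'   (on the log scale), as a fraction of baseline amplitude.
#' @slot interferenceTones data.frame with columns \code{freq} (Hz),
#'   \code{amplitude} (uV).
#' @slot fs acquisition sampling rate in Hz.
#' @slot heartRate heart rate in bpm used for the ECG template train.
#' @slot burst baseline \code{BurstParams}.
#' @slot gapDuration silent gap between consecutive task events, seconds.
#' @slot seed integer seed.
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(nSubjects = "numeric", conditions = "data.frame",
                 segmentsPerCondition = "list", segmentDuration = "numeric",
                 subjectInterceptSd = "numeric", interferenceTones = "data.frame",
                 fs = "numeric", heartRate = "numeric", burst = "BurstParams",
                 gapDuration = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@nSubjects < 2) return("nSubjects must be >= 2")
    cd <- object@conditions
    if (!all(c("label", "amplitude_gain", "rate_gain") %in% names(cd)))
      return("conditions needs label, amplitude_gain, rate_gain")
    if (any(cd$amplitude_gain <= 0) || any(cd$rate_gain <= 0))
      return("condition gains must be > 0")
    ns <- object@segmentDuration * object@fs
    if (abs(ns - round(ns)) > 1e-9)
      return("segmentDuration * fs must be an integer number of samples")
    if (length(object@segmentsPerCondition) != nrow(cd))
      return("one segmentsPerCondition entry per condition")
    TRUE
  })

#' SimulatedStudy: a generated multi-subject dataset plus ground truth
#'
#' @slot recordings list of \code{EcgRecording} (one per subject x condition).
#' @slot truth list with per-condition gains, per-subject intercepts, seed.
#' @slot config the \code{StudyConfig} used.
#' @exportClass SimulatedStudy
setClass("SimulatedStudy",
  representation(recordings = "list", truth = "list", config = "StudyConfig"))

#' FirSpec: a designed linear-phase FIR filter
#'
#' @slot kind \code{"bandpass"}, \code{"highpass"} or \code{"lowpass"}.
#' @slot edges passband edge frequencies in Hz.
#' @slot fs design sampling rate in Hz.
#' @slot stopbandAtten target stopband attenuation in dB.
#' @slot transitionWidth transition width in Hz.
#' @slot taps symmetric (linear-phase) coefficient vector.
#' @slot realizedAtten measured minimum stopband attenuation in dB.
#' @exportClass FirSpec
setClass("FirSpec",
  representation(kind = "character", edges = "numeric", fs = "numeric",
                 stopbandAtten = "numeric", transitionWidth = "numeric",
                 taps = "numeric", realizedAtten = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("bandpass", "highpass", "lowpass"))
      return("kind must be bandpass/highpass/lowpass")
    n <- length(object@taps)
    if (n && max(abs(object@taps - rev(object@taps))) > 1e-12)
      return("taps must be symmetric (linear phase)")
    TRUE
  })

#' InterferenceReport: narrowband interference detected by PSD analysis
#'
#' Frequencies whose Welch-PSD peak prominence exceeds the threshold in every
#' provided condition (condition-independent artifacts).
#'
#' @slot detectedFreqs detected frequencies in Hz.
#' @slot peakProminenceDb minimum (across conditions) prominence per frequency.
#' @slot conditionsPresentIn condition labels searched.
#' @slot binWidth PSD bin width in Hz.
#' @exportClass InterferenceReport
setClass("InterferenceReport",
  representation(detectedFreqs = "numeric", peakProminenceDb = "numeric",
                 conditionsPresentIn = "character", binWidth = "numeric"))

#' LmmFit: a fitted random-intercept mixed model for one SKNA index
#'
#' @slot model the underlying \code{lmerMod} fit (REML, random intercept for
#'   subject).
#' @slot anovaTable data.frame: omnibus ANOVA with Satterthwaite df.
#' @slot varianceComponents named numeric: \code{sigma2_subject},
#'   \code{sigma2_residual}.
#' @slot fixedEffects data.frame of estimates and SEs.
#' @slot converged,singular logical flags.
#' @slot formulaKind which model formula was fitted.
#' @exportClass LmmFit
setClass("LmmFit",
  representation(model = "ANY", anovaTable = "data.frame",
                 varianceComponents = "numeric", fixedEffects = "data.frame",
                 converged = "logical", singular = "logical",
                 formulaKind = "character"))

#' RocResult: segment-level ROC analysis of one index
#'
#' @slot auc area under the ROC curve (Mann-Whitney, ties 0.5).
#' @slot ciLow,ciHigh 95 percent DeLong confidence bounds.
#' @slot orientation label of the class treated as class 1 (the condition with
#'   the higher mean index value).
#' @slot nPos,nNeg class sizes.
#' @slot se DeLong standard error of the AUC.
#' @exportClass RocResult
setClass("RocResult",
  representation(auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 orientation = "character", nPos = "numeric", nNeg = "numeric",
                 se = "numeric"),
  validity = function(object) {
    if (object@auc < 0 || object@auc > 1) return("auc must be in [0, 1]")
    TRUE
  })

#' StatsReport: full statistical report of one pipeline run
#'
#' @slot features the tidy feature table (one row per segment x signal x index
#'   x parameter setting).
#' @slot models named list of \code{LmmFit} (one per signal x index).
#' @slot contrasts data.frame of Tukey-adjusted pairwise contrasts with
#'   Cohen's d and confidence intervals.
#' @slot roc data.frame of segment-level AUC results.
#' @slot rmcorr data.frame of repeated-measures correlations with VAS.
#' @slot audit list: filter specs, interference reports, segment counts.
#' @slot config the run configuration (fully serializable).
#' @slot seed integer seed of the run.
#' @exportClass StatsReport
setClass("StatsReport",
  representation(features = "data.frame", models = "list",
                 contrasts = "data.frame", roc = "data.frame",
                 rmcorr = "data.frame", audit = "list", config = "list",
                 seed = "numeric"))
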