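#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers: \code{samples()}
#' returns the raw sample vector, \code{samplingRate()} the sampling rate in
#' Hz, \code{taskEvents()} the annotation data.frame, \code{subjectId()} the
#' subject identifier, \code{sknaValues()}/\code{sknaKind()} the envelope and
#' its kind, \code{centerFreqs()}/\code{components()} the VFCDM grid, and
#' \code{firTaps()} the coefficient vector of a designed filter.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the corresponding slot value.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("taskEvents", function(x) standardGeneric("taskEvents"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("sknaValues", function(x) standardGeneric("sknaValues"))
#' @rdname accessors
#' @export
setGeneric("sknaKind", function(x) standardGeneric("sknaKind"))
#' @rdname accessors
#' @export
setGeneric("centerFreqs", function(x) standardGeneric("centerFreqs"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("firTaps", function(x) standardGeneric("firTaps"))
#' @rdname accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname accessors
#' @export
setGeneric("studyTruth", function(x) standardGeneric("studyTruth"))

#' Compute the integrated SKNA envelope (neuECG)
#'
#' Bandpass (default 500-1000 Hz, Kaiser-window FIR, 60 dB stopband, applied
#' zero-phase), full-wave rectification, then a 100 ms moving average.
#'
#' @param x numeric sample vector or an \code{EcgRecording} (already at the
#'   analysis rate).
#' @param fs sampling rate in Hz (ignored for \code{EcgRecording}).
#' @param band bandpass edges in Hz, default \code{c(500, 1000)}.
#' @param windowS smoothing window in seconds, default 0.1.
#' @param ... passed to methods.
#' @return an \code{SknaSeries} of kind \code{"iSKNA"}.
#' @export
setGeneric("computeIskna", function(x, ...) standardGeneric("computeIskna"))

#' Compute the time-varying SKNA envelope (VFCDM-based)
#'
#' 150 Hz highpass, VFCDM decomposition at 160 Hz component spacing, summation
#' of components with centers inside the target band (default 160-1120 Hz),
#' Hilbert instantaneous amplitude, then a 100 ms moving average.
#'
#' @param x numeric sample vector or an \code{EcgRecording} (already at the
#'   analysis rate).
#' @param fs sampling rate in Hz (ignored for \code{EcgRecording}).
#' @param band component-center band in Hz, default \code{c(160, 1120)}.
#' @param highpass highpass edge in Hz, default 150.
#' @param windowS smoothing window in seconds, default 0.1.
#' @param ... passed to methods.
#' @return an \code{SknaSeries} of kind \code{"TVSKNA"}.
#' @export
setGeneric("computeTvskna", function(x, ...) standardGeneric("computeTvskna"))
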