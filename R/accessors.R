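#' @rdname accessors
#' @export
setMethod("samples", "EcgRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EcgRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SknaSeries", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Segment", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TFDecomposition", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("taskEvents", "EcgRecording", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("subjectId", "EcgRecording", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "Segment", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("sknaValues", "SknaSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("sknaValues", "Segment", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("sknaKind", "SknaSeries", function(x) x@kind)
#' @rdname accessors
#' @export
setMethod("sknaKind", "Segment", function(x) x@signal)
#' @rdname accessors
#' @export
setMethod("centerFreqs", "TFDecomposition", function(x) x@centerFreqs)
#' @rdname accessors
#' @export
setMethod("components", "TFDecomposition", function(x) x@components)
#' @rdname accessors
#' @export
setMethod("firTaps", "FirSpec", function(x) x@taps)
#' @rdname accessors
#' @export
setMethod("recordings", "SimulatedStudy", function(x) x@recordings)
#' @rdname accessors
#' @export
setMethod("studyTruth", "SimulatedStudy", function(x) x@truth)

setMethod("show", "EcgRecording", function(object) {
  cat(sprintf("EcgRecording: subject %s, %.1f s @ %g Hz, %d event(s)\n",
              object@subjectId, length(object@samples) / object@fs,
              object@fs, nrow(object@events)))
})

setMethod("show", "SknaSeries", function(object) {
  cat(sprintf("SknaSeries (%s): %.1f s @ %g Hz, mean %.3g uV\n",
              object@kind, length(object@values) / object@fs, object@fs,
              mean(object@values)))
})

setMethod("show", "TFDecomposition", function(object) {
  cat(sprintf("TFDecomposition: %d components at %g-%g Hz @ %g Hz, LPF %g Hz\n",
              length(object@centerFreqs), min(object@centerFreqs),
              max(object@centerFreqs), object@fs, object@lpfBandwidth))
})

setMethod("show", "Segment", function(object) {
  cat(sprintf("Segment %s (%s, %s): subject %s, %.1f s @ %g Hz, VAS %s\n",
              object@segmentId, object@signal, object@condition,
              object@subjectId, length(object@values) / object@fs, object@fs,
              ifelse(is.na(object@vas), "-", format(object@vas))))
})

setMethod("show", "FirSpec", function(object) {
  cat(sprintf("FirSpec %s [%s] Hz @ %g Hz: %d taps, %g dB target, %.1f dB realized\n",
              object@kind, paste(object@edges, collapse = "-"), object@fs,
              length(object@taps), object@stopbandAtten, object@realizedAtten))
})

setMethod("show", "InterferenceReport", function(object) {
  if (!length(object@detectedFreqs)) {
    cat("InterferenceReport: no condition-independent narrowband interference\n")
  } else {
    cat(sprintf("InterferenceReport: %s Hz (prominence %s dB) across %s\n",
                paste(round(object@detectedFreqs, 2), collapse = ", "),
                paste(round(object@peakProminenceDb, 1), collapse = ", "),
                paste(object@conditionsPresentIn, collapse = "/")))
  }
})

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: %d subjects x %d conditions (%d recordings), seed %d\n",
              object@config@nSubjects, nrow(object@config@conditions),
              length(object@recordings), as.integer(object@truth$seed)))
})

setMethod("show", "LmmFit", function(object) {
  cat(sprintf("LmmFit (%s): converged=%s singular=%s\n", object@formulaKind,
              object@converged, object@singular))
  cat(sprintf("  sigma2_subject=%.4g sigma2_residual=%.4g\n",
              object@varianceComponents[["sigma2_subject"]],
              object@varianceComponents[["sigma2_residual"]]))
  print(object@anovaTable)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC %.3f (95%% CI %.3f-%.3f), class 1 = %s (n=%d vs %d)\n",
              object@auc, object@ciLow, object@ciHigh, object@orientation,
              object@nPos, object@nNeg))
})

setMethod("show", "StatsReport", function(object) {
  cat(sprintf("StatsReport: %d feature rows, %d model(s), %d contrast row(s), %d ROC row(s), seed %d\n",
              nrow(object@features), length(object@models),
              nrow(object@contrasts), nrow(object@roc),
              as.integer(object@seed)))
})
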