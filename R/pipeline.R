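## Orchestration: configuration, preprocessing, SKNA extraction, feature
## computation and the statistical report, tied together deterministically.

#' Build a pipeline run configuration
#'
#' Collects every tunable constant of the analysis in one serializable list.
#' Defaults follow the established SKNA processing conventions: acquisition
#' at 10 kHz, analysis at 4 kHz, iSKNA band 500-1000 Hz, TVSKNA band
#' 160-1120 Hz above a 150 Hz highpass, 100 ms smoothing, entropy at m = 2,
#' r = 0.2 x SD.
#'
#' @param simulation a \code{StudyConfig} describing the synthetic study to
#'   generate (required; file-based input can be assembled with
#'   \code{\link{readRecordingCsv}} and the stage functions directly).
#' @param fsAnalysis analysis sampling rate in Hz, default 4000.
#' @param isknaBand iSKNA bandpass edges, default \code{c(500, 1000)}.
#' @param tvsknaBand TVSKNA component band, default \code{c(160, 1120)}.
#' @param highpass TVSKNA highpass edge in Hz, default 150.
#' @param windowS smoothing window in seconds, default 0.1.
#' @param signals signal kinds to compute, subset of
#'   \code{c("iSKNA", "TVSKNA")}.
#' @param indices feature indices to compute, default all six.
#' @param grid \code{"default"}, \code{"sensitivity"}, or a data.frame with
#'   columns \code{m}, \code{r_coeff}.
#' @param notch list: \code{auto} (detect interference per subject),
#'   \code{freqs} (manual notch list, overrides detection), \code{Q},
#'   \code{prominenceDb}.
#' @param gateP omnibus significance gate for post hoc contrasts.
#' @param seed integer seed for the run (overrides the simulation seed).
#' @return a named list of class-free configuration values.
#' @export
runConfig <- function(simulation = studyConfig(),
                      fsAnalysis = 4000,
                      isknaBand = c(500, 1000),
                      tvsknaBand = c(160, 1120),
                      highpass = 150,
                      windowS = 0.1,
                      signals = c("iSKNA", "TVSKNA"),
                      indices = c("ApEn", "SampEn", "Mobility", "Complexity",
                                  "KFD", "SD"),
                      grid = "default",
                      notch = list(auto = FALSE, freqs = numeric(), Q = 30,
                                   prominenceDb = 12),
                      gateP = 0.05,
                      seed = 1) {
  if (is.character(grid))
    grid <- switch(match.arg(grid, c("default", "sensitivity")),
                   default = entropyGrid(), sensitivity = sensitivityGrid())
  stopifnot(all(c("m", "r_coeff") %in% names(grid)))
  if (any(c(isknaBand, tvsknaBand, highpass) >= fsAnalysis / 2))
    stop("all bands must lie below the analysis Nyquist frequency")
  notch <- modifyList(list(auto = FALSE, freqs = numeric(), Q = 30,
                           prominenceDb = 12), notch)
  list(simulation = simulation, fsAnalysis = fsAnalysis,
       isknaBand = isknaBand, tvsknaBand = tvsknaBand, highpass = highpass,
       windowS = windowS, signals = match.arg(signals,
                                              c("iSKNA", "TVSKNA"),
                                              several.ok = TRUE),
       indices = indices, grid = grid, notch = notch, gateP = gateP,
       seed = seed)
}

#' Preprocess a recording for SKNA analysis
#'
#' Polyphase downsampling to the analysis rate followed by zero-phase notch
#' removal of the listed interference frequencies.
#'
#' @param rec an \code{EcgRecording}.
#' @param fsTarget analysis sampling rate in Hz.
#' @param notchFreqs interference frequencies to remove (Hz).
#' @param Q notch quality factor, default 30.
#' @return an \code{EcgRecording} at \code{fsTarget}.
#' @export
preprocessRecording <- function(rec, fsTarget = 4000, notchFreqs = numeric(),
                                Q = 30) {
  stopifnot(is(rec, "EcgRecording"))
  x <- rec@samples
  if (rec@fs != fsTarget) x <- resamplePoly(x, rec@fs, fsTarget)
  for (f0 in notchFreqs) x <- notchFilter(x, fsTarget, f0, Q = Q)
  new("EcgRecording", samples = x, fs = fsTarget, subjectId = rec@subjectId,
      events = rec@events)
}

.sknaForKind <- function(rec, kind, config) {
  if (kind == "iSKNA")
    computeIskna(rec, band = config$isknaBand, windowS = config$windowS)
  else
    computeTvskna(rec, band = config$tvsknaBand, highpass = config$highpass,
                  windowS = config$windowS)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Simulation, preprocessing (downsampling and interference removal), iSKNA /
#' TVSKNA extraction, segment extraction, feature computation, and the
#' statistical layer (random-intercept mixed model with Tukey-adjusted
#' contrasts and Cohen's d per index, segment-level DeLong ROC per condition
#' pair, repeated-measures correlation with VAS). Identical (config, seed)
#' yields an identical report.
#'
#' @param config a list from \code{\link{runConfig}}.
#' @return a \code{StatsReport}.
#' @export
runPipeline <- function(config) {
  simCfg <- config$simulation
  simCfg@seed <- config$seed
  study <- simulateStudy(simCfg)
  audit <- list(segmentCounts = NULL, filters = list(), interference = list())

  ## interference handling: manual list wins; otherwise optional per-subject
  ## detection on conditions-by-subject pooled spectra
  notchBySubject <- list()
  subjects <- unique(vapply(study@recordings, slot, "", "subjectId"))
  for (sid in subjects) notchBySubject[[sid]] <- config$notch$freqs
  if (config$notch$auto && !length(config$notch$freqs)) {
    for (sid in subjects) {
      recs <- Filter(function(r) r@subjectId == sid, study@recordings)
      byCond <- lapply(recs, slot, "samples")
      names(byCond) <- vapply(recs, function(r) r@events$condition[1], "")
      rep <- tryCatch(detectInterference(byCond, simCfg@fs,
                                         config$notch$prominenceDb),
                      error = function(e) NULL)
      if (!is.null(rep)) {
        notchBySubject[[sid]] <- rep@detectedFreqs
        audit$interference[[sid]] <- rep
      }
    }
  }

  segments <- list()
  for (rec in study@recordings) {
    pre <- preprocessRecording(rec, config$fsAnalysis,
                               notchFreqs = notchBySubject[[rec@subjectId]],
                               Q = config$notch$Q)
    for (kind in config$signals) {
      skna <- .sknaForKind(pre, kind, config)
      segs <- extractSegments(skna, pre@events, simCfg@segmentDuration,
                              subjectId = rec@subjectId)
      segments <- c(segments, segs)
    }
  }
  features <- computeFeatures(segments, grid = config$grid,
                              indices = config$indices)
  condLevels <- simCfg@conditions$label
  features$condition <- factor(features$condition, levels = condLevels)
  audit$segmentCounts <- as.data.frame(table(
    condition = features$condition[features$index == features$index[1] &
                                   features$signal == features$signal[1]]))
  for (key in ls(.firCache))
    audit$filters[[key]] <- .firCache[[key]]@realizedAtten

  models <- list(); contrasts <- list(); rocRows <- list(); rmRows <- list()
  firstGrid <- config$grid[1, ]
  for (kind in unique(features$signal)) {
    for (idx in unique(features$index)) {
      sub <- features[features$signal == kind & features$index == idx, ]
      if (idx %in% c("ApEn", "SampEn"))
        subMain <- sub[sub$m == firstGrid$m & sub$r_coeff == firstGrid$r_coeff, ]
      else subMain <- sub
      key <- paste(kind, idx, sep = ".")
      fit <- tryCatch(fitSknaLmm(subMain, "condition"),
                      error = function(e) NULL)
      if (is.null(fit)) next
      models[[key]] <- fit
      ct <- if (fit@converged) posthocContrasts(fit, gateP = config$gateP)
            else data.frame()
      d <- if (fit@converged) lmmCohensD(fit) else data.frame()
      if (nrow(ct) && nrow(d)) {
        m <- merge(ct, d, by = "contrast")
        m$signal <- kind; m$index <- idx
        m$omnibus_p <- .omnibusP(fit)
        contrasts[[key]] <- m
      }
      if (idx %in% c("ApEn", "SampEn") && nrow(config$grid) > 1) {
        gfit <- tryCatch(fitSknaLmm(sub, "entropy_grid"),
                         error = function(e) NULL)
        if (!is.null(gfit)) models[[paste0(key, ".grid")]] <- gfit
      }
      cl <- levels(droplevels(subMain$condition))
      if (length(cl) >= 2) {
        prs <- utils::combn(cl, 2, simplify = FALSE)
        for (pr in prs) {
          s2 <- subMain[subMain$condition %in% pr & !is.na(subMain$value), ]
          roc <- tryCatch(aucDeLong(s2$value, as.character(s2$condition)),
                          error = function(e) NULL)
          if (!is.null(roc))
            rocRows[[length(rocRows) + 1]] <- data.frame(
              signal = kind, index = idx, pair = paste(pr, collapse = " vs "),
              auc = roc@auc, ci_low = roc@ciLow, ci_high = roc@ciHigh,
              class1 = roc@orientation, n_pos = roc@nPos, n_neg = roc@nNeg)
        }
      }
      hasVas <- !is.na(subMain$value) & !is.na(.vasOf(subMain))
      if (sum(hasVas) > 3) {
        rc <- rmCorr(subMain$subject_id[hasVas], .vasOf(subMain)[hasVas],
                     subMain$value[hasVas])
        rmRows[[length(rmRows) + 1]] <- data.frame(
          signal = kind, index = idx, r = rc$r, ci_low = rc$ci_low,
          ci_high = rc$ci_high, df = rc$df, p = rc$p)
      }
    }
  }
  serializableCfg <- config
  serializableCfg$simulation <- .configAsList(simCfg)
  new("StatsReport", features = features, models = models,
      contrasts = if (length(contrasts)) do.call(rbind, contrasts)
                  else data.frame(),
      roc = if (length(rocRows)) do.call(rbind, rocRows) else data.frame(),
      rmcorr = if (length(rmRows)) do.call(rbind, rmRows) else data.frame(),
      audit = audit, config = serializableCfg, seed = config$seed)
}

## VAS is carried through the feature table via the pain group; recover the
## numeric score from the segment annotations stored alongside
.vasOf <- function(sub) {
  if ("vas" %in% names(sub)) return(sub$vas)
  rep(NA_real_, nrow(sub))
}

.configAsList <- function(simCfg) {
  list(nSubjects = simCfg@nSubjects,
       conditions = simCfg@conditions[, c("label", "amplitude_gain",
                                          "rate_gain")],
       segmentsPerCondition = simCfg@segmentsPerCondition,
       segmentDuration = simCfg@segmentDuration,
       subjectInterceptSd = simCfg@subjectInterceptSd,
       fs = simCfg@fs, heartRate = simCfg@heartRate,
       burst = list(rate = simCfg@burst@burstRate,
                    durationMean = simCfg@burst@burstDurationMean,
                    amplitude = simCfg@burst@burstAmplitude,
                    band = c(simCfg@burst@bandLow, simCfg@burst@bandHigh),
                    backgroundNoiseSd = simCfg@burst@backgroundNoiseSd),
       interferenceTones = simCfg@interferenceTones,
       gapDuration = simCfg@gapDuration, seed = simCfg@seed)
}

#' Write a statistical report to disk
#'
#' JSON summary (contrasts, ROC, repeated-measures correlations, audit,
#' config, seed) plus tidy CSV tables.
#'
#' @param report a \code{StatsReport}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeStatsReport <- function(report, dir) {
  stopifnot(is(report, "StatsReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(report@features, file.path(dir, "features.csv"))
  if (nrow(report@contrasts))
    write.csv(report@contrasts, file.path(dir, "contrasts.csv"),
              row.names = FALSE)
  if (nrow(report@roc))
    write.csv(report@roc, file.path(dir, "roc.csv"), row.names = FALSE)
  if (nrow(report@rmcorr))
    write.csv(report@rmcorr, file.path(dir, "rmcorr.csv"), row.names = FALSE)
  js <- list(seed = report@seed,
             config = report@config[setdiff(names(report@config),
                                            c("simulation", "grid"))],
             simulation = report@config$simulation,
             grid = report@config$grid,
             audit = list(filters = report@audit$filters,
                          segmentCounts = report@audit$segmentCounts),
             contrasts = report@contrasts, roc = report@roc,
             rmcorr = report@rmcorr)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, dataframe = "rows")
  invisible(dir)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: a configuration list (see
#'   \code{\link{runConfig}}).
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$simulation
  sim <- if (is.null(simArgs)) studyConfig() else {
    conds <- if (!is.null(simArgs$conditions))
      do.call(rbind, lapply(simArgs$conditions, function(cc)
        data.frame(label = cc$label, amplitude_gain = cc$amplitude_gain,
                   rate_gain = cc$rate_gain))) else NULL
    if (!is.null(conds))
      conds$vas_probs <- lapply(simArgs$conditions, function(cc)
        if (is.null(cc$vas_probs)) NULL else as.numeric(cc$vas_probs))
    do.call(studyConfig, c(
      list(conditions = conds),
      simArgs[intersect(names(simArgs),
                        c("nSubjects", "segmentsPerCondition",
                          "segmentDuration", "subjectInterceptSd", "fs",
                          "heartRate", "gapDuration", "seed"))]))
  }
  args <- y[intersect(names(y), c("fsAnalysis", "isknaBand", "tvsknaBand",
                                  "highpass", "windowS", "signals", "indices",
                                  "grid", "notch", "gateP", "seed"))]
  for (nm in c("isknaBand", "tvsknaBand"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(args[[nm]])
  do.call(runConfig, c(list(simulation = sim), args))
}
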