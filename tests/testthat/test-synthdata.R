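test_that("simulated ECG has the requested length, beat count and spectrum", {
  ecg <- simulateEcg(10, 10000, heartRate = 60, seed = 1)
  expect_length(ecg, 100000)

  ecg60 <- simulateEcg(60, 10000, heartRate = 60, seed = 2)
  peaks <- which(diff(sign(diff(ecg60))) == -2) + 1
  peaks <- peaks[ecg60[peaks] > 500]          # R-wave amplitude threshold
  expect_true(abs(length(peaks) - 60) <= 2)

  expect_lt(1 - powerFraction(ecg60, 10000, 0, 150), 0.05)

  expect_error(simulateEcg(-1, 10000), "positive")
  expect_error(simulateEcg(10, 1000), "2000")
})

test_that("burst process is linear in amplitude, band-confined and seeded", {
  p0 <- burstParams(burstRate = 0, backgroundNoiseSd = 0)
  expect_true(all(as.numeric(simulateBursts(2, 4000, p0, seed = 1)) == 0))

  p1 <- burstParams(burstAmplitude = 3, backgroundNoiseSd = 0)
  p2 <- burstParams(burstAmplitude = 6, backgroundNoiseSd = 0)
  b1 <- as.numeric(simulateBursts(5, 4000, p1, seed = 3))
  b2 <- as.numeric(simulateBursts(5, 4000, p2, seed = 3))
  expect_identical(2 * b1, b2)

  pb <- burstParams(burstRate = 1, burstAmplitude = 5, backgroundNoiseSd = 1)
  bb <- as.numeric(simulateBursts(20, 4000, pb, seed = 4))
  expect_gt(powerFraction(bb, 4000, 150, 1000), 0.95)

  expect_identical(simulateBursts(3, 4000, pb, seed = 9),
                   simulateBursts(3, 4000, pb, seed = 9))

  bad <- burstParams(bandHigh = 3000)
  expect_error(simulateBursts(1, 4000, bad), "Nyquist")
})

test_that("recordings are additive, annotated and reproducible", {
  ev <- data.frame(condition = "task", start_s = 2, end_s = 7, vas = 5, das = 10)
  quiet <- burstParams(burstRate = 0, backgroundNoiseSd = 0)
  rec <- simulateRecording(10, 10000, events = ev, burst = quiet, seed = 5)
  expect_identical(samples(rec), simulateEcg(10, 10000, seed = 5))

  tone <- simulateRecording(20, 10000, events = ev, burst = quiet,
                            interferenceTones = data.frame(freq = 60,
                                                           amplitude = 20),
                            seed = 5)
  p <- welchPsd(samples(tone), 10000)
  i60 <- which.min(abs(p$freq - 60))
  local <- 10 * log10(p$psd[i60] / median(p$psd[abs(p$freq - 60) < 30]))
  expect_gt(local, 12)

  r1 <- simulateRecording(5, 10000, events = ev[0, ], seed = 7)
  r2 <- simulateRecording(5, 10000, events = ev[0, ], seed = 7)
  expect_identical(samples(r1), samples(r2))

  overlap <- data.frame(condition = c("a", "b"), start_s = c(1, 3),
                        end_s = c(4, 6))
  expect_error(simulateRecording(10, 10000, events = overlap), "overlap")
  outside <- data.frame(condition = "a", start_s = 8, end_s = 12)
  expect_error(simulateRecording(10, 10000, events = outside), "within")
})

test_that("study layout follows the configured per-subject segment counts", {
  cfg <- defaultStudyConfig("vm", fs = 4000)
  counts <- sknatools:::.perSubjectCounts(cfg, 2)
  expect_identical(sum(sknatools:::.perSubjectCounts(cfg, 1)), 22L)
  expect_identical(sum(counts), 90L)
  expect_identical(cfg@segmentDuration, 20)

  small <- studyConfig(nSubjects = 2, segmentsPerCondition = c(1L, 2L),
                       segmentDuration = 1, fs = 4000,
                       burst = burstParams(burstRate = 2))
  st <- simulateStudy(small)
  expect_length(recordings(st), 4)
  evs <- do.call(rbind, lapply(recordings(st), taskEvents))
  expect_identical(sum(evs$condition == "baseline"), 2L)
  expect_identical(sum(evs$condition == "activation"), 4L)
  expect_true(all(evs$vas[evs$condition == "baseline"] == 0))
  expect_identical(studyTruth(st)$seed, small@seed)

  flat <- studyConfig(nSubjects = 3, subjectInterceptSd = 0,
                      segmentDuration = 1, fs = 4000)
  expect_true(all(studyTruth(simulateStudy(flat))$subjectIntercepts == 1))
})

test_that("higher amplitude gain raises the burst-channel segment SD", {
  ## noiseless burst channel, amplitude gain 2.5 vs 1.0, many seeded draws
  p1 <- burstParams(burstRate = 2, burstAmplitude = 5, backgroundNoiseSd = 0)
  p2 <- burstParams(burstRate = 2, burstAmplitude = 12.5,
                    backgroundNoiseSd = 0)
  wins <- 0L
  for (s in 1:25) {
    sdA <- sd(as.numeric(simulateBursts(5, 4000, p1, seed = 100 + s)))
    sdB <- sd(as.numeric(simulateBursts(5, 4000, p2, seed = 200 + s)))
    wins <- wins + (sdB > sdA)
  }
  expect_gte(wins, 24L)
})

test_that("recording CSV round-trips with annotations", {
  ev <- data.frame(condition = "task", start_s = 0.2, end_s = 0.8, vas = 6,
                   das = 16)
  rec <- simulateRecording(1, 4000, subjectId = "S07", events = ev, seed = 3)
  f <- tempfile(fileext = ".csv"); fa <- tempfile(fileext = ".csv")
  writeRecordingCsv(rec, f, fa)
  back <- readRecordingCsv(f, fa)
  expect_identical(samplingRate(back), 4000)
  expect_identical(subjectId(back), "S07")
  expect_equal(samples(back), samples(rec), tolerance = 1e-12)
  expect_equal(taskEvents(back)$vas, 6)
  unlink(c(f, fa))
})
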