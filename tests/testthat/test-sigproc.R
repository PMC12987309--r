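test_that("polyphase resampler preserves the passband and kills images", {
  t <- (0:99999) / 1e4
  expect_length(resamplePoly(sin(2 * pi * 100 * t), 1e4, 4e3), 40000)

  dc <- resamplePoly(rep(2.5, 1e5), 1e4, 4e3)
  expect_lt(max(abs(dc[2001:38000] - 2.5)), 1e-6)

  tone <- resamplePoly(sin(2 * pi * 100 * t), 1e4, 4e3)
  expect_lt(abs(toneAmplitude(tone[2001:38000], 4000, 100) - 1), 0.01)

  hi <- resamplePoly(sin(2 * pi * 2200 * t), 1e4, 4e3)
  residual <- max(Mod(fft(hi[2001:38000]))) / (36000 / 2)
  expect_lt(20 * log10(residual), -60)

  expect_error(resamplePoly(t, 10000.5, 4000), "integral")
})

test_that("Kaiser FIR designs meet the attenuation spec and are symmetric", {
  bp <- designFir("bandpass", c(500, 1000), 4000)
  expect_gte(bp@realizedAtten, 60)
  expect_lte(20 * log10(Mod(firResponse(bp, 250))), -60)
  expect_gte(20 * log10(Mod(firResponse(bp, 750))), -1)
  expect_identical(firTaps(bp), rev(firTaps(bp)))

  hp <- designFir("highpass", 150, 4000)
  expect_lte(20 * log10(Mod(firResponse(hp, 50))), -60)
  expect_gte(hp@realizedAtten, 60)

  expect_error(designFir("bandpass", c(500, 2100), 4000), "inside")
  expect_error(designFir("highpass", 10, 4000, transitionWidth = 50), "fit")
})

test_that("zero-phase filtering has zero lag and squared attenuation", {
  bp <- designFir("bandpass", c(500, 1000), 4000)
  n <- 8000
  imp <- numeric(n); k <- 4000L; imp[k] <- 1
  y <- zeroPhaseFilter(imp, bp)
  expect_identical(which.max(abs(y)), k)
  win <- 300
  expect_equal(y[(k - win):(k - 1)], rev(y[(k + 1):(k + win)]),
               tolerance = 1e-9)

  t <- (0:(n - 1)) / 4000
  xs <- sin(2 * pi * 750 * t)
  ys <- zeroPhaseFilter(xs, bp)
  expect_identical(peakXcorrLag(xs[2000:6000], ys[2000:6000]), 0L)

  xstop <- sin(2 * pi * 200 * t)
  ystop <- zeroPhaseFilter(xstop, bp)
  att <- 20 * log10(max(abs(ystop[3000:5000])))
  expect_lt(att, -120)

  expect_error(zeroPhaseFilter(rnorm(100), bp), "too short")
})

test_that("notch removes its tone, preserves DC and has the right bandwidth", {
  fs <- 4000
  t <- (0:39999) / fs
  x <- sin(2 * pi * 60 * t)
  y <- notchFilter(x, fs, 60, Q = 30)
  expect_lt(sd(y[10000:30000]) / sd(x), 0.03)

  expect_lt(max(abs(notchFilter(rep(1.25, 20000), fs, 60) - 1.25)), 1e-6)

  ## -3 dB bandwidth of the single-pass biquad ~ f0 / Q = 2 Hz
  w0 <- 2 * pi * 60 / fs; alpha <- sin(w0) / (2 * 30)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  H <- function(f) {
    z <- exp(-2i * pi * f / fs)
    (b[1] + b[2] * z + b[3] * z^2) / (1 + a[2] * z + a[3] * z^2)
  }
  fgrid <- seq(55, 65, by = 0.01)
  mag <- Mod(vapply(fgrid, H, complex(1)))
  bw <- diff(range(fgrid[mag <= 1 / sqrt(2)]))
  expect_equal(bw, 2, tolerance = 0.1)

  far <- notchFilter(sin(2 * pi * 80 * t), fs, 60, Q = 30)
  expect_gt(sd(far[10000:30000]) / sd(x), 10^(-1 / 20))

  expect_error(notchFilter(x, fs, 2500), "inside")
})

test_that("interference detection requires presence in every condition", {
  fs <- 4000
  set.seed(11)
  t <- (0:59999) / fs
  mk <- function(toneAmp) rnorm(60000) + toneAmp * sin(2 * pi * 60 * t)
  both <- detectInterference(list(baseline = mk(2), task = mk(2)), fs)
  expect_length(both@detectedFreqs, 1)
  expect_lt(abs(both@detectedFreqs - 60), 2 * both@binWidth)

  onlyTask <- detectInterference(list(baseline = mk(0), task = mk(2)), fs)
  expect_length(onlyTask@detectedFreqs, 0)

  none <- detectInterference(list(baseline = mk(0), task = mk(0)), fs)
  expect_length(none@detectedFreqs, 0)

  expect_error(detectInterference(list(), fs), "non-empty")
})

test_that("analytic signal recovers amplitude and quadrature phase", {
  t <- (0:9999) / 1000
  z <- analyticSignal(3 * cos(2 * pi * 50 * t))
  expect_equal(Mod(z)[500:9500], rep(3, 9001), tolerance = 1e-3)
  expect_equal(Re(z), 3 * cos(2 * pi * 50 * t), tolerance = 1e-10)
})
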