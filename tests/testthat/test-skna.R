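test_that("moving average matches its definition and a brute-force oracle", {
  expect_identical(movingAverage(rep(3, 100), 100, 0.1), rep(3, 100))

  fs <- 100; W <- 10
  imp <- numeric(50); imp[25] <- 1
  y <- movingAverage(imp, fs, W / fs)
  expect_equal(sum(y > 0), W)
  expect_equal(max(y), 1 / W)
  expect_equal(sum(y), 1)

  set.seed(5)
  x <- rnorm(200)
  yv <- movingAverage(x, 100, 0.07)
  Wb <- 7; l <- (Wb - 1) %/% 2; r <- Wb - 1 - l
  xe <- c(x[l:1], x, x[200:(200 - r + 1)])
  oracle <- vapply(seq_along(x), function(i) mean(xe[i:(i + Wb - 1)]),
                   numeric(1))
  expect_equal(yv, oracle, tolerance = 1e-12)

  expect_error(movingAverage(rnorm(5), 100, 1), "longer")
})

test_that("iSKNA rectifies a steady tone to its analytic mean level", {
  fs <- 4000
  expect_identical(sknaValues(computeIskna(numeric(20000), fs)),
                   numeric(20000))

  A <- 2
  x <- A * sin(2 * pi * 750 * (0:39999) / fs)
  env <- sknaValues(computeIskna(x, fs))[5000:35000]
  expect_equal(mean(env), 2 * A / pi, tolerance = 0.02)

  expect_error(computeIskna(rnorm(10000), fs = 1500), "twice|2000")
})

test_that("iSKNA peaks align with synthetic burst times", {
  fs <- 4000
  t <- (0:(8 * fs - 1)) / fs
  centers <- seq(1, 7, by = 0.6)
  x <- numeric(length(t))
  for (cc in centers) {
    idx <- which(abs(t - cc) <= 0.05)
    x[idx] <- x[idx] + sin(2 * pi * 700 * t[idx]) *
      (0.5 + 0.5 * cos(pi * (t[idx] - cc) / 0.05))
  }
  env <- sknaValues(computeIskna(x, fs))
  for (cc in centers) {
    win <- which(abs(t - cc) <= 0.3)
    peakT <- t[win[which.max(env[win])]]
    expect_lt(abs(peakT - cc), 0.05)
  }
})

test_that("VFCDM localizes tones and reconstructs band-limited noise", {
  fs <- 4000
  z <- vfcdmDecompose(numeric(20000), fs)
  expect_true(all(Mod(components(z)) == 0))
  expect_identical(centerFreqs(z), 160 * (1:12))

  tt <- (0:39999) / fs
  d5 <- vfcdmDecompose(sin(2 * pi * 500 * tt), fs)
  en <- colSums(Mod(components(d5)[4000:36000, ])^2)
  expect_gt(en[centerFreqs(d5) == 480] / sum(en), 0.90)

  set.seed(7)
  bp <- designFir("bandpass", c(160, 1120), fs, transitionWidth = 40)
  xn <- zeroPhaseFilter(rnorm(60000), bp)
  rec <- reconstructSignal(vfcdmDecompose(xn, fs))
  int <- 4000:56000
  relErr <- sqrt(mean((xn[int] - rec[int])^2)) / sqrt(mean(xn[int]^2))
  expect_lte(relErr, 0.05)

  expect_error(vfcdmDecompose(rnorm(100), fs), "short")
  expect_error(vfcdmDecompose(rnorm(20000), fs, spacing = 2500), "0, fs/2")
})

test_that("TVSKNA tracks an AM envelope and rejects sub-highpass tones", {
  fs <- 4000
  expect_identical(sknaValues(computeTvskna(numeric(20000), fs)),
                   numeric(20000))

  tt <- (0:39999) / fs
  modu <- 1 + 0.8 * sin(2 * pi * 2 * tt)
  tv <- computeTvskna(modu * sin(2 * pi * 600 * tt), fs)
  int <- 4000:36000
  expect_gte(cor(sknaValues(tv)[int], modu[int]), 0.95)

  low <- computeTvskna(sin(2 * pi * 60 * tt), fs)
  expect_lt(mean(sknaValues(low)[int]), 0.01 * sqrt(0.5))
})

test_that("SKNA envelopes are non-negative, reject QRS and scale with bursts", {
  fs4 <- 4000
  ecg <- resamplePoly(simulateEcg(12, 10000, seed = 3), 10000, 4000)
  quietI <- sknaValues(computeIskna(ecg, fs4))
  quietT <- sknaValues(computeTvskna(ecg, fs4))
  expect_true(all(quietI >= 0) && all(quietT >= 0))

  means <- matrix(0, 3, 2)
  for (g in 1:3) {
    amp <- c(6, 12, 24)[g]
    pb <- burstParams(burstRate = 1, burstAmplitude = amp,
                      backgroundNoiseSd = 1)
    xb <- ecg + as.numeric(simulateBursts(12, fs4, pb, seed = 21))
    means[g, 1] <- mean(sknaValues(computeIskna(xb, fs4)))
    means[g, 2] <- mean(sknaValues(computeTvskna(xb, fs4)))
  }
  ## QRS rejection: envelope of pure ECG under 5% of the with-bursts level
  expect_lt(mean(quietI), 0.05 * means[1, 1])
  expect_lt(mean(quietT), 0.05 * means[1, 2])
  ## monotone response to burst amplitude at fixed seed
  expect_true(all(diff(means[, 1]) > 0))
  expect_true(all(diff(means[, 2]) > 0))
})
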