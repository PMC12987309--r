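.mkSeries <- function(values, fs, kind = "iSKNA", subj = "S1")
  new("SknaSeries", values = values, fs = fs, kind = kind,
      provenance = list(subjectId = subj))

.mkSegment <- function(values, fs = 100, kind = "iSKNA", cond = "baseline",
                       vas = NA_real_, das = NA_real_, id = "s1")
  new("Segment", values = values, fs = fs, subjectId = "S1", condition = cond,
      signal = kind, segmentId = id, vas = vas, das = das)

test_that("segment extraction yields exact lengths and the mid-baseline rule", {
  fs <- 4000
  s <- .mkSeries(abs(rnorm(130 * fs)), fs)
  ev5 <- data.frame(condition = "task", start_s = 2, end_s = 7, vas = 5)
  expect_length(sknaValues(extractSegments(s, ev5, 5)[[1]]), 20000)

  ev20 <- data.frame(condition = "task", start_s = 10, end_s = 30, vas = 5)
  expect_length(sknaValues(extractSegments(s, ev20, 20)[[1]]), 80000)

  base <- data.frame(condition = "baseline", start_s = 0, end_s = 120, vas = 0)
  seg <- extractSegments(s, base, 10)[[1]]
  expect_identical(sknaValues(seg),
                   sknaValues(s)[(55 * fs + 1):(65 * fs)])

  evBad <- data.frame(condition = "task", start_s = 128, end_s = 133, vas = 5)
  expect_error(extractSegments(s, evBad, 5), "bounds")
})

test_that("entropies match the brute-force oracles across the parameter grid", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(300)
    for (m in 2:3) for (rc in c(0.15, 0.2, 0.25)) {
      r <- rc * sd(x)
      expect_lt(abs(apEn(x, m, rc) - bruteApEn(x, m, r)), 1e-10)
      se <- sampEn(x, m, rc)
      ref <- bruteSampEn(x, m, r)
      if (is.finite(ref)) expect_lt(abs(se - ref), 1e-10)
      else expect_true(is.na(se))   # no matches: both sides undefined
    }
  }
})

test_that("entropies order regular below irregular signals", {
  set.seed(3)
  n <- 1500
  periodic <- rep(c(1, -1), n / 2)
  noise <- rnorm(n)
  expect_lt(apEn(periodic), apEn(noise))

  tt <- seq_len(2000)
  sine <- sin(2 * pi * tt / 40)     # 40 samples per cycle
  wn <- rnorm(2000)
  expect_lt(sampEn(sine), 0.3 * sampEn(wn))
  expect_gte(sampEn(wn), 0)
})

test_that("entropy conventions: constants, affine invariance, missing flags", {
  cst <- rep(2, 50)
  expect_identical(as.numeric(apEn(cst)), 0)
  expect_true(attr(apEn(cst), "degenerate"))
  expect_true(is.na(sampEn(cst)))

  set.seed(9)
  x <- rnorm(200)
  expect_equal(apEn(3 * x + 7), apEn(x), tolerance = 1e-12)
  expect_equal(sampEn(3 * x + 7), sampEn(x), tolerance = 1e-12)
})

test_that("Hjorth parameters hit analytic limits and scale invariance", {
  tt <- (0:199999) / 1000
  hs <- hjorthParams(sin(2 * pi * 5 * tt))
  expect_equal(hs$mobility, 2 * sin(pi * 5 / 1000), tolerance = 0.01)
  expect_equal(hs$complexity, 1, tolerance = 0.01)

  set.seed(2)
  wn <- rnorm(100000)
  hw <- hjorthParams(wn)
  expect_equal(hw$mobility, sqrt(2), tolerance = 0.02)
  expect_equal(hw$complexity, sqrt(1.5), tolerance = 0.02)

  h1 <- hjorthParams(wn[1:5000]); h2 <- hjorthParams(5 * wn[1:5000])
  expect_equal(h1$mobility, h2$mobility, tolerance = 1e-12)
  expect_equal(h1$complexity, h2$complexity, tolerance = 1e-12)

  expect_true(is.na(hjorthParams(rep(1, 10))$mobility))
})

test_that("Katz fractal dimension: lines, oracle agreement, noise ordering", {
  for (b in c(-2, 0, 0.5, 10))
    expect_equal(katzFd(3 + b * (1:500)), 1, tolerance = 1e-9)

  set.seed(8)
  walk <- cumsum(rnorm(2000))
  expect_equal(katzFd(walk), bruteKfd(walk), tolerance = 1e-12)

  tt <- seq_len(4000)
  sine <- sin(2 * pi * tt / 100)
  expect_lt(katzFd(sine), katzFd(sine + rnorm(4000, 0, 1)))

  expect_equal(katzFd(rep(4, 10)), 1)   # constant = zero-slope line

  ## point-count variant differs negligibly at segment lengths
  expect_equal(katzFd(walk, "points"), katzFd(walk, "steps"),
               tolerance = 1e-3)
})

test_that("segment SD matches hand computation and is homogeneous", {
  expect_equal(segmentSd(c(1, 2, 3, 4, 5)), sqrt(2.5), tolerance = 1e-12)
  expect_identical(segmentSd(rep(7, 10)), 0)
  set.seed(1); x <- rnorm(100)
  expect_equal(segmentSd(-3 * x), 3 * segmentSd(x), tolerance = 1e-12)
})

test_that("feature table has one row per segment/kind/index/setting", {
  set.seed(12)
  segs <- list(.mkSegment(rnorm(400), vas = 0, das = 10),
               .mkSegment(rnorm(400), kind = "TVSKNA", vas = 0, das = 10))
  ft <- computeFeatures(segs)
  expect_identical(nrow(ft), 12L)        # 6 indices x 2 kinds
  expect_setequal(unique(ft$index),
                  c("ApEn", "SampEn", "Mobility", "Complexity", "KFD", "SD"))
  expect_true(all(ft$pain_group == "NP"))
  expect_true(all(ft$anxiety_group == "NSA"))

  fts <- computeFeatures(segs[1], grid = sensitivityGrid())
  expect_identical(sum(fts$index == "ApEn"), 6L)
  expect_identical(sum(fts$index == "SampEn"), 6L)
  expect_identical(nrow(fts), 16L)       # 2 x 6 entropy + 4 others

  expect_identical(computeFeatures(segs), ft)

  bad <- list(.mkSegment(rnorm(400)), .mkSegment(rnorm(300)))
  expect_error(computeFeatures(bad), "uniform")
})
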