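.simLmmData <- function(nS, nRep, effect, sdS, sdE, seed) {
  set.seed(seed)
  subj <- rep(sprintf("S%02d", 1:nS), each = 2 * nRep)
  cond <- rep(rep(c("A", "B"), each = nRep), nS)
  b <- rep(rnorm(nS, 0, sdS), each = 2 * nRep)
  data.frame(value = 1 + effect * (cond == "B") + b +
               rnorm(length(b), 0, sdE),
             condition = cond, subject_id = subj)
}

test_that("pain and anxiety grouping follow the clinical thresholds", {
  expect_identical(as.character(assignPainGroup(c(0, 3, 4, 10))),
                   c("NP", "CSP-", "CSP+", "CSP+"))
  expect_identical(as.character(assignAnxietyGroup(c(14, 15, 20))),
                   c("NSA", "SA", "SA"))
  expect_error(assignPainGroup(11), "0, 10")
  expect_error(assignAnxietyGroup(3), "4, 20")
})

test_that("REML variance components match balanced closed-form estimators", {
  d <- .simLmmData(12, 8, 0.5, 0.6, 0.9, seed = 10)
  fit <- fitSknaLmm(d, "condition")
  aov2 <- stats::anova(lm(value ~ condition + subject_id, d))
  msS <- aov2["subject_id", "Mean Sq"]; msE <- aov2["Residuals", "Mean Sq"]
  expect_equal(fit@varianceComponents[["sigma2_subject"]], (msS - msE) / 16,
               tolerance = 1e-6)
  expect_equal(fit@varianceComponents[["sigma2_residual"]], msE,
               tolerance = 1e-6)
})

test_that("degenerate random effects collapse to OLS", {
  ## zero between-subject variability: every subject sees identical data
  set.seed(20)
  one <- data.frame(value = rnorm(12) + 0.4 * rep(0:1, each = 6),
                    condition = rep(c("A", "B"), each = 6))
  d0 <- do.call(rbind, lapply(sprintf("S%02d", 1:8), function(s)
    cbind(one, subject_id = s)))
  f0 <- suppressMessages(suppressWarnings(fitSknaLmm(d0, "condition")))
  expect_lt(f0@varianceComponents[["sigma2_subject"]],
            1e-6 * sum(f0@varianceComponents))

  ## one observation per subject: fixed effects equal OLS
  set.seed(21)
  d1 <- data.frame(value = rnorm(14), condition = rep(c("A", "B"), 7),
                   subject_id = sprintf("S%02d", 1:14))
  f1 <- suppressMessages(suppressWarnings(fitSknaLmm(d1, "condition")))
  ols <- coef(lm(value ~ condition, d1))
  expect_equal(f1@fixedEffects$Estimate, as.numeric(ols), tolerance = 1e-8)
})

test_that("post hoc contrasts honor the omnibus gate and Tukey dominance", {
  dSig <- .simLmmData(10, 6, 1.5, 0.3, 0.8, seed = 30)
  dSig3 <- rbind(dSig, within(dSig[dSig$condition == "A", ],
                              condition <- "C"))
  fit3 <- fitSknaLmm(dSig3, "condition")
  ct <- posthocContrasts(fit3)
  expect_identical(nrow(ct), 3L)          # 3 conditions -> 3 pairs
  expect_true(attr(ct, "gatePassed"))

  fit2 <- fitSknaLmm(dSig, "condition")
  expect_identical(nrow(posthocContrasts(fit2)), 1L)

  em <- emmeans::emmeans(fit3@model, ~condition, lmer.df = "satterthwaite")
  raw <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))$p.value
  expect_true(all(ct$p.value >= raw - 1e-12))

  dNull <- .simLmmData(10, 6, 0, 0.3, 0.8, seed = 31)
  ctNull <- posthocContrasts(fitSknaLmm(dNull, "condition"))
  expect_identical(nrow(ctNull), 0L)
  expect_false(attr(ctNull, "gatePassed"))
})

test_that("Cohen's d is zero for identical conditions and labelled sensibly", {
  set.seed(40)
  half <- data.frame(value = rnorm(30), condition = "A",
                     subject_id = rep(sprintf("S%d", 1:10), 3))
  dup <- rbind(half, within(half, condition <- "B"))
  fit <- fitSknaLmm(dup, "condition")
  d0 <- lmmCohensD(fit)
  expect_equal(d0$d, 0, tolerance = 1e-10)

  dBig <- .simLmmData(14, 6, 2.6, 0.4, 0.9, seed = 41)
  dd <- lmmCohensD(fitSknaLmm(dBig, "condition"))
  expect_identical(dd$magnitude, "huge")
  expect_true(dd$ci_low <= dd$d && dd$d <= dd$ci_high)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_identical(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  set.seed(50)
  p <- runif(20)
  a <- fdrAdjust(p)
  expect_true(all(a >= p))
  expect_identical(order(a[order(p)]), seq_len(20))  # order-preserving
  expect_error(fdrAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("AUC equals pair counting and is monotone-transform invariant", {
  expect_equal(aucDeLong(c(3, 4, 1, 2), c("x", "x", "y", "y"))@auc, 1)
  expect_equal(aucDeLong(c(1, 3, 2, 4), rep(c("one", "zero"), each = 2),
                         class1 = "one")@auc, 0.25)

  set.seed(60)
  for (i in 1:25) {
    v <- round(rnorm(40), 1)              # rounded -> ties occur
    lab <- rep(c("a", "b"), each = 20)
    r <- aucDeLong(v, lab, class1 = "b")
    expect_equal(r@auc, bruteAuc(v[21:40], v[1:20]), tolerance = 1e-12)
    rMono <- aucDeLong(exp(2 * v), lab, class1 = "b")
    expect_equal(rMono@auc, r@auc, tolerance = 1e-12)
  }

  expect_error(aucDeLong(1:4, rep("a", 4)), "two classes")
})

test_that("DeLong CI and paired test agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  v <- rnorm(80); lab <- rep(c("a", "b"), each = 40)
  v[lab == "b"] <- v[lab == "b"] + 0.8
  mine <- aucDeLong(v, lab, class1 = "b")
  ref <- pROC::roc(response = lab, predictor = v, levels = c("a", "b"),
                   direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(mine@auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(c(mine@ciLow, mine@ciHigh), as.numeric(ci)[c(1, 3)],
               tolerance = 1e-9)

  w <- v + rnorm(80, 0, 0.6)
  mineT <- deLongTest(v, w, lab, class1 = "b")
  refT <- pROC::roc.test(
    pROC::roc(lab, v, levels = c("a", "b"), direction = "<", quiet = TRUE),
    pROC::roc(lab, w, levels = c("a", "b"), direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(mineT$p, as.numeric(refT$p.value), tolerance = 1e-9)

  expect_equal(deLongTest(v, v, lab, class1 = "b")$p, 1)
  swap <- deLongTest(w, v, lab, class1 = "b")
  expect_equal(swap$statistic, -mineT$statistic, tolerance = 1e-12)
  expect_equal(swap$p, mineT$p, tolerance = 1e-12)
  expect_error(deLongTest(v, w[-1], lab[-1]), "same cases")
})

test_that("repeated-measures correlation nails its limiting cases", {
  s <- rep(c("a", "b"), each = 5)
  xv <- c(1:5, 1:5); yv <- c(1:5 + 10, 1:5 - 3)
  expect_equal(rmCorr(s, xv, yv)$r, 1, tolerance = 1e-12)

  set.seed(70)
  xx <- rnorm(25); yy <- 0.5 * xx + rnorm(25, 0, 0.8)
  rc <- rmCorr(rep("solo", 25), xx, yy)
  ct <- cor.test(xx, yy)
  expect_equal(rc$r, as.numeric(ct$estimate), tolerance = 1e-10)
  expect_equal(rc$p, ct$p.value, tolerance = 1e-10)
  expect_equal(c(rc$ci_low, rc$ci_high), as.numeric(ct$conf.int),
               tolerance = 1e-6)

  ## negative within-subject slope is recovered with high probability
  hits <- 0L
  for (i in 1:40) {
    set.seed(700 + i)
    subj <- rep(sprintf("P%d", 1:6), each = 6)
    off <- rep(rnorm(6, 0, 3), each = 6)
    xg <- rnorm(36)
    yg <- off - 0.7 * xg + rnorm(36, 0, 0.6)
    hits <- hits + (rmCorr(subj, xg, yg)$r < 0)
  }
  expect_gte(hits, 38L)

  expect_true(is.na(rmCorr(c("a", "a"), c(1, 2), c(1, 2))$r))
})
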