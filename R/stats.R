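## Segment-level statistics: group assignment, random-intercept mixed models,
## Tukey-adjusted contrasts, Cohen's d, FDR, DeLong ROC, repeated-measures
## correlation.

#' Assign VAS-based pain groups
#'
#' \code{NP} (no pain, VAS = 0), \code{CSP-} (clinically non-significant,
#' 0 < VAS < 4), \code{CSP+} (clinically significant, VAS >= 4).
#'
#' @param vas numeric VAS scores in [0, 10].
#' @return factor with levels \code{NP}, \code{CSP-}, \code{CSP+}.
#' @examples
#' assignPainGroup(c(0, 3, 4, 10))
#' @export
assignPainGroup <- function(vas) {
  if (any(is.na(vas)) || any(vas < 0) || any(vas > 10))
    stop("vas must lie in [0, 10]")
  factor(ifelse(vas == 0, "NP", ifelse(vas < 4, "CSP-", "CSP+")),
         levels = c("NP", "CSP-", "CSP+"))
}

#' Assign DAS-based anxiety groups
#'
#' \code{SA} (severe anxiety, total score >= 15) versus \code{NSA}.
#'
#' @param das numeric DAS total scores in [4, 20].
#' @return factor with levels \code{NSA}, \code{SA}.
#' @export
assignAnxietyGroup <- function(das) {
  if (any(is.na(das)) || any(das < 4) || any(das > 20))
    stop("das must lie in [4, 20]")
  factor(ifelse(das >= 15, "SA", "NSA"), levels = c("NSA", "SA"))
}

#' Fit a random-intercept linear mixed model for one SKNA index
#'
#' REML fit of \code{value ~ condition + (1 | subject_id)} (or the sex/age
#' and entropy-grid variants) with Satterthwaite degrees of freedom for the
#' omnibus analysis-of-variance table. Random-intercept structure only;
#' singular fits are flagged, not refitted.
#'
#' @param features feature-table subset (one index, one signal kind) with
#'   columns \code{value}, \code{condition}, \code{subject_id}, plus
#'   \code{sex}/\code{age} or \code{m}/\code{r_coeff} as required by
#'   \code{formulaKind}.
#' @param formulaKind \code{"condition"} (value ~ condition),
#'   \code{"condition_sex_age"} (condition x sex + age) or
#'   \code{"entropy_grid"} (condition x m x r).
#' @return an \code{LmmFit}.
#' @export
fitSknaLmm <- function(features,
                       formulaKind = c("condition", "condition_sex_age",
                                       "entropy_grid")) {
  formulaKind <- match.arg(formulaKind)
  need <- c("value", "condition", "subject_id",
            switch(formulaKind, condition = NULL,
                   condition_sex_age = c("sex", "age"),
                   entropy_grid = c("m", "r_coeff")))
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  d <- features[!is.na(features$value), , drop = FALSE]
  if (length(unique(d$subject_id)) < 2) stop("need >= 2 subjects")
  if (length(unique(d$condition)) < 2) stop("need >= 2 conditions")
  d$condition <- factor(d$condition)
  d$subject_id <- factor(d$subject_id)
  form <- switch(formulaKind,
    condition = value ~ condition + (1 | subject_id),
    condition_sex_age = value ~ condition * sex + age + (1 | subject_id),
    entropy_grid = value ~ condition * factor(m) * factor(r_coeff) +
      (1 | subject_id))
  fit <- lmerTest::lmer(form, data = d, REML = TRUE,
                        control = lme4::lmerControl(
                          check.nobs.vs.nlev = "ignore",
                          check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2s <- vc$vcov[vc$grp == "subject_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  an <- as.data.frame(stats::anova(fit))  # lmerTest: Satterthwaite type III
  an$term <- rownames(an)
  fe <- as.data.frame(summary(fit)$coefficients)
  fe$term <- rownames(fe)
  msgs <- fit@optinfo$conv$lme4$messages
  new("LmmFit", model = fit, anovaTable = an,
      varianceComponents = c(sigma2_subject = s2s, sigma2_residual = s2e),
      fixedEffects = fe,
      converged = is.null(msgs) || !length(msgs),
      singular = lme4::isSingular(fit), formulaKind = formulaKind)
}

.omnibusP <- function(fit) {
  an <- fit@anovaTable
  row <- grep("^condition$", an$term)
  if (!length(row)) row <- 1L
  an[["Pr(>F)"]][row]
}

#' Tukey-adjusted pairwise condition contrasts
#'
#' Estimated-marginal-mean contrasts over all condition pairs with
#' studentized-range (Tukey) adjustment, computed only when the omnibus
#' analysis of variance is significant at \code{gateP}; otherwise an empty
#' table with attribute \code{gatePassed = FALSE} is returned.
#'
#' @param fit an \code{LmmFit} (converged).
#' @param gateP omnibus significance gate, default 0.05.
#' @return data.frame with columns \code{contrast, estimate, SE, df,
#'   t.ratio, p.value} (Tukey-adjusted p), attribute \code{gatePassed}.
#' @export
posthocContrasts <- function(fit, gateP = 0.05) {
  stopifnot(is(fit, "LmmFit"))
  if (!fit@converged) stop("contrasts require a converged fit")
  empty <- data.frame(contrast = character(), estimate = numeric(),
                      SE = numeric(), df = numeric(), t.ratio = numeric(),
                      p.value = numeric())
  if (.omnibusP(fit) >= gateP)
    return(structure(empty, gatePassed = FALSE))
  em <- emmeans::emmeans(fit@model, ~condition, lmer.df = "satterthwaite")
  ct <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  structure(as.data.frame(summary(ct)), gatePassed = TRUE)
}

.sawilowsky <- function(d) {
  a <- abs(d)
  cut(a, breaks = c(-Inf, 0.01, 0.2, 0.5, 0.8, 1.2, 2, Inf),
      labels = c("negligible", "very small", "small", "medium", "large",
                 "very large", "huge"), right = FALSE)
}

#' Cohen's d for condition contrasts from a mixed model
#'
#' Standardizes each estimated-marginal-mean difference by the model's total
#' standard deviation \code{sqrt(sigma2_subject + sigma2_residual)}; the
#' confidence interval divides the contrast's Wald interval (Satterthwaite
#' df) by the same denominator. Magnitudes are labelled on Sawilowsky's
#' scale.
#'
#' @param fit an \code{LmmFit}.
#' @param conf confidence level, default 0.95.
#' @return data.frame with \code{contrast, d, ci_low, ci_high, magnitude}.
#' @export
lmmCohensD <- function(fit, conf = 0.95) {
  stopifnot(is(fit, "LmmFit"))
  if (!fit@converged) stop("effect sizes require a converged fit")
  denom <- sqrt(sum(fit@varianceComponents))
  if (denom <= 0) return(structure(data.frame(), reason = "zero total variance"))
  em <- emmeans::emmeans(fit@model, ~condition, lmer.df = "satterthwaite")
  pr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                adjust = "none")))
  tcrit <- qt(1 - (1 - conf) / 2, pr$df)
  d <- pr$estimate / denom
  data.frame(contrast = pr$contrast, d = d,
             ci_low = (pr$estimate - tcrit * pr$SE) / denom,
             ci_high = (pr$estimate + tcrit * pr$SE) / denom,
             magnitude = as.character(.sawilowsky(d)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
fdrAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

## DeLong placement values: for each positive case the fraction of negatives
## it beats (ties 0.5), and symmetrically for negatives.
.delongPlacements <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  rAll <- rank(c(pos, neg), ties.method = "average")
  v10 <- (rAll[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (rAll[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Segment-level ROC with DeLong confidence interval
#'
#' AUC as the Mann-Whitney statistic (ties counted 0.5) with a DeLong
#' variance estimate for the confidence interval. Class 1 defaults to the
#' group with the higher mean index value, so AUC >= 0.5 corresponds to the
#' expected direction; the chosen orientation is recorded.
#'
#' @param values numeric index values.
#' @param labels two-level grouping vector, same length as \code{values}.
#' @param class1 label to treat as class 1, or NULL for the
#'   higher-mean-group rule.
#' @param conf confidence level, default 0.95.
#' @return a \code{RocResult}.
#' @examples
#' aucDeLong(c(3, 4, 1, 2), c("a", "a", "b", "b"))
#' @export
aucDeLong <- function(values, labels, class1 = NULL, conf = 0.95) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must contain exactly two classes")
  if (is.null(class1)) {
    mu <- tapply(values, labels, mean)
    class1 <- names(mu)[which.max(mu)]
  } else if (!class1 %in% lv) stop("class1 must be one of the labels")
  pos <- values[labels == class1]
  neg <- values[labels != class1]
  pl <- .delongPlacements(pos, neg)
  se <- sqrt(var(pl$v10) / length(pos) + var(pl$v01) / length(neg))
  if (!is.finite(se)) se <- 0
  z <- qnorm(1 - (1 - conf) / 2)
  new("RocResult", auc = pl$auc,
      ciLow = max(0, pl$auc - z * se), ciHigh = min(1, pl$auc + z * se),
      orientation = class1, nPos = length(pos), nNeg = length(neg), se = se)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided test of equal AUC for two index score vectors measured on the
#' same cases, using the DeLong covariance of the paired placement values.
#' Identical scores give a zero statistic and p = 1.
#'
#' @param valuesA,valuesB numeric score vectors on the same cases.
#' @param labels two-level grouping vector shared by both score vectors.
#' @param class1 label treated as class 1 for both curves; default: the
#'   group with the higher mean of \code{valuesA}.
#' @return list with \code{p}, \code{statistic} (z), \code{deltaAuc},
#'   \code{aucA}, \code{aucB}.
#' @export
deLongTest <- function(valuesA, valuesB, labels, class1 = NULL) {
  if (length(valuesA) != length(valuesB) ||
      length(valuesA) != length(labels))
    stop("paired curves must share the same cases")
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must contain exactly two classes")
  if (is.null(class1)) {
    mu <- tapply(valuesA, labels, mean)
    class1 <- names(mu)[which.max(mu)]
  }
  isPos <- labels == class1
  plA <- .delongPlacements(valuesA[isPos], valuesA[!isPos])
  plB <- .delongPlacements(valuesB[isPos], valuesB[!isPos])
  dv10 <- plA$v10 - plB$v10
  dv01 <- plA$v01 - plB$v01
  v <- var(dv10) / sum(isPos) + var(dv01) / sum(!isPos)
  delta <- plA$auc - plB$auc
  if (!is.finite(v) || v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(p = p, statistic = z, deltaAuc = delta, aucA = plA$auc, aucB = plB$auc)
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation via analysis of covariance with subject
#' as a factor: the sign comes from the common slope, the magnitude from the
#' covariate and error sums of squares. The confidence interval uses the
#' Fisher z transform with the error degrees of freedom
#' (\code{N - #subjects - 1}); for a single subject this reduces exactly to
#' the Pearson correlation.
#'
#' @param subject subject identifiers.
#' @param x,y paired observations (e.g. VAS and an index value).
#' @param conf confidence level, default 0.95.
#' @return list with \code{r}, \code{ci_low}, \code{ci_high}, \code{df},
#'   \code{p}; flagged \code{NA} when the error degrees of freedom are
#'   insufficient.
#' @export
rmCorr <- function(subject, x, y, conf = 0.95) {
  ok <- !is.na(subject) & !is.na(x) & !is.na(y)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  N <- length(x); k <- nlevels(subject)
  df <- N - k - 1
  if (df < 1 || stats::sd(x) == 0)
    return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                df = df, p = NA_real_, reason = "insufficient df"))
  fit <- if (k > 1) lm(y ~ subject + x) else lm(y ~ x)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits warn harmlessly
  ssX <- an["x", "Sum Sq"]; ssE <- an["Residuals", "Sum Sq"]
  r <- sign(coef(fit)[["x"]]) * sqrt(ssX / (ssX + ssE))
  p <- an["x", "Pr(>F)"]
  if (df > 2 && abs(r) < 1) {
    zr <- atanh(r); zs <- 1 / sqrt(df - 1)
    zq <- qnorm(1 - (1 - conf) / 2)
    ci <- tanh(zr + c(-1, 1) * zq * zs)
  } else ci <- c(NA_real_, NA_real_)
  list(r = r, ci_low = ci[1], ci_high = ci[2], df = df, p = p)
}
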