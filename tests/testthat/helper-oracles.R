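## Independent brute-force oracles used to validate the fast implementations.
## These deliberately re-derive each quantity from its definition and share no
## code with the package internals.

## Chebyshev distance matrix between all templates of length m, built
## incrementally from the pairwise sample distances.
.chebTemplateDist <- function(x, m, nT) {
  D1 <- abs(outer(x, x, "-"))
  D <- D1[seq_len(nT), seq_len(nT)]
  if (m > 1) for (k in seq_len(m - 1))
    D <- pmax(D, D1[seq_len(nT) + k, seq_len(nT) + k])
  D
}

## Approximate entropy by direct evaluation of phi(m) - phi(m+1), self-matches
## included, N - m + 1 templates at length m.
bruteApEn <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nT <- N - mm + 1
    D <- .chebTemplateDist(x, mm, nT)
    mean(log(rowSums(D <= r) / nT))
  }
  phi(m) - phi(m + 1)
}

## Sample entropy by direct pair counting over the N - m templates usable at
## both lengths, self-matches excluded.
bruteSampEn <- function(x, m, r) {
  N <- length(x)
  nT <- N - m
  Dm <- .chebTemplateDist(x, m, nT)
  B <- (sum(Dm <= r) - nT) / 2
  Dm1 <- .chebTemplateDist(x, m + 1, nT)
  A <- (sum(Dm1 <= r) - nT) / 2
  -log(A / B)
}

## Katz fractal dimension transcribed literally from its defining formula.
bruteKfd <- function(x) {
  N <- length(x)
  L <- 0
  for (i in 2:N) L <- L + sqrt(1 + (x[i] - x[i - 1])^2)
  d <- 0
  for (i in 2:N) d <- max(d, sqrt((i - 1)^2 + (x[i] - x[1])^2))
  n <- N - 1
  log10(n) / (log10(d / L) + log10(n))
}

## Mann-Whitney AUC by explicit pair enumeration (ties count one half).
bruteAuc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

## Fraction of total periodogram power inside [lo, hi] Hz.
powerFraction <- function(x, fs, lo, hi) {
  p <- welchPsd(x, fs)
  sum(p$psd[p$freq >= lo & p$freq <= hi]) / sum(p$psd)
}

## Single-bin amplitude of a tone at frequency f from an interior stretch.
toneAmplitude <- function(x, fs, f) {
  n <- length(x)
  2 * Mod(fft(x)[round(f * n / fs) + 1]) / n
}

## Lag (samples) of the peak cross-correlation between two equal-length
## series, restricted to |lag| <= maxLag.
peakXcorrLag <- function(a, b, maxLag = 50) {
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(a[1:(length(a) - l)] * b[(1 + l):length(b)])
    else sum(a[(1 - l):length(a)] * b[1:(length(b) + l)])
  }, numeric(1))
  lags[which.max(cc)]
}
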