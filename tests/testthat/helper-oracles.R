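# Independent oracles used by the tests. Each is a deliberately naive,
# self-contained implementation kept separate from the package internals.

# single-component NIPALS PLS1 (centered y, column-centered X assumed)
pls1_oracle <- function(X, y) {
  yc <- y - mean(y)
  w <- t(X) %*% yc
  w <- w / sqrt(sum(w^2))
  t <- X %*% w
  q <- sum(yc * t) / sum(t^2)
  y_hat <- mean(y) + c(t) * q
  list(w = c(w), t = c(t), q = q, y_hat = y_hat,
       r2y = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2))
}

# one manual orthogonal-signal-correction deflation step
osc_deflate_oracle <- function(X, y) {
  yc <- y - mean(y)
  w <- t(X) %*% yc; w <- w / sqrt(sum(w^2))
  t <- X %*% w
  p <- t(X) %*% t / sum(t^2)
  wo <- p - c(t(w) %*% p) * w
  wo <- wo / sqrt(sum(wo^2))
  to <- X %*% wo
  po <- t(X) %*% to / sum(to^2)
  X - to %*% t(po)
}

# median-of-quotients PQN by explicit loops
pqn_oracle <- function(mat) {
  totals <- apply(mat, 1, sum)
  common <- median(totals)
  xr <- mat
  for (i in seq_len(nrow(mat))) xr[i, ] <- mat[i, ] / (totals[i] / common)
  ref <- apply(xr, 2, median)
  fac <- numeric(nrow(mat))
  out <- xr
  for (i in seq_len(nrow(mat))) {
    q <- (xr[i, ] / ref)[ref != 0]
    fac[i] <- median(q)
    out[i, ] <- xr[i, ] / fac[i]
  }
  list(table = out, factors = (totals / common) * fac)
}

# AUC by exhaustive pair counting (concordant + half ties)
auc_oracle <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# interval overlap by dense sampling (brute force)
overlaps_oracle <- function(lo, hi, rlo, rhi, n = 10000) {
  x <- seq(lo, hi, length.out = n)
  x <- x[x < hi]                       # half-open bucket
  any(x >= rlo & x < rhi)
}

# bucket integration by fine-grid Riemann sums on a densely resampled
# piecewise-linear interpolant of the spectrum
riemann_buckets_oracle <- function(ppm, intensity, width, range, per = 400) {
  n <- round((range[2] - range[1]) / width)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    lo <- range[1] + (i - 1) * width
    g <- seq(lo, lo + width, length.out = per + 1)
    f <- approx(ppm, intensity, xout = g)$y
    vals[i] <- sum((f[-1] + f[-length(f)]) / 2) * width / per
  }
  vals
}

# closed-form integral of a unit-area Lorentzian over [a, b]
lorentz_integral_oracle <- function(a, b, x0, fwhm) {
  (atan(2 * (b - x0) / fwhm) - atan(2 * (a - x0) / fwhm)) / pi
}

# pooled-variance two-sided Student t by the textbook formula
ttest_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), na + nb - 2)
  list(t = t, p = p)
}

# a small fast cohort for pipeline-level tests: coarse axis, small groups
make_test_cohort <- function(seed = 1, n_s = 8, n_n = 8,
                             paired = c(1, 1), ...) {
  design <- cohort_design(n_survivors = n_s, n_nonsurvivors = n_n,
                          paired_fraction = paired, seed = seed, ...)
  simulate_cohort(design, ppm = ppm_axis(step = 0.002))
}
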