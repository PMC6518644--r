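flat_spectrum <- function(value = 1, step = 0.01, from = -1.5, to = 10.5) {
  ppm <- ppm_axis(from, to, step)
  nmr_spectrum(ppm, rep(value, length(ppm)), "flat")
}

test_that("bucketing reproduces the forced arithmetic of the grid", {
  b <- bucket_spectrum(flat_spectrum(), width_ppm = 0.001,
                       range_ppm = c(-1, 10))
  expect_equal(length(b$values), 11000)
  # constant integrand: every bucket = value * width
  expect_true(all(abs(b$values - 1 * 0.001) < 1e-12))
})

test_that("bucket integrals match a fine-grid Riemann oracle on a ramp", {
  ppm <- ppm_axis(-1.5, 10.5, 0.01)
  sp <- nmr_spectrum(ppm, 2 + 0.5 * ppm, "ramp")
  b <- bucket_spectrum(sp, width_ppm = 0.05, range_ppm = c(-1, 10))
  want <- riemann_buckets_oracle(sp$ppm, sp$intensity, 0.05, c(-1, 10))
  expect_equal(b$values, want, tolerance = 1e-8)
  # area conservation: buckets sum to the full-range integral
  total <- pracma::trapz(ppm[ppm >= -1 & ppm <= 10],
                         sp$intensity[ppm >= -1 & ppm <= 10])
  expect_equal(sum(b$values), total, tolerance = 1e-10)
})

test_that("a spectrum not covering the range is rejected with the gap named", {
  sp <- nmr_spectrum(ppm_axis(0, 9, 0.01), rep(1, 901), "short")
  expect_error(bucket_spectrum(sp), "does not cover")
})

test_that("region exclusion drops exactly the intersecting buckets", {
  tab <- bucket_spectra(list(flat_spectrum()), width_ppm = 0.001)
  expect_equal(ncol(tab$values), 11000)
  kept <- exclude_regions(tab)
  expect_equal(ncol(kept$values), 9260)

  # a region outside the grid changes nothing
  same <- exclude_regions(tab, regions = list(c(11, 12)))
  expect_equal(same$values, tab$values)

  # half-open semantics against a brute-force overlap oracle
  tab2 <- bucket_spectra(list(flat_spectrum()), width_ppm = 0.13)
  for (region in list(c(4.6, 5.5), c(0.065, 0.195), c(-0.5, 0.02))) {
    kept2 <- exclude_regions(tab2, regions = list(region))
    want_keep <- !vapply(seq_len(nrow(tab2$edges)), function(i)
      overlaps_oracle(tab2$edges[i, 1], tab2$edges[i, 2],
                      region[1], region[2]),
      logical(1))
    expect_equal(kept2$edges[, 1], tab2$edges[want_keep, 1])
  }
})

test_that("bucketing segments then concatenating equals bucket-then-exclude", {
  sp <- flat_spectrum()
  sp$intensity <- 1 + sin(sp$ppm)
  whole <- exclude_regions(bucket_spectra(list(sp), width_ppm = 0.01))
  parts <- lapply(list(c(-1, 3.16), c(4, 4.6), c(5.5, 10)), function(rg)
    bucket_spectrum(sp, width_ppm = 0.01, range_ppm = rg)$values)
  expect_equal(unname(whole$values[1, ]), unname(unlist(parts)),
               tolerance = 1e-10)
})

test_that("PQN recovers pure dilution and matches the brute-force oracle", {
  base <- matrix(c(1, 2, 3, 4, 5,
                   2, 1, 4, 3, 5,
                   5, 4, 3, 2, 1,
                   1, 1, 2, 2, 3), 4, 5, byrow = TRUE)
  edges <- cbind(0:4, 1:5)

  # identical rows: factors 1, table unchanged
  same <- bucket_table(matrix(rep(base[1, ], 3), 3, byrow = TRUE), edges)
  r <- pqn_normalize(same)
  expect_equal(unname(r$factors), rep(1, 3))
  expect_equal(r$table$values, same$values, ignore_attr = TRUE)

  # one row a scalar multiple of another: factor ratio equals the dilution
  two <- bucket_table(rbind(base[1, ], 2 * base[1, ]), edges)
  r2 <- pqn_normalize(two)
  expect_equal(unname(r2$factors[2] / r2$factors[1]), 2)
  expect_equal(r2$table$values[1, ], r2$table$values[2, ],
               ignore_attr = TRUE)

  # toy matrix against the loop-coded oracle, exactly
  tab <- bucket_table(base, edges)
  got <- pqn_normalize(tab)
  want <- pqn_oracle(base)
  expect_equal(unname(got$factors), want$factors)
  expect_equal(unname(got$table$values), unname(want$table))

  # zero-area row is rejected with the sample named
  bad <- bucket_table(rbind(base[1, ], 0 * base[1, ]), edges,
                      sample_ids = c("ok", "empty"))
  expect_error(pqn_normalize(bad), "empty")
})

test_that("auto-scaling centers, scales, and projects consistently", {
  x <- matrix(c(1, 4, 2, 8, 3, 6), 3, 2, byrow = TRUE)
  tab <- bucket_table(x, cbind(0:1, 1:2), normalized = TRUE)
  sc <- autoscale(tab)
  expect_true(all(abs(colMeans(sc$table$values)) < 1e-10))
  expect_equal(unname(apply(sc$table$values, 2, sd)), c(1, 1))

  # hand-computed 3x2 case
  want <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
  expect_equal(unname(sc$table$values), unname(want))

  # idempotence: applying the fitted constants reproduces the output
  again <- apply_scaling(tab, sc$constants)
  expect_equal(again$values, sc$table$values)

  # constant bucket: warned, unit divisor
  xc <- cbind(x, 7)
  tabc <- bucket_table(xc, cbind(0:2, 1:3))
  expect_warning(scc <- autoscale(tabc), "constant")
  expect_equal(unname(scc$table$values[, 3]), c(0, 0, 0))

  # center-only variant
  cen <- autoscale(tab, center_only = TRUE)
  expect_equal(unname(cen$table$values), unname(sweep(x, 2, colMeans(x))))
})

test_that("PCA screen flags gross outliers and matches an eigen oracle", {
  set.seed(42)
  x <- matrix(rnorm(60 * 12), 60, 12)
  x[7, ] <- x[7, ] * 100
  scr <- pca_outlier_screen(x, n_components = 3)
  expect_true("7" %in% scr$flagged || 7 %in% as.integer(scr$flagged))

  # scores equal an independent eigendecomposition up to column sign
  set.seed(43)
  x2 <- matrix(rnorm(40 * 6), 40, 6)
  scr2 <- pca_outlier_screen(x2, n_components = 4)
  xc <- sweep(x2, 2, colMeans(x2))
  ev <- eigen(cov(xc))
  want <- xc %*% ev$vectors[, 1:4]
  for (j in 1:4) {
    agree <- max(abs(scr2$scores[, j] - want[, j]))
    flip <- max(abs(scr2$scores[, j] + want[, j]))
    expect_lt(min(agree, flip), 1e-8)
  }
})

test_that("PCA screen false-positive rate is near alpha under the null", {
  set.seed(7)
  x <- matrix(rnorm(500 * 20), 500, 20)
  scr <- pca_outlier_screen(x, n_components = 3, alpha = 0.01)
  rate <- length(scr$flagged) / 500
  # binomial 99% interval around 0.01 at n = 500
  expect_lte(rate, 0.01 + 2.58 * sqrt(0.01 * 0.99 / 500))
})

test_that("planted dilution factors are recovered by PQN at low noise", {
  design <- cohort_design(n_survivors = 10, n_nonsurvivors = 10,
                          paired_fraction = 0, noise_sd = 0.05,
                          seed = 9)
  co <- simulate_cohort(design, ppm = ppm_axis(step = 0.002))
  tab <- exclude_regions(bucket_spectra(co$spectra, width_ppm = 0.005))
  r <- pqn_normalize(tab)
  planted <- co$truth$dilution[tab$sample_ids]
  expect_gt(cor(r$factors, planted), 0.99)
  ratio <- r$factors / planted
  expect_lt(max(ratio) / min(ratio) - 1, 0.04)
})
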