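centered <- function(x) sweep(x, 2, colMeans(x))

random_instance <- function(seed, n = 10, k = 8, signal = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  X <- matrix(rnorm(n * k), n, k) + signal * y %o% rnorm(k)
  list(X = centered(X), y = y)
}

test_that("rank-1 aligned data is fitted perfectly", {
  set.seed(1)
  y <- rep(c(1, -1), 5)
  v <- rnorm(6)
  X <- centered(y %o% v)
  m <- fit_opls_da(X, y, n_orth = 0)
  expect_equal(m$fitted, y, tolerance = 1e-10)
  expect_equal(m$R2Y, 1, tolerance = 1e-10)
})

test_that("an exactly orthogonal structured component is filtered out", {
  set.seed(2)
  n <- 12
  y <- rep(c(1, -1), n / 2)
  z <- rnorm(n); z <- z - mean(z)
  z <- z - y * sum(z * y) / sum(y * y)        # z strictly orthogonal to y
  v1 <- rnorm(7); v2 <- rnorm(7)
  X <- centered(y %o% v1 + z %o% v2)
  m <- fit_opls_da(X, y, n_orth = 1)
  expect_equal(m$n_orth, 1)
  expect_lt(abs(cor(m$T_orth[, 1], y)), 1e-8)
  expect_equal(m$R2Y, 1, tolerance = 1e-10)
})

test_that("with n_orth = 0 the fit equals an independent PLS1 oracle", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    m <- fit_opls_da(inst$X, inst$y, n_orth = 0)
    o <- pls1_oracle(inst$X, inst$y)
    expect_equal(m$w, o$w, tolerance = 1e-10)
    expect_equal(m$fitted, o$y_hat, tolerance = 1e-10)
    expect_equal(m$R2Y, o$r2y, tolerance = 1e-10)
  }
})

test_that("orthogonal filtering equals manual deflation plus PLS1", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    m <- fit_opls_da(inst$X, inst$y, n_orth = 1)
    o <- pls1_oracle(osc_deflate_oracle(inst$X, inst$y), inst$y)
    expect_equal(m$fitted, o$y_hat, tolerance = 1e-10)
  }
})

test_that("fitted models satisfy the orthogonality constraints", {
  for (seed in c(3, 4, 5)) {
    inst <- random_instance(seed, n = 14, k = 10)
    m <- fit_opls_da(inst$X, inst$y, n_orth = 2)
    expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
    for (j in seq_len(m$n_orth)) {
      expect_equal(sum(m$W_orth[, j]^2), 1, tolerance = 1e-12)
      expect_lt(abs(sum(m$t * m$T_orth[, j])),
                1e-8 * sqrt(sum(m$t^2) * sum(m$T_orth[, j]^2)))
      expect_lt(abs(cor(m$T_orth[, j], m$y)), 1e-8)
      expect_lt(abs(sum(m$w * m$W_orth[, j])), 1e-8)
    }
  }
})

test_that("projection reproduces training scores and acts row-wise", {
  inst <- random_instance(6, n = 12, k = 9)
  m <- fit_opls_da(inst$X, inst$y, n_orth = 2)
  pr <- predict(m, inst$X)
  expect_equal(pr$t_pred, m$t, tolerance = 1e-12)
  expect_equal(pr$T_orth, m$T_orth, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(pr$y_hat, m$fitted, tolerance = 1e-12)

  dup <- rbind(inst$X[3, ], inst$X[3, ])
  pd <- predict(m, dup)
  expect_equal(pd$t_pred[1], pd$t_pred[2])
})

test_that("held-out classification works on planted two-group structure", {
  set.seed(10)
  n <- 60; k <- 40
  y <- rep(c(1, -1), n / 2)
  X <- matrix(rnorm(n * k), n, k) + 0.8 * y %o% (rbinom(k, 1, 0.4) * rnorm(k))
  tr <- seq_len(n) %% 3 != 0
  sc <- nmropls:::.scale_fit(X[tr, ])
  m <- fit_opls_da(nmropls:::.scale_apply(X[tr, ], sc), y[tr], n_orth = 1)
  pr <- predict(m, nmropls:::.scale_apply(X[!tr, ], sc), y = y[!tr])
  acc <- mean(sign(pr$y_hat) == y[!tr])
  expect_gte(acc, 0.9)
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- centered(matrix(rnorm(20), 5, 4))
  expect_error(fit_opls_da(X, rep(1, 5)), "both classes")
  expect_error(fit_opls_da(matrix(0, 6, 3), rep(c(1, -1), 3)),
               "zero variance")
  expect_error(fit_opls_da(X[1:3, ], c(1, -1, 1), n_orth = 2), "samples")
  # X'y = 0: no covariance direction exists
  Xo <- matrix(c(1, -1, 1, -1), 4, 1)
  yo <- c(1, 1, -1, -1)
  expect_error(fit_opls_da(cbind(Xo, Xo), yo, n_orth = 0), "covariance")
})

test_that("cross-validation separates signal from noise", {
  # noiseless rank-1: nearly perfect predictability
  set.seed(20)
  y <- rep(c(1, -1), 10)
  X <- y %o% rnorm(8)
  cv <- cross_validate(X, y, n_orth = 0, k_folds = 5, seed = 1)
  expect_gt(cv$Q2Y, 0.99)

  # pure noise: no predictability
  set.seed(21)
  yn <- rep(c(1, -1), 30)
  Xn <- matrix(rnorm(60 * 100), 60, 100)
  cvn <- cross_validate(Xn, yn, n_orth = 0, k_folds = 7, seed = 1)
  expect_lt(cvn$Q2Y, 0.1)
})

test_that("leave-one-out PRESS equals an explicit refit loop", {
  set.seed(22)
  y <- rep(c(1, -1), 3)
  X <- matrix(rnorm(6 * 4), 6, 4) + 0.5 * y %o% rnorm(4)
  cv <- cross_validate(X, y, n_orth = 0, k_folds = 6, seed = 3)
  for (k in seq_len(6)) {
    te <- which(cv$fold == k)
    tr <- setdiff(1:6, te)
    sc <- nmropls:::.scale_fit(X[tr, , drop = FALSE])
    o <- pls1_oracle(nmropls:::.scale_apply(X[tr, , drop = FALSE], sc),
                     y[tr])
    xte <- nmropls:::.scale_apply(X[te, , drop = FALSE], sc)
    yh <- mean(y[tr]) + c(xte %*% o$w) * o$q
    expect_equal(cv$press[k], sum((y[te] - yh)^2), tolerance = 1e-10)
  }
})

test_that("R2Y is non-decreasing in n_orth; sample order is immaterial", {
  inst <- random_instance(30, n = 16, k = 12, signal = 0.5)
  r2 <- vapply(0:3, function(a)
    fit_opls_da(inst$X, inst$y, n_orth = a)$R2Y, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))

  set.seed(31)
  perm <- sample(16)
  m1 <- fit_opls_da(inst$X, inst$y, n_orth = 2)
  m2 <- fit_opls_da(inst$X[perm, ], inst$y[perm], n_orth = 2)
  expect_equal(m2$t, m1$t[perm], tolerance = 1e-10)
  expect_equal(m2$w, m1$w, tolerance = 1e-10)
})

test_that("VIP obeys its normalization identity and limits", {
  inst <- random_instance(40, n = 12, k = 9)
  m <- fit_opls_da(inst$X, inst$y, n_orth = 1)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)

  # single informative variable among near-silent ones: VIP -> sqrt(K)
  set.seed(41)
  y <- rep(c(1, -1), 8)
  X <- cbind(y, matrix(rnorm(16 * 5, sd = 1e-8), 16, 5))
  X <- sweep(X, 2, colMeans(X))
  v1 <- vip(fit_opls_da(X, y, n_orth = 0))
  expect_equal(v1[1], sqrt(6), tolerance = 1e-6)

  # 3-variable toy model against the hand formula sqrt(K)|w|/||w||
  set.seed(42)
  y3 <- rep(c(1, -1), 4)
  X3 <- centered(matrix(rnorm(24), 8, 3) + y3 %o% c(1, 0.5, 0))
  m3 <- fit_opls_da(X3, y3, n_orth = 0)
  expect_equal(vip(m3), sqrt(3) * abs(m3$w) / sqrt(sum(m3$w^2)))
})

test_that("loading correlations equal the Pearson formula, with orientation", {
  inst <- random_instance(50, n = 14, k = 6)
  m <- fit_opls_da(inst$X, inst$y, n_orth = 0)
  raw <- loading_correlations(m, inst$X, positive_class = NULL)
  want <- apply(inst$X, 2, function(col) cor(col, m$t))
  expect_equal(raw, want, tolerance = 1e-12)

  # a column equal to the score correlates exactly 1; orthogonal -> 0
  orth_col <- inst$X[, 1] - mean(inst$X[, 1])
  orth_col <- orth_col - m$t * sum(orth_col * m$t) / sum(m$t^2)
  r2 <- unname(loading_correlations(m, cbind(m$t, orth_col),
                                    positive_class = NULL))
  expect_equal(abs(r2[1]), 1, tolerance = 1e-12)
  expect_lt(abs(r2[2]), 1e-10)

  # oriented version: a variable elevated in SSN must come out positive
  set.seed(51)
  y <- rep(c("SSS", "SSN"), 10)
  ynum <- ifelse(y == "SSS", 1, -1)
  X3 <- centered(matrix(rnorm(20 * 4), 20, 4) - 1.5 * ynum %o% c(1, 0, 0, 0))
  m3 <- fit_opls_da(X3, y, n_orth = 0)
  r3 <- loading_correlations(m3, X3, positive_class = "SSN")
  expect_gt(r3[1], 0.5)
})

test_that("automatic orthogonal-component selection stops when Q2 stalls", {
  inst <- random_instance(60, n = 30, k = 10, signal = 0.8)
  sel <- select_n_orth(inst$X, inst$y, max_orth = 3, scale = FALSE, seed = 2)
  expect_true(sel$n_orth >= 0 && sel$n_orth <= 3)
  expect_equal(length(sel$q2) >= sel$n_orth + 1, TRUE)
})
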