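#' Permutation validation of an OPLS-DA model
#'
#' Re-runs the full modeling pipeline (fold-internal scaling, orthogonal
#' filtering, cross-validation) for `n_perm` random permutations of the
#' class vector against the fixed data matrix, recording each
#' permutation's R2Y, Q2Y and the absolute correlation between the
#' permuted and original response. Empirical p-values use the standard
#' add-one rule `p = (1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of permutations (`>= 1`).
#' @return An object of class `permutation_result`: `observed` (R2Y,
#'   Q2Y), `r2`, `q2`, `y_correlation` (per permutation), `p_r2`, `p_q2`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(X, y, n_orth = 0, n_perm = 500, k_folds = 7,
                             seed = 1, groups = NULL, scale = TRUE,
                             coding = c(SSS = 1, SSN = -1)) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  if (!is.numeric(y)) y <- unname(coding[as.character(y)])
  obs <- cross_validate(X, y, n_orth = n_orth, k_folds = k_folds,
                        seed = seed, groups = groups, scale = scale)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm_seeds <- sample.int(2147483629, n_perm)
  r2 <- q2 <- yc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    yp <- sample(y)
    cv <- cross_validate(X, yp, n_orth = n_orth, k_folds = k_folds,
                         seed = perm_seeds[b], groups = groups,
                         scale = scale)
    r2[b] <- cv$R2Y; q2[b] <- cv$Q2Y
    yc[b] <- abs(stats::cor(yp, y))
  }
  structure(list(
    observed = c(R2Y = obs$R2Y, Q2Y = obs$Q2Y),
    r2 = r2, q2 = q2, y_correlation = yc,
    p_r2 = (1 + sum(r2 >= obs$R2Y)) / (n_perm + 1),
    p_q2 = (1 + sum(q2 >= obs$Q2Y)) / (n_perm + 1),
    n_perm = n_perm, seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d permutations\n  observed R2Y = %.3f (p = %.4g), Q2Y = %.3f (p = %.4g)\n",
    x$n_perm, x$observed["R2Y"], x$p_r2, x$observed["Q2Y"], x$p_q2))
  invisible(x)
}

#' Permutation validation plot
#'
#' Scatter of permuted R2 and Q2 against the absolute correlation between
#' permuted and original response, with the observed values at
#' correlation 1.
#'
#' @param x A `permutation_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.permutation_result <- function(x, ...) {
  ylim <- range(c(x$r2, x$q2, x$observed), finite = TRUE)
  graphics::plot(x$y_correlation, x$r2, col = "darkgreen", pch = 19,
                 xlim = c(0, 1), ylim = ylim,
                 xlab = "|corr(permuted y, y)|", ylab = expression(R^2 ~ "/" ~ Q^2),
                 ...)
  graphics::points(x$y_correlation, x$q2, col = "steelblue", pch = 19)
  graphics::points(c(1, 1), x$observed, col = c("darkgreen", "steelblue"),
                   pch = 17, cex = 1.4)
  graphics::legend("bottomright", c("R2", "Q2"), pch = 19,
                   col = c("darkgreen", "steelblue"), bty = "n")
  invisible(x)
}
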