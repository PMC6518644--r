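#' @title OPLS-DA: orthogonal projections to latent structures
#' @description Two-class discriminant analysis in which predictor
#'   variation is split into one y-predictive latent component and
#'   `n_orth` y-orthogonal components (structured noise) before the
#'   discriminant direction is estimated, following the NIPALS-style
#'   orthogonal signal correction sequence.
#' @name opls
NULL

# minimal fitting core on a column-centered/scaled matrix X and centered y.
# Returns predictive (w, t, p, q) and orthogonal (W, P, T) parts.
.opls_core <- function(X, yc, n_orth) {
  K <- ncol(X)
  W_o <- P_o <- matrix(0, K, 0)
  T_o <- matrix(0, nrow(X), 0)
  Xf <- X
  for (i in seq_len(n_orth)) {
    w <- crossprod(Xf, yc)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) stop("X carries no covariance with y")
    w <- w / nw
    t <- Xf %*% w
    p <- crossprod(Xf, t) / sum(t^2)
    wo <- p - c(crossprod(w, p)) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- Xf %*% wo
    po <- crossprod(Xf, to) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    W_o <- cbind(W_o, wo); P_o <- cbind(P_o, po); T_o <- cbind(T_o, to)
  }
  w <- crossprod(Xf, yc)
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stop("X carries no covariance with y")
  w <- w / nw
  t <- Xf %*% w
  p <- crossprod(Xf, t) / sum(t^2)
  q <- c(crossprod(yc, t) / sum(t^2))
  list(w = c(w), t = c(t), p = c(p), q = q,
       W_orth = W_o, P_orth = P_o, T_orth = T_o)
}

#' Fit an OPLS-DA model
#'
#' NIPALS sequence: the candidate predictive weight `w` is proportional to
#' `X'y`; each orthogonal component is extracted from the loading part
#' orthogonal to `w`, its variation removed from `X`, and after `n_orth`
#' such deflations the predictive component is computed on the filtered
#' matrix. With `n_orth = 0` the model coincides with single-component
#' PLS1.
#'
#' @param X Numeric matrix, columns centered (typically auto-scaled);
#'   samples in rows. A scaled [bucket_table()] is also accepted.
#' @param y Class labels: a numeric -1/+1 vector, or a factor/character
#'   vector with exactly two levels coded via `coding`.
#' @param n_orth Number of orthogonal components (`>= 0`).
#' @param coding Named vector mapping the two class labels to +1/-1;
#'   default `c(SSS = 1, SSN = -1)`.
#' @param scaling Optional `scaling_constants` stored for projecting raw
#'   test data with [predict.opls_model()].
#' @return An object of class `opls_model`: predictive weight `w` (unit
#'   norm), loading `p`, score `t_pred`, y-loading `q`; orthogonal
#'   `W_orth`, `P_orth`, `T_orth`; `fitted` values, `R2Y`, the class
#'   `coding` and `y_mean`.
#' @export
fit_opls_da <- function(X, y, n_orth = 0, coding = c(SSS = 1, SSN = -1),
                        scaling = NULL) {
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  if (!is.numeric(y)) {
    y <- as.character(y)
    if (!all(y %in% names(coding)))
      stop("y labels not covered by the class coding")
    y <- unname(coding[y])
  }
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (n_orth < 0) stop("n_orth must be >= 0")
  if (nrow(X) <= n_orth + 1)
    stop("need more than n_orth + 1 samples")
  if (all(apply(X, 2, function(col) stats::sd(col) == 0)))
    stop("X has zero variance")
  y_mean <- mean(y)
  core <- .opls_core(X, y - y_mean, n_orth)
  fitted <- y_mean + core$t * core$q
  r2y <- 1 - sum((y - fitted)^2) / sum((y - y_mean)^2)
  structure(c(core, list(
    n_orth = ncol(core$T_orth), y = y, y_mean = y_mean,
    fitted = fitted, R2Y = r2y, Q2Y = NA_real_,
    coding = coding, scaling = scaling
  )), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> 1 predictive +", x$n_orth, "orthogonal component(s),",
      length(x$t), "samples x", length(x$w), "variables\n")
  cat(sprintf("  R2Y = %.3f", x$R2Y))
  if (!is.na(x$Q2Y)) cat(sprintf("  Q2Y = %.3f", x$Q2Y))
  cat("\n")
  invisible(x)
}

#' Project new samples through a fitted OPLS-DA model
#'
#' Orthogonal variation is removed sequentially with the stored orthogonal
#' weights/loadings, then the predictive score and class prediction are
#' computed. Input may be pre-scaled or raw; raw input requires scaling
#' constants (stored in the model or passed here).
#'
#' @param object A fitted `opls_model`.
#' @param newdata Matrix or [bucket_table()] with the model's variables.
#' @param y Optional true labels (numeric or coded classes) for
#'   `R2Y_pred`.
#' @param scaling Optional `scaling_constants` to apply to `newdata`
#'   before projection (overrides constants stored in the model).
#' @param ... Unused.
#' @return List with `t_pred`, `T_orth`, `y_hat`, `class` (predicted
#'   labels under the model's coding, threshold 0), and `R2Y_pred` when
#'   `y` is supplied.
#' @export
predict.opls_model <- function(object, newdata, y = NULL, scaling = NULL,
                               ...) {
  sc <- scaling %||% object$scaling
  if (inherits(newdata, "bucket_table")) {
    if (!newdata$scaled && !is.null(sc))
      newdata <- apply_scaling(newdata, sc)
    newdata <- newdata$values
  } else if (!is.null(scaling)) {
    newdata <- .scale_apply(as.matrix(newdata), scaling)
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$w))
    stop("newdata has ", ncol(X), " variables; model expects ",
         length(object$w))
  n_o <- object$n_orth
  T_o <- matrix(0, nrow(X), n_o)
  for (i in seq_len(n_o)) {
    to <- X %*% object$W_orth[, i]
    X <- X - tcrossprod(to, object$P_orth[, i])
    T_o[, i] <- to
  }
  t_pred <- c(X %*% object$w)
  y_hat <- object$y_mean + t_pred * object$q
  cls <- names(object$coding)[ifelse(sign(y_hat) == sign(object$coding[1]),
                                     1L, 2L)]
  out <- list(t_pred = t_pred, T_orth = T_o, y_hat = y_hat, class = cls)
  if (!is.null(y)) {
    if (!is.numeric(y)) y <- unname(object$coding[as.character(y)])
    out$R2Y_pred <- 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  }
  out
}

# stratified fold assignment; with `groups`, whole groups are assigned to
# folds (stratified by the group's majority class)
.make_folds <- function(y, k_folds, seed, groups = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  if (is.null(groups)) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- rep_len(seq_len(k_folds), length(idx))[sample(length(idx))]
    }
  } else {
    gs <- unique(groups)
    gf <- rep_len(seq_len(k_folds), length(gs))[sample(length(gs))]
    fold <- gf[match(groups, gs)]
  }
  fold
}

#' Cross-validated predictive ability (Q2Y)
#'
#' Stratified k-fold cross-validation of the OPLS-DA model. Auto-scaling
#' is refit inside each training fold (no leakage); held-out samples are
#' projected with the training constants. `Q2Y = 1 - sum(PRESS) /
#' SS(y - mean(y))`.
#'
#' @param X Numeric matrix or [bucket_table()]; when `scale = TRUE` it
#'   should be unscaled (normalized) data.
#' @param y Class labels as in [fit_opls_da()].
#' @param n_orth Number of orthogonal components.
#' @param k_folds Number of folds (`>= 2`).
#' @param seed Integer seed for the fold assignment.
#' @param groups Optional grouping vector (e.g. subject ids); whole groups
#'   are held out together.
#' @param scale If `TRUE`, auto-scale within each fold (and for the full
#'   fit); set `FALSE` when `X` is already scaled.
#' @param coding Class coding as in [fit_opls_da()].
#' @return An object of class `cv_result`: `Q2Y`, `R2Y` (full fit),
#'   per-fold `press`, `fold` assignment, `y_hat_cv`, `n_orth`, `k_folds`.
#' @export
cross_validate <- function(X, y, n_orth = 0, k_folds = 7, seed = 1,
                           groups = NULL, scale = TRUE,
                           coding = c(SSS = 1, SSN = -1)) {
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  if (!is.numeric(y)) y <- unname(coding[as.character(y)])
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (k_folds > nrow(X)) stop("more folds than samples")
  fold <- .make_folds(y, k_folds, seed, groups)
  y_mean <- mean(y)
  y_hat_cv <- numeric(length(y))
  press <- numeric(k_folds)
  for (k in seq_len(k_folds)) {
    tr <- fold != k; te <- !tr
    if (!any(te)) next
    if (length(unique(y[tr])) < 2)
      stop("fold ", k, " leaves a single-class training set")
    Xtr <- X[tr, , drop = FALSE]
    if (scale) {
      sc <- .scale_fit(Xtr)
      Xtr <- .scale_apply(Xtr, sc)
      Xte <- .scale_apply(X[te, , drop = FALSE], sc)
    } else {
      Xte <- X[te, , drop = FALSE]
    }
    ytr <- y[tr]
    core <- .opls_core(Xtr, ytr - mean(ytr), n_orth)
    for (i in seq_len(ncol(core$T_orth)))
      Xte <- Xte - tcrossprod(Xte %*% core$W_orth[, i], core$P_orth[, i])
    yh <- mean(ytr) + c(Xte %*% core$w) * core$q
    y_hat_cv[te] <- yh
    press[k] <- sum((y[te] - yh)^2)
  }
  q2 <- 1 - sum(press) / sum((y - y_mean)^2)
  Xs <- if (scale) .scale_apply(X, .scale_fit(X)) else X
  full <- .opls_core(Xs, y - y_mean, n_orth)
  r2 <- 1 - sum((y - (y_mean + full$t * full$q))^2) / sum((y - y_mean)^2)
  structure(list(Q2Y = q2, R2Y = r2, press = press, fold = fold,
                 y_hat_cv = y_hat_cv, n_orth = n_orth, k_folds = k_folds,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> Q2Y = %.3f, R2Y = %.3f (%d-fold, %d orth)\n",
              x$Q2Y, x$R2Y, x$k_folds, x$n_orth))
  invisible(x)
}

#' Choose the number of orthogonal components automatically
#'
#' Adds orthogonal components while cross-validated Q2Y improves by more
#' than `min_gain`.
#'
#' @inheritParams cross_validate
#' @param max_orth Largest number of orthogonal components to consider.
#' @param min_gain Minimal Q2Y improvement to accept a component.
#' @return List with `n_orth` and the per-candidate `q2` path.
#' @export
select_n_orth <- function(X, y, max_orth = 5, k_folds = 7, seed = 1,
                          groups = NULL, scale = TRUE, min_gain = 0.01,
                          coding = c(SSS = 1, SSN = -1)) {
  q2 <- numeric(0)
  best <- 0
  for (a in 0:max_orth) {
    q2[a + 1] <- cross_validate(X, y, n_orth = a, k_folds = k_folds,
                                seed = seed, groups = groups, scale = scale,
                                coding = coding)$Q2Y
    if (a > 0 && q2[a + 1] < q2[best + 1] + min_gain) break
    if (a > 0) best <- a
  }
  list(n_orth = best, q2 = q2)
}

#' Variable importance in projection (VIP)
#'
#' Predictive-component VIP: with a single predictive component,
#' `VIP_j = sqrt(K) * |w_j| / ||w||`, so the mean squared VIP is exactly 1.
#' The `total` variant weighs predictive and orthogonal weights by the
#' y-variance each component explains (orthogonal components explain none,
#' so the two variants agree up to numerical noise).
#'
#' @param model A fitted `opls_model`.
#' @param total If `TRUE`, include orthogonal components weighted by
#'   explained y-variance.
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip <- function(model, total = FALSE) {
  stopifnot(inherits(model, "opls_model"))
  K <- length(model$w)
  if (!total) return(sqrt(K) * abs(model$w) / sqrt(sum(model$w^2)))
  yc <- model$y - model$y_mean
  comp_w <- cbind(model$w, model$W_orth)
  comp_t <- cbind(model$t, model$T_orth)
  ssy <- apply(comp_t, 2, function(t) {
    b <- sum(yc * t) / sum(t^2)
    sum((b * t)^2)
  })
  sqrt(K * colSums(t(comp_w^2) * ssy) / sum(ssy))
}

#' Correlation loadings
#'
#' Pearson correlation of each variable with the predictive score, oriented
#' so that a positive value means the variable is elevated in
#' `positive_class` (default: the class coded -1, i.e. non-survivors under
#' the default coding, matching the usual loading-plot convention).
#'
#' @param model A fitted `opls_model`.
#' @param X_scaled The training matrix the model was fitted on (matrix or
#'   scaled [bucket_table()]).
#' @param positive_class Class whose elevation is reported as positive
#'   correlation; `NULL` for the raw (unoriented) correlation with the
#'   predictive score.
#' @return Numeric vector of correlations, one per variable.
#' @export
loading_correlations <- function(model, X_scaled, positive_class = "SSN") {
  stopifnot(inherits(model, "opls_model"))
  if (inherits(X_scaled, "bucket_table")) X_scaled <- X_scaled$values
  t <- model$t
  tc <- t - mean(t)
  xc <- sweep(as.matrix(X_scaled), 2, colMeans(X_scaled))
  denom <- unname(sqrt(colSums(xc^2))) * sqrt(sum(tc^2))
  r <- as.numeric(crossprod(xc, tc)) / ifelse(denom == 0, Inf, denom)
  if (!is.null(positive_class)) {
    if (!positive_class %in% names(model$coding))
      stop("positive_class not in the model's coding")
    r <- r * sign(model$q) * unname(model$coding[positive_class])
  }
  r
}

#' Score plot of a fitted OPLS-DA model
#'
#' @param x A fitted `opls_model`.
#' @param labels Optional class labels for coloring.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.opls_model <- function(x, labels = NULL, ...) {
  t2 <- if (x$n_orth > 0) x$T_orth[, 1] else seq_along(x$t)
  col <- if (is.null(labels)) 1L else as.integer(factor(labels)) + 1L
  graphics::plot(x$t, t2, col = col, pch = 19,
                 xlab = "T_pred",
                 ylab = if (x$n_orth > 0) "T_orth[1]" else "sample index",
                 ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
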