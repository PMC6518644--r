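#' Within/between-subject decomposition
#'
#' Splits a repeated-measures data matrix into the between-subject part
#' (subject means) and the within-subject part (each sample minus its
#' subject mean). The decomposition is exact: broadcasting the subject
#' means back over samples and adding the within part reconstructs `X`.
#' This removes inter-individual offsets so that paired (e.g. admission
#' vs 24 h) effects can be modeled on the within part alone.
#'
#' @param X Numeric matrix or [bucket_table()], samples in rows.
#' @param subject_ids Subject identifier per row; every subject must have
#'   at least two samples.
#' @return An object of class `paired_split`: `X_within` (samples x
#'   variables), `X_between` (subjects x variables), `subject_ids`,
#'   `subject_of_row` (row index into `X_between`).
#' @export
split_within_between <- function(X, subject_ids) {
  if (inherits(X, "bucket_table")) X <- X$values
  X <- as.matrix(X)
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(X))
    stop("one subject id is required per row")
  counts <- table(subject_ids)
  if (any(counts < 2))
    stop("subject(s) with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  between <- rowsum(X, subject_ids) / as.vector(counts[sort(unique(subject_ids))])
  # rowsum sorts groups; align explicitly
  subj_levels <- rownames(between)
  idx <- match(subject_ids, subj_levels)
  within <- X - between[idx, , drop = FALSE]
  structure(list(X_within = within, X_between = between,
                 subject_ids = subject_ids, subject_of_row = idx),
            class = "paired_split")
}

#' Paired multilevel OPLS-DA (H0 vs H24 within one outcome group)
#'
#' Fits an OPLS-DA model separating the two timepoints of paired samples
#' on the within-subject part of the training subjects, then projects the
#' held-out pairs. Test pairs are centered by their own subject mean (the
#' subject mean is a nuisance parameter by construction, so the projection
#' is self-contained) and scaled with the training constants.
#'
#' @param table A normalized (unscaled) [bucket_table()] or numeric matrix.
#' @param meta Sample metadata data frame with `sample_id`, `subject_id`,
#'   `timepoint` (`"H0"`/`"H24"`), `outcome`, `role` (`"train"`/`"test"`);
#'   rows must align with the table.
#' @param outcome Which outcome group to model (`"SSS"` or `"SSN"`).
#' @param n_orth Number of orthogonal components.
#' @param k_folds,seed Cross-validation parameters; folds hold out whole
#'   subjects (pairs are never split).
#' @param coding Timepoint coding; default `c(H0 = 1, H24 = -1)`.
#' @return List of class `paired_model`: `model` (the fitted
#'   `opls_model`), `cv` (`cv_result` on the training within part),
#'   `scaling`, `train_meta`, `test_report` (data frame with per-sample
#'   predicted timepoint), `test_accuracy`, `test_r2y_pred`.
#' @export
fit_paired_model <- function(table, meta, outcome = c("SSS", "SSN"),
                             n_orth = 0, k_folds = 7, seed = 1,
                             coding = c(H0 = 1, H24 = -1)) {
  outcome <- match.arg(outcome)
  X <- if (inherits(table, "bucket_table")) table$values else as.matrix(table)
  if (nrow(X) != nrow(meta)) stop("table and meta must align row-wise")
  keep <- meta$outcome == outcome
  meta <- meta[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  # complete pairs only
  tp <- base::table(meta$subject_id, meta$timepoint)
  if (!all(c("H0", "H24") %in% colnames(tp)))
    stop("no complete H0/H24 pairs for outcome ", outcome)
  complete <- rownames(tp)[rowSums(tp[, c("H0", "H24"), drop = FALSE] > 0) == 2]
  if (length(complete) == 0)
    stop("no complete H0/H24 pairs for outcome ", outcome)
  keep <- meta$subject_id %in% complete
  meta <- meta[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]

  is_train <- meta$role == "train"
  if (sum(is_train) < 4) stop("too few training pairs for outcome ", outcome)
  split_tr <- split_within_between(X[is_train, , drop = FALSE],
                                   meta$subject_id[is_train])
  sc <- .scale_fit(split_tr$X_within)
  Xtr <- .scale_apply(split_tr$X_within, sc)
  y_tr <- unname(coding[meta$timepoint[is_train]])
  model <- fit_opls_da(Xtr, y_tr, n_orth = n_orth, coding = coding,
                       scaling = structure(sc, class = "scaling_constants"))
  cv <- cross_validate(split_tr$X_within, y_tr, n_orth = n_orth,
                       k_folds = min(k_folds, length(unique(meta$subject_id[is_train]))),
                       seed = seed, groups = meta$subject_id[is_train],
                       scale = TRUE, coding = coding)
  model$Q2Y <- cv$Q2Y

  test_report <- NULL; test_accuracy <- NA_real_; test_r2y <- NA_real_
  if (any(!is_train)) {
    split_te <- split_within_between(X[!is_train, , drop = FALSE],
                                     meta$subject_id[!is_train])
    Xte <- .scale_apply(split_te$X_within, sc)
    y_te <- unname(coding[meta$timepoint[!is_train]])
    pr <- predict(model, Xte, y = y_te)
    test_report <- data.frame(
      sample_id = meta$sample_id[!is_train],
      subject_id = meta$subject_id[!is_train],
      timepoint = meta$timepoint[!is_train],
      t_pred = pr$t_pred, y_hat = pr$y_hat,
      predicted_timepoint = pr$class,
      stringsAsFactors = FALSE
    )
    test_accuracy <- mean(test_report$predicted_timepoint ==
                            test_report$timepoint)
    test_r2y <- pr$R2Y_pred
  }
  structure(list(model = model, cv = cv,
                 scaling = structure(sc, class = "scaling_constants"),
                 outcome = outcome, coding = coding,
                 train_meta = meta[is_train, , drop = FALSE],
                 X_train_scaled = Xtr,
                 test_report = test_report,
                 test_accuracy = test_accuracy,
                 test_r2y_pred = test_r2y),
            class = "paired_model")
}

#' @export
print.paired_model <- function(x, ...) {
  cat("<paired_model>", x$outcome, ": ",
      nrow(x$train_meta) / 2, "training pairs\n")
  cat(sprintf("  R2Y = %.3f, Q2Y = %.3f", x$model$R2Y, x$cv$Q2Y))
  if (!is.na(x$test_accuracy))
    cat(sprintf(", test accuracy = %.2f, test R2Y_pred = %.3f",
                x$test_accuracy, x$test_r2y_pred))
  cat("\n")
  invisible(x)
}
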