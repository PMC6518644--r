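#' Two-sample Student's t screen with Bonferroni adjustment
#'
#' Pooled-variance two-sided Student's t test of one feature between two
#' groups, with the Bonferroni-adjusted p-value for a family of
#' `m_tests` features (`min(1, m * p)`). Welch's unequal-variance test is
#' available via `var_equal = FALSE`.
#'
#' @param group_a,group_b Numeric vectors (each `n >= 2`).
#' @param m_tests Number of tests in the family.
#' @param var_equal Pooled variance (Student, default) or Welch.
#' @return List with `t`, `p`, `p_adj`.
#' @export
ttest_screen <- function(group_a, group_b, m_tests = 1, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::sd(c(group_a, group_b)) == 0) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       p_adj = min(1, m_tests * tt$p.value))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values; features with `q` above the
#' screening threshold (0.1 in the serum profiling workflow) are treated
#' as non-discriminant.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Integrate a spectral window
#'
#' Trapezoidal integral of a (typically dilution-normalized, unscaled)
#' spectrum over a ppm window.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param window Length-2 `c(lo, hi)` ppm window inside the spectral range.
#' @return The integral (area).
#' @export
integrate_signal <- function(spectrum, window) {
  if (window[1] >= window[2]) stop("empty integration window")
  if (window[1] < min(spectrum$ppm) || window[2] > max(spectrum$ppm))
    stop("window outside the spectral range")
  ci <- .cum_integral_at(spectrum$ppm, spectrum$intensity, window)
  ci[2] - ci[1]
}

#' Per-metabolite signal areas from a bucket table
#'
#' Sums bucket integrals over each metabolite's integration windows
#' (overlap-weighted at window borders). Intended for a PQN-normalized,
#' unscaled table.
#'
#' @param table A [bucket_table()].
#' @param library Assignment library, see [default_metabolite_library()].
#' @return Samples x metabolites matrix of areas.
#' @export
metabolite_areas <- function(table, library) {
  stopifnot(inherits(table, "bucket_table"))
  lo <- table$edges[, 1]; hi <- table$edges[, 2]
  w <- hi - lo
  areas <- vapply(library, function(ms) {
    weight <- numeric(length(lo))
    for (i in seq_len(nrow(ms$peaks))) {
      ov <- pmin(hi, ms$peaks$window_hi[i]) - pmax(lo, ms$peaks$window_lo[i])
      weight <- weight + pmax(ov, 0) / w
    }
    weight <- pmin(weight, 1)
    as.numeric(table$values %*% weight)
  }, numeric(nrow(table$values)))
  areas <- matrix(areas, nrow = nrow(table$values),
                  dimnames = list(table$sample_ids, names(library)))
  areas
}

#' Per-subject time-trend change of integrated signals
#'
#' For paired samples, computes each subject's signed difference
#' `delta = area_H24 - area_H0`, plus group summaries (mean, SD) and the
#' two-sample comparison between outcome groups.
#'
#' @param areas Named numeric vector of areas (names = sample ids) for one
#'   metabolite, or a samples x metabolites matrix.
#' @param meta Metadata data frame (`sample_id`, `subject_id`,
#'   `timepoint`, `outcome`); only complete pairs are used.
#' @param m_tests Bonferroni family size for the group comparison.
#' @return For a vector input: list with `delta` (per-subject, named),
#'   `outcome` (per subject), `summary` (data frame per group), and the
#'   `t`/`p`/`p_adj` of the SSS vs SSN comparison. For a matrix: list of
#'   such results plus a combined `summary` data frame.
#' @export
delta_time_trend <- function(areas, meta, m_tests = 1) {
  if (is.matrix(areas)) {
    per <- lapply(colnames(areas), function(m)
      delta_time_trend(stats::setNames(areas[, m], rownames(areas)), meta,
                       m_tests = m_tests))
    names(per) <- colnames(areas)
    summary <- do.call(rbind, lapply(names(per), function(m) {
      s <- per[[m]]
      pick <- function(col, g) {
        v <- s$summary[[col]][s$summary$outcome == g]
        if (length(v)) v else NA_real_
      }
      data.frame(metabolite = m,
                 delta_mean_sss = pick("mean", "SSS"),
                 delta_sd_sss = pick("sd", "SSS"),
                 delta_mean_ssn = pick("mean", "SSN"),
                 delta_sd_ssn = pick("sd", "SSN"),
                 t = s$t, p = s$p, p_adj = s$p_adj,
                 stringsAsFactors = FALSE)
    }))
    return(list(per_metabolite = per, summary = summary))
  }
  idx <- match(meta$sample_id, names(areas))
  if (anyNA(idx)) stop("areas are missing some samples in meta")
  tp <- base::table(meta$subject_id, meta$timepoint)
  if (!all(c("H0", "H24") %in% colnames(tp)))
    stop("no complete H0/H24 pairs")
  complete <- rownames(tp)[rowSums(tp[, c("H0", "H24"), drop = FALSE] > 0) == 2]
  if (length(complete) == 0) stop("no complete H0/H24 pairs")
  delta <- vapply(complete, function(s) {
    a24 <- areas[meta$sample_id[meta$subject_id == s & meta$timepoint == "H24"]]
    a0 <- areas[meta$sample_id[meta$subject_id == s & meta$timepoint == "H0"]]
    unname(a24 - a0)
  }, numeric(1))
  outcome <- meta$outcome[match(complete, meta$subject_id)]
  summary <- do.call(rbind, lapply(unique(outcome), function(g)
    data.frame(outcome = g, n = sum(outcome == g),
               mean = mean(delta[outcome == g]),
               sd = stats::sd(delta[outcome == g]),
               stringsAsFactors = FALSE)))
  tt <- if (length(unique(outcome)) == 2)
    ttest_screen(delta[outcome == "SSS"], delta[outcome == "SSN"], m_tests)
  else list(t = NA_real_, p = NA_real_, p_adj = NA_real_)
  list(delta = delta, outcome = outcome, summary = summary,
       t = tt$t, p = tt$p, p_adj = tt$p_adj)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC computed from midranks (ties counted as half-concordant), with the
#' ROC curve from a full threshold sweep. Orientation is chosen
#' automatically so the reported AUC is `>= 0.5`, with the direction
#' recorded; set `auto_orient = FALSE` to keep the raw orientation
#' ("higher value predicts `positive`").
#'
#' @param values Numeric marker values.
#' @param labels Binary labels (factor, character or logical).
#' @param positive The label treated as positive (default: `"SSN"` if
#'   present, otherwise the second sorted level), so that by default a
#'   higher value predicting non-survival yields AUC > 0.5.
#' @param auto_orient Flip direction when the raw AUC is below 0.5.
#' @return List of class `roc_result` with `auc`, `direction` (`">"` if
#'   higher values indicate the positive class, `"<"` otherwise), and
#'   `curve` (data frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(values, labels, positive = NULL, auto_orient = TRUE) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- if ("SSN" %in% lev) "SSN" else lev[2]
  if (!positive %in% lev) stop("positive class not present in labels")
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(values)                       # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  direction <- ">"
  if (auto_orient && auc < 0.5) {
    auc <- 1 - auc
    direction <- "<"
  }
  v <- if (direction == ">") values else -values
  thr <- c(Inf, sort(unique(v), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(s) mean(v[pos] >= s), numeric(1)),
    fpr = vapply(thr, function(s) mean(v[!pos] >= s), numeric(1))
  )
  structure(list(auc = auc, direction = direction, positive = positive,
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (positive = %s, direction %s)\n",
              x$auc, x$positive, x$direction))
  invisible(x)
}

#' Per-metabolite feature report (the machine-readable screening table)
#'
#' Assembles, for each metabolite in the library, the univariate and
#' multivariate screening statistics of a two-group comparison: group
#' means of the integrated (normalized) signal, Student's t and raw p,
#' Bonferroni-adjusted p, Benjamini-Hochberg q, VIP (maximum over the
#' metabolite's buckets), oriented loading correlation, and ROC AUC.
#'
#' @param table_norm PQN-normalized, unscaled [bucket_table()].
#' @param meta Metadata aligned with the table rows.
#' @param library Assignment library.
#' @param model A fitted `opls_model` on the scaled version of the table
#'   (for VIP and loading correlations); may be `NULL` to skip those
#'   columns.
#' @param X_scaled The scaled matrix the model was fitted on.
#' @param group_var Metadata column holding the two classes.
#' @param positive_class Class reported as "elevated" for positive
#'   correlations and the ROC positive class.
#' @param fdr_threshold Features with `q` at or below this are flagged
#'   discriminant.
#' @return Data frame of class `feature_report`, one row per metabolite.
#' @export
feature_report <- function(table_norm, meta, library, model = NULL,
                           X_scaled = NULL, group_var = "outcome",
                           positive_class = "SSN", fdr_threshold = 0.1) {
  areas <- metabolite_areas(table_norm, library)
  groups <- meta[[group_var]]
  lev <- unique(groups)
  if (length(lev) != 2) stop("group_var must define exactly two groups")
  other <- setdiff(lev, positive_class)
  m <- ncol(areas)
  stats_list <- lapply(seq_len(m), function(j)
    ttest_screen(areas[groups == positive_class, j],
                 areas[groups == other, j], m_tests = m))
  p_raw <- vapply(stats_list, `[[`, numeric(1), "p")
  out <- data.frame(
    metabolite = colnames(areas),
    mean_positive = colMeans(areas[groups == positive_class, , drop = FALSE]),
    mean_reference = colMeans(areas[groups == other, , drop = FALSE]),
    t = vapply(stats_list, `[[`, numeric(1), "t"),
    p = p_raw,
    p_adj = vapply(stats_list, `[[`, numeric(1), "p_adj"),
    q = fdr_bh(p_raw),
    auc = vapply(seq_len(m), function(j)
      roc_auc(areas[, j], groups, positive = positive_class)$auc,
      numeric(1)),
    stringsAsFactors = FALSE
  )
  names(out)[names(out) == "mean_positive"] <-
    paste0("mean_", positive_class)
  names(out)[names(out) == "mean_reference"] <- paste0("mean_", other)
  if (!is.null(model)) {
    v <- vip(model)
    r_all <- loading_correlations(model, X_scaled,
                                  positive_class = positive_class)
    lo <- table_norm$edges[, 1]; hi <- table_norm$edges[, 2]
    out$vip <- NA_real_; out$correlation <- NA_real_
    for (j in seq_len(m)) {
      ms <- library[[out$metabolite[j]]]
      in_win <- rep(FALSE, length(lo))
      for (i in seq_len(nrow(ms$peaks)))
        in_win <- in_win | (pmin(hi, ms$peaks$window_hi[i]) -
                              pmax(lo, ms$peaks$window_lo[i]) > 0)
      if (any(in_win)) {
        out$vip[j] <- max(v[in_win])
        out$correlation[j] <- r_all[in_win][which.max(abs(r_all[in_win]))]
      }
    }
  }
  out$discriminant <- out$q <= fdr_threshold
  out <- out[order(-abs(out$t)), ]
  rownames(out) <- NULL
  class(out) <- c("feature_report", "data.frame")
  out
}
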