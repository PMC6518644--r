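#' Read / write spectra and metadata
#'
#' Spectra travel as two-column delimited text (ppm, intensity) with a
#' header; a descending ppm axis is accepted and reordered ascending.
#' Metadata is a CSV with columns `sample_id`, `subject_id`, `timepoint`
#' (`H0`/`H24`), `outcome` (`SSS`/`SSN`), `role` (`train`/`test`).
#'
#' @param path File path.
#' @param sample_id Sample id for the spectrum; defaults to the file name.
#' @return `read_spectrum_file()`: an [nmr_spectrum()];
#'   `read_metadata()`: a validated data frame.
#' @export
read_spectrum_file <- function(path, sample_id = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = ",")
  if (ncol(d) < 2) stop("expected two columns (ppm, intensity) in ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  nmr_spectrum(d[[1]], d[[2]], sample_id)
}

#' @rdname read_spectrum_file
#' @param spectrum An [nmr_spectrum()].
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectrum_file
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "subject_id", "timepoint", "outcome", "role")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ",
                        paste(unique(dup), collapse = ", "))
  key <- paste(meta$subject_id, meta$timepoint)
  dup <- key[duplicated(key)]
  if (length(dup)) stop("duplicate (subject_id, timepoint): ",
                        paste(unique(dup), collapse = ", "))
  if (!all(meta$timepoint %in% c("H0", "H24")))
    stop("timepoint must be H0 or H24")
  if (!all(meta$outcome %in% c("SSS", "SSN")))
    stop("unknown outcome label(s): ",
         paste(setdiff(meta$outcome, c("SSS", "SSN")), collapse = ", "))
  if (!all(meta$role %in% c("train", "test")))
    stop("role must be train or test")
  meta
}

#' Write / read a simulated cohort as plain-text files
#'
#' One CSV per spectrum plus `metadata.csv` and `truth.csv` (planted
#' concentrations and dilution factors).
#'
#' @param cohort An `nmr_cohort` from [simulate_cohort()].
#' @param dir Output / input directory.
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a list
#'   with `spectra`, `meta`, and (if present) `truth`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in cohort$spectra)
    write_spectrum(sp, file.path(dir, paste0(sp$sample_id, ".csv")))
  utils::write.csv(cohort$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  truth <- data.frame(sample_id = rownames(cohort$truth$concentrations),
                      dilution = unname(cohort$truth$dilution),
                      cohort$truth$concentrations, check.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  spectra <- lapply(meta$sample_id, function(id)
    read_spectrum_file(file.path(dir, paste0(id, ".csv")), sample_id = id))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, check.names = FALSE) else NULL
  list(spectra = spectra, meta = meta, truth = truth)
}

#' Pipeline configuration defaults
#'
#' All defaults equal the study's stated processing parameters: 0.001 ppm
#' buckets over -1..10 ppm, exclusion of the residual water (4.6-5.5 ppm)
#' and HES infusion (3.16-4.0 ppm) regions, PQN normalization, full
#' auto-scaling, 7-fold cross-validation, 500 permutations, FDR screening
#' threshold 0.1.
#'
#' @param ... Overrides of individual fields.
#' @return A named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    width_ppm = 0.001, range_ppm = c(-1, 10),
    exclude = list(c(4.6, 5.5), c(3.16, 4.0)),
    n_orth = 2, k_folds = 7, n_perm = 500,
    fdr_threshold = 0.1, seed = 1,
    coding = c(SSS = 1, SSN = -1),
    paired_coding = c(H0 = 1, H24 = -1)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run one of the study's analyses end to end
#'
#' Orchestrates the full chain for one analysis: bucketing, region
#' exclusion, PQN normalization, then either an unpaired OPLS-DA of
#' survivors vs non-survivors at one timepoint (`"h0"` / `"h24"`) with
#' auto-scaling, cross-validation, optional permutation validation and a
#' per-metabolite feature report, or a paired multilevel model separating
#' H0 from H24 within one outcome group (`"paired-sss"` / `"paired-ssn"`)
#' with held-out pair projection and time-trend quantification.
#'
#' @param spectra List of [nmr_spectrum()] (or an `nmr_cohort`, in which
#'   case `meta` is taken from it).
#' @param meta Sample metadata (see [read_metadata()]).
#' @param analysis One of `"h0"`, `"h24"`, `"paired-sss"`, `"paired-ssn"`.
#' @param library Assignment library.
#' @param config A [pipeline_config()].
#' @param permutations If `TRUE`, run the permutation validation
#'   (`config$n_perm` permutations).
#' @param out_dir Optional directory; when given, scores, loadings,
#'   feature report, permutation rows and a provenance record (resolved
#'   parameters and seed) are written as CSV/JSON.
#' @return A list of class `nmr_analysis` whose elements depend on the
#'   analysis: always `table_norm`, `pqn_factors`, `config`; unpaired:
#'   `model`, `cv`, `features`, optionally `permutation`; paired:
#'   `paired` (a `paired_model`), `delta` (time trends).
#' @export
run_analysis <- function(spectra, meta = NULL,
                         analysis = c("h0", "h24", "paired-sss",
                                      "paired-ssn"),
                         library = default_metabolite_library(),
                         config = pipeline_config(),
                         permutations = FALSE, out_dir = NULL) {
  analysis <- match.arg(analysis)
  if (inherits(spectra, "nmr_cohort")) {
    meta <- spectra$meta
    spectra <- spectra$spectra
  }
  if (is.null(meta)) stop("sample metadata is required")
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  if (!setequal(ids, meta$sample_id))
    stop("spectra and metadata sample ids disagree")
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]

  tab <- bucket_spectra(spectra, width_ppm = config$width_ppm,
                        range_ppm = config$range_ppm)
  tab <- exclude_regions(tab, regions = config$exclude)
  pqn <- pqn_normalize(tab)
  tab_n <- pqn$table

  res <- list(table_norm = tab_n, pqn_factors = pqn$factors,
              meta = meta, analysis = analysis, config = config)

  if (analysis %in% c("h0", "h24")) {
    tp <- toupper(analysis)
    keep <- meta$timepoint == tp
    if (!any(keep)) stop("no samples at timepoint ", tp)
    sub <- bucket_table(tab_n$values[keep, , drop = FALSE], tab_n$edges,
                        tab_n$sample_ids[keep], normalized = TRUE)
    sub_meta <- meta[keep, , drop = FALSE]
    if (length(unique(sub_meta$outcome)) < 2)
      stop("both outcome groups are required at ", tp)
    sc <- autoscale(sub)
    y <- sub_meta$outcome
    model <- fit_opls_da(sc$table, y, n_orth = config$n_orth,
                         coding = config$coding, scaling = sc$constants)
    cv <- cross_validate(sub, y, n_orth = config$n_orth,
                         k_folds = config$k_folds, seed = config$seed,
                         coding = config$coding)
    model$Q2Y <- cv$Q2Y
    res$model <- model; res$cv <- cv
    res$features <- feature_report(sub, sub_meta, library, model = model,
                                   X_scaled = sc$table,
                                   fdr_threshold = config$fdr_threshold)
    if (permutations)
      res$permutation <- permutation_test(sub, y, n_orth = config$n_orth,
                                          n_perm = config$n_perm,
                                          k_folds = config$k_folds,
                                          seed = config$seed,
                                          coding = config$coding)
  } else {
    outcome <- if (analysis == "paired-sss") "SSS" else "SSN"
    res$paired <- fit_paired_model(tab_n, meta, outcome = outcome,
                                   n_orth = config$n_orth,
                                   k_folds = config$k_folds,
                                   seed = config$seed,
                                   coding = config$paired_coding)
    # time-trend quantification compares the two outcome groups, so it
    # uses every complete pair regardless of the modeled group
    areas <- metabolite_areas(tab_n, library)
    paired_subj <- names(which(base::table(meta$subject_id) == 2))
    keep <- meta$subject_id %in% paired_subj
    res$delta <- delta_time_trend(areas[keep, , drop = FALSE],
                                  meta[keep, , drop = FALSE],
                                  m_tests = ncol(areas))
  }
  class(res) <- "nmr_analysis"
  if (!is.null(out_dir)) .write_analysis(res, out_dir)
  res
}

#' @export
print.nmr_analysis <- function(x, ...) {
  cat("<nmr_analysis>", x$analysis, "\n")
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$paired)) print(x$paired)
  invisible(x)
}

.write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  if (!is.null(res$model)) {
    w(data.frame(sample_id = res$model$scores_ids %||%
                   seq_along(res$model$t),
                 t_pred = res$model$t, res$model$T_orth,
                 y_hat = res$model$fitted), "scores.csv")
    w(data.frame(variable = seq_along(res$model$w), w = res$model$w,
                 p = res$model$p, vip = vip(res$model)), "loadings.csv")
    w(as.data.frame(res$features), "feature_report.csv")
  }
  if (!is.null(res$permutation))
    w(data.frame(r2 = res$permutation$r2, q2 = res$permutation$q2,
                 y_correlation = res$permutation$y_correlation),
      "permutations.csv")
  if (!is.null(res$paired)) {
    if (!is.null(res$paired$test_report))
      w(res$paired$test_report, "paired_test_report.csv")
    w(res$delta$summary, "delta_summary.csv")
  }
  prov <- list(analysis = res$analysis, config = res$config,
               n_samples = nrow(res$meta),
               package_version = as.character(utils::packageVersion("nmropls")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export a bucket table as CSV (+ JSON sidecar of edges and flags)
#'
#' @param table A [bucket_table()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `read_bucket_table()`: the restored [bucket_table()].
#' @export
write_bucket_table <- function(table, path) {
  stopifnot(inherits(table, "bucket_table"))
  d <- data.frame(sample_id = table$sample_ids, table$values,
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(
    list(lo = table$edges[, 1], hi = table$edges[, 2],
         normalized = table$normalized, scaled = table$scaled),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bucket_table
#' @export
read_bucket_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bucket_table(as.matrix(d[, -1, drop = FALSE]),
               cbind(side$lo, side$hi), sample_ids = d$sample_id,
               normalized = side$normalized, scaled = side$scaled)
}
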