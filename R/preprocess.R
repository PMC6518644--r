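#' Construct a bucket table
#'
#' The samples x buckets matrix that every downstream model consumes, with
#' the half-open ppm interval of each bucket and provenance flags.
#'
#' @param values Numeric matrix, samples in rows.
#' @param edges Two-column matrix of bucket intervals `[lo, hi)` in ppm,
#'   strictly increasing and non-overlapping.
#' @param sample_ids Row identifiers.
#' @param normalized,scaled Provenance flags.
#' @return An object of class `bucket_table`.
#' @export
bucket_table <- function(values, edges, sample_ids = rownames(values),
                         normalized = FALSE, scaled = FALSE) {
  values <- as.matrix(values)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L || nrow(edges) != ncol(values))
    stop("edges must be a 2-column matrix with one row per bucket")
  if (any(edges[, 2] <= edges[, 1])) stop("bucket intervals must be non-empty")
  if (nrow(edges) > 1 && any(edges[-1, 1] < edges[-nrow(edges), 2] - 1e-12))
    stop("bucket intervals must be increasing and non-overlapping")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  rownames(values) <- sample_ids
  colnames(values) <- sprintf("%.4f", rowMeans(edges))
  structure(list(values = values, edges = edges,
                 sample_ids = as.character(sample_ids),
                 normalized = normalized, scaled = scaled),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat("<bucket_table>", nrow(x$values), "samples x", ncol(x$values),
      "buckets,", sprintf("%.3f..%.3f ppm", min(x$edges), max(x$edges)),
      if (x$normalized) "(normalized)" else "",
      if (x$scaled) "(scaled)" else "", "\n")
  invisible(x)
}

#' @export
dim.bucket_table <- function(x) dim(x$values)

# cumulative trapezoidal integral of a spectrum evaluated at arbitrary ppm
# positions (linear interpolation between grid points)
.cum_integral_at <- function(ppm, intensity, at) {
  ci <- c(pracma::cumtrapz(ppm, intensity))
  stats::approx(ppm, ci, xout = at, rule = 2)$y
}

#' Bucket one spectrum onto a fixed-width grid
#'
#' Divides the spectral range into half-open `[lo, lo + width)` buckets and
#' integrates the intensity (trapezoidal rule) over each interval. Bucket
#' values are integrals, not means, so total spectral area is conserved and
#' dilution acts multiplicatively on every bucket.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param width_ppm Bucket width in ppm.
#' @param range_ppm Length-2 retained spectral range in ppm.
#' @return List with `values` (numeric vector) and `edges` (2-column matrix).
#' @export
bucket_spectrum <- function(spectrum, width_ppm = 0.001,
                            range_ppm = c(-1, 10)) {
  if (width_ppm <= 0) stop("width_ppm must be > 0")
  lo <- min(spectrum$ppm); hi <- max(spectrum$ppm)
  tol <- 1e-9
  if (lo > range_ppm[1] + tol || hi < range_ppm[2] - tol)
    stop(sprintf(
      "spectrum [%.4f, %.4f] does not cover the bucketing range [%.4f, %.4f]",
      lo, hi, range_ppm[1], range_ppm[2]))
  n <- round((range_ppm[2] - range_ppm[1]) / width_ppm)
  breaks <- range_ppm[1] + (0:n) * width_ppm
  ci <- .cum_integral_at(spectrum$ppm, spectrum$intensity, breaks)
  list(values = diff(ci),
       edges = cbind(lo = breaks[-(n + 1)], hi = breaks[-1]))
}

#' Bucket a set of spectra into a bucket table
#'
#' @param spectra List of [nmr_spectrum()] objects.
#' @inheritParams bucket_spectrum
#' @return A [bucket_table()].
#' @export
bucket_spectra <- function(spectra, width_ppm = 0.001, range_ppm = c(-1, 10)) {
  rows <- lapply(spectra, bucket_spectrum, width_ppm = width_ppm,
                 range_ppm = range_ppm)
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  ids <- vapply(spectra, `[[`, character(1), "sample_id")
  bucket_table(values, rows[[1]]$edges, sample_ids = ids)
}

#' Drop buckets intersecting excluded spectral regions
#'
#' Removes every bucket whose half-open interval has a non-degenerate
#' overlap with any of the given regions (default: the residual water
#' signal 4.6-5.5 ppm and the hydroxyethyl-starch infusion region
#' 3.16-4.0 ppm).
#'
#' @param table A [bucket_table()].
#' @param regions List of length-2 `c(lo, hi)` ppm regions, treated as
#'   half-open `[lo, hi)`.
#' @return The reduced [bucket_table()].
#' @export
exclude_regions <- function(table,
                            regions = list(c(4.6, 5.5), c(3.16, 4.0))) {
  stopifnot(inherits(table, "bucket_table"))
  keep <- rep(TRUE, nrow(table$edges))
  tol <- 1e-9
  for (r in regions) {
    ov <- pmin(table$edges[, 2], r[2]) - pmax(table$edges[, 1], r[1])
    keep <- keep & (ov <= tol)
  }
  bucket_table(table$values[, keep, drop = FALSE],
               table$edges[keep, , drop = FALSE],
               sample_ids = table$sample_ids,
               normalized = table$normalized, scaled = table$scaled)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: each row is first normalized to the common
#' total area, a reference spectrum is formed as the per-bucket median
#' across rows, and each row is divided by the median of its bucket-wise
#' quotients against the reference. The returned `factors` are the overall
#' per-sample dilution estimates (area factor x quotient factor), so
#' `original_row / factor = normalized_row` up to the common area constant.
#'
#' @param table A [bucket_table()] (not yet scaled).
#' @param reference Reference spectrum rule; only `"median"` (the
#'   per-bucket median across samples) is implemented.
#' @return List with `table` (normalized [bucket_table()]) and `factors`
#'   (named numeric vector of estimated dilution factors).
#' @export
pqn_normalize <- function(table, reference = c("median")) {
  stopifnot(inherits(table, "bucket_table"))
  reference <- match.arg(reference)
  if (table$scaled) stop("normalize before scaling")
  x <- table$values
  totals <- rowSums(x)
  if (any(totals <= 0))
    stop("non-positive total area for sample(s): ",
         paste(table$sample_ids[totals <= 0], collapse = ", "))
  common <- stats::median(totals)
  area_factor <- totals / common
  xr <- x / area_factor
  ref <- apply(xr, 2, stats::median)
  use <- ref != 0
  if (!any(use)) stop("reference spectrum is identically zero")
  quot_factor <- apply(xr[, use, drop = FALSE], 1,
                       function(r) stats::median(r / ref[use]))
  out <- xr / quot_factor
  factors <- area_factor * quot_factor
  names(factors) <- table$sample_ids
  list(table = bucket_table(out, table$edges, table$sample_ids,
                            normalized = TRUE, scaled = FALSE),
       factors = factors)
}

#' Auto-scale a bucket table (fit) / apply stored scaling constants
#'
#' `autoscale()` centers every bucket and divides by its sample standard
#' deviation (n - 1), capturing the constants so that held-out samples can
#' be projected with `apply_scaling()`. Buckets with zero variance get a
#' unit divisor (with a warning).
#'
#' @param table A [bucket_table()].
#' @param center_only If `TRUE`, only mean-center (no variance scaling).
#' @return `autoscale()`: list with `table` and `constants` (class
#'   `scaling_constants`: per-bucket `mean` and `sd`). `apply_scaling()`:
#'   the scaled [bucket_table()].
#' @export
autoscale <- function(table, center_only = FALSE) {
  stopifnot(inherits(table, "bucket_table"))
  x <- table$values
  mu <- colMeans(x)
  if (center_only) {
    sdv <- rep(1, ncol(x))
  } else {
    sdv <- apply(x, 2, stats::sd)
    if (anyNA(sdv)) sdv[is.na(sdv)] <- 0
    if (any(sdv == 0)) {
      warning(sum(sdv == 0), " constant bucket(s); unit variance assumed")
      sdv[sdv == 0] <- 1
    }
  }
  constants <- structure(list(mean = mu, sd = sdv), class = "scaling_constants")
  list(table = apply_scaling(table, constants), constants = constants)
}

#' @rdname autoscale
#' @param constants A `scaling_constants` object from `autoscale()`.
#' @export
apply_scaling <- function(table, constants) {
  stopifnot(inherits(table, "bucket_table"),
            inherits(constants, "scaling_constants"))
  if (length(constants$mean) != ncol(table$values))
    stop("scaling constants do not match the bucket count")
  x <- sweep(sweep(table$values, 2, constants$mean), 2, constants$sd, "/")
  bucket_table(x, table$edges, table$sample_ids,
               normalized = table$normalized, scaled = TRUE)
}

# fast internal scaling on plain matrices (used inside CV loops)
.scale_fit <- function(x) {
  mu <- colMeans(x)
  n <- nrow(x)
  v <- (colSums(x * x) - n * mu^2) / (n - 1)
  sdv <- sqrt(pmax(v, 0))
  sdv[sdv < .Machine$double.eps^0.5] <- 1
  list(mean = mu, sd = sdv)
}
.scale_apply <- function(x, sc) {
  x <- sweep(x, 2, sc$mean)
  sweep(x, 2, sc$sd, "/")
}

#' PCA outlier screen via Hotelling's T-squared
#'
#' Principal component analysis by singular value decomposition; a sample
#' is flagged as an outlier when its Hotelling T-squared over the retained
#' components exceeds the F-distribution critical value at level
#' `1 - alpha`.
#'
#' @param table A [bucket_table()] (centered or scaled) or numeric matrix.
#' @param n_components Number of retained components.
#' @param alpha Flagging level.
#' @return List with `scores` (samples x components), `t2` (per-sample
#'   T-squared), `limit` (critical value), and `flagged` (sample ids).
#' @export
pca_outlier_screen <- function(table, n_components = 2, alpha = 0.01) {
  x <- if (inherits(table, "bucket_table")) table$values else as.matrix(table)
  n <- nrow(x)
  a <- n_components
  if (a >= n) stop("n_components must be smaller than the sample count")
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x, nu = a, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(a)], a, a)
  lambda <- sv$d[seq_len(a)]^2 / (n - 1)
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  limit <- a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
  ids <- if (inherits(table, "bucket_table")) table$sample_ids
         else rownames(x) %||% as.character(seq_len(n))
  list(scores = scores, t2 = t2, limit = limit, flagged = ids[t2 > limit])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
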