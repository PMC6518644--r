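#' Uniform ppm axis
#'
#' @param from,to Axis limits in ppm (ascending).
#' @param step Grid step in ppm.
#' @return Numeric vector of ppm values, strictly ascending, uniform.
#' @export
ppm_axis <- function(from = -1, to = 10, step = 5e-4) {
  if (step <= 0 || to <= from) stop("invalid axis specification")
  n <- round((to - from) / step)
  from + (0:n) * step
}

#' Construct a spectrum object
#'
#' @param ppm Strictly monotone ppm axis.
#' @param intensity Intensity values, same length as `ppm`.
#' @param sample_id Sample identifier.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id = "sample") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have the same length")
  d <- diff(ppm)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("ppm axis must be strictly monotone")
  if (d[1] < 0) {            # store ascending; files may come reversed
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id)),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("<nmr_spectrum>", x$sample_id, ":", length(x$ppm), "points,",
      sprintf("%.3f..%.3f ppm\n", min(x$ppm), max(x$ppm)))
  invisible(x)
}

# Unit-area Lorentzian (Cauchy) line; fwhm in ppm.
.lorentz <- function(x, x0, fwhm) {
  (2 / (pi * fwhm)) / (1 + (2 * (x - x0) / fwhm)^2)
}

# Compact-support artifact shapes: identically zero outside their region so
# the downstream exclusion windows remove them completely.
.water_hump <- function(ppm, amplitude, region = c(4.6, 5.5)) {
  inside <- ppm >= region[1] & ppm <= region[2]
  out <- numeric(length(ppm))
  out[inside] <- amplitude *
    sin(pi * (ppm[inside] - region[1]) / diff(region))^2
  out
}

.hes_signal <- function(ppm, amplitude, region = c(3.16, 4.0)) {
  centers <- c(3.35, 3.45, 3.58, 3.72, 3.85)
  out <- numeric(length(ppm))
  inside <- ppm >= region[1] & ppm <= region[2]
  if (!any(inside)) return(out)
  x <- ppm[inside]
  v <- 0
  for (c0 in centers) v <- v + .lorentz(x, c0, 0.04)
  # taper to zero at the region boundaries
  taper <- sin(pi * (x - region[1]) / diff(region))^2
  out[inside] <- amplitude * 0.04 * v * taper
  out
}

#' Render a synthetic serum 1H NMR spectrum
#'
#' Forward model: each metabolite contributes unit-area Lorentzian lines at
#' its multiplet positions, scaled by concentration and relative area; the
#' whole serum signal (metabolites, smooth macromolecule baseline, and
#' HES-like infusion signals in 3.16-4.0 ppm) is multiplied by the sample
#' dilution factor; a residual-water hump (solvent, not scaled by dilution)
#' is added inside 4.6-5.5 ppm; finally i.i.d. Gaussian noise is added.
#'
#' @param concentrations Named numeric vector of metabolite concentrations
#'   (arbitrary units, all `>= 0`); names must exist in `library`.
#' @param library Assignment library, see [default_metabolite_library()].
#' @param ppm Uniform ascending ppm axis, see [ppm_axis()].
#' @param dilution Multiplicative dilution factor.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (intensity units).
#' @param baseline_amplitude Amplitude of the smooth baseline (intensity
#'   units); the baseline is a fixed smooth positive shape.
#' @param water_amplitude,hes_amplitude Amplitudes of the residual-water
#'   hump and the HES-like signals.
#' @param linewidth_ppm Lorentzian full width at half maximum in ppm
#'   (default 0.002 ppm, i.e. 1 Hz at 500 MHz).
#' @param frequency_mhz Spectrometer frequency used to convert coupling
#'   constants from Hz to ppm.
#' @param sample_id Sample identifier stored in the spectrum.
#' @param seed Optional integer seed for the noise draw.
#' @return An [nmr_spectrum()].
#' @export
render_spectrum <- function(concentrations, library, ppm = ppm_axis(),
                            dilution = 1, noise_sd = 0,
                            baseline_amplitude = 0,
                            water_amplitude = 0, hes_amplitude = 0,
                            linewidth_ppm = 0.002, frequency_mhz = 500,
                            sample_id = "sample", seed = NULL) {
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  d <- diff(ppm)
  if (any(abs(d - d[1]) > 1e-9 * abs(d[1])) || d[1] <= 0)
    stop("ppm must be a uniform ascending grid")
  unknown <- setdiff(names(concentrations), names(library))
  if (length(unknown))
    stop("metabolites not in library: ", paste(unknown, collapse = ", "))

  signal <- numeric(length(ppm))
  for (nm in names(concentrations)) {
    conc <- concentrations[[nm]]
    if (conc == 0) next
    peaks <- library[[nm]]$peaks
    for (i in seq_len(nrow(peaks))) {
      pat <- .multiplet_pattern(peaks$multiplicity[i],
                                peaks$j_hz[i] / frequency_mhz)
      for (k in seq_along(pat$offsets)) {
        signal <- signal + conc * peaks$relative_area[i] * pat$weights[k] *
          .lorentz(ppm, peaks$center_ppm[i] + pat$offsets[k], linewidth_ppm)
      }
    }
  }
  if (baseline_amplitude > 0) {
    # fixed smooth positive macromolecule-like envelope
    signal <- signal + baseline_amplitude *
      (1 + 0.4 * exp(-(ppm - 1.3)^2 / 2) + 0.2 * sin(0.6 * ppm))
  }
  if (hes_amplitude > 0) signal <- signal + .hes_signal(ppm, hes_amplitude)
  intensity <- dilution * signal
  if (water_amplitude > 0)
    intensity <- intensity + .water_hump(ppm, water_amplitude)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    intensity <- intensity + stats::rnorm(length(ppm), 0, noise_sd)
  }
  nmr_spectrum(ppm, intensity, sample_id)
}

#' Default per-metabolite effect table
#'
#' Encodes the data-generating assumptions for the synthetic cohorts: a
#' baseline serum concentration per metabolite, a log-scale group effect at
#' admission (positive means elevated in non-survivors), and signed
#' log-scale admission-to-24h trends for survivors and non-survivors.
#' Metabolites reported with opposite within-subject evolutions in the two
#' outcome groups (amino acids, citrate, lactate, pyruvate, creatinine,
#' N-acetyl glycoprotein) carry opposite-signed trends; magnitudes are
#' scaled by `effect_scale`/`trend_scale`.
#'
#' @param effect_scale Multiplier applied to the admission group effects.
#' @param trend_scale Multiplier applied to the time trends.
#' @return Data frame with columns `metabolite`, `base_conc`,
#'   `h0_group_log_effect`, `trend_survivor`, `trend_nonsurvivor`.
#' @export
default_effect_table <- function(effect_scale = 1, trend_scale = 1) {
  .affine_effect <- function(r) ifelse(r == 0, 0, sign(r) * (0.12 + 0.40 * abs(r)))
  tab <- data.frame(
    metabolite = c("3-hydroxyisobutyrate", "urea", "phenylalanine",
                   "glutamate", "glutamine", "creatinine", "lactate",
                   "methionine", "alanine", "tyrosine", "pyruvate",
                   "citrate", "lysine", "fumarate", "1-methylhistidine",
                   "glycoprotein", "acetate", "isopropanol",
                   "2-hydroxyisovalerate", "lipid"),
    base_conc = c(0.6, 2.5, 0.8, 1.0, 1.2, 1.0, 3.0,
                  0.5, 1.0, 0.6, 0.8, 1.0, 0.9, 0.4, 0.4,
                  1.5, 0.7, 0.5, 0.5, 1.2),
    # admission (H0) group contrast, log scale; sign = direction in
    # non-survivors relative to survivors
    # admission effects carry the admission-table correlations' signs with
    # an affine magnitude map (floor keeps weak discriminators detectable);
    # the last metabolite (lipid) discriminates only at 24 h (trend-driven)
    h0_group_log_effect = .affine_effect(
      c(0.52, 0.45, 0.44, 0.44, 0.43, 0.41, 0.40,
        0.37, 0.26, 0.34, 0.34, 0.33, 0.27, 0.32,
        0.28, -0.28, 0.25, 0.26, 0.20, 0)),
    # H0 -> H24 log trends (0 where the evolution is not significant)
    trend_survivor = 0.5 * c(0, 0, -0.53, -0.62, -0.49, 0, -0.62,
                             0, -0.42, 0, -0.38, -0.59, 0, 0, 0,
                             0, 0, 0, 0, 0),
    trend_nonsurvivor = 0.5 * c(0, 0, 0.40, 0.49, 0.44, 0.47, 0,
                                0, 0.42, 0, 0, 0.59, 0, 0, 0,
                                -0.48, 0, 0, 0.41, -0.44),
    stringsAsFactors = FALSE
  )
  tab$h0_group_log_effect <- tab$h0_group_log_effect * effect_scale
  tab$trend_survivor <- tab$trend_survivor * trend_scale
  tab$trend_nonsurvivor <- tab$trend_nonsurvivor * trend_scale
  tab
}

#' Cohort design for synthetic serum NMR studies
#'
#' Defines the statistical structure of a simulated two-timepoint
#' (admission H0, 24 h H24) two-outcome (survivor SSS, non-survivor SSN)
#' cohort. Defaults emulate a 70-patient septic-shock cohort: 40 survivors
#' and 30 non-survivors sampled at admission, of whom 32 survivors and 19
#' non-survivors also have a paired 24-h sample.
#'
#' @param n_survivors,n_nonsurvivors Number of subjects per outcome group.
#' @param paired_fraction Fraction of subjects with both H0 and H24 samples;
#'   a single number or a length-2 vector `c(survivors, nonsurvivors)`.
#' @param effect_table See [default_effect_table()].
#' @param within_subject_sd,between_subject_sd Log-scale standard deviations
#'   of the within-subject (per-sample) and between-subject concentration
#'   variation.
#' @param dilution_range Range of per-sample multiplicative dilution
#'   factors, drawn uniformly.
#' @param noise_sd Spectral noise standard deviation (intensity units).
#' @param baseline_amplitude Baseline amplitude (intensity units).
#' @param water_amplitude,hes_amplitude Artifact amplitudes.
#' @param train_fraction Fraction of paired subjects assigned to the
#'   training role (split at the subject level).
#' @param seed Integer master seed.
#' @return An object of class `cohort_design` (a validated list).
#' @export
cohort_design <- function(n_survivors = 40, n_nonsurvivors = 30,
                          paired_fraction = c(32 / 40, 19 / 30),
                          effect_table = default_effect_table(),
                          within_subject_sd = 0.12,
                          between_subject_sd = 0.25,
                          dilution_range = c(0.7, 1.4),
                          noise_sd = 4, baseline_amplitude = 10,
                          water_amplitude = 400, hes_amplitude = 150,
                          train_fraction = 2 / 3, seed = 1) {
  if (n_survivors < 0 || n_nonsurvivors < 0) stop("counts must be >= 0")
  paired_fraction <- rep_len(paired_fraction, 2L)
  if (any(paired_fraction < 0 | paired_fraction > 1))
    stop("paired_fraction must lie in [0, 1]")
  if (any(dilution_range <= 0) || diff(dilution_range) < 0)
    stop("dilution_range must be positive and ordered")
  if (within_subject_sd < 0 || between_subject_sd < 0 || noise_sd < 0)
    stop("standard deviations must be >= 0")
  req <- c("metabolite", "base_conc", "h0_group_log_effect",
           "trend_survivor", "trend_nonsurvivor")
  if (!all(req %in% names(effect_table)))
    stop("effect_table must have columns: ", paste(req, collapse = ", "))
  structure(list(
    n_survivors = n_survivors, n_nonsurvivors = n_nonsurvivors,
    paired_fraction = paired_fraction, effect_table = effect_table,
    within_subject_sd = within_subject_sd,
    between_subject_sd = between_subject_sd,
    dilution_range = dilution_range, noise_sd = noise_sd,
    baseline_amplitude = baseline_amplitude,
    water_amplitude = water_amplitude, hes_amplitude = hes_amplitude,
    train_fraction = train_fraction, seed = as.integer(seed)
  ), class = "cohort_design")
}

# deterministic per-sample sub-seed from the master seed and a counter, so
# appending samples never perturbs earlier ones
.sample_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * counter) %% 2147483629)
}

#' Simulate a two-timepoint serum NMR cohort
#'
#' Draws per-subject metabolite concentrations on the log scale
#' (`baseline + between-subject + group effect + time trend + within-subject
#' noise`), renders one spectrum per sample with a per-sample dilution
#' factor, and returns the spectra together with sample metadata and the
#' planted truth (concentrations and dilutions) for recovery testing.
#'
#' @param design A [cohort_design()].
#' @param library Assignment library; defaults to
#'   [default_metabolite_library()].
#' @param ppm Spectral axis, see [ppm_axis()].
#' @return A list of class `nmr_cohort` with elements `spectra` (list of
#'   [nmr_spectrum()]), `meta` (data frame: `sample_id`, `subject_id`,
#'   `timepoint`, `outcome`, `role`), `truth` (list with `concentrations`
#'   samples x metabolites matrix and `dilution` vector), and `design`.
#' @export
simulate_cohort <- function(design, library = default_metabolite_library(),
                            ppm = ppm_axis()) {
  if (!inherits(design, "cohort_design")) stop("design must be a cohort_design")
  n_s <- design$n_survivors; n_n <- design$n_nonsurvivors
  if (n_s + n_n == 0) stop("empty cohort: no subjects in either group")
  eff <- design$effect_table
  metab <- eff$metabolite
  if (!all(metab %in% names(library)))
    stop("effect_table metabolites missing from library")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(design$seed)

  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_s + n_n)),
    outcome = rep(c("SSS", "SSN"), c(n_s, n_n)),
    stringsAsFactors = FALSE
  )
  # which subjects are paired (have an H24 sample), per group
  paired <- logical(n_s + n_n)
  if (n_s > 0)
    paired[sample(which(subjects$outcome == "SSS"),
                  round(design$paired_fraction[1] * n_s))] <- TRUE
  if (n_n > 0)
    paired[sample(which(subjects$outcome == "SSN"),
                  round(design$paired_fraction[2] * n_n))] <- TRUE
  subjects$paired <- paired
  # subject-level train/test split among paired subjects (pairs never split)
  subjects$role <- "train"
  for (g in c("SSS", "SSN")) {
    idx <- which(subjects$outcome == g & subjects$paired)
    if (length(idx) >= 2) {
      n_test <- length(idx) - round(design$train_fraction * length(idx))
      if (n_test > 0) subjects$role[sample(idx, n_test)] <- "test"
    }
  }

  n_subj <- nrow(subjects)
  m <- length(metab)
  between <- matrix(stats::rnorm(n_subj * m, 0, design$between_subject_sd),
                    n_subj, m, dimnames = list(subjects$subject_id, metab))

  # sample roster: H0 for everyone, H24 for paired subjects
  roster <- data.frame(
    subject = c(seq_len(n_subj), which(subjects$paired)),
    timepoint = rep(c("H0", "H24"), c(n_subj, sum(subjects$paired))),
    stringsAsFactors = FALSE
  )
  roster$sample_id <- paste0(subjects$subject_id[roster$subject], "_",
                             roster$timepoint)
  dilution <- stats::runif(nrow(roster), design$dilution_range[1],
                           design$dilution_range[2])

  conc <- matrix(NA_real_, nrow(roster), m,
                 dimnames = list(roster$sample_id, metab))
  spectra <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    s <- roster$subject[i]
    is_ssn <- subjects$outcome[s] == "SSN"
    at_h24 <- roster$timepoint[i] == "H24"
    trend <- if (is_ssn) eff$trend_nonsurvivor else eff$trend_survivor
    # per-sample stream: within-subject noise, then the spectral noise seed
    set.seed(.sample_seed(design$seed, i))
    within <- stats::rnorm(m, 0, design$within_subject_sd)
    logc <- log(eff$base_conc) + between[s, ] +
      if (is_ssn) eff$h0_group_log_effect else 0
    if (at_h24) logc <- logc + trend
    conc[i, ] <- exp(logc + within)
    spectra[[i]] <- render_spectrum(
      stats::setNames(conc[i, ], metab), library, ppm,
      dilution = dilution[i], noise_sd = design$noise_sd,
      baseline_amplitude = design$baseline_amplitude,
      water_amplitude = design$water_amplitude,
      hes_amplitude = design$hes_amplitude * stats::runif(1, 0.5, 1.5),
      sample_id = roster$sample_id[i],
      seed = .sample_seed(design$seed, i + nrow(roster))
    )
  }

  meta <- data.frame(
    sample_id = roster$sample_id,
    subject_id = subjects$subject_id[roster$subject],
    timepoint = roster$timepoint,
    outcome = subjects$outcome[roster$subject],
    role = subjects$role[roster$subject],
    stringsAsFactors = FALSE
  )
  names(dilution) <- roster$sample_id
  structure(list(spectra = spectra, meta = meta,
                 truth = list(concentrations = conc, dilution = dilution),
                 design = design),
            class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat("<nmr_cohort>", nrow(x$meta), "samples,",
      length(unique(x$meta$subject_id)), "subjects\n")
  print(table(x$meta$outcome, x$meta$timepoint))
  invisible(x)
}
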