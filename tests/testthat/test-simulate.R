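test_that("default library carries the standard serum assignments", {
  lib <- default_metabolite_library()
  expect_gte(length(lib), 18)

  lac <- lib$lactate$peaks
  expect_equal(lac$center_ppm, c(1.32, 4.11))
  expect_equal(lac$multiplicity, c("d", "q"))

  cit <- lib$citrate$peaks
  expect_equal(cit$center_ppm, c(2.52, 2.62))
  expect_equal(cit$multiplicity, c("d", "d"))

  all_peaks <- do.call(rbind, lapply(lib, `[[`, "peaks"))
  expect_true(all(all_peaks$center_ppm >= -1 & all_peaks$center_ppm <= 10))
  expect_true(all(all_peaks$relative_area > 0))
  expect_true(all(all_peaks$window_lo < all_peaks$window_hi))
  expect_true(all(all_peaks$window_lo >= -1 & all_peaks$window_hi <= 10))
})

test_that("metabolite_signal validates its invariants", {
  expect_error(metabolite_signal("x", 11, "s"), "ppm")
  expect_error(metabolite_signal("x", 1, "z"), "multiplicity")
  expect_error(metabolite_signal("x", 1, "s", relative_areas = -1), "> 0")
})

test_that("rendered spectra are a linear forward model", {
  lib <- default_metabolite_library()
  ppm <- ppm_axis(step = 0.002)

  # null signal: zero everywhere outside the water/HES artifact regions
  sp0 <- render_spectrum(c(lactate = 0), lib, ppm, noise_sd = 0,
                         baseline_amplitude = 0, water_amplitude = 5,
                         hes_amplitude = 5)
  outside <- !(ppm >= 4.6 & ppm <= 5.5) & !(ppm >= 3.16 & ppm <= 4.0)
  expect_true(all(sp0$intensity[outside] == 0))
  expect_gt(max(sp0$intensity[!outside]), 0)

  # linearity in dilution and concentration (noise off)
  conc <- c(lactate = 2, alanine = 1)
  s1 <- render_spectrum(conc, lib, ppm, dilution = 1, baseline_amplitude = 1)
  s2 <- render_spectrum(conc, lib, ppm, dilution = 2, baseline_amplitude = 1)
  expect_equal(s2$intensity, 2 * s1$intensity, tolerance = 1e-12)
  s3 <- render_spectrum(conc * 3, lib, ppm)
  s4 <- render_spectrum(conc, lib, ppm)
  expect_equal(s3$intensity, 3 * s4$intensity, tolerance = 1e-12)
})

test_that("a singlet's window integral matches the Lorentzian closed form", {
  lib <- list(probe = metabolite_signal("probe", 5, "s", relative_areas = 2,
                                        window_halfwidth = 0.3))
  ppm <- ppm_axis(from = 3, to = 7, step = 1e-4)
  conc <- 1.7; dil <- 1.3; fwhm <- 0.002
  sp <- render_spectrum(c(probe = conc), lib, ppm, dilution = dil,
                        linewidth_ppm = fwhm)
  got <- integrate_signal(sp, c(4.7, 5.3))
  want <- conc * 2 * dil * lorentz_integral_oracle(4.7, 5.3, 5, fwhm)
  expect_equal(got, want, tolerance = 1e-6)
  # and over a wide window the full planted area is recovered
  wide <- integrate_signal(sp, c(3, 7))
  expect_equal(wide, conc * 2 * dil, tolerance = 1e-3)
})

test_that("render_spectrum rejects invalid input", {
  lib <- default_metabolite_library()
  expect_error(render_spectrum(c(lactate = -1), lib, ppm_axis(step = 0.01)),
               ">= 0")
  expect_error(render_spectrum(c(lactate = 1), lib, c(0, 0.1, 0.3)),
               "uniform")
  expect_error(render_spectrum(c(nope = 1), lib, ppm_axis(step = 0.01)),
               "not in library")
})

test_that("cohort simulation is reproducible and honors the design", {
  co1 <- make_test_cohort(seed = 11)
  co2 <- make_test_cohort(seed = 11)
  expect_identical(co1$truth, co2$truth)
  expect_identical(lapply(co1$spectra, `[[`, "intensity"),
                   lapply(co2$spectra, `[[`, "intensity"))

  co3 <- make_test_cohort(seed = 12)
  expect_false(identical(co1$truth$concentrations,
                         co3$truth$concentrations))

  # cohort shape: H0 for everyone, H24 for paired subjects only
  design <- cohort_design(seed = 5)
  co <- simulate_cohort(design, ppm = ppm_axis(step = 0.05))
  tab <- table(co$meta$outcome, co$meta$timepoint)
  expect_equal(unname(tab["SSS", "H0"]), 40)
  expect_equal(unname(tab["SSN", "H0"]), 30)
  expect_equal(unname(tab["SSS", "H24"]), 32)
  expect_equal(unname(tab["SSN", "H24"]), 19)
  # (subject, timepoint) unique; every H24 subject also has H0
  expect_false(any(duplicated(paste(co$meta$subject_id, co$meta$timepoint))))
  h24 <- co$meta$subject_id[co$meta$timepoint == "H24"]
  expect_true(all(h24 %in% co$meta$subject_id[co$meta$timepoint == "H0"]))
})

test_that("degenerate design yields identical spectra", {
  eff <- default_effect_table()
  eff$h0_group_log_effect <- 0
  eff$trend_survivor <- 0
  eff$trend_nonsurvivor <- 0
  design <- cohort_design(n_survivors = 3, n_nonsurvivors = 3,
                          paired_fraction = 1, effect_table = eff,
                          within_subject_sd = 0, between_subject_sd = 0,
                          dilution_range = c(1, 1), noise_sd = 0,
                          hes_amplitude = 0, seed = 3)
  co <- simulate_cohort(design, ppm = ppm_axis(step = 0.01))
  ref <- co$spectra[[1]]$intensity
  for (sp in co$spectra) expect_equal(sp$intensity, ref, tolerance = 1e-12)
})

test_that("planted admission effects raise lactate in non-survivors", {
  co <- simulate_cohort(cohort_design(seed = 2), ppm = ppm_axis(step = 0.05))
  h0 <- co$meta$timepoint == "H0"
  lac <- co$truth$concentrations[h0, "lactate"]
  grp <- co$meta$outcome[h0]
  expect_gt(mean(lac[grp == "SSN"]), mean(lac[grp == "SSS"]))
})

test_that("invalid designs are rejected", {
  expect_error(cohort_design(paired_fraction = 1.2), "\\[0, 1\\]")
  expect_error(cohort_design(n_survivors = -1), ">= 0")
  expect_error(cohort_design(dilution_range = c(-1, 2)), "positive")
  expect_error(
    simulate_cohort(cohort_design(n_survivors = 0, n_nonsurvivors = 0)),
    "empty cohort")
})
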