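test_that("default band library carries the published windows", {
  lib <- default_band_library()
  mods <- vapply(lib, `[[`, "", "modality")
  expect_gte(sum(mods == "FTIR"), 7)
  expect_gte(sum(mods == "RAMAN"), 4)
  for (b in lib) {
    expect_lt(b$window[1], b$window[2])
    expect_gte(diff(b$window), 5)
  }
  expect_equal(lib_band("cc_1661")$window, c(1655, 1670))
  expect_equal(lib_band("amide_I")$window, c(1605, 1687))
  expect_equal(lib_band("po2_asym")$window, c(1214, 1261))
  expect_equal(lib_band("ch_window_a")$window, c(2847, 2863))
  expect_equal(lib_band("ch_window_b")$window, c(2936, 2965))
  expect_equal(lib_band("co_o_c")$window, c(1144, 1191))
})

test_that("default ratio panel is referentially sound with stated directions", {
  panel <- default_ratio_panel()
  lib_names <- vapply(default_band_library(), `[[`, "", "name")
  for (r in panel) {
    expect_true(all(c(r$numerator, r$denominator) %in% lib_names))
    expect_length(intersect(r$numerator, r$denominator), 0)
  }
  uns <- Filter(function(r) r$name == "unsaturation", panel)[[1]]
  expect_identical(uns$numerator, "cc_1661")
  expect_identical(uns$denominator, "ch_def_1447")
  acyl <- Filter(function(r) r$name == "acyl_shortening", panel)[[1]]
  expect_identical(expected_direction(acyl, "dgal"), "UP")
  chol <- Filter(function(r) r$name == "cholesterol_esters", panel)[[1]]
  expect_identical(expected_direction(chol, "dgal"), "DOWN")
  expect_identical(expected_direction(chol, "natural"), "UP")
})

test_that("band integration matches analytic areas and is additive", {
  s <- gauss_spec(1236, 5, 1)
  b <- band_definition("po2", "FTIR", 1236, c(1211, 1261))
  area <- integrate_band(s, b)
  expect_equal(area, sqrt(2 * pi) * 5, tolerance = 0.005)

  zero <- spectrum(s$wavenumbers, rep(0, length(s$wavenumbers)), "FTIR")
  expect_equal(integrate_band(zero, b), 0)

  # chord baseline removes a constant offset exactly
  soff <- gauss_spec(1236, 5, 1, offset = 0.37)
  expect_equal(integrate_band(soff, b, baseline = "local_linear"),
               integrate_band(s, b, baseline = "local_linear"),
               tolerance = 1e-9)
  expect_equal(integrate_band(soff, b, baseline = "local_linear"), area,
               tolerance = 0.005)

  # additivity over adjacent windows, split at a non-grid point
  b1 <- band_definition("lo", "FTIR", 1220, c(1211, 1236.5))
  b2 <- band_definition("hi", "FTIR", 1250, c(1236.5, 1261))
  expect_equal(integrate_band(s, b1) + integrate_band(s, b2), area,
               tolerance = 1e-9 * area)

  bad <- band_definition("oob", "FTIR", 600, c(500, 950))
  expect_error(integrate_band(s, bad), "oob")
  expect_error(integrate_band(gauss_spec(1236, 5, 1, grid = seq(400, 1800, 1),
                                         modality = "RAMAN"), b), "RAMAN")
})

test_that("second-derivative lobe magnitudes follow the sign convention", {
  s <- gauss_spec(1650, 9)
  d2 <- second_derivative(s)
  expect_gt(second_derivative_band_intensity(d2, 1650), 0)

  flat <- spectrum(seq(900, 3800, 1), rep(0, 2901), "FTIR",
                   stage = "SECOND_DERIVATIVE")
  expect_equal(second_derivative_band_intensity(flat, 1650), 0)

  expect_error(second_derivative_band_intensity(s, 1650), "SECOND_DERIVATIVE")

  # amplitude-ratio recovery in the resolvable sub-band regime (sigma 9,
  # FWHM ~21 cm^-1); overlap biases broader bands (see vignette)
  nu <- seq(900, 3800, 1)
  two <- spectrum(nu, exp(-((nu - 1650)^2) / (2 * 81)) +
                    0.5 * exp(-((nu - 1660)^2) / (2 * 81)), "FTIR")
  d2b <- second_derivative(two)
  r <- second_derivative_band_intensity(d2b, 1660) /
    second_derivative_band_intensity(d2b, 1650)
  expect_lt(abs(r - 0.5), 0.15 * 0.5)
})

test_that("compute_panel: unit ratios, tied cohorts, missing groups", {
  cfgq <- quiet_config(n_control = 3, n_treated = 3, seed = 2)
  cohort <- generate_cohort(cfgq)
  # noise-free spectra legitimately trip the despiking over-flag siren
  # (MAD of second differences ~ 0); the op returns them unchanged
  pp <- suppressWarnings(preprocess_cohort(cohort, with_second_derivative = FALSE))

  # two distinct bands over the identical window give a unit ratio
  bands <- list(band_definition("a", "RAMAN", 1447, c(1420, 1480)),
                band_definition("b", "RAMAN", 1447, c(1420, 1480)))
  ratios <- list(ratio_definition("unit", "a", "b"))
  res <- compute_panel(pp$set, bands = bands, ratios = ratios)
  expect_true(all(abs(res$values$value - 1) < 1e-12))

  # treated spectra identical to control -> maximal ties -> p = 1
  ctrl <- Filter(function(s) s$group == "control", pp$set$spectra)
  dup <- lapply(ctrl, function(s) {
    s$group <- "treated"; s$sample_id <- paste0("t_", s$sample_id); s
  })
  tied <- spectrum_set(c(ctrl, dup))
  res2 <- compute_panel(tied, bands = bands, ratios = ratios)
  expect_equal(res2$comparisons$p, 1)
})

test_that("panel ratios are invariant to global scaling of raw spectra", {
  cfgq <- cohort_config(n_control = 2, n_treated = 2, seed = 9)
  cohort <- generate_cohort(cfgq)
  scaled <- cohort
  scaled$set <- spectrum_set(lapply(cohort$set$spectra, function(s) {
    s$intensities <- 7.3 * s$intensities
    s
  }))
  p1 <- compute_panel(preprocess_cohort(cohort, with_second_derivative = FALSE)$set)
  p2 <- compute_panel(preprocess_cohort(scaled, with_second_derivative = FALSE)$set)
  expect_lt(max(abs(p1$values$value - p2$values$value)), 1e-9)
})

test_that("trapezoid areas agree with adaptive quadrature of the band model", {
  cfgq <- quiet_config(seed = 21)
  gs <- generate_spectrum(cfgq, "FTIR", "control", 1)
  models <- cfgq$band_models$FTIR
  amps <- gs$truth$amplitudes
  for (bn in c("amide_II", "po2_asym", "co_o_c")) {
    b <- lib_band(if (bn == "amide_II") "amide_II" else bn)
    f <- function(nu) {
      y <- 0
      for (mn in names(models))
        y <- y + amps[[mn]] * exp(-((nu - models[[mn]]$center)^2) /
                                    (2 * models[[mn]]$width^2))
      y
    }
    quad <- integrate(f, b$window[1], b$window[2], rel.tol = 1e-10)$value
    expect_equal(integrate_band(gs$spectrum, b), quad, tolerance = 0.005)
  }
})

test_that("programmed PO2 suppression is detected with high power", {
  # spec example scaled to the FTIR modality only (the affected band is FTIR);
  # 100 seeded replicates at n = 10/group, amplitude CV 5%
  hits <- 0L
  medians_lower <- 0L
  for (k in seq_len(100)) {
    cfg <- cohort_config(n_control = 10, n_treated = 10, modalities = "FTIR",
                         effect_multipliers = c(po2_asym = 0.7),
                         seed = 5000 + k)
    pp <- preprocess_cohort(generate_cohort(cfg), with_second_derivative = FALSE)
    ftir_ratios <- Filter(function(r) r$name %in% c("phospholipid", "total_protein"),
                          default_ratio_panel())
    res <- compute_panel(pp$set, ratios = ftir_ratios)
    row <- res$comparisons[res$comparisons$ratio == "phospholipid", ]
    if (row$p < 0.05) hits <- hits + 1L
    if (row$median2 < row$median1) medians_lower <- medians_lower + 1L
  }
  expect_gte(hits, 90)
  expect_gte(medians_lower, 95)
})
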