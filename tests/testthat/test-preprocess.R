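cfg <- preprocess_config()

test_that("SG smoothing reproduces low-order polynomials and constants", {
  nu <- seq(1000, 1200, 1)
  quad <- spectrum(nu, 3e-4 * nu^2 - 0.1 * nu + 2, "FTIR")
  sm <- savitzky_golay_smooth(quad, cfg)
  interior <- 10:190
  expect_lt(max(abs(sm$intensities[interior] - quad$intensities[interior])),
            1e-9 * max(abs(quad$intensities)))
  expect_identical(sm$wavenumbers, quad$wavenumbers)   # axis bit-exact

  const <- spectrum(nu, rep(2.5, length(nu)), "FTIR")
  expect_equal(savitzky_golay_smooth(const, cfg)$intensities,
               const$intensities, tolerance = 1e-12)
})

test_that("SG white-noise variance reduction matches the sum-of-squares factor", {
  # oracle: output variance of a linear filter on white noise is sigma^2*sum(c^2)
  factor <- sum(rbcspec:::sg_coefficients(13, 3, 0)^2)
  expect_lt(factor, 0.5)
  nu <- seq_len(10000)
  set.seed(101)
  noise <- rnorm(length(nu))
  sm <- savitzky_golay_smooth(spectrum(nu, noise, "FTIR"), cfg)
  ratio <- var(sm$intensities[50:9950]) / var(noise[50:9950])
  expect_lt(ratio, 0.5)
  expect_lt(abs(ratio - factor), 0.15 * factor)
})

test_that("SG second derivative matches closed forms", {
  nu <- seq(1000, 1400, 1)
  interior <- 20:380
  d2 <- second_derivative(spectrum(nu, nu^2, "FTIR"), cfg)
  expect_lt(max(abs(d2$intensities[interior] - 2)), 1e-6)
  expect_identical(d2$stage, "SECOND_DERIVATIVE")

  lin <- second_derivative(spectrum(nu, 5 * nu - 3, "FTIR"), cfg)
  expect_lt(max(abs(lin$intensities[interior])), 1e-8)

  om <- 0.05                              # omega * step = 0.05
  sine <- second_derivative(spectrum(nu, sin(om * nu), "FTIR"), cfg)
  expect_lt(max(abs(sine$intensities[interior] + om^2 * sin(om * nu[interior]))),
            0.01 * om^2)
})

test_that("SG filters reject bad configurations and short spectra", {
  expect_error(preprocess_config(sg_window = 12), "odd")
  expect_error(preprocess_config(sg_window = 3, sg_polyorder = 3), "polyorder")
  short <- spectrum(1:5, rnorm(5), "FTIR")
  expect_error(savitzky_golay_smooth(short, cfg), "shorter than")
  uneven <- spectrum(c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512, 1024, 2048, 4096,
                       8192, 16384), rnorm(15), "FTIR")
  expect_error(savitzky_golay_smooth(uneven, cfg), "near-uniform")
})

test_that("cosmic-ray removal replaces spikes and nothing else", {
  set.seed(7)
  nu <- seq(400, 1800, 1)
  clean <- exp(-((nu - 1000)^2) / 200) + 0.2
  prespike <- clean + rnorm(length(nu), 0, 0.01)
  spiked <- prespike
  spiked[700] <- spiked[700] + 50 * (abs(clean[700]) + 0.05)
  s <- spectrum(nu, spiked, "RAMAN")
  out <- remove_cosmic_rays(s, cfg)
  flags <- attr(out, "cosmic_flags")
  expect_true(700 %in% flags)
  untouched <- setdiff(seq_along(nu), flags)
  expect_identical(out$intensities[untouched], spiked[untouched])
  # residual against the pre-spike spectrum the generator retains
  expect_lt(max(abs(out$intensities - prespike)), 2 * 0.01)

  # spike-free spectrum returned unchanged
  s0 <- spectrum(nu, prespike, "RAMAN")
  out0 <- remove_cosmic_rays(s0, cfg)
  expect_identical(out0$intensities, prespike)

  # two adjacent spikes both replaced
  spiked2 <- prespike
  spiked2[900:901] <- spiked2[900:901] + 40 * (abs(clean[900:901]) + 0.05)
  out2 <- remove_cosmic_rays(spectrum(nu, spiked2, "RAMAN"), cfg)
  expect_true(all(c(900, 901) %in% attr(out2, "cosmic_flags")))
  expect_lt(max(abs(out2$intensities - prespike)), 2 * 0.01)

  expect_error(remove_cosmic_rays(spectrum(nu, clean, "FTIR"), cfg), "RAMAN")
})

test_that("over-flagging triggers a warning, not silent damage", {
  set.seed(8)
  nu <- 1:100
  wild <- rnorm(100, sd = c(0.001, 50))    # alternating variance
  s <- spectrum(nu, wild, "RAMAN")
  expect_warning(out <- remove_cosmic_rays(s, preprocess_config(cosmic_z_threshold = 0.1)),
                 ">10%")
  expect_identical(out$intensities, wild)  # returned unmodified with flags
})

test_that("rubberband baseline: ramps vanish, Gaussian areas survive", {
  nu <- seq(400, 1800, 1)
  ramp <- spectrum(nu, 0.5 + 1e-3 * nu, "RAMAN")
  out <- remove_baseline(ramp, cfg)
  expect_lt(max(abs(out$intensities)), 1e-9)

  g <- gauss_spec(1100, 12, 1, grid = nu, modality = "RAMAN",
                  offset = 0.2, slope = 1e-4)
  corr <- remove_baseline(g, cfg)
  b <- band_definition("g", "RAMAN", 1100, c(1100 - 36, 1100 + 36))
  expect_equal(integrate_band(corr, b),
               gauss_window_area(1100, 12, 1, 1064, 1136),
               tolerance = 0.05)

  expect_error(remove_baseline(ramp, cfg, method = "what"), "unknown")
})

test_that("rubberband leaves baseline-free marker-band areas nearly unchanged", {
  cfgq <- quiet_config(seed = 5)
  gs <- generate_spectrum(cfgq, "RAMAN", "control", 1)$spectrum
  corr <- remove_baseline(gs, cfg)
  for (bn in c("ester_co_raman", "cc_1661", "ch_def_1447", "phe_1007")) {
    b <- lib_band(bn)
    a0 <- integrate_band(gs, b)
    expect_lt(abs(integrate_band(corr, b) - a0), 0.02 * abs(a0))
  }
})

test_that("polynomial baseline removes smooth backgrounds under peaks", {
  nu <- seq(400, 1800, 1)
  bg <- 0.4 - 2e-4 * nu + 1e-7 * nu^2
  g <- 1.5 * exp(-((nu - 1200)^2) / (2 * 100))
  s <- spectrum(nu, g + bg, "RAMAN")
  out <- remove_baseline(s, preprocess_config(baseline_method = "poly"))
  b <- band_definition("g", "RAMAN", 1200, c(1170, 1230))
  expect_equal(integrate_band(out, b, baseline = "local_linear"),
               integrate_band(spectrum(nu, g, "RAMAN"), b, baseline = "local_linear"),
               tolerance = 0.05)
})

test_that("vector normalization has unit in-range norm and scale invariance", {
  s <- gauss_spec(1650, 20, 0.8)
  n1 <- normalize_spectrum(s, cfg)
  sel <- n1$wavenumbers >= 900 & n1$wavenumbers <= 3600
  expect_lt(abs(sqrt(sum(n1$intensities[sel]^2)) - 1), 1e-12)
  expect_identical(n1$stage, "PREPROCESSED")

  s2 <- set_scaled <- spectrum(s$wavenumbers, 7.3 * s$intensities, "FTIR")
  n2 <- normalize_spectrum(s2, cfg)
  expect_equal(n2$intensities, n1$intensities, tolerance = 1e-12)

  zero <- spectrum(s$wavenumbers, rep(0, length(s$wavenumbers)), "FTIR")
  expect_error(normalize_spectrum(zero, cfg), "all-zero")
})

test_that("ATR correction scales linearly in wavenumber", {
  nu <- seq(900, 3800, 1)
  flat <- spectrum(nu, rep(1, length(nu)), "FTIR")
  out <- atr_correct(flat, cfg)
  expect_equal(out$intensities[nu == 1650], 1)          # fixed point
  expect_equal(out$intensities[nu == 3300], 2)          # doubles at 2x ref
  expect_equal(out$intensities, nu / 1650)              # flat -> proportional
  expect_error(atr_correct(spectrum(nu, rep(1, length(nu)), "RAMAN"), cfg),
               "FTIR")
})

test_that("preprocess chain records provenance in fixed order", {
  cfgq <- cohort_config(seed = 3, cosmic_rate = 2, amplitude_cv = 0)
  s <- generate_spectrum(cfgq, "RAMAN", "control", 1)$spectrum
  pp <- preprocess_spectrum(s, default_chain_config("RAMAN"))
  prov <- attr(pp, "provenance")
  expect_match(prov[1], "remove_cosmic_rays")
  expect_match(prov[2], "savitzky_golay_smooth")
  expect_match(prov[3], "remove_baseline")
  expect_match(prov[length(prov)], "normalize")
  expect_identical(pp$wavenumbers, s$wavenumbers)
})
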