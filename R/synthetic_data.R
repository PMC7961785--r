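# Synthetic two-group cohort generator.
#
# The generator states the world the analysis assumes: FTIR absorbance
# spectra on a 900-3800 cm^-1 grid and Raman spectra on 400-1800 cm^-1, each
# built as a sum of analytic band profiles plus a smooth polynomial baseline
# and white noise, with Raman spectra additionally hit by Poisson-distributed
# cosmic-ray spikes. Band amplitudes vary log-normally across samples
# (multiplicative biological variation, amplitudes stay positive); treated
# samples have their mean amplitudes multiplied by per-band effect
# multipliers. A truth store keeps every sample's noise-free, baseline-free
# twin plus analytic in-window band areas, so downstream estimates can be
# checked against closed forms.

band_model <- function(shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                       center, width, amplitude, cv = 0.05, eta = 0.5) {
  shape <- match.arg(shape)
  stopifnot(width > 0, amplitude >= 0, cv >= 0)
  list(shape = shape, center = center, width = width, amplitude = amplitude,
       cv = cv, eta = eta)
}

# unit-amplitude profile value(s)
profile_value <- function(m, nu) {
  g <- exp(-((nu - m$center)^2) / (2 * m$width^2))
  l <- 1 / (1 + ((nu - m$center) / m$width)^2)
  switch(m$shape,
         gaussian = g,
         lorentzian = l,
         pseudo_voigt = m$eta * l + (1 - m$eta) * g)
}

# analytic integral of the unit-amplitude profile over [lo, hi]
profile_window_integral <- function(m, lo, hi) {
  gauss <- m$width * sqrt(2 * pi) *
    (stats::pnorm((hi - m$center) / m$width) -
       stats::pnorm((lo - m$center) / m$width))
  lorentz <- m$width * (atan((hi - m$center) / m$width) -
                          atan((lo - m$center) / m$width))
  switch(m$shape,
         gaussian = gauss,
         lorentzian = lorentz,
         pseudo_voigt = m$eta * lorentz + (1 - m$eta) * gauss)
}

# full-line analytic area of the unit-amplitude profile
profile_full_integral <- function(m) {
  switch(m$shape,
         gaussian = m$width * sqrt(2 * pi),
         lorentzian = m$width * pi,
         pseudo_voigt = m$eta * m$width * pi +
           (1 - m$eta) * m$width * sqrt(2 * pi))
}

default_band_models <- function(amplitude_cv = 0.05) {
  bm <- function(...) band_model("gaussian", ..., cv = amplitude_cv)
  list(
    FTIR = list(
      # amide I fine structure: alpha-helix 1650, turns 1660, unordered 1640
      amide_alpha = bm(center = 1650, width = 12, amplitude = 0.90),
      amide_turns = bm(center = 1660, width = 12, amplitude = 0.45),
      amide_unordered = bm(center = 1640, width = 12, amplitude = 0.55),
      amide_II = bm(center = 1544, width = 14, amplitude = 0.55),
      ch_window_a = bm(center = 2852, width = 6, amplitude = 0.25),
      ch_window_b = bm(center = 2950, width = 8, amplitude = 0.20),
      po2_asym = bm(center = 1236, width = 12, amplitude = 0.18),
      co_o_c = bm(center = 1167, width = 11, amplitude = 0.12),
      ester_co_ftir = bm(center = 1738, width = 10, amplitude = 0.08),
      oh_nh_stretch = bm(center = 3300, width = 80, amplitude = 0.30)),
    RAMAN = list(
      ester_co_raman = bm(center = 1743, width = 10, amplitude = 0.10),
      cc_1661 = bm(center = 1661, width = 7, amplitude = 0.45),
      ch_def_1447 = bm(center = 1447, width = 12, amplitude = 0.60),
      phe_1007 = bm(center = 1007, width = 6, amplitude = 0.30),
      amide_I_raman = bm(center = 1620, width = 15, amplitude = 0.15)))
}

#' Synthetic cohort configuration
#'
#' The stated world of the simulator. Defaults emulate the measured cohorts:
#' n = 3 per group (the published membrane group sizes), FTIR grid 900-3800
#' cm\eqn{^{-1}} and Raman grid 400-1800 cm\eqn{^{-1}} at 1 cm\eqn{^{-1}},
#' log-normal band-amplitude variation with CV 5\%, and the `"dgal"`
#' accelerated-aging scenario: PO\eqn{_2^-} \eqn{\times}0.75, Raman C=C
#' \eqn{\times}0.8, CH3 stretch window \eqn{\times}1.25, amide bands
#' unchanged. The `"natural"` scenario shares the lipid effects but reverses
#' the two ester indices; `"null"` applies no effects.
#'
#' @param n_control,n_treated samples per group.
#' @param modalities subset of `c("FTIR", "RAMAN")`.
#' @param scenario `"dgal"`, `"natural"` or `"null"`.
#' @param amplitude_cv log-normal coefficient of variation of band amplitudes.
#' @param effect_multipliers named list/vector of per-band multipliers applied
#'   to treated-group mean amplitudes; `NULL` selects the scenario default.
#' @param grids per-modality `c(start, stop, step)` in cm\eqn{^{-1}}.
#' @param band_models per-modality named lists of band models (see defaults).
#' @param baseline_coeffs per-modality polynomial coefficients (ascending
#'   powers of \eqn{\nu}).
#' @param noise_sd per-modality white-noise standard deviation.
#' @param cosmic_rate expected cosmic-ray spikes per Raman spectrum.
#' @param seed integer seed; every draw descends deterministically from it.
#' @return a `synthetic_cohort_config`.
#' @export
cohort_config <- function(n_control = 3L, n_treated = 3L,
                          modalities = c("FTIR", "RAMAN"),
                          scenario = c("dgal", "natural", "null"),
                          amplitude_cv = 0.05,
                          effect_multipliers = NULL,
                          grids = list(FTIR = c(900, 3800, 1),
                                       RAMAN = c(400, 1800, 1)),
                          band_models = NULL,
                          baseline_coeffs = list(
                            FTIR = c(0.005, 1e-6),
                            RAMAN = c(0.35, -3.5e-4, 1.2e-7)),
                          noise_sd = c(FTIR = 0.002, RAMAN = 0.004),
                          cosmic_rate = 1.0,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  modalities <- match.arg(toupper(modalities), MODALITIES, several.ok = TRUE)
  if (is.null(band_models)) band_models <- default_band_models(amplitude_cv)
  if (is.null(effect_multipliers)) {
    # the stated default aging world: phospholipid down, unsaturation down,
    # CH3 stretch window up, amide (protein) bands unchanged
    effect_multipliers <- switch(scenario,
      dgal = c(po2_asym = 0.75, cc_1661 = 0.8, ch_window_b = 1.25),
      natural = c(po2_asym = 0.75, cc_1661 = 0.8, ch_window_b = 1.25),
      null = c())
  }
  if (length(effect_multipliers) && any(effect_multipliers <= 0))
    abort("effect multipliers must be > 0", class = "rbcspec_config_error")
  for (mdl in modalities) {
    g <- grids[[mdl]]
    if (is.null(g) || length(g) != 3L || g[3] <= 0 || g[1] >= g[2])
      abort("invalid grid for ", mdl, class = "rbcspec_config_error")
    for (bn in names(band_models[[mdl]])) {
      ctr <- band_models[[mdl]][[bn]]$center
      if (ctr < g[1] || ctr > g[2])
        abort("band '", bn, "' center outside the ", mdl, " grid",
              class = "rbcspec_config_error")
    }
  }
  if (any(unlist(noise_sd) < 0) || amplitude_cv < 0 || cosmic_rate < 0)
    abort("noise_sd, amplitude_cv and cosmic_rate must be >= 0",
          class = "rbcspec_config_error")
  structure(list(n_control = as.integer(n_control),
                 n_treated = as.integer(n_treated),
                 modalities = modalities, scenario = scenario,
                 amplitude_cv = amplitude_cv,
                 effect_multipliers = effect_multipliers,
                 grids = grids, band_models = band_models,
                 baseline_coeffs = baseline_coeffs, noise_sd = noise_sd,
                 cosmic_rate = cosmic_rate, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# log-normal with mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

poly_eval <- function(coeffs, x) {
  y <- numeric(length(x))
  for (k in seq_along(coeffs)) y <- y + coeffs[k] * x^(k - 1L)
  y
}

#' Generate one synthetic spectrum
#'
#' Draws per-band amplitudes (log-normal, treated means scaled by the effect
#' multipliers), sums the band profiles with the modality baseline and white
#' noise, and adds cosmic-ray spikes for Raman. The returned truth entry
#' holds the drawn amplitudes, the noise-free baseline-free twin, and the
#' analytic full-line areas of every band.
#'
#' @param cfg [cohort_config()].
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param group `"control"` or `"treated"`.
#' @param sample_index 1-based index within the cohort.
#' @return list with elements `spectrum` ([spectrum()]) and `truth`.
#' @export
generate_spectrum <- function(cfg, modality, group, sample_index) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  modality <- match.arg(toupper(modality), MODALITIES)
  g <- cfg$grids[[modality]]
  nu <- seq(g[1], g[2], by = g[3])
  models <- cfg$band_models[[modality]]
  stream <- child_seed(cfg$seed, 1000L * sample_index +
                         match(modality, MODALITIES) * 131L +
                         match(group, c("control", "treated")))
  with_seed(stream, {
    amps <- vapply(names(models), function(bn) {
      m <- models[[bn]]
      mult <- if (group == "treated" && bn %in% names(cfg$effect_multipliers))
        cfg$effect_multipliers[[bn]] else 1
      rlnorm_mean_cv(1L, m$amplitude * mult, m$cv)
    }, 0)
    clean <- numeric(length(nu))
    for (bn in names(models))
      clean <- clean + amps[[bn]] * profile_value(models[[bn]], nu)
    y <- clean + poly_eval(cfg$baseline_coeffs[[modality]], nu) +
      stats::rnorm(length(nu), 0, cfg$noise_sd[[modality]])
    spikes <- integer(0)
    if (modality == "RAMAN" && cfg$cosmic_rate > 0) {
      k <- stats::rpois(1L, cfg$cosmic_rate)
      if (k > 0) {
        spikes <- sample.int(length(nu), k)
        local_amp <- abs(clean[spikes]) + 0.05
        y[spikes] <- y[spikes] + stats::runif(k, 20, 100) * local_amp
      }
    }
    sid <- sprintf("%s_%02d", substr(group, 1, 4), sample_index)
    truth <- list(sample_id = sid, modality = modality, group = group,
                  amplitudes = amps,
                  full_areas = vapply(names(models), function(bn)
                    amps[[bn]] * profile_full_integral(models[[bn]]), 0),
                  clean = spectrum(nu, clean, modality, sample_id = sid,
                                   group = group),
                  spikes = sort(spikes))
    list(spectrum = spectrum(nu, y, modality, sample_id = sid, group = group),
         truth = truth)
  })
}

# analytic area of the modelled signal inside a library band window: sums the
# windowed contribution of *every* model component (tails included), so it is
# exact truth regardless of band overlap
analytic_window_area <- function(cfg, modality, amplitudes, lo, hi) {
  models <- cfg$band_models[[modality]]
  sum(vapply(names(models), function(bn)
    amplitudes[[bn]] * profile_window_integral(models[[bn]], lo, hi), 0))
}

#' Generate a synthetic two-group cohort
#'
#' @param cfg [cohort_config()].
#' @return list with `set` (raw [spectrum_set()]), `truth` (list of truth
#'   entries keyed by `modality:sample_id`, plus `config`), and the
#'   programmed `directions` (per default panel ratio under `cfg$scenario`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  spectra <- list()
  truth <- list()
  groups <- c(rep("control", cfg$n_control), rep("treated", cfg$n_treated))
  idx <- c(seq_len(cfg$n_control), seq_len(cfg$n_treated))
  for (mdl in cfg$modalities) {
    for (i in seq_along(groups)) {
      gs <- generate_spectrum(cfg, mdl, groups[i], idx[i])
      spectra[[length(spectra) + 1L]] <- gs$spectrum
      truth[[paste(mdl, gs$truth$sample_id, sep = ":")]] <- gs$truth
    }
  }
  list(set = spectrum_set(spectra),
       truth = c(truth, list(config = cfg)),
       directions = programmed_directions(cfg))
}

#' Programmed effect directions of a synthetic cohort
#'
#' Computes, analytically from the band models and effect multipliers, the
#' expected treated/control shift of every default panel ratio: mean-amplitude
#' window areas are evaluated in closed form for both groups and compared.
#' `"NONE"` means the programmed relative change is below 0.1\%.
#'
#' @param cfg [cohort_config()].
#' @param bands band library, default [default_band_library()].
#' @param ratios ratio panel, default [default_ratio_panel()].
#' @return named character vector of `"UP"`, `"DOWN"`, `"NONE"` per ratio.
#' @export
programmed_directions <- function(cfg, bands = default_band_library(),
                                  ratios = default_ratio_panel()) {
  mean_amps <- function(modality, treated) {
    models <- cfg$band_models[[modality]]
    vapply(names(models), function(bn) {
      mult <- if (treated && bn %in% names(cfg$effect_multipliers))
        cfg$effect_multipliers[[bn]] else 1
      models[[bn]]$amplitude * mult
    }, 0)
  }
  band_by_name <- stats::setNames(bands, vapply(bands, `[[`, "", "name"))
  area_of <- function(band_name, treated) {
    b <- band_by_name[[band_name]]
    if (!b$modality %in% cfg$modalities) return(NA_real_)
    analytic_window_area(cfg, b$modality, mean_amps(b$modality, treated),
                         b$window[1], b$window[2])
  }
  out <- vapply(ratios, function(r) {
    val <- function(treated) {
      num <- sum(vapply(r$numerator, area_of, 0, treated = treated))
      den <- if (length(r$denominator))
        sum(vapply(r$denominator, area_of, 0, treated = treated)) else 1
      num / den
    }
    rel <- val(TRUE) / val(FALSE)
    if (is.na(rel)) "NONE"
    else if (rel > 1.001) "UP" else if (rel < 0.999) "DOWN" else "NONE"
  }, "")
  stats::setNames(out, vapply(ratios, `[[`, "", "name"))
}

#' Preprocess a generated cohort
#'
#' Applies the default per-modality chains and builds the FTIR
#' second-derivative set.
#'
#' @param cohort result of [generate_cohort()].
#' @param cfg_ftir,cfg_raman optional [preprocess_config()] overrides.
#' @param with_second_derivative build the FTIR second-derivative set
#'   (default `TRUE`); disable when only band-area ratios are needed.
#' @return list with `set` (preprocessed) and `set2d` (FTIR second
#'   derivative, or `NULL`).
#' @export
preprocess_cohort <- function(cohort,
                              cfg_ftir = default_chain_config("FTIR"),
                              cfg_raman = default_chain_config("RAMAN"),
                              with_second_derivative = TRUE) {
  pp <- lapply(cohort$set$spectra, function(s) {
    preprocess_spectrum(s, if (s$modality == "FTIR") cfg_ftir else cfg_raman)
  })
  set2d <- NULL
  if (with_second_derivative) {
    ftir <- Filter(function(s) s$modality == "FTIR", cohort$set$spectra)
    if (length(ftir))
      set2d <- spectrum_set(lapply(ftir, preprocess_second_derivative,
                                   cfg = cfg_ftir))
  }
  list(set = spectrum_set(pp), set2d = set2d)
}

#' Generate synthetic deformability records
#'
#' Shear sweeps follow the saturating curve
#' EI(\eqn{\sigma}) = EImax \eqn{\sigma / (\sigma + \sigma_{1/2})} sampled on
#' a fixed 0.5-20 Pa grid; per-sample EImax is normal around the group mean
#' and measurement noise is added per stop.
#'
#' @param n_per_group samples per group.
#' @param eimax_mean named group means, default `c(control = 0.60,
#'   treated = 0.54)`.
#' @param eimax_sd between-sample SD of EImax.
#' @param sigma_half half-saturation shear stress in Pa.
#' @param noise_sd per-stop measurement noise SD.
#' @param seed integer seed.
#' @return named list of [deformability_record()] lists per group.
#' @export
generate_deformability <- function(n_per_group = 3L,
                                   eimax_mean = c(control = 0.60,
                                                  treated = 0.54),
                                   eimax_sd = 0.02, sigma_half = 2,
                                   noise_sd = 0.01, seed = 1L) {
  shear <- c(0.5, 0.8, 1.25, 2, 3.2, 5, 8, 12.5, 16, 20)
  with_seed(seed, {
    out <- lapply(names(eimax_mean), function(grp) {
      lapply(seq_len(n_per_group), function(i) {
        em <- stats::rnorm(1, eimax_mean[[grp]], eimax_sd)
        ei <- em * shear / (shear + sigma_half) +
          stats::rnorm(length(shear), 0, noise_sd)
        ei <- pmin(pmax(ei, 1e-4), 0.999)
        S <- 8                                     # pattern scale, a.u.
        deformability_record(sprintf("%s_%02d", grp, i), shear,
                             L = S * (1 + ei), W = S * (1 - ei))
      })
    })
    names(out) <- names(eimax_mean)
    out
  })
}

#' Generate synthetic complete blood counts
#'
#' Normal draws per analyte around group means (defaults are mouse-typical;
#' the treated group emulates aged blood: lower HCT at equal HGB, so MCV
#' falls and MCHC rises).
#'
#' @param n_per_group samples per group.
#' @param means named list of per-group `c(HGB, HCT, RBC)` means.
#' @param sds `c(HGB, HCT, RBC)` standard deviations.
#' @param seed integer seed.
#' @return data frame with group, sample_id, inputs and derived indices.
#' @export
generate_cbc <- function(n_per_group = 3L,
                         means = list(control = c(HGB = 14.5, HCT = 45, RBC = 9.5),
                                      treated = c(HGB = 14.5, HCT = 42, RBC = 9.6)),
                         sds = c(HGB = 0.5, HCT = 1.5, RBC = 0.3),
                         seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (grp in names(means)) {
      m <- means[[grp]]
      for (i in seq_len(n_per_group)) {
        v <- c(HGB = max(stats::rnorm(1, m[["HGB"]], sds[["HGB"]]), 0.1),
               HCT = max(stats::rnorm(1, m[["HCT"]], sds[["HCT"]]), 0.1),
               RBC = max(stats::rnorm(1, m[["RBC"]], sds[["RBC"]]), 0.1))
        cb <- derive_cbc(v[["HGB"]], v[["HCT"]], v[["RBC"]])
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, sample_id = sprintf("%s_%02d", grp, i),
          HGB = cb$HGB, HCT = cb$HCT, RBC = cb$RBC,
          MCV = cb$MCV, MCH = cb$MCH, MCHC = cb$MCHC)
      }
    }
    do.call(rbind, rows)
  })
}
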