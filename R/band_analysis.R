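# Marker-band integration and the biomarker ratio panel.
#
# Band windows are stored as [low, high] in ascending cm^-1 regardless of how
# sources print them. Windows, not nominal peak positions, are authoritative:
# the published CH-stretch labels conflict with their own windows, so the two
# CH windows are named by position (ch_window_a = 2847-2863,
# ch_window_b = 2936-2965) and the acyl-chain-shortening index is B/A, a
# CH3-to-CH2 stretch ratio.

#' Define a marker band
#'
#' @param name short identifier used in ratio definitions.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param nominal_position peak position in cm\eqn{^{-1}}.
#' @param window integration window `c(low, high)`; accepted in either order
#'   and normalized to ascending; width must be at least 5 cm\eqn{^{-1}}.
#' @param assignment free-text vibrational assignment.
#' @return a `band_definition` list.
#' @export
band_definition <- function(name, modality, nominal_position, window,
                            assignment = "") {
  modality <- match.arg(toupper(modality), MODALITIES)
  window <- sort(as.double(window))
  if (length(window) != 2L || diff(window) < 5)
    abort("band window must span at least 5 cm^-1")
  structure(list(name = as.character(name), modality = modality,
                 nominal_position = as.double(nominal_position),
                 window = window, assignment = assignment),
            class = "band_definition")
}

#' Define a biomarker ratio (or sum) of band areas
#'
#' The value is the sum of the numerator band areas divided by the sum of the
#' denominator band areas; with an empty denominator the value is the plain
#' numerator sum (used for total protein, phospholipid and cholesterol-ester
#' indices, which are reported as areas, not ratios).
#'
#' @param name ratio identifier.
#' @param numerator character vector of band names (summed).
#' @param denominator character vector of band names (summed); may be empty.
#' @param interpretation free text.
#' @param direction expected direction of change in an aged group relative to
#'   control, one of `"UP"`, `"DOWN"`, `"NONE"`; may be a named vector with
#'   one entry per aging scenario (e.g. `c(dgal = "DOWN", natural = "UP")`).
#' @return a `ratio_definition` list.
#' @export
ratio_definition <- function(name, numerator, denominator = character(),
                             interpretation = "", direction = "NONE") {
  if (!length(numerator)) abort("numerator must name at least one band")
  if (length(intersect(numerator, denominator)))
    abort("numerator and denominator bands must be disjoint")
  stopifnot(all(direction %in% c("UP", "DOWN", "NONE")))
  structure(list(name = as.character(name),
                 numerator = as.character(numerator),
                 denominator = as.character(denominator),
                 interpretation = interpretation, direction = direction),
            class = "ratio_definition")
}

#' Default marker-band library
#'
#' Published integration windows for RBC-membrane FTIR-ATR and Raman marker
#' bands (printed "(high-low)" pairs normalized to ascending). The 1738
#' cm\eqn{^{-1}} FTIR ester C=O band has no published window and uses a
#' symmetric \eqn{\pm}25 cm\eqn{^{-1}} default, flagged in its assignment.
#'
#' @return list of [band_definition()] objects.
#' @export
default_band_library <- function() {
  list(
    band_definition("amide_I", "FTIR", 1651, c(1605, 1687),
                    "amide I, protein backbone C=O stretch"),
    band_definition("amide_II", "FTIR", 1544, c(1502, 1560),
                    "amide II, N-H bend / C-N stretch"),
    band_definition("ch_window_a", "FTIR", 2852, c(2847, 2863),
                    "CH2 symmetric stretch window"),
    band_definition("ch_window_b", "FTIR", 2950, c(2936, 2965),
                    "CH3 asymmetric stretch window"),
    band_definition("po2_asym", "FTIR", 1236, c(1214, 1261),
                    "PO2- asymmetric stretch, phospholipids"),
    band_definition("co_o_c", "FTIR", 1167, c(1144, 1191),
                    "-CO-O-C- asymmetric stretch, cholesterol esters"),
    band_definition("ester_co_ftir", "FTIR", 1738, c(1713, 1763),
                    "ester C=O stretch (non-verbatim +/-25 cm^-1 window)"),
    band_definition("ester_co_raman", "RAMAN", 1743, c(1715, 1764),
                    "C=O symmetric stretch, esterified lipids"),
    band_definition("cc_1661", "RAMAN", 1661, c(1655, 1670),
                    "C=C symmetric stretch, lipid unsaturation"),
    band_definition("ch_def_1447", "RAMAN", 1447, c(1420, 1480),
                    "CH2/CH3 scissoring and bending"),
    band_definition("phe_1007", "RAMAN", 1007, c(990, 1015),
                    "phenylalanine aromatic ring breathing"))
}

#' Default biomarker ratio panel
#'
#' The semi-quantitative membrane panel: total protein (amide I + II sum),
#' amide II / amide I, phospholipid content (PO\eqn{_2^-} area), acyl chain
#' shortening (CH3/CH2 stretch window ratio), cholesterol esters (CO-O-C
#' area), lipid unsaturation (Raman 1661/1447) and esterified lipids (Raman
#' 1743/1007). Expected directions of change under accelerated (`"dgal"`)
#' and natural aging differ only for the two ester indices.
#'
#' @param scenario `"dgal"` or `"natural"`; selects which stored direction
#'   [expected_direction()] reports.
#' @return list of [ratio_definition()] objects with attribute `"scenario"`.
#' @export
default_ratio_panel <- function(scenario = c("dgal", "natural")) {
  scenario <- match.arg(scenario)
  panel <- list(
    ratio_definition("total_protein", c("amide_I", "amide_II"),
                     interpretation = "total protein content (amide I + II)",
                     direction = c(dgal = "NONE", natural = "NONE")),
    ratio_definition("amideII_over_amideI", "amide_II", "amide_I",
                     interpretation = "membrane protein secondary-structure shift",
                     direction = c(dgal = "NONE", natural = "NONE")),
    ratio_definition("phospholipid", "po2_asym",
                     interpretation = "phospholipid content (PO2- asym)",
                     direction = c(dgal = "DOWN", natural = "DOWN")),
    ratio_definition("acyl_shortening", "ch_window_b", "ch_window_a",
                     interpretation = "acyl chain shortening (CH3/CH2 stretch)",
                     direction = c(dgal = "UP", natural = "UP")),
    ratio_definition("cholesterol_esters", "co_o_c",
                     interpretation = "cholesterol esters (-CO-O-C-)",
                     direction = c(dgal = "DOWN", natural = "UP")),
    ratio_definition("unsaturation", "cc_1661", "ch_def_1447",
                     interpretation = "lipid unsaturation (C=C / CH def)",
                     direction = c(dgal = "DOWN", natural = "DOWN")),
    ratio_definition("esterified_lipids", "ester_co_raman", "phe_1007",
                     interpretation = "total esterified lipids (C=O / Phe)",
                     direction = c(dgal = "DOWN", natural = "UP")))
  attr(panel, "scenario") <- scenario
  panel
}

#' Expected direction of a ratio under a scenario
#' @param ratio a [ratio_definition()].
#' @param scenario `"dgal"` or `"natural"`.
#' @return `"UP"`, `"DOWN"` or `"NONE"`.
#' @export
expected_direction <- function(ratio, scenario = "dgal") {
  d <- ratio$direction
  if (!is.null(names(d)) && scenario %in% names(d)) unname(d[[scenario]])
  else unname(d[[1]])
}

#' Write / read a band library as a human-editable table
#'
#' Columns: name, modality, nominal_position, low, high, assignment.
#'
#' @param bands list of [band_definition()]s.
#' @param path TSV path.
#' @return `write_band_library` the path invisibly; `read_band_library` a
#'   list of band definitions.
#' @export
write_band_library <- function(bands, path) {
  df <- do.call(rbind, lapply(bands, function(b)
    data.frame(name = b$name, modality = b$modality,
               nominal_position = b$nominal_position,
               low = b$window[1], high = b$window[2],
               assignment = b$assignment)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_band_library
#' @export
read_band_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    band_definition(df$name[i], df$modality[i], df$nominal_position[i],
                    c(df$low[i], df$high[i]), df$assignment[i] %||% ""))
}

#' Integrate a marker band
#'
#' Trapezoidal integral of the intensity over the band window, with exact
#' linear interpolation of the window endpoints (so adjacent windows add
#' exactly). With `baseline = "local_linear"` the chord joining the two
#' window endpoints is subtracted first, which removes any constant or linear
#' local offset exactly.
#'
#' @param s spectrum covering the window, matching modality.
#' @param b [band_definition()].
#' @param baseline `"none"` or `"local_linear"`.
#' @return band area in intensity \eqn{\times} cm\eqn{^{-1}}.
#' @export
integrate_band <- function(s, b, baseline = c("none", "local_linear")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(s, "rbc_spectrum"), inherits(b, "band_definition"))
  if (s$modality != b$modality)
    abort("band '", b$name, "' is ", b$modality, " but spectrum is ", s$modality)
  lo <- b$window[1]; hi <- b$window[2]
  wn <- s$wavenumbers
  if (lo < wn[1] || hi > wn[length(wn)])
    abort("spectrum does not fully cover window of band '", b$name, "'")
  inner <- wn > lo & wn < hi
  x <- c(lo, wn[inner], hi)
  y <- c(interp1(wn, s$intensities, lo), s$intensities[inner],
         interp1(wn, s$intensities, hi))
  if (baseline == "local_linear") {
    chord <- y[1] + (y[length(y)] - y[1]) * (x - lo) / (hi - lo)
    y <- y - chord
  }
  trapz(x, y)
}

#' Negative-lobe magnitude of a second-derivative band
#'
#' Absorbance bands point downward in second-derivative spectra; this returns
#' the integral of \eqn{\max(0, -d^2A/d\nu^2)} over
#' `position` \eqn{\pm} `halfwidth`, i.e. the magnitude of the negative lobe.
#' Areas rather than point minima are used for noise robustness.
#'
#' @param s2 spectrum with stage `"SECOND_DERIVATIVE"`.
#' @param position lobe centre in cm\eqn{^{-1}}.
#' @param halfwidth half window width, default 5 cm\eqn{^{-1}}.
#' @return non-negative lobe magnitude.
#' @export
second_derivative_band_intensity <- function(s2, position, halfwidth = 5) {
  stopifnot(inherits(s2, "rbc_spectrum"))
  if (s2$stage != "SECOND_DERIVATIVE")
    abort("second_derivative_band_intensity requires a SECOND_DERIVATIVE spectrum")
  lo <- position - halfwidth; hi <- position + halfwidth
  wn <- s2$wavenumbers
  if (lo < wn[1] || hi > wn[length(wn)])
    abort("second-derivative window not covered by spectrum")
  inner <- wn > lo & wn < hi
  x <- c(lo, wn[inner], hi)
  y <- c(interp1(wn, s2$intensities, lo), s2$intensities[inner],
         interp1(wn, s2$intensities, hi))
  trapz(x, pmax(0, -y))
}

# scale a second-derivative spectrum by its amide-region min-max range.
# Pure scaling (no shift) so the negative-lobe sign convention survives; any
# global scale cancels in lobe ratios, making the choice benign but recorded.
scale_amide_region <- function(s2, region = c(1600, 1700)) {
  sel <- s2$wavenumbers >= region[1] & s2$wavenumbers <= region[2]
  y <- s2$intensities
  rng <- range(y[sel])
  if (diff(rng) == 0) return(s2)
  set_intensities(s2, y / diff(rng), stage = "SECOND_DERIVATIVE")
}

band_table_for_set <- function(set, bands, baselines) {
  rows <- list()
  for (s in set$spectra) {
    for (b in bands) {
      if (b$modality != s$modality) next
      area <- integrate_band(s, b, baseline = baselines[[s$modality]])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, group = s$group, modality = s$modality,
        band = b$name, area = area)
    }
  }
  do.call(rbind, rows)
}

#' Compute the biomarker panel for a cohort
#'
#' Integrates every library band for every spectrum, forms the panel ratios
#' per sample, and summarises per group (median, IQR, min, max) with a
#' Mann-Whitney comparison per ratio. If a second-derivative spectrum set is
#' supplied, the amide I secondary-structure indices `turns_over_alpha`
#' (1660/1650) and `unordered_over_alpha` (1640/1650) are appended, computed
#' as negative-lobe magnitude ratios on min-max-scaled amide-region spectra.
#'
#' @param set preprocessed [spectrum_set()].
#' @param set2d optional [spectrum_set()] of stage-`SECOND_DERIVATIVE` FTIR
#'   spectra.
#' @param bands band library, default [default_band_library()].
#' @param ratios ratio panel, default [default_ratio_panel()].
#' @param band_baseline named list of per-modality integration baselines;
#'   default none for FTIR (normalized absorbance) and local_linear for Raman
#'   (residual offsets after rubberband).
#' @param control_group label of the reference group; default `"control"` if
#'   present, else the first group.
#' @return a `biomarker_panel` object: list with `band_table`, `values`
#'   (per-sample ratio values), `summary` (per group x ratio box statistics)
#'   and `comparisons` (per ratio U, p, stars).
#' @export
compute_panel <- function(set, set2d = NULL,
                          bands = default_band_library(),
                          ratios = default_ratio_panel(),
                          band_baseline = list(FTIR = "none",
                                               RAMAN = "local_linear"),
                          control_group = NULL) {
  bt <- band_table_for_set(set, bands, band_baseline)
  band_mod <- vapply(bands, `[[`, character(1), "modality")
  names(band_mod) <- vapply(bands, `[[`, character(1), "name")

  lookup <- function(sample, band) {
    v <- bt$area[bt$sample_id == sample & bt$band == band]
    if (length(v) == 1L) v else NA_real_
  }
  sample_info <- unique(bt[c("sample_id", "group")])

  vals <- list()
  for (r in ratios) {
    need <- c(r$numerator, r$denominator)
    bad <- setdiff(need, names(band_mod))
    if (length(bad)) abort("ratio '", r$name, "' references unknown band(s): ",
                           paste(bad, collapse = ", "))
    for (i in seq_len(nrow(sample_info))) {
      sid <- sample_info$sample_id[i]
      num <- sum(vapply(r$numerator, function(b) lookup(sid, b), 0))
      den <- if (length(r$denominator))
        sum(vapply(r$denominator, function(b) lookup(sid, b), 0)) else 1
      v <- num / den
      if (is.na(v))
        warning("ratio '", r$name, "' unavailable for sample '", sid,
                "' (missing modality)", call. = FALSE)
      vals[[length(vals) + 1L]] <- data.frame(
        sample_id = sid, group = sample_info$group[i], ratio = r$name,
        value = v)
    }
  }
  values <- do.call(rbind, vals)

  if (!is.null(set2d)) {
    sd_ratios <- list(turns_over_alpha = c(1660, 1650),
                      unordered_over_alpha = c(1640, 1650))
    for (s2 in set2d$spectra) {
      if (s2$stage != "SECOND_DERIVATIVE") abort("set2d spectra must be SECOND_DERIVATIVE")
      sc <- scale_amide_region(s2)
      for (rn in names(sd_ratios)) {
        pos <- sd_ratios[[rn]]
        a <- second_derivative_band_intensity(sc, pos[1])
        b <- second_derivative_band_intensity(sc, pos[2])
        values <- rbind(values, data.frame(
          sample_id = s2$sample_id, group = s2$group, ratio = rn,
          value = if (b > 0) a / b else NA_real_))
      }
    }
  }

  values <- values[!is.na(values$value), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(values, list(values$group, values$ratio),
                                      drop = TRUE), function(d) {
    bs <- box_summary(d$value)
    data.frame(group = d$group[1], ratio = d$ratio[1], n = bs$n,
               median = bs$median, q1 = bs$q1, q3 = bs$q3,
               min = bs$min, max = bs$max)
  }))
  rownames(summ) <- NULL

  groups <- unique(values$group)
  if (is.null(control_group))
    control_group <- if ("control" %in% groups) "control" else groups[1]
  comparisons <- NULL
  if (length(groups) == 2L) {
    other <- setdiff(groups, control_group)
    comparisons <- do.call(rbind, lapply(split(values, values$ratio),
                                         function(d) {
      x <- d$value[d$group == control_group]
      y <- d$value[d$group == other]
      if (length(x) < 2L || length(y) < 2L) {
        warning("group with n<2 for ratio '", d$ratio[1],
                "'; statistics skipped", call. = FALSE)
        return(data.frame(ratio = d$ratio[1], n1 = length(x), n2 = length(y),
                          median1 = stats::median(x), median2 = stats::median(y),
                          U = NA_real_, p = NA_real_, stars = "",
                          method = NA_character_))
      }
      mw <- mann_whitney_u(x, y)
      data.frame(ratio = d$ratio[1], n1 = mw$n1, n2 = mw$n2,
                 median1 = stats::median(x), median2 = stats::median(y),
                 U = mw$U, p = mw$p_two_sided, stars = mw$stars,
                 method = mw$method)
    }))
    rownames(comparisons) <- NULL
  } else if (length(groups) > 2L) {
    warning("more than two groups; pairwise statistics not computed",
            call. = FALSE)
  }

  structure(list(band_table = bt, values = values, summary = summ,
                 comparisons = comparisons, control_group = control_group),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("<biomarker_panel>\n")
  if (!is.null(x$comparisons)) print(x$comparisons) else print(x$summary)
  invisible(x)
}
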