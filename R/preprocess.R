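# Preprocessing chains for FTIR-ATR and Raman spectra.
#
# Fixed op order: (cosmic-ray removal, Raman only) -> Savitzky-Golay smooth ->
# baseline removal -> (optional ATR correction, FTIR only) -> vector
# normalization. Second derivatives branch from the smoothed spectrum, by
# default after normalization. Every op preserves the wavenumber axis
# bit-exactly; provenance (op order and parameters) is accumulated in the
# "provenance" attribute of the spectrum.

#' Preprocessing configuration
#'
#' Defaults mirror the published workflow: a 13-point Savitzky-Golay window,
#' vector normalization over 900-3600 cm\eqn{^{-1}}, rubberband baseline for
#' Raman. The ATR penetration-depth correction is a documented first-order
#' \eqn{\nu}-proportional rescaling and is off by default because ratios of
#' nearby bands are insensitive to it.
#'
#' @param sg_window odd integer, number of smoothing points (default 13).
#' @param sg_polyorder polynomial order of the SG fit (default 3).
#' @param norm_range normalization window in cm\eqn{^{-1}} (default
#'   `c(900, 3600)`).
#' @param baseline_method `"rubberband"`, `"poly"` or `"none"`.
#' @param poly_degree degree for the polynomial baseline (default 3).
#' @param cosmic_z_threshold modified z-score threshold for Raman despiking
#'   (default 8).
#' @param atr_correction logical; apply the first-order ATR correction.
#' @param atr_reference_wavenumber wavenumber left unchanged by the ATR
#'   correction (default 1650 cm\eqn{^{-1}}).
#' @param derivative_after_normalization logical; compute second derivatives
#'   from the normalized (`TRUE`, default) or merely smoothed spectrum.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(sg_window = 13L, sg_polyorder = 3L,
                              norm_range = c(900, 3600),
                              baseline_method = c("rubberband", "poly", "none"),
                              poly_degree = 3L,
                              cosmic_z_threshold = 8,
                              atr_correction = FALSE,
                              atr_reference_wavenumber = 1650,
                              derivative_after_normalization = TRUE) {
  baseline_method <- match.arg(baseline_method)
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L)
    abort("sg_window must be odd", class = "rbcspec_config_error")
  if (sg_window < sg_polyorder + 2L)
    abort("sg_window must be >= sg_polyorder + 2", class = "rbcspec_config_error")
  if (length(norm_range) != 2L || norm_range[1] >= norm_range[2])
    abort("norm_range must be c(low, high) with low < high",
          class = "rbcspec_config_error")
  if (!is_scalar_number(cosmic_z_threshold) || cosmic_z_threshold <= 0)
    abort("cosmic_z_threshold must be > 0", class = "rbcspec_config_error")
  structure(list(
    sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
    norm_range = as.double(norm_range), baseline_method = baseline_method,
    poly_degree = as.integer(poly_degree),
    cosmic_z_threshold = cosmic_z_threshold,
    atr_correction = isTRUE(atr_correction),
    atr_reference_wavenumber = atr_reference_wavenumber,
    derivative_after_normalization = isTRUE(derivative_after_normalization)),
    class = "preprocess_config")
}

log_provenance <- function(s, op, ...) {
  pars <- list(...)
  entry <- if (length(pars))
    paste0(op, "(", paste(names(pars), unlist(pars), sep = "=", collapse = ", "), ")")
  else op
  attr(s, "provenance") <- c(attr(s, "provenance"), entry)
  s
}

check_uniform_grid <- function(s) {
  d <- diff(s$wavenumbers)
  if (max(d) / min(d) > 1.01)
    abort("wavenumber grid is not near-uniform (max/min step ratio > 1.01)")
  mean(d)
}

# Savitzky-Golay convolution coefficients for estimating the deriv-th
# derivative at the window centre, per unit step. Least-squares polynomial fit
# via the pseudoinverse of the local Vandermonde matrix.
sg_coefficients <- function(window, polyorder, deriv = 0L) {
  m <- (window - 1L) %/% 2L
  x <- seq.int(-m, m)
  A <- outer(x, 0:polyorder, `^`)
  pinv <- solve(crossprod(A), t(A))
  pinv[deriv + 1L, ] * factorial(deriv)
}

# Apply an SG filter with edge handling by polynomial refit: the first/last
# half-windows are replaced by evaluating the polynomial fitted to the
# first/last `window` points (the standard 'interp' edge mode).
apply_sg <- function(y, window, polyorder, deriv, h) {
  n <- length(y)
  if (n < window) abort("spectrum shorter than the SG window")
  m <- (window - 1L) %/% 2L
  cf <- sg_coefficients(window, polyorder, deriv)
  out <- as.double(stats::filter(y, rev(cf), method = "convolution", sides = 2))
  # edge refit
  x <- seq.int(0, window - 1L)
  A <- outer(x, 0:polyorder, `^`)
  coef_l <- qr.solve(A, y[seq_len(window)])
  coef_r <- qr.solve(A, y[seq.int(n - window + 1L, n)])
  dfac <- factorial(deriv)
  eval_poly_deriv <- function(beta, at) {
    p <- seq_along(beta) - 1L      # powers 0..polyorder
    keep <- p >= deriv
    sapply(at, function(t)
      sum(beta[keep] * (factorial(p[keep]) / factorial(p[keep] - deriv)) *
            t^(p[keep] - deriv)))
  }
  out[seq_len(m)] <- eval_poly_deriv(coef_l, seq.int(0, m - 1L))
  out[seq.int(n - m + 1L, n)] <- eval_poly_deriv(coef_r,
                                                 seq.int(window - m, window - 1L))
  out / h^deriv
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; polynomial signals of degree
#' \eqn{\le} `sg_polyorder` pass through unchanged away from the edges. Edges
#' are handled by refitting the boundary windows.
#'
#' @param s spectrum on a near-uniform grid (max/min step ratio \eqn{\le} 1.01).
#' @param cfg [preprocess_config()].
#' @return smoothed spectrum, same axis and stage.
#' @export
savitzky_golay_smooth <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "rbc_spectrum"))
  h <- check_uniform_grid(s)
  y <- apply_sg(s$intensities, cfg$sg_window, cfg$sg_polyorder, 0L, h)
  log_provenance(set_intensities(s, y),
                 "savitzky_golay_smooth", window = cfg$sg_window,
                 polyorder = cfg$sg_polyorder)
}

#' Savitzky-Golay second derivative
#'
#' Combined smoothing/differentiation filter; the result has units of
#' intensity per (cm\eqn{^{-1}})\eqn{^2} and stage `"SECOND_DERIVATIVE"`.
#' Absorbance peaks appear as negative lobes.
#'
#' @inheritParams savitzky_golay_smooth
#' @return second-derivative spectrum.
#' @export
second_derivative <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "rbc_spectrum"))
  h <- check_uniform_grid(s)
  po <- max(cfg$sg_polyorder, 2L)
  y <- apply_sg(s$intensities, cfg$sg_window, po, 2L, h)
  log_provenance(set_intensities(s, y, stage = "SECOND_DERIVATIVE"),
                 "second_derivative", window = cfg$sg_window, polyorder = po)
}

#' Remove cosmic-ray spikes from a Raman spectrum
#'
#' Flags points whose modified z-score of the second difference exceeds
#' `cosmic_z_threshold` and replaces them by linear interpolation between the
#' nearest unflagged neighbours; all other points are returned bit-identical.
#' If more than 10\% of points are flagged the spectrum is returned with a
#' warning and the flags attached (threshold misconfiguration signal).
#'
#' @param s Raman spectrum.
#' @param cfg [preprocess_config()].
#' @return despiked spectrum with attribute `"cosmic_flags"` (integer indices).
#' @export
remove_cosmic_rays <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "rbc_spectrum"))
  if (s$modality != "RAMAN")
    abort("cosmic-ray removal applies to RAMAN spectra only")
  y <- s$intensities
  n <- length(y)
  d2 <- diff(y, differences = 2)            # second difference, centres 2..n-1
  med <- stats::median(d2)
  madv <- stats::median(abs(d2 - med))
  if (madv == 0) madv <- stats::sd(d2) * 0.6745 + .Machine$double.eps
  mz <- 0.6745 * (d2 - med) / madv
  flagged <- which(abs(mz) > cfg$cosmic_z_threshold) + 1L
  if (!length(flagged)) {
    out <- log_provenance(s, "remove_cosmic_rays", flagged = 0)
    attr(out, "cosmic_flags") <- integer(0)
    return(out)
  }
  if (length(flagged) > 0.1 * n) {
    warning("remove_cosmic_rays: >10% of points flagged; check cosmic_z_threshold",
            call. = FALSE)
    attr(s, "cosmic_flags") <- flagged
    return(log_provenance(s, "remove_cosmic_rays",
                          flagged = length(flagged), applied = FALSE))
  }
  keep <- setdiff(seq_len(n), flagged)
  y[flagged] <- stats::approx(s$wavenumbers[keep], y[keep],
                              xout = s$wavenumbers[flagged], rule = 2)$y
  out <- log_provenance(set_intensities(s, y), "remove_cosmic_rays",
                        flagged = length(flagged))
  attr(out, "cosmic_flags") <- flagged
  out
}

# lower convex hull (Andrew's monotone chain) over ascending-x points;
# returns indices of hull vertices
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # pop b if it lies above the chord a-i (cross product <= 0)
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        k <- k - 1L
      else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

rubberband_baseline <- function(x, y) {
  idx <- lower_hull_idx(x, y)
  stats::approx(x[idx], y[idx], xout = x, rule = 2)$y
}

# iteratively clipped polynomial baseline (ModPoly-style): fit, clip the
# signal to the fit so peaks stop pulling the polynomial up, refit
poly_baseline <- function(x, y, degree, maxiter = 100L, tol = 1e-8) {
  xc <- (x - mean(x)) / stats::sd(x)
  w <- y
  fit <- NULL
  for (it in seq_len(maxiter)) {
    fit <- stats::lm.fit(outer(xc, 0:degree, `^`), w)$fitted.values
    wn <- pmin(w, fit)
    if (max(abs(wn - w)) < tol * (max(abs(y)) + tol)) { w <- wn; break }
    w <- wn
  }
  fit
}

#' Remove the baseline of a spectrum
#'
#' `"rubberband"` subtracts the lower convex hull of the (wavenumber,
#' intensity) points (output is exactly zero at hull anchors); `"poly"`
#' subtracts an iteratively clipped least-squares polynomial of degree
#' `poly_degree`; `"none"` is the identity.
#'
#' @inheritParams savitzky_golay_smooth
#' @param method override of `cfg$baseline_method`.
#' @return baseline-corrected spectrum.
#' @export
remove_baseline <- function(s, cfg = preprocess_config(), method = NULL) {
  stopifnot(inherits(s, "rbc_spectrum"))
  method <- method %||% cfg$baseline_method
  if (!method %in% c("rubberband", "poly", "none"))
    abort("unknown baseline method '", method, "'",
          class = "rbcspec_config_error")
  if (method == "none")
    return(log_provenance(s, "remove_baseline", method = "none"))
  if (length(s$wavenumbers) < 10L)
    abort("baseline removal needs at least 10 points")
  bl <- switch(method,
    rubberband = rubberband_baseline(s$wavenumbers, s$intensities),
    poly = poly_baseline(s$wavenumbers, s$intensities, cfg$poly_degree))
  log_provenance(set_intensities(s, s$intensities - bl),
                 "remove_baseline", method = method)
}

#' Vector normalization over a wavenumber range
#'
#' Divides all intensities by the Euclidean norm of the points falling inside
#' `cfg$norm_range`, so the in-range norm of the result is exactly 1. Ratios
#' of band areas become invariant to global scaling of the raw spectrum.
#'
#' @inheritParams savitzky_golay_smooth
#' @return normalized spectrum, stage `"PREPROCESSED"`.
#' @export
normalize_spectrum <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "rbc_spectrum"))
  rng <- cfg$norm_range
  sel <- s$wavenumbers >= rng[1] & s$wavenumbers <= rng[2]
  if (!any(sel))
    abort("spectrum does not cover the normalization range")
  nrm <- sqrt(sum(s$intensities[sel]^2))
  if (nrm == 0) abort("all-zero intensities in normalization range")
  log_provenance(set_intensities(s, s$intensities / nrm, stage = "PREPROCESSED"),
                 "normalize", low = rng[1], high = rng[2])
}

#' First-order ATR penetration-depth correction
#'
#' The evanescent-wave penetration depth in ATR scales as \eqn{1/\nu}, so
#' uncorrected ATR absorbance under-weights high wavenumbers. This correction
#' multiplies intensities by \eqn{\nu / \nu_{ref}}, leaving the reference
#' wavenumber unchanged. It is a documented simple stand-in for proprietary
#' extended ATR corrections and is off by default.
#'
#' @inheritParams savitzky_golay_smooth
#' @return corrected spectrum.
#' @export
atr_correct <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "rbc_spectrum"))
  if (s$modality != "FTIR") abort("ATR correction applies to FTIR spectra only")
  if (any(s$wavenumbers <= 0)) abort("non-positive wavenumbers")
  scale <- s$wavenumbers / cfg$atr_reference_wavenumber
  log_provenance(set_intensities(s, s$intensities * scale),
                 "atr_correct", reference = cfg$atr_reference_wavenumber)
}

#' Run the full preprocessing chain on one spectrum
#'
#' Fixed order: cosmic-ray removal (Raman only) \eqn{\to} SG smoothing
#' \eqn{\to} baseline removal \eqn{\to} ATR correction (FTIR, if enabled)
#' \eqn{\to} vector normalization. The op order and parameters are recorded in
#' the `"provenance"` attribute.
#'
#' @param s raw spectrum.
#' @param cfg [preprocess_config()]. The conventional defaults differ by
#'   modality: use `baseline_method = "none"` for FTIR absorbance and
#'   `"rubberband"` for Raman (see [default_chain_config()]).
#' @return preprocessed spectrum.
#' @export
preprocess_spectrum <- function(s, cfg = preprocess_config()) {
  if (s$modality == "RAMAN") s <- remove_cosmic_rays(s, cfg)
  s <- savitzky_golay_smooth(s, cfg)
  s <- remove_baseline(s, cfg)
  if (s$modality == "FTIR" && cfg$atr_correction) s <- atr_correct(s, cfg)
  normalize_spectrum(s, cfg)
}

#' Default per-modality preprocessing configuration
#'
#' FTIR: no baseline removal (normalized absorbance analysed directly, as in
#' common ATR workflows); Raman: rubberband baseline after despiking and
#' smoothing.
#'
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return a [preprocess_config()].
#' @export
default_chain_config <- function(modality) {
  modality <- match.arg(toupper(modality), MODALITIES)
  if (modality == "FTIR") preprocess_config(baseline_method = "none")
  else preprocess_config(baseline_method = "rubberband")
}

#' Second-derivative branch of the preprocessing chain
#'
#' Smooths, optionally normalizes (per
#' `cfg$derivative_after_normalization`), then applies the SG second
#' derivative. Used for amide I secondary-structure analysis.
#'
#' @inheritParams preprocess_spectrum
#' @return spectrum with stage `"SECOND_DERIVATIVE"`.
#' @export
preprocess_second_derivative <- function(s, cfg = preprocess_config()) {
  if (s$modality == "RAMAN") s <- remove_cosmic_rays(s, cfg)
  s <- savitzky_golay_smooth(s, cfg)
  if (cfg$derivative_after_normalization) s <- normalize_spectrum(s, cfg)
  second_derivative(s, cfg)
}
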