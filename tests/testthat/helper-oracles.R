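# Independent oracles and fixture builders, written before the code paths
# they check and kept independent of them.

# Brute-force exact two-sided Mann-Whitney p: enumerate every C(N, n1)
# labeling, compute U by direct pairwise comparison (0.5 per tie), and count
# labelings at least as far from the null mean as observed. Used as the
# enumeration oracle for the implementation's DP / midrank paths.
oracle_mw_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  N <- length(v)
  u_of <- function(idx) {
    xs <- v[idx]
    ys <- v[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combos <- utils::combn(N, n1)
  us <- apply(combos, 2, u_of)
  mu <- n1 * (N - n1) / 2
  u_obs <- u_of(seq_len(n1))
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Gaussian band fixture on a uniform grid
gauss_spec <- function(center, sigma, amp = 1, grid = seq(900, 3800, 1),
                       modality = "FTIR", offset = 0, slope = 0, ...) {
  y <- amp * exp(-((grid - center)^2) / (2 * sigma^2)) +
    offset + slope * (grid - grid[1])
  spectrum(grid, y, modality, ...)
}

# analytic windowed Gaussian area
gauss_window_area <- function(center, sigma, amp, lo, hi) {
  amp * sigma * sqrt(2 * pi) *
    (pnorm((hi - center) / sigma) - pnorm((lo - center) / sigma))
}

# analytic windowed Lorentzian area (half-width gamma)
lorentz_window_area <- function(center, gamma, amp, lo, hi) {
  amp * gamma * (atan((hi - center) / gamma) - atan((lo - center) / gamma))
}

lib_band <- function(name) {
  Filter(function(b) b$name == name, default_band_library())[[1]]
}

# noiseless deterministic cohort config used by several truth tests
quiet_config <- function(...) {
  cohort_config(amplitude_cv = 0, cosmic_rate = 0,
                noise_sd = c(FTIR = 0, RAMAN = 0),
                baseline_coeffs = list(FTIR = 0, RAMAN = 0), ...)
}
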