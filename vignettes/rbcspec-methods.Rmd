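---
title: "Semi-quantitative vibrational spectroscopy of red blood cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rbcspec methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcspec)
```

## The problem

Aging red blood cells (RBCs) remodel their membranes: phospholipids are
cleaved after peroxidation, acyl chains shorten, C=C unsaturation drops, and
the secondary structure of membrane and cytosolic proteins shifts. Vibrational
spectroscopy sees these changes without labels. FTIR-ATR absorbance and Raman
scattering of isolated membranes (and of intact cells for the amide I region)
are summarised into a small panel of marker-band area ratios, each with a
biochemical reading and an expected direction of change under aging; groups
are compared nonparametrically. `rbcspec` implements this entire workflow,
plus an ektacytometry elongation-index module and a synthetic cohort
generator, so that every stage can be validated without access to measured
animal data.

## The measurement model

A preprocessed spectrum is treated as a sum of marker bands over a smooth
residual background. For a band $b$ with integration window $[\nu_1,\nu_2]$
the semi-quantitative abundance estimate is the trapezoidal integral

$$A_b \;=\; \int_{\nu_1}^{\nu_2} I(\nu)\, d\nu ,$$

optionally after subtracting the chord through the window endpoints
(`local_linear`), which removes any locally linear offset exactly. Panel
indices are sums or ratios of such areas, e.g. lipid unsaturation
$A_{1661}/A_{1447}$ (Raman C=C stretch over CH$_2$/CH$_3$ deformation) or
acyl-chain shortening as the CH$_3$/CH$_2$ stretch-window ratio. Windows, not
nominal peak labels, are authoritative: the published CH-stretch labels
conflict with their own windows, so the package names these bands
`ch_window_a` (2847–2863 cm$^{-1}$) and `ch_window_b` (2936–2965 cm$^{-1}$)
and defines acyl shortening as B/A.

Protein secondary structure is read from the Savitzky–Golay second derivative
of the amide I region, where absorbance sub-bands appear as negative lobes
($\alpha$-helix $\approx$ 1650, turns $\approx$ 1660, unordered $\approx$
1640 cm$^{-1}$). The indices are ratios of negative-lobe magnitudes,
$\int \max(0, -d^2A/d\nu^2)\,d\nu$ over position $\pm 5$ cm$^{-1}$; areas are
used instead of point minima for noise robustness.

## Preprocessing chains and their parameters

The op order is fixed and logged: cosmic-ray removal (Raman only) →
Savitzky–Golay smoothing → baseline removal → optional ATR correction (FTIR)
→ vector normalization; the second-derivative branch leaves the chain after
normalization by default.

| parameter | default | units | rationale |
|---|---|---|---|
| `sg_window` | 13 | points | the published smoothing window |
| `sg_polyorder` | 3 | – | standard order preserving band shape; the source states only the window |
| `norm_range` | 900–3600 | cm$^{-1}$ | the published normalization range |
| `baseline_method` | rubberband (Raman), none (FTIR) | – | the source says only "background removal"; rubberband is the common Raman default, while ATR absorbance is analysed as normalized |
| `cosmic_z_threshold` | 8 | – | modified z-score of the second difference; spikes are 20–100$\times$ band amplitude, far above this |
| `atr_correction` | off | – | first-order $\nu/\nu_{ref}$ stand-in for proprietary extended ATR corrections; ratios of nearby bands are insensitive to it |

Normalization is *vector* normalization (unit Euclidean norm over
`norm_range`): the source states only that spectra "were normalized", so the
choice is isolated behind the config. It guarantees that every panel index is
invariant to global scaling of the raw spectrum, which the test suite checks
end to end at $10^{-9}$.

Savitzky–Golay filters are implemented from the local least-squares
polynomial fit (pseudoinverse of the window Vandermonde matrix). Edges are
handled by refitting the first/last full window and evaluating the fitted
polynomial there; all integration windows are interior by construction, so
edge points never enter band areas. Second derivatives are divided by the
squared mean step, and require a near-uniform grid (max/min step ratio
$\le 1.01$).

The rubberband baseline is the lower convex hull of the $(\nu, I)$ points
(Andrew's monotone chain), linearly interpolated and subtracted; the output
is exactly zero at hull anchors. The polynomial alternative iteratively clips
the signal to the fit so peaks stop attracting the baseline.

Cosmic-ray removal flags points whose modified z-score
$0.6745\,(d_i - \tilde d)/\mathrm{MAD}(d)$ of the second difference $d$
exceeds the threshold, and replaces only flagged points by linear
interpolation between the nearest unflagged neighbours. On noise-free
synthetic spectra the MAD collapses and the >10% over-flag guard fires; the
spectrum is then returned unchanged with a warning — despiking is only
meaningful for noisy data.

## Group statistics

Group summaries are box statistics (median, interquartile range by linear
interpolation — quantile type 7, a convention the source never states —
and min–max whiskers). Two-group comparison uses the Mann–Whitney U test with
U computed from midranks. The exact two-sided p-value is defined as the null
probability of $|U - n_1 n_2/2| \ge |u_{obs} - n_1 n_2/2|$ under the
permutation distribution conditional on the tie pattern: a single definition
that reduces to the usual doubled tail in the symmetric tie-free case and
needs no special-casing under ties. Without ties the distribution comes from
the exact integer recurrence
$N(u; n_1, n_2) = N(u - n_2;\, n_1{-}1, n_2) + N(u;\, n_1, n_2{-}1)$; with
ties, from full enumeration of the $\binom{N}{n_1}$ midrank assignments
(doubled midranks are integers, so tail comparisons are exact). Exact mode is
automatic for $n_1 + n_2 \le 20$; beyond that a tie- and
continuity-corrected normal approximation is used. No multiple-testing
correction is applied across the panel, matching the source analysis.
Shapiro–Wilk normality is reported alongside but never switches the test —
the source reports both without stating a decision rule.

## The synthetic world

`cohort_config()` states the simulated world once:

* two groups, default $n = 3$ per group (the published membrane cohort
  sizes; power studies use 10),
* FTIR grid 900–3800 cm$^{-1}$, Raman 400–1800 cm$^{-1}$, 1 cm$^{-1}$ step,
* Gaussian marker bands at the library positions with mouse-membrane-like
  relative amplitudes; the amide I envelope is built from three sub-bands
  (1650/1660/1640 cm$^{-1}$, width 12 cm$^{-1}$) so the same spectra serve
  band integration and secondary-structure analysis,
* log-normal band-amplitude variation with CV 5% (multiplicative biological
  variation keeps amplitudes positive),
* a small linear FTIR baseline, a quadratic Raman fluorescence background,
  white noise, and Poisson($1$) cosmic spikes of 20–100$\times$ local
  amplitude per Raman spectrum,
* the `"dgal"` accelerated-aging scenario: PO$_2^-$ $\times$0.75, Raman C=C
  $\times$0.8, CH$_3$ window $\times$1.25, protein bands unchanged — the
  stated direction pattern (phospholipids ↓, unsaturation ↓, acyl shortening
  ↑, total protein unchanged). The ester indices are direction-tagged per
  scenario (down under accelerated aging, up under natural aging, following
  the source's Results over its self-contradictory abstract) but are not
  perturbed by the default multipliers.

Every generated spectrum retains a noise-free, baseline-free twin and its
drawn amplitudes; analytic in-window areas (error-function/arctangent closed
forms summed over *all* model components, so band overlap is handled exactly)
are the oracle for integration tests. All randomness descends from a single
integer seed through an explicit child-seed scheme; generation never touches
the caller's RNG state.

What the generator does **not** emulate: detector response and atmospheric
lines, resonance-Raman effects of heme (the reason intact RBCs are analysed
by FTIR only), water-vapor bands, Mie scattering, instrument-specific ATR
corrections. A green end-to-end test therefore establishes that the pipeline
recovers programmed compositional shifts from spectra with realistic noise,
baselines and spikes — not that it reproduces any instrument's systematics.

## Numerical choices and degenerate inputs

* Band windows printed as "(high–low)" are normalized to ascending on load;
  descending spectral files are reversed.
* Window endpoints are linearly interpolated during integration, so adjacent
  windows add exactly (tested at $10^{-9}$ relative).
* NaN or missing intensities are rejected at read time; no imputation rule
  exists in the source.
* Zero spectra cannot be normalized (error); constant samples have no
  Shapiro–Wilk W (error); sweeps ending below 19.5 Pa have no EImax (error,
  tolerance for instrument grids ending just under 20 Pa).
* W > L in ektacytometry gives a negative EI with a warning, not an error
  (diffraction axes can swap at low shear).
* Ratios with an empty denominator are plain area sums: the panel reports
  total protein, phospholipid and cholesterol-ester content as areas, as the
  source does.

## Validity regime of the lobe-ratio index

The 1660/1650 negative-lobe ratio recovers the generative amplitude ratio
within 15% when sub-bands are resolvable (width $\sigma \approx 9$
cm$^{-1}$, FWHM $\approx 21$ cm$^{-1}$, typical of amide I components). For
broader sub-bands (including the generator's default width 12) lobe overlap
biases the absolute value upward; the index remains monotone in the
underlying ratio and identically biased in both groups, so group *contrasts*
— the quantity the panel reports — remain valid. This is documented rather
than "fixed": real amide I analysis has the same property.

## Known limitations

* No scattering (Mie/resonant-Mie) or water-vapor correction; no band
  deconvolution or Voigt fitting — indices are semi-quantitative by design.
* The exact test enumerates up to $n_1 + n_2 = 20$ with ties; larger tied
  samples fall back to the corrected normal approximation.
* The ATR correction is first-order only and off by default.
* The deformability module consumes diffraction-pattern lengths/widths; it
  does not fit the diffraction images themselves.
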