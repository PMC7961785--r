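# rbcspec

Semi-quantitative vibrational biospectroscopy of red blood cells (RBCs) in R.

Aging remodels the RBC membrane — phospholipids fall, acyl chains shorten,
lipid unsaturation drops, protein secondary structure shifts — and these
changes are visible in FTIR-ATR and Raman spectra long before they are
quantifiable by wet chemistry. `rbcspec` is for researchers who run such
panels: it turns raw spectral tables into a marker-band biomarker panel with
nonparametric group statistics, and ships a fully seeded synthetic cohort
generator so the entire pipeline is testable without any measured data.

## What it computes

For each preprocessed spectrum the package integrates a library of published
marker-band windows (trapezoid, optional local-linear chord subtraction)

    A_b = ∫ I(ν) dν  over  [ν1, ν2]

and reports the panel

| index | definition | reading | aging direction |
|---|---|---|---|
| `total_protein` | A(amide I) + A(amide II) | total protein | none |
| `amideII_over_amideI` | A(amide II)/A(amide I) | protein structure shift | scenario-specific |
| `phospholipid` | A(PO₂⁻ asym, 1214–1261) | phospholipid content | down |
| `acyl_shortening` | A(2936–2965)/A(2847–2863) | CH₃/CH₂, chain shortening | up |
| `cholesterol_esters` | A(CO–O–C, 1144–1191) | cholesterol esters | down (accelerated) / up (natural) |
| `unsaturation` | A(1661)/A(1447), Raman | lipid unsaturation | down |
| `esterified_lipids` | A(1743)/A(1007), Raman | esterified lipids | down (accelerated) / up (natural) |
| `turns_over_alpha` | 2nd-derivative lobes 1660/1650 | turns vs α-helix | down |
| `unordered_over_alpha` | 2nd-derivative lobes 1640/1650 | unordered vs α-helix | none |

Preprocessing follows the standard chain — cosmic-ray despiking (modified
z-score of the second difference), 13-point Savitzky–Golay smoothing,
rubberband (convex-hull) or polynomial baseline removal, vector normalization
over 900–3600 cm⁻¹, optional first-order ATR penetration-depth correction —
and group comparison uses an exact Mann–Whitney U test (full permutation
enumeration, tie-aware) with box-plot summaries. Companion modules cover
ektacytometry (EI = (L−W)/(L+W), EImax at 20 Pa) and red-cell indices
(MCV = 10·HCT/RBC, MCH = 10·HGB/RBC, MCHC = 100·HGB/HCT).

## Worked example

Simulate an accelerated-aging cohort (3 control + 3 treated mice, both
modalities), run the full pipeline, and read the comparison table:

```r
library(rbcspec)
out <- tempfile()
panel <- run_pipeline(run_config(
  out_dir = out,
  simulate = list(n_control = 3, n_treated = 3, scenario = "dgal"),
  seed = 1))
panel$comparisons
#>                  ratio n1 n2   median1    median2 U   p stars method
#> 2  amideII_over_amideI  3  3 0.2732720 0.28638564 4 1.0        exact
#> 4    esterified_lipids  3  3 0.8806342 0.84539311 9 0.1        exact
#> 5         phospholipid  3  3 0.5661863 0.42873688 9 0.1        exact
#> 6        total_protein  3  3 7.7434807 7.84498713 4 1.0        exact
#> 9         unsaturation  3  3 0.1046321 0.08032941 9 0.1        exact
#> ...
```

The programmed effects show: the treated phospholipid median falls from 0.57
to 0.43 and unsaturation from 0.105 to 0.080 (U = 9, the complete-separation
value for n = 3 vs 3), while total protein barely moves. With n = 3 per group
the *smallest achievable* exact two-sided p is 0.1 — exactly why the original
membrane cohorts report trends at these sizes; at n = 10 per group the same
effects are significant in ≥ 90% of replicates (see the acceptance suite).
The output directory also receives `band_table.csv`, `panel_values.csv`,
`panel_summary.csv`, `comparisons.csv` and a `provenance.json` recording the
op order, parameters and seed.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/rbcspec", package = "rbcspec"))')" \
  run --scenario dgal --n 3 --seed 1 --out results/
```

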