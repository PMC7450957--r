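# mitedamage

Automated quantification of spider-mite feeding damage on whole plant
rosette scans.

The two-spotted spider mite (*Tetranychus urticae*) is a cell-content feeder:
it empties mesophyll cells one by one, leaving diffuse pale-yellow chlorotic
spots instead of the sharp holes chewing insects make. Rating that damage on
Arabidopsis rosettes is central to susceptibility screens and resistance
breeding, but the manual reference method — a rater marking chlorotic squares
on a grid overlay — is slow, subjective, and systematically biased upward:
any grid square that contains one damaged pixel is counted whole, so healthy
tissue inside counted squares inflates the estimate.

`mitedamage` implements an automated measurement pipeline for flatbed scans
of whole rosettes, together with the comparator methods and the agreement
statistics needed to validate it:

1. **Pixel classification.** A random forest over a multi-scale feature
   stack (raw RGB; Gaussian-smoothed RGB, gradient magnitude, Laplacian and
   structure-tensor eigenvalues per scale) assigns each pixel to
   `background`, `healthy` or `damaged`, trained from sparse rater
   annotations with an uncertainty map (`1 − p₁ + p₂`) to drive active
   relabelling.
2. **Cluster-size noise filtering.** Connected components of the damage mask
   smaller than a threshold are discarded. The threshold is calibrated on
   control (uninfested) rosettes: every cluster detected there is a false
   positive, and the filter cut-off is the mean false-cluster size.
3. **Control correction.** Per genotype and scan condition, the mean control
   damage fraction x̄_c = mean(DA_c/TA_c) is estimated from uninfested
   plants, and each treated rosette is corrected as
   **A = DA_t − x̄_c · TA_t**; non-positive corrections are kept as explicit
   `dropped_nonpositive` records.
4. **Comparators.** A two-stage colour-plane threshold segmenter, a
   grid-average green-deficiency segmenter with a 9-level sensitivity
   ladder, and an emulator of the manual grid standard (any-overlap or
   majority counting on 0.25 mm squares).
5. **Agreement statistics.** Bland–Altman bias and limits of agreement
   (absolute or percent-of-pair-mean differences), the coefficient of
   repeatability `1.96·sd(d)` with chi-square intervals, Lin's concordance
   correlation `ccc = 2s_xy / (s_x² + s_y² + (x̄−ȳ)²)`, Spearman's ρ, and
   genotype damage quotients.

No public scan set accompanies the method, so the package ships a seeded
synthetic rosette generator with per-pixel ground truth (overlapping leaves
with petioles, chlorotic lesions, trichome-like specks, pale centres,
brightened margins, white/black backgrounds, scanner brightness/contrast
emulation). Every stage of the pipeline is exercised and validated on these
synthetic cohorts.

## Worked example

```r
library(mitedamage)
library(dplyr)

specs <- list(
  phenotype_spec("low",  damage_fraction = 0.01, pale_center = TRUE),
  phenotype_spec("mid",  damage_fraction = 0.015),
  phenotype_spec("high", damage_fraction = 0.05)
)
cfg <- run_config(seed = 7, dpi = 150, specs = specs, n_replicates = 8)
res <- run_pipeline(cfg)   # simulate, train, classify, filter, correct

attr(res$measurements, "cluster_threshold")
#> [1] 3

res$comparison |>
  group_by(genotype) |>
  summarise(mean_corrected = mean(corrected_area_mm2, na.rm = TRUE),
            mean_truth     = mean(true_damage_area_mm2))
#> # A tibble: 3 × 3
#>   genotype mean_corrected mean_truth
#>   <chr>             <dbl>      <dbl>
#> 1 high              24.2       24.4
#> 2 low                5.23       5.29
#> 3 mid                8.41       8.18

damage_quotient(res$comparison, corrected_area_mm2, genotype,
                "high", "mid")$quotient
#> [1] 2.878
```

The cohort simulates 8 infested + 8 control rosettes for three genotypes
whose true damage fractions are 1%, 1.5% and 5% of rosette area. The
pipeline is trained on six scans, auto-calibrates its cluster filter on the
24 controls (3 px here), and recovers the per-genotype mean damage to within
a few percent; the high/mid quotient (2.88 vs a true ratio of about 3)
preserves the susceptibility ranking that screens depend on. Comparing
methods against ground truth shows the expected structure: the manual-grid
emulator overestimates (positive Bland–Altman bias), while the ML pipeline's
bias is near zero and slightly negative.

```r
ba <- bland_altman(tibble::tibble(x = est, y = truth), x, y)
autoplot(ba)          # classic mean-difference plot with ±1.96 sd lines
tidy(lin_ccc(df, x, y))
```

A thin command-line wrapper over the same functions lives at
`inst/cli/mitedamage.R` (subcommands `simulate`, `quantify`, `correct`,
`compare`, all driven by a YAML run config).

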