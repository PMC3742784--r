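# corneamosaic

Quantification of clonal mosaicism and cell turnover in the mouse corneal
epithelium, for researchers studying limbal epithelial stem cells (LESCs),
X-inactivation mosaics and pulse-chase labelling — e.g. in models of
aniridia-related corneal deterioration.

The adult cornea is maintained by stem-cell clones on the limbal ring whose
progeny paint radial stripes in marker mosaics. The package implements the
corrected run statistics that connect visible patterns to clone numbers, the
BrdU labelling indices that measure basal-to-suprabasal cell movement, and
label-retaining-cell (LRC) image quantification — together with stochastic
simulators of every input, so each statistic is validated by parameter
recovery against generator ground truth.

## The statistics

For a one-dimensional mosaic with labelled proportion *p*, adjacent
same-colour coherent clones merge into visible patches; the expected number
of clones per positive patch is **1/(1 − p)**. Hence:

- **Corrected mean patch length** = mean positive-patch length × (1 − p) —
  estimates the mean coherent clone length (developmental cell mixing),
  independently of *p* (`corrected_mean_patch_length()`).
- **Corrected stripe number** = observed stripes / (1 − p) — estimates the
  number of labelled stem-cell clones: on a ring of *K* clones,
  E[stripes] = *K p*(1 − *p*) exactly, so the correction recovers *K p*
  (`corrected_stripe_number()`, with `stripes_per_mm()` normalising by the
  corneal circumference and `total_clone_number()` extending to *K*).
- **Labelling indices**: BLI (positive basal / total basal), SLI (positive
  suprabasal / total suprabasal) and ASLI (positive suprabasal / total
  *basal*, which removes the dependence on layer number; identically
  ASLI/SLI = suprabasal/basal cells), per corneal region (P/I/C six-group
  partition) and whole eye; plus the suprabasal fraction
  100·SLI/(SLI + BLI) and a pulse-chase turnover-time bound.
- **LRC quantification**: Otsu threshold, 8-connected components, 150–5000 px
  (3–15 µm) particle filter, 340×200 µm sector sampling boxes, extrapolation
  to the limbal circumference, and cross-experiment LRC indices that sum to
  100% within each experiment.

Simulators: `generate_mosaic()` (geometric coherent-clone mosaics on lines
and rings), `simulate_ring()` / `hypothesis_experiment()` (reduced clone
number vs reduced mixing), `moran_drift()` (neutral drift on the ring),
`generate_cohort_timecourse()` (basal → suprabasal → shed labelled cohorts
with exact cell conservation), `generate_limbal_image()` (calibrated
synthetic whole-mount fields with ground truth).

## Worked example

Score a simulated 400-cell mosaic section and estimate the clone length:

```r
library(corneamosaic)
ms <- generate_mosaic(n_cells = 400, p = 0.5, clone_len_mean = 4, seed = 7)
extract_patches(ms)
#> <patch_summary> 400 cells, 52 patches (26 +, 26 -), p = 0.5000 (supplied)
#>   + patches: mean 5.500, median 5.0
#>   - patches: mean 9.885, median 6.0
```

A single ~400-cell section is a noisy estimator, so analyses pool eyes:

```r
est <- sapply(1:12, function(eye) {
  ms <- generate_mosaic(400, p = 0.5, clone_len_mean = 4, seed = 100 + eye)
  corrected_mean_patch_length(extract_patches(ms))
})
round(est, 2)
#>  [1] 4.16 3.62 3.28 2.90 4.12 3.82 5.06 3.54 3.08 2.93 4.46 3.07
mean(est)   # true clone length 4
#> [1] 3.67
```

Stripe counts correct the same way: 9 stripes observed at p = 0.48 on a
3.2 mm cornea,

```r
corrected_stripe_number(9, p = 0.48)          # labelled clone estimate
#> [1] 17.30769
stripes_per_mm(corrected_stripe_number(9, 0.48), pi * 3.2)
#> [1] 1.722
```

and a pulse-chase cohort gives labelling indices and a turnover bound:

```r
tc <- generate_cohort_timecourse(cohort_params(), times = c(1/6, 1, 3, 7, 14),
                                 seed = 1)
labelling_indices(tc[[2]])   # day 1
#>   region   BLI  SLI ASLI defined
#> 1      P 12.21 1.84 3.05    TRUE
#> 2      I  6.85 2.75 4.11    TRUE
#> 3      C 10.81 3.57 5.41    TRUE
#> 4  whole  9.88 2.73 4.24    TRUE
estimate_turnover_time(tc)
#> <turnover_estimate> turnover time <= 14 days (first time below 10% of the peak at day 3)
```

The BLI row says ~10% of basal cells are labelled a day after the pulse; the
ASLI column re-expresses suprabasal label on the basal denominator so
epithelia with different layer numbers are comparable.

## Analysis workflow

Numbered drivers under `analysis/` run the shipped studies end-to-end and
write their tables under `results/`:

1. `01_patch_statistics.R` — developmental patch statistics for a reference
   vs a finer-mixed group.
2. `02_stripe_hypotheses.R` — exact enumeration checks, clone-number
   proportionality, the reduced-clones vs reduced-mixing contrast, neutral
   drift.
3. `03_turnover_indices.R` — labelling indices over the chase, day-1
   suprabasal fractions, turnover time.
4. `04_lrc_quantification.R` — synthetic whole-mount imaging, detection,
   sampling boxes, LRC indices.

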