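# lsfgflow

Retinal and choroidal blood-flow quantification from laser speckle
flowgraphy (LSFG) composite maps, for paired-eye ophthalmic cohorts —
e.g. patients treated with ¹²⁵I-plaque brachytherapy for uveal melanoma,
where the fellow eye is each patient's internal control and reduced flow
is an early marker of radiation retinopathy.

LSFG reports a per-pixel **mean blur rate** (MBR, arbitrary units),
proportional to relative blood-flow velocity. `lsfgflow` implements:

- **Peripapillary analysis** — concentric annuli centered on the optic
  nerve head; Otsu histogram thresholding splits the outer band into
  superficial retinal-vessel pixels (mean MBR = **MV**) and choroidal
  tissue pixels (mean MBR = **MT**).
- **Whole-scan superpixel analysis** — SLIC segmentation (~1500
  superpixels, compactness 50) of the full frame, per-superpixel mean
  MBR, and the percent of superpixels in the flow ranges < 5, 5–10,
  10–15, 15–20 and ≥ 20 AU. `% ≥ 20` indexes retinal-vessel flow area,
  `% < 5` the lowest choroidal flow area.
- **Perfusion metrics** — MAP = DBP + (SBP − DBP)/3 and
  OPP = ⅔·MAP − IOP, per eye.
- **Cohort statistics** — three-scan averaging per eye, paired
  two-tailed t-tests (treated vs fellow eye), per-patient differences,
  OLS regressions of each measure on time from treatment, and a
  Spearman correlation matrix (two-tailed, significance at α = 0.01).
- **A synthetic paired-eye cohort generator** — vessel trees over a
  correlated choroidal background with a programmable irradiation
  effect, m(t) = max(m_min, 1 − k·t), so the whole pipeline is testable
  without patient data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted results
have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

Simulate a small cohort, analyze every scan, and fit the cohort
statistics:

```r
library(lsfgflow)

coh <- generate_cohort(8, effect = effect_model(choroid_corr_px = 10),
                       seed = 42, shape = c(120, 200), disc_radius = 15)
coh
#> <lsfg_cohort> 8 patients, 48 scans (synthetic)
#>   master seed: 42

res <- analyze_cohort(coh, n_superpixels = 400)
fit <- fit_cohort_stats(res$per_eye)
dplyr::select(fit$paired, measure, statistic, p_value, n_decreased)
#> # A tibble: 7 × 4
#>   measure   statistic  p_value n_decreased
#>   <chr>         <dbl>    <dbl>       <int>
#> 1 mv            -3.28 0.0135             8
#> 2 mt            -3.98 0.00533            8
#> 3 pct_ge20      -3.82 0.00653            7
#> 4 pct_lt5        1.75 0.123              0
#> 5 pct_5_10       6.64 0.000294           0
#> 6 pct_10_15     -3.72 0.00742            8
#> 7 pct_15_20     -6.79 0.000256           8
```

Reading: retinal-vessel flow (MV) and choroidal flow (MT) in the
peripapillary band are significantly lower in the treated eye (paired
t-test, p = 0.0135 and 0.0053), MV decreased in 8 of 8 patients, and the
superpixel retinal flow area (`pct_ge20`) is significantly reduced
(p = 0.0065). With only 8 patients the `% < 5` increase has not reached
significance here (p = 0.123); at the n = 25 study scale it does.

```r
glance(fit)
#> # A tibble: 1 × 5
#>   n_patients n_paired_sig strongest_time_corr_var strongest_time_corr_rho
#>        <dbl>        <int> <chr>                                     <dbl>
#> 1          8            6 pct_superpx_ge20                         -0.946

mean_arterial_pressure(136, 80)
#> [1] 98.66667
ocular_perfusion_pressure(mean_arterial_pressure(136, 80), 14.4)
#> [1] 51.37778
```

`run_pipeline(pipeline_config(...))` orchestrates the same steps end to
end (simulate or load a cohort from disk), writing tidy CSV tables,
figure PDFs and a manifest; `inst/cli/lsfg-superpix.R` is a thin
command-line wrapper around it. `read_scan()`/`write_scan()` support a
lossless headerless-CSV dialect and a 32-bit float TIFF dialect, and
`write_cohort()`/`read_cohort()` round-trip whole cohorts with a
documented metadata CSV.

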