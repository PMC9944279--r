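# aggsink

Biophysics of sinking phytoplankton aggregates ("lake/marine snow") and the
infection censuses of their fungal microparasites.

When diatom blooms collapse, cells coagulate into millimetre-scale
aggregates that sink at up to hundreds of meters per day and carry
particulate organic carbon (POC) to depth. Chytrid fungi — microparasites
that encyst on phytoplankton cells and grow epibiotic sporangia — change
that fate: infected cells are colonised by more bacteria, are enriched
inside aggregates, and form aggregates that respire faster and settle more
slowly. `aggsink` packages the complete analysis chain of such an
experiment for R users who work with roller-tank (rotating-cylinder)
aggregates, shadowgraph imaging, settling columns, and oxygen
microsensor incubations:

* **imaging** — the particle-quantification procedure: background
  flattening, red-minus-blue channel arithmetic for stained micrographs,
  inversion plus one global threshold, connected-component measurement
  (`A`, `ECD = 2√(A/π)`), size filters (3 µm for polymer particles,
  0.4 mm for aggregates), and count-to-concentration conversion;
* **spectra** — geometric size classes (each upper edge 1.3× the lower)
  with the number spectrum `n(d) = N(d)/Δd` and volume spectrum
  `nVd = n(d)·V_agg·Δd`, with the `log10(0) = −1.0` sentinel convention;
* **biophysics** — Stokes-law excess density `Δρ = 18 U ν/(g d²)`,
  porosity `φ = 1 − Δρ/ρ_s`, Reynolds number `Re = d U/ν`, drag
  coefficient `C_D = 24/Re + 6/(1+√Re) + 0.4`, density-gradient
  assignment of solid hydrated density, power-law settling fits
  `U = a·d^b`, and the three-dimensional fractal number `D₃ = b + 1`
  from the log–log slope of `U` on `d`;
* **respiration** — drift-corrected O₂ drawdown to carbon-specific
  respiration (`RQ = 1.2` mol O₂ : mol CO₂), the remineralization length
  scale `L = k/U` (% of POC respired per meter settled), and
  depth-resolved carbon-loss curves;
* **census_stats** — infection prevalence (early + mature + post infected
  over all five cell stages), aggregate-vs-ambient fold-enrichment,
  bacteria per aggregate, a Shapiro/F-test driven decision tree for
  pairwise tests (t / Welch / Mann–Whitney), Kruskal–Wallis with
  Bonferroni post hoc and compact-letter displays, and first-order
  Gaussian error propagation;
* **synthetic data** — seeded generators for every input above
  (populations, shadowgraph frames, stained RGB micrographs, settling
  trials, O₂ assays, stage-structured cell censuses) with the statistical
  structure the analysis assumes, so the full pipeline is testable
  without any raw data;
* **pipeline** — a configuration-driven orchestration
  (`run_config() |> run_pipeline() |> export_report()`) that simulates,
  images, detects, bins, fits, converts and compares two treatments and
  emits a per-treatment summary table.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fits, `autoplot()` for spectra and fits.

## Worked example

A mean non-infected aggregate (d = 2.4 mm) timed at 201 m d⁻¹:

```r
library(aggsink)

excess_density(u_m_d = 201, d_mm = 2.4)   # 0.8040685 mg cm^-3
porosity(0.6, 1.258)                      # 0.9995231
```

A twelve-aggregate synthetic settling experiment, from generation to the
fractal dimension:

```r
pop    <- generate_aggregate_population(population_params(
  n_aggregates = 12, size_dist = "log_uniform",
  d3_true = 2.37, velocity_noise_sd = 0.05, seed = 42))
trials <- generate_settling_trials(pop, seed = 42)

records <- tibble::tibble(
  d_mm  = pop$d_mm,
  u_m_d = settling_velocity(trials$time_s)) |>
  aggregate_biophysics(rho_s_g_cm3 = 1.284)

fractal_dimension(records)
#> # A tibble: 1 × 3
#>      d3     se     n
#>   <dbl>  <dbl> <int>
#> 1  2.28 0.0499    12

fit <- fit_power_law(records)
fit
#> Power-law fit (nonlinear_ls): u = 72.77 * d^1.203  (n = 12, se_b = 0.0732)

100 * remineralization_length(0.16, predict(fit, d = 2.4))
#> [1] 0.07666577   # % of POC respired per meter settled
```

The estimated `d3` of 2.28 ± 0.05 recovers the generating truth of 2.37
to within two standard errors at this sample size; the remineralization
length says a mean aggregate loses ~0.08% of its carbon per meter sunk.

The full two-treatment comparison in one call:

```r
report <- run_pipeline(run_config(seed = 1))
report           # Table-1-style per-treatment summaries + curve F-test
export_report(report, "out/")
```

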