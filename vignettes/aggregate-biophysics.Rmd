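---
title: "Methods: aggregate biophysics, respiration, and infection censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregate biophysics, respiration, and infection censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggsink)
```

## The system and the measurement chain

Diatom aggregates formed in rotating cylinders are measured along five
largely independent chains, and `aggsink` implements each as a composable
stage:

1. **Images to particles.** Back-lit shadowgraph frames (dark aggregates
   on a light background) or stained brightfield micrographs (RGB) are
   background-corrected, reduced to one channel, inverted, thresholded
   once globally, and measured as connected components. Each detection
   carries its cross-sectional area $A$ and equivalent circular diameter
   $ECD = 2\sqrt{A/\pi}$; spherical geometry gives the volume
   $V = (\pi/6)\,d^3$ with $d = ECD$.
2. **Particles to spectra.** Detections are counted into geometric size
   classes whose upper edge is 1.3× the lower edge (default anchor
   0.35 mm, eleven classes, so the smallest class is 0.35–0.455 mm and
   the largest upper edge 6.27 mm). The number spectrum is
   $n(d) = N(d)/\Delta d$ and the volume spectrum
   $nVd = n(d)\,V_{agg}\,\Delta d$, where $V_{agg}$ is the mean volume of
   the aggregates actually observed in the class — not the class
   midpoint — so that summing $nVd$ over classes returns exactly the
   cumulative aggregate volume concentration.
3. **Settling to structure.** Aggregates timed over a fixed settling
   distance (default 15 cm) yield $U$ in m d⁻¹ (1 cm s⁻¹ = 864 m d⁻¹).
   Stokes' law gives the excess density
   $\Delta\rho = 18\,U\nu/(g\,d^2)$; combined with the solid hydrated
   density $\rho_s$ from a density gradient it gives the porosity
   $\varphi = 1 - \Delta\rho/\rho_s$ (the aggregate volume cancels
   algebraically). $Re = dU/\nu$ and
   $C_D = 24/Re + 6/(1+\sqrt{Re}) + 0.4$ are reported as descriptors.
   The three-dimensional fractal number follows from
   $U \sim d^{\,D_3 - 1}$: $D_3$ is one plus the slope of the
   log–log OLS regression of $U$ on $d$, with the slope's standard
   error attached.
4. **Oxygen to carbon.** Two-point O₂ concentrations in gas-tight vials,
   drift-corrected by aggregate-free controls, are converted to
   carbon-specific respiration $k$ (d⁻¹) with a respiratory quotient of
   1.2 mol O₂ per mol CO₂ and a carbon molar mass of 12.011 g mol⁻¹.
   The remineralization length scale is $L = k/U$ — the POC fraction
   respired per meter settled — and depth losses are $\min(Lz, 1)$
   (linear, the default, matching the "% m⁻¹" framing) or
   $1 - e^{-Lz}$ (exponential, provided because the functional form of a
   depth-integrated loss is not uniquely determined by $L$).
5. **Censuses to statistics.** Host cells are scored in five stages
   (non-, early-, maturely-, post-infected, decaying). Prevalence counts
   the three infected stages over all five; decaying cells dilute the
   denominator but never count as infected, since decay is not
   specifically an infection outcome. Enrichment is the
   aggregate-to-ambient prevalence ratio, kept unrounded until
   reporting. Pairwise comparisons run a fixed decision tree — Shapiro
   on each group, either rejection routing to Mann–Whitney, otherwise an
   F-test on variances routing to Welch or Student's t — two-sided at
   α = 0.05 throughout. Multi-group contrasts use Kruskal–Wallis with
   Bonferroni-corrected pairwise tests and a compact-letter display.

## Parameters that matter

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| kinematic viscosity ν | cm² s⁻¹ | 1.085 × 10⁻² | freshwater at 17 °C |
| gravitational acceleration g | cm s⁻² | 981 | standard |
| settling distance | cm | 15 | settling-column timing span |
| respiratory quotient | mol O₂/mol CO₂ | 1.2 | aerobic degradation of mixed organic matter |
| vial volume | mL | 5.9 | gas-tight Exetainer |
| incubation duration | h | 24 | dark incubation at culture temperature |
| size-class ratio | — | 1.3 | geometric classes, upper edge 1.3× lower |
| class anchor | mm | 0.35 | smallest aggregate class 0.35–0.46 mm |
| aggregate ECD cutoff | mm | 0.4 | detections below are excluded (closed bound at the cutoff: a particle exactly at it is kept) |
| polymer-particle ECD cutoff | µm | 3 | micrograph resolution limit |
| cells per aggregate | — | 20 000 | census scaling assumption |
| α | — | 0.05 | two-sided significance level |

Internally all Stokes computations run in cgs; mm and m d⁻¹ are accepted
at the boundaries and converted explicitly (1 mm = 0.1 cm; 1 cm s⁻¹ =
864 m d⁻¹). Excess densities are reported in mg cm⁻³ while solid
hydrated densities arrive in g cm⁻³; `porosity()` applies the mg→g
conversion itself so user code never mixes the two scales.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes:

* **Populations.** Diameters come from a truncated power law (steep
  number spectra, as in tank populations) or log-uniform draws
  (individually picked, similar-sized aggregates, as in the
  single-aggregate characterization sets — the pipeline demo uses this).
  Velocities follow $U = a\,d^{D_3-1}\varepsilon$ with multiplicative
  lognormal noise $\varepsilon$: noise that is symmetric in log space is
  the natural error model for an estimator defined on log-transformed
  data, and it keeps $U > 0$. Each aggregate's recorded ground truth is
  Stokes-consistent: $\Delta\rho$ from its realized $(U, d)$, porosity
  from $\Delta\rho$ and the treatment's $\rho_s$, and POC proportional
  to the *solid* volume $V(1-\varphi)$ — at porosities ≳0.999, scaling
  carbon with total volume would be physically meaningless. A
  consequence worth knowing: POC then scales as $d^{D_3}$, so the
  largest aggregates carry tens of µg C. The pipeline demo therefore
  incubates in 20 mL vials — sized so the largest aggregate cannot
  exhaust the vial's oxygen inventory in 24 h — while the assay
  generator's own default stays at the 5.9 mL Exetainer.
* **Respiration.** Between-aggregate variability of the carbon-specific
  rate is mean-preserving lognormal (`resp_rate_cv`, log-scale sd). The
  demo uses 0.45 (non-infected) and 0.25 (infected), matching the
  reported sd/mean ratios of the two treatments; the generator default
  is 0 so that forward–inverse tests recover rates to machine precision.
* **Scenes.** Shadowgraph frames are rasterized discs — a pixel belongs
  to a blob iff its center lies inside the disc — dark on a light
  background, with optional linear illumination ramps and Gaussian pixel
  noise. Stained micrographs render polymer blobs blue-dominant, cell
  bodies red-dominant, and the background mildly warm, so red-minus-blue
  channel subtraction zeroes the polymer against an elevated background
  and removes cells, exactly as the detection chain expects.
* **Censuses.** `aggregate_enrichment` is defined as the prevalence
  fold-enrichment: infected-stage fractions are scaled by the factor and
  the non-infected+decaying fractions absorb the complement
  proportionally. The downstream `enrichment()` ratio therefore recovers
  the parameter in expectation, and an infeasible factor (enrichment ×
  prevalence > 1) is rejected rather than silently renormalized.
  Bacterial loads per cell are negative-binomial with stage-specific
  means (defaults 6.5/9.9/9.6/16.1/24.2 from non-infected through
  decaying) and a common dispersion (size 4, chosen so the per-cell
  distributions are about as wide as observed).

What the generators do **not** emulate: overlapping or touching
aggregates, out-of-focus optics and motion blur, non-spherical and
porous-textured particle silhouettes, fluorescence channels, spatial
correlation of noise, and cell-associated (as opposed to free) polymer
particles. Passing tests therefore demonstrate the correctness of the
measurement chain on data satisfying its assumptions, not detection
performance on difficult real imagery.

## Numerical choices

* **Thresholding.** The image is reversed (`max(image) − image`) and one
  global threshold applied; Otsu (over the image's own intensity range,
  making the mask invariant to adding a constant) is the default, a
  fixed value the regression-test override. A single-valued image is an
  explicit error under Otsu, never a silently empty mask. On noisy
  frames where blobs occupy a small fraction of pixels, the broad
  background mode can dominate Otsu's histogram; an optional light
  Gaussian denoise (`denoise_sigma`, default 0) applied before
  inversion stabilises the threshold while keeping clean scenes
  pixel-exact under the default.
* **Background flattening** estimates the illumination field with a
  large-σ Gaussian blur (default max(dim)/8, capped so the ~6σ kernel
  fits the frame) under *replicate* boundary conditions — a circular
  boundary would wrap an illumination ramp around the frame — then
  subtracts it and restores the original mean.
* **Component labeling** is a two-pass union-find supporting both 4- and
  8-connectivity (8 is the default; border-touching particles are kept
  unless `exclude_border`). Centroids are means of pixel centers.
* **Binning** uses lower-closed, upper-open intervals with widths from
  exact edges, never from rounded labels; detections outside the grid
  are counted and reported, not dropped. `log10(0)` maps to the −1.0
  sentinel so empty classes stay plottable.
* **Fits.** $D_3$ always comes from log–log OLS. The display fit of
  $U(d)$ defaults to nonlinear least squares (Levenberg–Marquardt,
  initialized from the log fit) because absolute velocity residuals are
  the natural loss for prediction; both routes are selectable. The
  two-treatment curve comparison is an extra-sum-of-squares F-test of a
  pooled single curve against separate curves, in log space by default
  so it matches the OLS framework; with two parameters per curve the
  test has df₁ = 2 and df₂ = n − 4.
* **Compact letters** use the insert-and-absorb algorithm on
  group-mean order; groups sharing any letter are not significantly
  different after Bonferroni correction.
* **Degenerate inputs.** Identical zero-variance samples yield a
  declared "degenerate" comparison with no p-value; corrected O₂ rates
  below zero are clipped to zero with a warning; an item settling below
  the densest gradient layer raises an "exceeds gradient" error;
  drawdown beyond the vial's oxygen inventory is an anoxia error.
* **Seeds.** Every generator is a pure function of (parameters, seed);
  the pipeline fans one global seed out to per-stage child seeds keyed
  by stage and treatment name, so adding a stage never perturbs the
  streams of existing ones.

## Problem sizes used by the test suite

The suite exercises the chain at sizes chosen to finish in well under a
minute per file: populations of 200 aggregates for estimator-recovery
checks (±0.15 on $D_3$ at velocity noise 0.1, three seeds per exponent),
12-aggregate scenes at 250² px for detection recall/precision, 1000
random populations for spectrum conservation, 1000 simulated null pairs
(n = 20 each) for the decision tree's type-I error, 10⁵-cell censuses
for law-of-large-numbers checks, and exhaustive Mann–Whitney enumeration
at n ≤ 8 per group.

## Known limitations

* Stokes' law is applied outside its strict $Re \ll 1$ regime, as is
  standard for ballasted phytoplankton aggregates; $Re$ and $C_D$ are
  reported so users can judge each aggregate.
* Means of nonlinear per-aggregate descriptors ($Re$, $C_D$) are
  computed per aggregate and then averaged; they cannot be reproduced
  from mean inputs.
* The imaging stage measures geometry only; infection-stage
  classification from images is out of scope (done visually in
  practice), as is any time-series (GLMM) modelling of culture
  dynamics, and no spectral slope is fitted to $n(d)$.
* The linear depth-loss mode caps at 1 by construction; for
  $Lz \gtrsim 0.3$ the linear and exponential modes diverge noticeably
  and the choice should be stated with any reported depth loss.
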