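---
title: "From impedance spectra to barrier constants: the models behind ecisbarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From impedance spectra to barrier constants: the models behind ecisbarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecisbarrier)
```

## The measurement and the model

Electric cell-substrate impedance sensing (ECIS) grows a cell monolayer
on small gold-film electrodes and measures the complex impedance
$Z(f)$ that the covered electrode opposes to a weak AC current across a
range of frequencies. Because the current in solution is carried by
ions, the part of the impedance contributed by the intercellular
junctions is a direct electrical readout of paracellular permeability.

The package implements the classical cell-covered electrode model of Lo,
Ferrier and Giaever, in which the spectrum of the covered electrode is
fully determined by the measured cell-free (naked) electrode impedance
$Z_n(f)$ and three microscopic constants:

* $\alpha$ (Ω$^{1/2}$·cm) — the cell–substrate constriction parameter,
  $\alpha = r_c\sqrt{\rho/h}$ for cell radius $r_c$, medium resistivity
  $\rho$ and cell–substrate separation $h$. It governs how hard it is
  for current to spread radially in the thin channel beneath each cell.
* $R_b$ (Ω·cm²) — the barrier resistance of the cell–cell junctions,
  the quantity of biological interest.
* $C_m$ (µF/cm²) — the membrane capacitance. Current that does not pass
  the junctions must couple capacitively through the basal and apical
  membranes in series.

With $Z_m(f) = 1/(j\pi f C_m)$ (two identical membranes of capacitance
$C_m$ in series, see "Conventions" below) and
$\gamma = \alpha\sqrt{1/Z_n + 1/Z_m}$ (principal root), the model reads

$$
\frac{1}{Z_c} \;=\; \frac{1}{Z_n}\left[
\frac{Z_n}{Z_n+Z_m} \;+\;
\frac{Z_m/(Z_n+Z_m)}{\dfrac{\gamma}{2}\dfrac{I_0(\gamma)}{I_1(\gamma)}
 + R_b\!\left(\dfrac{1}{Z_n}+\dfrac{1}{Z_m}\right)}\right],
$$

where $I_0, I_1$ are modified Bessel functions of complex argument.
Two limits anchor the implementation and are enforced by tests:
$\alpha = R_b = 0$ gives $Z_c = Z_n$ exactly (no cell layer), and
$R_b \to \infty$ gives $Z_c \to Z_n + Z_m$ (all current through the
membranes). The approach to the second limit carries a finite-$R_b$
correction of order $|Z_m|/R_b$, so it is only meaningful where
$|Z_m|$ is not too large (in practice above a few hundred Hz for
physiological $C_m$). At finite $R_b$ the constriction term can push
$|Z_c|$ slightly *above* $|Z_n + Z_m|$; the membrane "ceiling" is an
asymptote, not a uniform bound.

`bessel_ratio()` evaluates $I_0(\gamma)/I_1(\gamma)$ with the continued
fraction derived from the three-term recurrence of $I_\nu$, iterated
backwards. This is accurate to machine precision over the whole domain
the fit visits, including arguments near $\arg z = \pi/2$ where a naive
power-series summation loses all significance to cancellation. The
test suite checks it against a frozen 40-digit arbitrary-precision
table and against an independent power series where that series is
stable; $\alpha = 0$ uses the analytic limit
$(\gamma/2)\,I_0/I_1 \to 1$ rather than evaluating at 0.

## Fitting

`fit_monolayer()` estimates $(\alpha, R_b, C_m)$ from one cell-covered
scan and one cell-free reference scan of the same array:

* Scans are converted to *specific* impedance (Ω·cm²) using the
  electrode area. The default geometry is the "8W10E" layout — ten
  250 µm circular electrodes, $4.91\times10^{-3}$ cm² in total — and is
  configurable, since array documentation rarely states the effective
  area.
* The reference is used *as measured*: it is windowed, interpolated
  onto the cell scan's grid (linearly in log-frequency, real and
  imaginary parts independently, no extrapolation) and inserted into
  the model. It is not itself modelled.
* Fits minimise the per-frequency **relative** complex residual
  $\sum_f |Z_\mathrm{model}(f) - Z_\mathrm{meas}(f)|^2 / |Z_\mathrm{meas}(f)|^2$.
  Relative weighting balances the three decades of $|Z|$ a scan spans
  and is the maximum-likelihood choice under the multiplicative noise
  observed on such instruments; absolute weighting is available as an
  option.
* Parameters are optimised in log space under box bounds
  (Levenberg–Marquardt via `minpack.lm`), from one heuristic start
  ($C_m = 2$ µF/cm², $R_b$ from the low-frequency real-part excess,
  $\alpha$ from the mid-frequency amplification) plus eight log-uniform
  random starts drawn deterministically from `fit_options(seed=)`.
  The best run wins (lowest rms; ties towards lower $R_b$). Fits are
  bit-reproducible given identical inputs and seed.
* Pre- and post-stimulation scans of one electrode are fitted
  independently, with no parameter sharing.

The log-space lower bounds ($10^{-6}$ for $\alpha$ and $R_b$) stand in
for zero; a fit of a cell-free scan against itself lands on them.

Three QC flags summarise fit health: `LOW_BARRIER` ($R_b$ below
0.2 Ω·cm², junctions effectively open — the regime reached by cadherin
depletion, where the model remains valid only as long as $\alpha$ is
still recovered), `POOR_FIT` (rms relative residual above 0.05) and
`UNSTABLE_CM` (curvature-based ~95% interval for $C_m$ spanning more
than a decade). With only nine windowed frequencies the $C_m$ interval
rarely spans a decade, so `UNSTABLE_CM` fires rarely even in the
depleted-junction regime where $C_m$ estimates are most variable.

### The frequency window

All fits are restricted to **62.5 Hz – 16000 Hz**, inclusive on both
ends. Recorded spectra carry a strong inductive artifact at higher
frequencies — the imaginary part of the recorded reference flips
positive inside the acquisition range — which the monolayer model
cannot represent. `window_sensitivity_study()` quantifies the
rationale on synthetic data: with the artifact present, windowed fits
move the recovered constants by well under 1% relative to the
artifact-free truth, while fits over the full 31.25 Hz – 64 kHz
acquisition grid are displaced by several percent to tens of percent.

## The synthetic data generator

No raw spectra ship with the package, so `synthetic-data` generates
every input the pipeline consumes, with known ground truth.

* **Reference electrode** — solution resistance in series with a
  constant-phase element,
  $Z(f) = R_{sol} + 1/(Q\,(j2\pi f)^\beta)$, defaults
  $R_{sol} = 1.5$ Ω·cm², $Q = 2\times10^{-5}$ s$^\beta$/(Ω·cm²),
  $\beta = 0.95$ — plausible values for small gold-film electrodes,
  invented for simulation.
* **Recording artifact** — every recorded spectrum additionally carries
  $Z_\mathrm{lead}(f) = j2\pi f L/(1 + (f_\mathrm{gate}/f)^8)$ with
  $L = 6\times10^{-6}$ H·cm² and $f_\mathrm{gate} = 24$ kHz. This is an
  empirical shape, not a circuit model: it reproduces the observed
  artifact structure (clean spectra through the analysis window, a
  steeply growing inductive component above it, with order-unity
  distortion and a sign flip of $\mathrm{Im}\,Z$ by the top of the
  acquisition grid). Lead traces differ between wells, so per-electrode
  lead inductances vary lognormally (CV 0.1).
* **Cell scans** — the monolayer model is applied to the artifact-free
  interface impedance; the lead artifact and multiplicative complex
  Gaussian noise (relative rms 1% by default, i.e. each quadrature
  $\sigma = 0.01/\sqrt2$) are added to the recording.
* **Scenarios** — baseline constants $\alpha = 6$, $R_b = 4$,
  $C_m = 1.8$ (invented plausible values), with per-experiment
  (CV 15%) and per-electrode (CV 5%) lognormal biological variation.
  Presets encode the effect directions of the studied perturbations as
  pre→post multipliers on the same electrode draw: stimulus-induced
  barrier tightening (×1.5, 8 experiments), Rap2 depletion (×2, 6),
  Rap1 depletion (×0.6, 8), combined depletion (×1, 4) and cadherin
  depletion ($R_b$ to 0.5% of baseline with $\alpha$ untouched and
  $C_m$ reduced, 4 experiments; the near-zero value is chosen well
  below the `LOW_BARRIER` threshold because the fitted-$R_b$ standard
  deviation at 1% noise is ≈0.07 Ω·cm² — the information limit of nine
  frequencies, not an optimiser deficiency).
* **Timecourses** — single-frequency (4000 Hz) traces with a logistic
  parameter transition after the stimulus (time constant 900 s).
* **qPCR** — knockdown to fraction $\phi$ shifts the target Ct by
  $-\log_2\phi$ cycles (noise sd 0.15 cycles); the housekeeping gene is
  unshifted, and an untreated reference sample is always included.
* **Images** — Voronoi mosaics of cells: channel A is a smooth ridge
  along the cell boundaries (junction marker), channel B mixes the same
  junctional component (weight $w$, the "junctionality") with per-cell
  sinusoidal transverse fibre patterns (weight $1-w$); both are
  blurred (σ = 1 px) and noised. The ground-truth junction mask is the
  ideal blurred junction channel above 30% of its unit peak.

Every generator is deterministic given its seed, restores the caller's
RNG state, and emits ground truth alongside the data, so the package's
validation surface is recovery against known truth. What the generator
does **not** emulate: cell micromotion, electrode drift, partial
coverage, temperature effects, non-Gaussian instrument noise, real
junction morphology or imaging point-spread functions. Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated stochastic model, not performance on any particular instrument's
data.

## Replicate structure and statistics

The studied designs measure four electrodes per array within an
experiment and repeat experiments independently. All statistics
therefore operate on **per-experiment means** of electrodes
(`aggregate_electrodes()`), mirroring how such data are plotted (one
dot per experiment):

* `anova_oneway()` — classical one-way fixed-effects ANOVA across
  conditions, reported in the compact annotation `A(F;P)`. Exact zero
  within-group variance with differing means is reported as
  $F = \infty$ with a below-machine-precision marker rather than a
  numerical overflow.
* `ttest()` — two-tailed Student's t-test, paired for pre/post
  comparisons within experiments, pooled-variance unpaired for
  between-group comparisons ("Student's" is taken literally: the
  pooled form is the default, Welch's correction an option).
* `ddct()` — relative qPCR quantification:
  $\Delta C_t$ against the housekeeping gene, $\Delta\Delta C_t$
  against the shared reference sample, fold change $2^{-\Delta\Delta C_t}$.
  The construction makes results exactly invariant to per-sample Ct
  offsets.

No multiple-testing correction is applied anywhere — a deliberate
mirror of the analysis conventions this pipeline reproduces, and a
documented limitation rather than a silent addition.

## Junctional colocalization

`correlation_coefficient()` quantifies how much F-actin coincides with
the junction marker. Both channels are segmented by threshold (Otsu by
default; fixed thresholds available) and the default score is the
Pearson correlation of the two binary masks over all pixels — for
binary data this equals the phi coefficient of the 2×2 pixel
contingency table (0 = random, 1 = perfect overlap). Whether
plugin-style analyses of this kind correlated masks or masked
intensities is generally not documented, so an intensity variant
(Pearson of raw intensities on the union mask) is provided; when the
two disagree by more than 0.1 the alternative value is attached to the
result. Edge pixels are included and no background subtraction is
applied. `batch_cc()` averages the score over an experiment's images
(classically five fields of view) and feeds the replicate statistics.

## Numerical choices and degenerate inputs

* Time convention $e^{+j\omega t}$: capacitive impedance has negative
  imaginary part. Instrument exports with the opposite sign must be
  conjugated on import.
* $C_m$ convention: $C_m$ is the capacitance of **one** membrane; the
  two-membranes-in-series impedance is $1/(j\pi f C_m)$. The
  alternative convention (treating $C_m$ as the series value) rescales
  fitted $C_m$ by exactly 2; the convention used is recorded in every
  `fit_result` and in pipeline provenance so results remain comparable.
* Square-root branch: $\gamma$ uses the principal root; with
  $\mathrm{Re}(1/Z_n + 1/Z_m) > 0$ in all physical cases this keeps
  $\mathrm{Re}\,\gamma > 0$, inside the Bessel kernel's domain.
* Windowing keeps both bounds inclusively; fewer than four surviving
  frequencies is an error (three free parameters).
* Degenerate statistics (zero-variance differences, constant images,
  empty or full masks) return explicit markers or errors naming the
  offending input, never silent NAs.
* Multi-start fitting stops early only when a start reaches an
  essentially exact fit (rms $< 10^{-12}$), which cannot change the
  selected optimum.

## Problem sizes

The shipped validation suite works at deliberately modest scale: the
12-frequency doubling acquisition grid (nine frequencies in-window), a
3×3×3 noiseless recovery grid, 50 Monte-Carlo noise draws, eight
lead-draw replicates for the window study, scenario bundles of 4–8
experiments × 4 electrodes (100 electrodes for the open-junction
flag-rate study), 256×256 images with 25 cells, and six qPCR
replicates. These sizes give stable summary statistics for every check
while keeping a full run in the low minutes on one core; all of them
are function arguments and scale up freely.

## Known limitations

* The model assumes a confluent monolayer; with $R_b$ near zero the
  analysis approaches its validity limit and only the preserved
  $\alpha$ certifies the fit (the `LOW_BARRIER` flag marks this
  regime). Near that limit the fitted-$R_b$ noise floor
  (≈0.07 Ω·cm² at 1% spectral noise on nine frequencies) is an
  information limit: individual electrodes will occasionally exceed a
  fixed flag threshold no matter the optimiser.
* At the low end of the constriction range (α ≲ 3 together with a
  large $R_b$) the constriction signature in the spectrum is weak:
  for some noise realisations the maximum-likelihood fit drives α
  toward zero with a compensating inflation of $R_b$ by ~10%.
  Truth-started optimisation converges to the same point, i.e. this is
  a property of the likelihood surface at nine frequencies and 1%
  noise, not of the optimiser; it appears as occasional outliers in
  Monte-Carlo recovery summaries.
* Single-layer model only: no transcellular/paracellular separation,
  no micromotion analysis, no wound-healing assays.
* Curvature-based confidence intervals are local approximations; no
  profile likelihoods.
* The vendor software's exact objective, $C_m$ convention and possible
  parameter sharing across scans are undocumented; this implementation
  makes its own documented choices (relative residuals, single-membrane
  $C_m$, independent pre/post fits), so absolute fitted values need not
  coincide with vendor output even on identical data.
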