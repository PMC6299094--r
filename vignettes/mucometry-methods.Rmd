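---
title: "Models and estimators in mucometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in mucometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucometry)
```

mucometry implements the measurement pipeline of a mucociliary-function and
lung-fibrosis study: passive microbead rheology of mucus, functional metrics
from micro-OCT B-scan time series, second-harmonic-generation collagen
quantification with histogram statistics and stereology, and the surrounding
plate/count assays. This vignette records the models, the
operationalizations chosen where the underlying protocols say only
"measured directly", the tunable parameters with their defaults, and what
the synthetic-data generators do and do not emulate.

## Microrheology

### Model

A bead embedded in mucus performs thermally driven motion whose per-axis
increments are stationary Gaussian. The package's generative null is

$$\mathrm{E}\,\Delta r^2(\tau) = 4\,D\,(\tau\,\Delta t)^{\alpha},$$

with $\alpha = 1$ ordinary Brownian motion (apparent diffusivity $D$,
µm²/s) and $\alpha \in (0,1)$ subdiffusion in a viscoelastic medium,
generated as fractional Gaussian increments with Hurst index $\alpha/2$
(Cholesky factorization of the exact Toeplitz covariance). The protocols
this emulates never state a generative model for mucus; fractional Gaussian
motion is the standard passive-microrheology null. $\alpha = 2$ is the
perfectly persistent (ballistic) limit, generated with one velocity draw
per bead. Optional linear drift adds $v\,\Delta t$ per frame; localization
noise adds i.i.d. Gaussian jitter of sd $\sigma_{loc}$ to every stored
coordinate.

### Estimators

`compute_msd()` is the overlapping-window time average at integer frame
lags,

$$\Delta r^2(\tau) = \frac{1}{N-\tau}\sum_{i=1}^{N-\tau}
  \bigl(x(t_i{+}\tau)-x(t_i)\bigr)^2 + \bigl(y(t_i{+}\tau)-y(t_i)\bigr)^2,$$

exactly — the unit tests assert equality with a brute-force double loop to
1e-12 relative. `n_terms(tau) = N - tau` always. The default `max_lag` is
$N/4$: the estimator is unbiased at all lags but its variance grows with
$\tau/(N-\tau)$, and $N/4$ is the field's customary stopping point.

`ensemble_msd()` averages per-bead curves with equal weight per bead
(default). The acquisition protocol computes a curve "for each bead" but
does not say how curves combine; equal weighting treats beads as the
replicate unit. `weighting = "pooled"` weights beads by their `n_terms`
instead.

`correct_linear_drift()` estimates drift as the per-axis least-squares
slope of the ensemble-mean position against time and subtracts it from
every trajectory; on noiseless drifted data the estimate is exact to
numerical precision, and the correction is idempotent.

`fit_scaling()` fits a line on log lag (s) vs log MSD: the slope is
$\hat\alpha$ and $\exp(\text{intercept})/4$ is $\hat D$. A stationary bead
observed with localization noise has a flat MSD floor of
$4\sigma_{loc}^2$; choose `fit_range` to start above the lag where the
true MSD clears roughly ten times that floor. This is documented, not
auto-detected.

### Detection and linking

`detect_and_link()` finds spots as local maxima above an intensity
percentile, refines them to sub-pixel centroids on a
background-subtracted window, and links frame to frame by greedy
nearest-neighbour assignment within `max_displacement` pixels per step,
tolerating gaps up to `memory` frames (gapped frames are filled by linear
interpolation so lag arithmetic stays uniform). Optimal (Hungarian)
assignment is deliberately not implemented: at fixture densities greedy
linking is equivalent and much simpler to reason about. Trajectories
shorter than `min_length` are dropped. The full chain — simulate, render,
detect, link, drift-correct, ensemble MSD, fit — recovers a planted
$D$ within 15% at 500 beads in the acceptance suite (looser than the
10% trajectory-level recovery because detection adds localization error).

## µOCT functional metrics

The phantom and the estimators share a geometry: frames are depth × lateral
images, top-left origin, depth increasing downward; the bright epithelial
surface is the deepest structure of interest, the periciliary layer (PCL)
sits immediately above it, the mucus layer above that, and air on top.
Total airway-surface-liquid (ASL) depth = mucus + PCL.

The source protocol measured depths "directly" (manual calipers on
images); the package has to operationalize this, and the choices are:

* **Epithelial surface** — the maximum-intensity row of the time-averaged
  depth profile.
* **Cilia-tip interface (PCL top)** — each row above the epithelium gets an
  oscillation score: the peak-to-median ratio of the column-averaged
  temporal power spectrum inside the physiological band (2–30 Hz). The PCL
  is the contiguous run of rows with score excess above `var_frac`
  (default 0.2) of the peak excess, ending at the epithelium. Earlier
  designs used raw or robust temporal variance; both fail in realistic
  phantoms — zero-clipped noise has depth-dependent dispersion, and mucus
  particulates sweeping the field inflate broadband variance — while the
  narrowband score isolates exactly the "oscillating reflectance" that
  defines the band.
* **Air–mucus interface (ASL top)** — the shallowest row whose mean
  intensity exceeds background by `intensity_frac` (default 0.15) of the
  background-to-epithelium range.

If no row passes a threshold the metric is flagged `"unmeasurable"`, never
fabricated.

`estimate_cbf()` mean-detrends each pixel of the ciliary band, applies a
Hann window, averages periodograms across pixels (Welch-style averaging in
space rather than time, preserving the full spectral resolution
frame_rate/n_frames), and reports the argmax frequency within 2–30 Hz. The
search band, window and averaging scheme are unstated in the source
protocol; they were chosen for the usual bias/variance balance and are
recorded in the output. A peak below `snr_threshold` (default 5) times the
median in-band power is flagged unmeasurable. The estimator is invariant
to affine intensity rescaling.

`build_kymograph()` max-projects, per frame, the band up to 50 µm above
the epithelial surface onto the lateral axis. `estimate_mct_rate()` finds
the streak orientation by maximizing the directional variance of the
binned projection over an angle grid (step 0.25°, range ±80°); the rate is
$\tan(\theta^*)\,dx/dt$. Orientation maximization was preferred to
per-streak tracing because it is deterministic, robust to streak crossings
and wrap-around, and testable against planted velocities; confidence is
the peak-to-median variance ratio over the grid (below 2 → unmeasurable,
as for an isotropic kymograph). Reversing the lateral axis negates the
estimate exactly.

Per-animal aggregation of multiple regions of interest uses the mean
(`muoct_metrics()` emits one row per ROI; the study driver averages per
animal before group testing), mirroring the per-mouse unit of analysis.
Whether the source used mean or median per mouse is not stated; mean is
the default and the choice is recorded here.

## SHG quantification and histogram statistics

`collagen_area_fraction()` is `100 * mean(image > threshold)`. The source
fixed acquisition settings but never states its segmentation threshold;
the default is Otsu's method with a fixed-threshold fallback (warning) on
degenerate images, and the method is an explicit argument so it lands in
any record that carries it. Volume normalization is multiplicative against
a cohort reference (`percent * volume / reference`, reference defaulting to
the cohort mean volume); the reciprocal convention is selectable. The
Cavalieri estimator is `thickness * sum(areas)`; point counting uses a
regular grid with a seed-randomized offset, which is what makes it
unbiased — on aligned periodic masks a single offset is deliberately
allowed to return 0 or 1, documenting the offset sensitivity.

`fit_gaussian_mixture_histogram()` fits, for $k = 1..\text{max\_peaks}$, a
sum of $k$ Gaussians to histogram bin counts by nonlinear least squares
minimizing $\chi^2 = \sum_j (o_j - f_j)^2 / \max(f_j, 1)$ (the floor keeps
near-empty bins from dominating). Numerical choices that matter:

* **Bins** — Freedman–Diaconis by default, floored at $3k_{max}+3$ bins so
  every candidate $k$ keeps at least one degree of freedom; FD alone
  collapses on strongly bimodal data because the IQR spans both modes.
* **Component width floor** — each sd is parameterized as
  `binwidth + exp(p)`: a "peak" narrower than one bin is bin noise, and
  allowing it lets the optimizer erase single-bin residuals with spikes.
* **Peak-count selection** — accept the smallest $k$ whose reduced
  $\chi^2$ is adequate (≤ 1.5, `adequacy`) or not improved by more than
  15% (`improvement`) by $k+1$. The adequacy stop is essential: with
  Poisson-like counts an extra component can always soak up more than 15%
  of a noise-level $\chi^2$, so the improvement rule alone over-selects.
  Fits are nested (the $k{+}1$ start includes the best $k$ solution), so
  the $\chi^2$ trace is non-increasing up to optimizer tolerance.

`rejection_region_test()` computes a two-sample t statistic (Welch by
default) and compares it with the upper-$\alpha$ critical value, using the
normal limit for df > 100 — which at $\alpha = 0.001$ gives the classical
rejection region $[3.09, \infty)$.

## Endpoint assays

* `standard_curve_concentration()` — least-squares line through ≥ 3
  standards; duplicates averaged before inversion; unknowns outside the
  calibrated range flagged as extrapolated rather than refused.
* `dtnb_rate()` — $A(t) = b + a(1 - e^{-kt})$, pseudo-first-order product
  formation under substrate excess. The source only says absorbance "was
  monitored over time"; the mono-exponential is this package's model
  choice. Flat series return $k = 0$ instead of failing; `nls` with
  heuristic starts, falling back to a Nelder-Mead grid over $\log k$.
* `linear_regime_viscosity()` — the linear regime is the leading run of
  the stress sweep within 10% (`tolerance`) of its running median
  (computed over at least 3 points), terminated only by a *sustained*
  departure: two consecutive out-of-tolerance points on the same side, or
  an out-of-tolerance final point. A single-point termination rule at 10%
  tolerance aborts on about 5% of ordinary 5%-noise sweeps; shear thinning
  is a sustained one-sided drop, and that is what the rule detects.
  $\eta^* = $ plateau modulus / angular frequency.
* `survival_chisq()` — Pearson $\chi^2$ on the groups × {died, survived}
  table without continuity correction; a warning is attached when any
  expected cell is below 1.
* `group_compare()` — Welch t (pooled optional), Mann–Whitney (exact when
  untied, with tie handling noted in the report), or one-way ANOVA with
  Holm–Šidák-adjusted pairwise Welch comparisons against a reference
  group. Identical groups return $F = 0,\ p = 1$ rather than NaN. All
  reports record method, parameters and group names.

## The synthetic world

The generators emulate the statistical structure the estimators assume, at
the acquisition settings the protocols state: 30 s bead movies at
60 frames/s (N = 1800), µOCT stacks at 100 frames/s with 256 lines/frame
(both overridable — the stated line rate and frame count are mutually
inconsistent, so frame rate is always an explicit parameter), 15
systematically sampled SHG fields per lung, duplicate plating, lavage arm
sizes of 12–13 animals.

Stated-world defaults chosen where neither protocol nor contract names a
value, with rationale:

* Bead diffusivity 0.25 µm²/s and drift ~0.05 µm/s — a 1 µm bead in
  mucus-like medium, drift small relative to diffusion as in a stabilized
  microscope.
* µOCT phantom intensities (epithelium 200, mucus 70, ciliary band 60 ± 40,
  particulates 150, noise up to 20% of the mucus signal) — ordered as
  reflectance images are, with the analyzers using only the ordering.
* Lavage counts negative-binomial with size 10. Overdispersion is real in
  lavage data but its magnitude is stated nowhere; size 10 is moderate
  overdispersion and is the value consistent with the contract's own
  power statement for the acute-clearance comparison (power > 80% at
  n = 12/13 for a 40% decrease). A Poisson switch gives the
  equidispersed limit.
* SHG fields are oriented thick segments, blurred and noised, with the
  closing fiber shortened so the truth mask lands on the target fraction
  within a fraction of a percentage point.

What the generators do **not** emulate — and hence what a green test does
not establish: optical physics (speckle statistics, coherence effects,
point-spread functions beyond an isotropic Gaussian), biological
within-animal correlation structure, instrument drift other than linear,
bead–bead hydrodynamic interactions, and real fibrillar-collagen texture.
Recovery on phantoms validates the estimators' arithmetic and their
stated operating envelopes, not their behaviour on adversarial real data.

## Reproducibility

Every stochastic function takes an explicit seed and restores the caller's
RNG state. The study driver fans a single master seed into per-stage child
seeds by the fixed rule `child = (seed * 7919 + 1000003 * k) mod (2^31-1)`,
so stages rerun independently yet bit-identically; reruns of
`run_study()` with the same configuration produce byte-identical reports.
Image stacks are serialized as plain-text frame matrices with a JSON
sidecar (pixel size, frame rate, seed, ground truth) — a text substitute
for multi-page TIFF chosen because no TIFF reader is available in the
target environment; tables are CSV with headers, reports JSON.

## Known limitations

* Greedy linking can swap labels when beads approach within one step
  bound; at fixture densities this is rare and perturbs the ensemble MSD
  negligibly, but dense fields need a proper assignment solver.
* The kymograph orientation search reports a single global velocity; it
  will average over spatially heterogeneous transport rather than flag it.
* The mixture fitter's peak count is a model-selection heuristic
  (adequacy + improvement thresholds); histograms with heavy tails or
  strong skew can legitimately support different counts under different
  bin rules.
* `estimate_cbf` assumes the beat is the dominant narrowband component of
  the band; strong periodic particulate traffic inside the PCL band could
  masquerade as a beat.
* The rejection-region test reports the classical one-sided large-df
  decision; it is a fidelity feature, not a recommendation to analyze
  pooled-image histograms as independent observations (pooling images
  across animals pseudoreplicates, which the study driver notes in its
  report).
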