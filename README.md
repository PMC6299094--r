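# mucometry

Quantitative image-analysis and assay computations for studies of
mucociliary function and lung fibrosis — the measurement side of mouse
models in which airway mucin (Muc5b) overexpression impairs mucociliary
clearance and worsens bleomycin-induced fibrosis, and mucolytic treatment
restores clearance. The package is aimed at lab analysts who have the raw
measurements (bead movies, B-scan time series, SHG micrographs, plate
reads, lavage counts) and want tested, scriptable implementations of the
standard quantitations, plus a synthetic-data module that generates every
input with known ground truth so the whole pipeline can be validated
end to end without instrument data.

## What it computes

**Microbead passive microrheology.** Beads embedded in mucus are tracked
(`detect_and_link()`), linear stage drift is removed
(`correct_linear_drift()`), and each bead's mean squared displacement is
the overlapping-window time average

    MSD(tau) = 1/(N - tau) * sum_{i=1}^{N-tau} [x(t_i+tau) - x(t_i)]^2 + [y(t_i+tau) - y(t_i)]^2

(`compute_msd()`, `ensemble_msd()`), with N = 1800 frames for the standard
30 s, 60 frames/s acquisition. `fit_scaling()` summarizes a curve as
`MSD = 4 D tau^alpha` (apparent diffusivity D, anomalous exponent alpha);
`msd_dose_response()` runs the ANOVA + Holm–Šidák comparison across
mucolytic dose groups.

**µOCT functional metrics.** From a B-scan time series:
airway-surface-liquid and periciliary-layer depths
(`measure_layer_depths()`), ciliary beat frequency by averaged Fourier
periodogram of the ciliary band (`estimate_cbf()`), and mucociliary
transport rate from the streak slope of a kymograph built over the 50 µm
band above the epithelium (`build_kymograph()`, `estimate_mct_rate()`).

**SHG collagen quantification and stereology.** Percent fibrillar-collagen
area per field (`collagen_area_fraction()`, Otsu or fixed threshold),
lung-volume normalization (`normalize_to_volume()`), Cavalieri volumes
(`cavalieri_volume()`), point counting (`point_count_fraction()`), least
chi-square Gaussian-mixture histogram fitting with peak-count selection
(`fit_gaussian_mixture_histogram()`), and the large-df rejection-region t
comparison with its 3.09 critical value at the 0.1% level
(`rejection_region_test()`).

**Endpoint assays.** Hydroxyproline standard-curve interpolation
(`standard_curve_concentration()`), DTNB reduction kinetics
(`dtnb_rate()`), acute endogenous clearance of lavage leukocytes
(`acute_endogenous_clearance()`), survival chi-square (`survival_chisq()`),
stress-sweep linear-regime complex viscosity
(`linear_regime_viscosity()`), viscosity-vs-molecular-mass regression
(`viscosity_mass_regression()`), and a shared group-comparison dispatcher
(`group_compare()`: Welch t, Mann–Whitney, ANOVA + Holm–Šidák).

**Synthetic data with ground truth.** `simulate_trajectories()` (Brownian
or fractional-Gaussian motion with drift and localization noise),
`render_bead_movie()`, `simulate_muoct_stack()`, `simulate_shg_field_set()`,
`simulate_plate_assay()`, `simulate_lavage_experiment()`,
`sample_fields_uniform()`. Every generator attaches the `ground_truth()`
it used; identical seeds reproduce identical output.

## Worked example

```r
library(mucometry)

# --- microrheology: 100 beads, 30 s at 60 frames/s, D = 0.25 um^2/s ---
ts  <- simulate_trajectories(n_beads = 100, n_frames = 1800, dt = 1/60,
                             diffusion_coeff = 0.25,
                             drift_velocity = c(0.05, -0.03), seed = 42)
dc  <- correct_linear_drift(ts)
fit <- fit_scaling(ensemble_msd(dc$trajectories), fit_range = c(2, 60))
fit$anomalous_exponent   # 1.004  (Brownian: alpha = 1)
fit$apparent_D           # 0.252  um^2/s (truth 0.25)

# --- muOCT phantom: ASL 25 um, PCL 7 um, CBF 8 Hz, MCT 40 um/s ---
st <- simulate_muoct_stack(asl_depth = 25, pcl_depth = 7, cbf = 8,
                           mct_rate = 40, frame_rate = 100, n_frames = 512,
                           lines_per_frame = 128, noise_sigma = 8, seed = 42)
muoct_metrics(st)
#>   roi_id asl_depth_um pcl_depth_um mucus_depth_um   cbf_hz mct_rate_um_s
#> 1   roi1           25            7             18 8.007812      39.89595
```

The MSD fit recovers the planted diffusivity within 1% and the depth,
beat-frequency and transport estimates land on the phantom truths (CBF to
the spectral resolution 100/512 ≈ 0.2 Hz, MCT within 0.3%).

A full synthetic study — generation, analysis, truth-vs-estimate table and
group statistics — runs with

```r
run_study(default_study_config(seed = 1, out_dir = "results/study"))
```

or from the command line:

```sh
Rscript inst/cli/mucometry.R study --seed 1 --out results/study
```

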