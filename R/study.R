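# Configuration-driven orchestration: generate a synthetic study, run every
# analysis stage, and emit a consolidated truth-vs-estimate report.
#
# A single master seed is fanned out to per-stage child seeds by the
# documented rule in child_seed(), so stages rerun independently yet
# reproducibly; a rerun with the same config is numerically identical.

#' Default study configuration
#'
#' Stage parameter blocks with the study's generator truths, estimator
#' settings and per-quantity recovery tolerances. Sizes are chosen to keep a
#' full run around a minute; truths mirror the mouse-study conditions
#' (Brownian beads at 60 frames/s, a 100 frames/s B-scan phantom, bimodal
#' collagen fractions, overdispersed lavage counts).
#'
#' @param seed master seed (fans out to per-stage child seeds)
#' @param out_dir output directory for artifacts; NULL = do not write
#' @return a nested config list (class `study_config`)
#' @export
default_study_config <- function(seed = 1L, out_dir = NULL) {
  structure(list(
    seed = assert_seed(seed),
    out_dir = out_dir,
    microrheology = list(
      n_beads = 80L, n_frames = 450L, dt = 1 / 60,
      diffusion_coeff = 0.25, anomalous_exponent = 1,
      drift_velocity = c(0.05, -0.03), localization_sigma = 0.01,
      fit_range = c(2L, 30L),
      tol_D = 0.15, tol_alpha = 0.1),
    muoct = list(
      asl_depth = 25, pcl_depth = 7, cbf = 8, mct_rate = 40,
      frame_rate = 100, n_frames = 400L, lines_per_frame = 96L,
      pixel_size = 1, noise_sigma = 8,
      tol_depth_px = 1, tol_mct_frac = 0.05),
    shg = list(
      n_images = 40L, control_fraction = 8, treated_fraction = 22,
      between_field_sd = 2, image_shape = c(96L, 96L),
      alpha = 0.001, tol_fraction_pp = 2),
    assays = list(
      curve_slope = 0.02, curve_intercept = 0.05, replicate_cv = 0.05,
      unknown_concentrations = c(5, 10, 20),
      dtnb_k_fast = 0.05, dtnb_k_slow = 0.01,
      lavage_sizes = c(vehicle = 12L, treated = 13L),
      lavage_means = c(vehicle = 100, treated = 60), dispersion = 10,
      deaths = c(vehicle = 4L, treated = 1L))
  ), class = "study_config")
}

stage_tests_significant <- function(report, alpha) {
  ps <- c(report$microrheology$dose_anova_p, report$muoct$tests$p,
          report$shg$rejection$t_p, report$assays$aec_p)
  any(ps < alpha, na.rm = TRUE)
}

#' Run the full synthetic study
#'
#' Executes synthetic generation and all analysis stages (microrheology,
#' B-scan functional metrics, SHG statistics, endpoint assays), producing a
#' truth-vs-estimate table and the stage test results. With
#' `config$out_dir` set, writes per-stage CSV artifacts and a JSON report.
#'
#' @param config a [default_study_config()] (possibly edited)
#' @return list (class `study_report`): `truth_vs_estimate` data.frame
#'   (quantity, truth, estimate, tolerance, recovered), per-stage results,
#'   `seed`, `version`
#' @export
run_study <- function(config = default_study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed
  tve <- list()
  add_tve <- function(quantity, truth, estimate, tol, relative = TRUE) {
    err <- if (relative) abs(estimate - truth) / abs(truth)
           else abs(estimate - truth)
    tve[[length(tve) + 1L]] <<- data.frame(
      quantity = quantity, truth = truth, estimate = estimate,
      tolerance = tol, recovered = is.finite(err) && err <= tol)
  }

  # -- microrheology ---------------------------------------------------------
  mc <- config$microrheology
  ts <- simulate_trajectories(mc$n_beads, mc$n_frames, mc$dt,
                              mc$diffusion_coeff, mc$anomalous_exponent,
                              mc$drift_velocity, mc$localization_sigma,
                              seed = child_seed(seed, 1L))
  dc <- correct_linear_drift(ts)
  ens <- ensemble_msd(dc$trajectories)
  fs <- fit_scaling(ens, fit_range = mc$fit_range)
  add_tve("diffusion_coeff_um2_s", mc$diffusion_coeff, fs$apparent_D, mc$tol_D)
  add_tve("anomalous_exponent", mc$anomalous_exponent, fs$anomalous_exponent,
          mc$tol_alpha, relative = FALSE)
  # dose response on per-replicate subsets at a reference lag (null split)
  beads <- unique(dc$trajectories$bead_id)
  splits <- split(beads, rep(1:4, length.out = length(beads)))
  reps <- lapply(splits, function(ids) {
    sub <- dc$trajectories[dc$trajectories$bead_id %in% ids, ]
    sub2 <- trajectory_set(sub, dt = mc$dt)
    vapply(split(ids, rep(1:2, length.out = length(ids))), function(ids2) {
      s3 <- trajectory_set(sub2[sub2$bead_id %in% ids2, ], dt = mc$dt)
      msd_at(ensemble_msd(s3), lag_s = 10 * mc$dt)
    }, numeric(1))
  })
  names(reps) <- paste0("split", seq_along(reps))
  dr <- msd_dose_response(reps)
  micro <- list(drift_estimate = dc$drift_estimate, fit = fs,
                dose_anova_p = dr$anova$p, msd = as.data.frame(ens))

  # -- muoct -----------------------------------------------------------------
  mo <- config$muoct
  stack <- simulate_muoct_stack(mo$asl_depth, mo$pcl_depth, mo$cbf, mo$mct_rate,
                                mo$frame_rate, mo$n_frames, mo$lines_per_frame,
                                mo$pixel_size, mo$noise_sigma,
                                seed = child_seed(seed, 2L))
  fm <- muoct_metrics(stack)
  add_tve("asl_depth_um", mo$asl_depth, fm$asl_depth_um,
          mo$tol_depth_px * mo$pixel_size, relative = FALSE)
  add_tve("pcl_depth_um", mo$pcl_depth, fm$pcl_depth_um,
          mo$tol_depth_px * mo$pixel_size, relative = FALSE)
  add_tve("cbf_hz", mo$cbf, fm$cbf_hz, mo$frame_rate / mo$n_frames,
          relative = FALSE)
  add_tve("mct_rate_um_s", mo$mct_rate, fm$mct_rate_um_s, mo$tol_mct_frac)
  muoct_res <- list(metrics = fm)

  # -- shg -------------------------------------------------------------------
  sh <- config$shg
  ctrl <- simulate_shg_field_set(sh$n_images, sh$control_fraction,
                                 between_field_sd = sh$between_field_sd,
                                 image_shape = sh$image_shape,
                                 seed = child_seed(seed, 3L))
  trt <- simulate_shg_field_set(sh$n_images, sh$treated_fraction,
                                between_field_sd = sh$between_field_sd,
                                image_shape = sh$image_shape,
                                seed = child_seed(seed, 4L))
  pa_ctrl <- vapply(ctrl$fields, collagen_area_fraction, numeric(1))
  pa_trt <- vapply(trt$fields, collagen_area_fraction, numeric(1))
  add_tve("collagen_fraction_control_pct", sh$control_fraction, mean(pa_ctrl),
          sh$tol_fraction_pp, relative = FALSE)
  add_tve("collagen_fraction_treated_pct", sh$treated_fraction, mean(pa_trt),
          sh$tol_fraction_pp, relative = FALSE)
  mixfit <- fit_gaussian_mixture_histogram(c(pa_ctrl, pa_trt), max_peaks = 3)
  rr <- rejection_region_test(pa_trt, pa_ctrl, alpha = sh$alpha)
  shg_res <- list(mixture = mixfit, rejection = rr,
                  percent_area = data.frame(
                    group = rep(c("control", "treated"), each = sh$n_images),
                    percent_area = c(pa_ctrl, pa_trt)),
                  note = paste("percent-area histograms pool images across",
                               "animals; image-level tests pseudoreplicate"))

  # -- assays ----------------------------------------------------------------
  asy <- config$assays
  plate <- simulate_plate_assay(asy$unknown_concentrations, asy$curve_slope,
                                asy$curve_intercept, asy$replicate_cv,
                                seed = child_seed(seed, 5L))
  stds <- stats::aggregate(absorbance ~ conc_true,
                           data = plate[plate$well_type == "standard", ], mean)
  names(stds) <- c("conc", "absorbance")
  unk <- plate[plate$well_type == "unknown", ]
  unk_m <- split(unk$absorbance, unk$sample_id)
  sc <- standard_curve_concentration(stds, unk_m)
  tt <- seq(0, 120, by = 2)
  fast <- dtnb_rate(tt, 0.02 + 0.5 * (1 - exp(-asy$dtnb_k_fast * tt)))
  slow <- dtnb_rate(tt, 0.02 + 0.5 * (1 - exp(-asy$dtnb_k_slow * tt)))
  lav <- simulate_lavage_experiment(asy$lavage_sizes, asy$lavage_means,
                                    asy$dispersion, asy$deaths,
                                    seed = child_seed(seed, 6L))
  veh <- lav$counts$total[lav$counts$group == "vehicle"]
  trtc <- lav$counts$total[lav$counts$group == "treated"]
  aec <- acute_endogenous_clearance(veh, trtc)
  surv <- survival_chisq(lav$survival$deaths, lav$survival$total)
  sweep_G <- c(rep(2, 6), 2 * (1 - 0.15 * seq_len(4)))
  lrv <- linear_regime_viscosity(seq_along(sweep_G), sweep_G, frequency = 1)
  vm <- viscosity_mass_regression(c(10, 20, 30, 40), c(2.1, 3.9, 6.2, 7.8))
  assays_res <- list(standard_curve = sc, dtnb_fast = fast, dtnb_slow = slow,
                     rate_ratio = kinetics_rate_ratio(fast, slow),
                     aec = aec, aec_p = aec$test$p, survival = surv,
                     viscosity = lrv, mass_regression = vm)
  conc_truth <- sort(asy$unknown_concentrations)
  conc_est <- sort(sc$concentrations$concentration)
  for (i in seq_along(conc_truth))
    add_tve(sprintf("hydroxyproline_conc_%d", i), conc_truth[i], conc_est[i], 0.10)

  report <- structure(list(
    truth_vs_estimate = do.call(rbind, tve),
    microrheology = micro, muoct = muoct_res, shg = shg_res,
    assays = assays_res, seed = seed,
    version = as.character(utils::packageVersion("mucometry"))),
    class = "study_report")

  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d, %d truth-vs-estimate rows (%d recovered)\n",
              x$seed, nrow(x$truth_vs_estimate), sum(x$truth_vs_estimate$recovered)))
  print(x$truth_vs_estimate, row.names = FALSE)
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$truth_vs_estimate,
                   file.path(out_dir, "truth_vs_estimate.csv"), row.names = FALSE)
  utils::write.csv(report$shg$percent_area,
                   file.path(out_dir, "shg_percent_area.csv"), row.names = FALSE)
  utils::write.csv(report$microrheology$msd,
                   file.path(out_dir, "ensemble_msd.csv"), row.names = FALSE)
  json <- list(
    seed = report$seed, version = report$version,
    truth_vs_estimate = report$truth_vs_estimate,
    drift_estimate = report$microrheology$drift_estimate,
    muoct_metrics = report$muoct$metrics,
    shg_n_peaks = report$shg$mixture$n_peaks,
    shg_rejection = report$shg$rejection[c("t_statistic", "critical_value", "decision")],
    assays = list(rate_ratio = report$assays$rate_ratio,
                  aec_percent_decrease = report$assays$aec$percent_decrease,
                  survival_chi2 = report$assays$survival$chi2,
                  complex_viscosity = report$assays$viscosity$complex_viscosity))
  jsonlite::write_json(json, file.path(out_dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Read a study configuration from JSON
#'
#' @param path JSON file with (a subset of) the [default_study_config()]
#'   fields; missing blocks keep their defaults
#' @return a `study_config`
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_study_config(seed = if (!is.null(raw$seed)) raw$seed else 1L,
                              out_dir = raw$out_dir)
  for (block in intersect(names(raw), c("microrheology", "muoct", "shg", "assays"))) {
    for (nm in names(raw[[block]])) cfg[[block]][[nm]] <- raw[[block]][[nm]]
  }
  cfg
}
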