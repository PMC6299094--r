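# Generators: trajectories, movies, B-scan phantoms, SHG fields, plates,
# lavage experiments, field sampling.

test_that("degenerate trajectory cases are exact", {
  still <- simulate_trajectories(3, 10, dt = 0.1, diffusion_coeff = 0, seed = 1)
  for (b in split_positions <- split(still, still$bead_id)) {
    expect_equal(b$x_um, rep(b$x_um[1], 10))
    expect_equal(b$y_um, rep(b$y_um[1], 10))
  }
  drift <- simulate_trajectories(1, 5, dt = 1, diffusion_coeff = 0,
                                 drift_velocity = c(1, 0), seed = 1)
  expect_equal(drift$x_um, 0:4)
  expect_equal(drift$y_um, rep(0, 5))
})

test_that("trajectory argument validation", {
  expect_error(simulate_trajectories(1, 1, 0.1, 1, seed = 1), "n_frames")
  expect_error(simulate_trajectories(1, 10, 0, 1, seed = 1), "dt")
  expect_error(simulate_trajectories(1, 10, 0.1, 1, anomalous_exponent = 0,
                                     seed = 1), "anomalous_exponent")
  expect_error(simulate_trajectories(1, 10, 0.1, 1, anomalous_exponent = 2.5,
                                     seed = 1), "anomalous_exponent")
  expect_error(simulate_trajectories(1, 10, 0.1, 1), "seed")
})

test_that("identical seeds reproduce identical output; different seeds differ", {
  a <- simulate_trajectories(5, 50, 1 / 60, 0.3, seed = 42)
  b <- simulate_trajectories(5, 50, 1 / 60, 0.3, seed = 42)
  c <- simulate_trajectories(5, 50, 1 / 60, 0.3, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$x_um, c$x_um))
  s1 <- simulate_muoct_stack(20, 6, 8, 30, n_frames = 8, lines_per_frame = 16,
                             noise_sigma = 5, seed = 9)
  s2 <- simulate_muoct_stack(20, 6, 8, 30, n_frames = 8, lines_per_frame = 16,
                             noise_sigma = 5, seed = 9)
  expect_identical(s1$frames, s2$frames)
})

test_that("Brownian increments have variance 2 D dt (3 SE at >= 1e5 increments)", {
  D <- 0.25; dt <- 1 / 60
  ts <- simulate_trajectories(200, 600, dt, D, seed = 5)
  inc <- unlist(lapply(split(ts, ts$bead_id),
                       function(b) diff(b$x_um)), use.names = FALSE)
  expect_gte(length(inc), 1e5)
  v <- mean(inc^2)
  se <- stats::sd(inc^2) / sqrt(length(inc))
  expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("ensemble MSD of 500 Brownian beads tracks 4 D tau dt within 5%", {
  D <- 0.25; dt <- 1 / 60
  ts <- simulate_trajectories(500, 1800, dt, D, seed = 11)
  ens <- ensemble_msd(ts, max_lag = 100)
  expect_true(all(abs(ens$msd_um2 - 4 * D * ens$lag_s) / (4 * D * ens$lag_s) < 0.05))
})

test_that("every generator attaches retrievable ground truth", {
  ts <- simulate_trajectories(2, 5, 0.1, 0.3, seed = 1)
  expect_s3_class(attr(ts, "ground_truth"), "ground_truth")
  expect_equal(attr(ts, "ground_truth")$diffusion_coeff, 0.3)
  st <- simulate_muoct_stack(20, 6, 8, 30, n_frames = 4, lines_per_frame = 16,
                             seed = 2)
  expect_equal(st$metadata$ground_truth$cbf, 8)
  fs <- simulate_shg_field_set(2, 15, seed = 3)
  expect_equal(fs$ground_truth$collagen_fraction, 15)
})

test_that("rendered movies place spots where the truth says", {
  side_px <- 33; ps <- 1
  centre <- c((side_px / 2) * ps, (side_px / 2) * ps)  # pixel 17 centre = 16.5 um
  ts <- simulate_trajectories(1, 5, 0.1, 0, seed = 1,
                              origins = matrix(centre, 1))
  mv <- render_bead_movie(ts, c(side_px, side_px), psf_sigma = 2,
                          peak_intensity = 50, background_noise_sigma = 0,
                          pixel_size = ps, seed = 1)
  for (t in 1:5) {
    expect_equal(which(mv$frames[t, , ] == max(mv$frames[t, , ]),
                       arr.ind = TRUE)[1, ], c(row = 17, col = 17))
  }
  # two beads >= 6 psf_sigma apart -> exactly two maxima above half peak
  # (positions on pixel centres so the noiseless spot has a unique maximum)
  ts2 <- simulate_trajectories(2, 3, 0.1, 0, seed = 1,
                               origins = rbind(c(7.5, 7.5), c(23.5, 23.5)))
  mv2 <- render_bead_movie(ts2, c(33, 33), psf_sigma = 2, peak_intensity = 50,
                           background_noise_sigma = 0, pixel_size = 1, seed = 1)
  img <- mv2$frames[1, , ]
  n_max <- sum(mucometry:::local_maxima(img) & img > 25)
  expect_identical(n_max, 2L)
})

test_that("out-of-frame positions are rejected with the offending bead named", {
  ts <- simulate_trajectories(1, 3, 0.1, 0, seed = 1,
                              origins = matrix(c(100, 5), 1))
  expect_error(render_bead_movie(ts, c(32, 32), 2, 50, 0, 1, seed = 1),
               "bead 1")
})

test_that("muoct phantom preconditions guard aliasing and layer order", {
  expect_error(simulate_muoct_stack(20, 6, cbf = 60, mct_rate = 0,
                                    frame_rate = 100, seed = 1), "Nyquist")
  expect_error(simulate_muoct_stack(5, 6, cbf = 8, mct_rate = 0, seed = 1),
               "asl_depth")
})

test_that("SHG field extremes and truth-mask calibration", {
  z <- simulate_shg_field_set(3, 0, noise_sigma = 0, seed = 1)
  expect_true(all(vapply(z$masks, function(m) !any(m), logical(1))))
  f <- simulate_shg_field_set(2, 100, noise_sigma = 0, seed = 1)
  expect_true(all(vapply(f$masks, all, logical(1))))
  m <- simulate_shg_field_set(20, 20, between_field_sd = 0, noise_sigma = 0,
                              seed = 2)
  expect_true(all(abs(m$true_fractions - 20) <= 1))
  expect_error(simulate_shg_field_set(1, 1, fiber_count = 50, fiber_width = 10,
                                      image_shape = c(16, 16), seed = 1),
               "infeasible")
})

test_that("plate assay is exactly linear at cv = 0 and calibrated at cv > 0", {
  p <- simulate_plate_assay(c(5, 10), 0.02, 0.05, replicate_cv = 0, seed = 1)
  expect_equal(p$absorbance, 0.05 + 0.02 * p$conc_true)
  dup <- split(p$absorbance, p$sample_id)
  expect_true(all(vapply(dup, function(v) diff(range(v)) == 0, logical(1))))
  big <- simulate_plate_assay(rep(10, 500), 0.02, 0.05, replicate_cv = 0.05,
                              seed = 2)
  wells <- big$absorbance[big$well_type == "unknown"]
  cv_hat <- stats::sd(wells) / mean(wells)
  expect_lt(abs(cv_hat - 0.05) / 0.05, 0.2)
})

test_that("lavage counts: negative binomial with Poisson limit; survival table", {
  lv <- simulate_lavage_experiment(c(a = 500, b = 500), c(100, 100),
                                   poisson = TRUE, seed = 3)
  x <- lv$counts$total
  expect_lt(abs(stats::var(x) / mean(x) - 1), 0.2)   # equidispersed limit
  nb <- simulate_lavage_experiment(c(a = 500), 100, dispersion = 5, seed = 4)
  expect_gt(stats::var(nb$counts$total) / mean(nb$counts$total), 5)
  expect_error(simulate_lavage_experiment(c(5, 5), c(10, 10), dispersion = 0,
                                          seed = 1), "dispersion")
  eq <- simulate_lavage_experiment(c(10, 10), c(50, 50), 5,
                                   deaths_per_group = c(3, 3), seed = 5)
  expect_equal(survival_chisq(eq$survival$deaths, eq$survival$total)$chi2, 0)
  expect_error(simulate_lavage_experiment(c(5), 10, 5, deaths_per_group = 6,
                                          seed = 1), "deaths")
})

test_that("systematic uniform random sampling of fields", {
  all60 <- sample_fields_uniform(c(6, 10), 60, seed = 1)
  expect_identical(sort(all60$index), 1:60)
  s <- sample_fields_uniform(c(6, 10), 15, seed = 2)
  expect_identical(unique(diff(s$index)), 4L)        # stride 60 / 15 = 4
  expect_false(any(duplicated(s$index)))
  expect_error(sample_fields_uniform(c(2, 3), 10, seed = 1), "exceeds")
  # inclusion probability 15/60 per position (4000 seeds; binomial noise at
  # 1000 seeds is ~1.4 pp, too close to the 3 pp band to assert reliably)
  hits <- integer(60)
  for (sd in 1:4000) {
    idx <- sample_fields_uniform(c(6, 10), 15, seed = sd)$index
    hits[idx] <- hits[idx] + 1L
  }
  expect_true(all(abs(hits / 4000 - 0.25) <= 0.03))
})

test_that("image stack text round trip preserves data and metadata", {
  st <- simulate_muoct_stack(20, 6, 8, 30, n_frames = 4, lines_per_frame = 16,
                             noise_sigma = 5, seed = 3)
  d <- withr::local_tempdir()
  write_image_stack(st, d)
  st2 <- read_image_stack(d)
  expect_lt(max(abs(st$frames - st2$frames)), 1e-10)
  expect_equal(st2$frame_rate, st$frame_rate)
  expect_equal(st2$metadata$ground_truth$cbf, 8)
})
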