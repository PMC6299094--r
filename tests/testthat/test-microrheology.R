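# MSD computation against closed forms and a brute-force oracle, drift
# correction, scaling fits, dose-response statistics.

brute_force_msd <- function(x, y, max_lag) {
  N <- length(x)
  vapply(seq_len(max_lag), function(tau) {
    s <- 0
    for (i in 1:(N - tau)) {
      s <- s + (x[i + tau] - x[i])^2 + (y[i + tau] - y[i])^2
    }
    s / (N - tau)
  }, numeric(1))
}

test_that("compute_msd closed forms: stationary and pure drift", {
  still <- data.frame(t_s = (0:19) * 0.1, x_um = rep(2, 20), y_um = rep(-1, 20))
  m <- compute_msd(still, max_lag = 10)
  expect_equal(m$msd_um2, rep(0, 10))
  drift <- data.frame(t_s = (0:49) * 0.1, x_um = (0:49) * 0.1, y_um = rep(0, 50))
  md <- compute_msd(drift, max_lag = 20)
  expect_equal(md$msd_um2, (0.1 * (1:20))^2)
  expect_equal(md$msd_um2[10], 1.0)
  expect_equal(md$n_terms, 50 - (1:20))
})

test_that("compute_msd matches the brute-force double loop exactly", {
  for (s in 1:20) {
    set.seed(s)
    x <- cumsum(rnorm(50)); y <- cumsum(rnorm(50))
    tr <- data.frame(t_s = (0:49) * 0.05, x_um = x, y_um = y)
    m <- compute_msd(tr, max_lag = 25)
    bf <- brute_force_msd(x, y, 25)
    expect_lt(max(abs(m$msd_um2 - bf) / bf), 1e-12)
  }
})

test_that("compute_msd input contracts", {
  tr <- data.frame(t_s = (0:9) * 0.1, x_um = rnorm(10), y_um = rnorm(10))
  expect_error(compute_msd(tr, max_lag = 10), "max_lag")
  bad <- data.frame(t_s = c(0, 0.1, 0.15, 0.4), x_um = 1:4, y_um = 1:4)
  expect_error(compute_msd(bad), "uniformly spaced")
  ts <- simulate_trajectories(3, 20, 0.1, 0.2, seed = 1)
  expect_error(compute_msd(ts), "single bead")
})

test_that("linear drift is estimated exactly on noiseless data and removal is idempotent", {
  ts <- simulate_trajectories(5, 100, dt = 0.5, diffusion_coeff = 0,
                              drift_velocity = c(2, -1), seed = 1,
                              origins = matrix(rnorm(10), 5))
  dc <- correct_linear_drift(ts)
  expect_lt(max(abs(dc$drift_estimate - c(2, -1))), 1e-6)
  for (b in split(as.data.frame(dc$trajectories), dc$trajectories$bead_id)) {
    expect_lt(diff(range(b$x_um)), 1e-9)
    expect_lt(diff(range(b$y_um)), 1e-9)
  }
  dc2 <- correct_linear_drift(dc$trajectories)
  expect_lt(max(abs(dc2$trajectories$x_um - dc$trajectories$x_um)), 1e-9)
  one <- trajectory_set(data.frame(bead_id = 1, frame = 1, t_s = 0,
                                   x_um = 0, y_um = 0), dt = 1)
  expect_error(correct_linear_drift(one), ">= 2 frames")
})

test_that("drift-free ensembles yield a null drift estimate", {
  ts <- simulate_trajectories(500, 200, 1 / 60, 0.25, seed = 7)
  dc <- correct_linear_drift(ts)
  # SE of the mean displacement rate ~ sqrt(2 D / T) / sqrt(n_beads * ...);
  # use the empirical slope SE from the per-frame ensemble means instead.
  mx <- tapply(ts$x_um, ts$t_s, mean)
  tt <- sort(unique(ts$t_s))
  se <- summary(stats::lm(mx ~ tt))$coefficients[2, 2]
  expect_lt(abs(dc$drift_estimate[1]), 3 * se * 3)  # generous 3x on the SE
})

test_that("drift correction removes the (v tau dt)^2 term from the ensemble MSD", {
  v <- 1; dt <- 0.1
  ts <- simulate_trajectories(200, 100, dt, 0.05, drift_velocity = c(v, 0),
                              seed = 8)
  before <- ensemble_msd(ts, max_lag = 50)
  after <- ensemble_msd(correct_linear_drift(ts)$trajectories, max_lag = 50)
  removed <- msd_at(before, 50 * dt) - msd_at(after, 50 * dt)
  expect_rel_equal(removed, (v * 50 * dt)^2, 0.15)
})

test_that("ensemble_msd: identical copies, weighting, and monotone dose response", {
  one <- simulate_trajectories(1, 60, 0.1, 0.2, seed = 2)
  df <- as.data.frame(one)
  three <- trajectory_set(rbind(df,
                                transform(df, bead_id = 2),
                                transform(df, bead_id = 3)), dt = 0.1)
  ens <- ensemble_msd(three, max_lag = 10)
  single <- compute_msd(df, max_lag = 10)
  expect_equal(ens$msd_um2, single$msd_um2)
  expect_equal(ens$sem, rep(0, 10))
  expect_equal(ens$n_beads, rep(3L, 10))
  # doubling D with the same seed scales every increment by sqrt(2):
  lo <- ensemble_msd(simulate_trajectories(50, 120, 0.1, 0.1, seed = 3))
  hi <- ensemble_msd(simulate_trajectories(50, 120, 0.1, 0.2, seed = 3))
  expect_true(all(hi$msd_um2 >= lo$msd_um2))
  expect_error(ensemble_msd(three, max_lag = 100), "longer than max_lag")
})

test_that("fit_scaling recovers exact power laws to 1e-9", {
  lags <- 1:40; dt <- 0.05
  exact <- msd_curve(data.frame(lag_frames = lags, lag_s = lags * dt,
                                msd_um2 = 4 * 0.1 * lags * dt,
                                n_terms = 100 - lags), dt = dt)
  f <- fit_scaling(exact)
  expect_equal(f$anomalous_exponent, 1, tolerance = 1e-9)
  expect_equal(f$apparent_D, 0.1, tolerance = 1e-9)
  ball <- msd_curve(data.frame(lag_frames = lags, lag_s = lags * dt,
                               msd_um2 = (2 * lags * dt)^2,
                               n_terms = 100 - lags), dt = dt)
  expect_equal(fit_scaling(ball)$anomalous_exponent, 2, tolerance = 1e-9)
  zero <- msd_curve(data.frame(lag_frames = 1:5, lag_s = (1:5) * dt,
                               msd_um2 = rep(0, 5), n_terms = 9:5), dt = dt)
  expect_error(fit_scaling(zero), "strictly positive")
})

test_that("subdiffusive exponent is recovered from fractional Gaussian motion", {
  ts <- simulate_trajectories(500, 200, 1 / 60, 0.1, anomalous_exponent = 0.5,
                              seed = 4)
  f <- fit_scaling(ensemble_msd(ts), fit_range = c(1, 25))
  expect_lt(abs(f$anomalous_exponent - 0.5), 0.1)
})

test_that("msd_dose_response: degenerate and hand-computed ANOVA", {
  same <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  r <- msd_dose_response(same)
  expect_equal(r$anova$F, 0)
  expect_equal(r$anova$p, 1)
  two <- msd_dose_response(list(vehicle = c(1, 2, 3), dose1 = c(4, 5, 6)))
  expect_equal(two$anova$F, 13.5)
  expect_equal(two$anova$df1, 1)
  expect_equal(two$anova$df2, 4)
  expect_error(msd_dose_response(list(a = 1, b = c(1, 2))), "replicates")
})

test_that("msd_dose_response accepts MSD curves and reads the reference lag", {
  curves <- lapply(1:3, function(i) {
    ts <- simulate_trajectories(10, 60, 0.1, 0.1, seed = i)
    ensemble_msd(ts)
  })
  r <- msd_dose_response(list(vehicle = curves[1:2], treated = curves[2:3]),
                         reference_lag = 0.5)
  expect_true(is.finite(r$anova$p))
  expect_identical(r$pairwise$group, "treated")
})
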