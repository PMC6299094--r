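# Standard curves, kinetics, clearance, survival, viscosity, regression,
# and the shared group-comparison dispatcher.

test_that("standard-curve interpolation inverts the generator exactly", {
  stds <- data.frame(conc = c(0, 5, 10, 20), absorbance = 0.05 + 0.02 * c(0, 5, 10, 20))
  r <- standard_curve_concentration(stds, 0.25)
  expect_equal(r$concentrations$concentration, 10)
  expect_equal(r$curve$r_squared, 1)
  # duplicates average before inversion
  r2 <- standard_curve_concentration(stds, list(s1 = c(0.24, 0.26)))
  expect_equal(r2$concentrations$concentration, 10)
  flat <- data.frame(conc = c(0, 5, 10), absorbance = rep(0.3, 3))
  expect_error(standard_curve_concentration(flat, 0.3), "degenerate")
  out <- standard_curve_concentration(stds, 2)  # far above calibration
  expect_true(out$concentrations$extrapolated)
})

test_that("noisy plates are recovered within 10% (median over 100 seeds)", {
  errs <- vapply(1:100, function(s) {
    p <- simulate_plate_assay(20, 0.02, 0.05, replicate_cv = 0.05, seed = s)
    stds <- stats::aggregate(absorbance ~ conc_true,
                             data = p[p$well_type == "standard", ], mean)
    names(stds) <- c("conc", "absorbance")
    unk <- p$absorbance[p$well_type == "unknown"]
    est <- standard_curve_concentration(stds, list(u = unk))
    abs(est$concentrations$concentration - 20) / 20
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("kinetics fit: exact, flat, and noisy recovery", {
  tt <- seq(0, 120, by = 2)
  exact <- dtnb_rate(tt, 0.02 + 0.5 * (1 - exp(-0.05 * tt)))
  expect_lt(abs(exact$rate_constant - 0.05), 1e-6)
  expect_lt(abs(exact$amplitude - 0.5), 1e-6)
  flat <- dtnb_rate(tt, rep(0.3, length(tt)))
  expect_equal(flat$rate_constant, 0)
  expect_equal(flat$amplitude, 0)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    y <- 0.02 + 0.5 * (1 - exp(-0.05 * seq(0, 118, by = 2))) +
      rnorm(60, sd = 0.01)
    abs(dtnb_rate(seq(0, 118, by = 2), y)$rate_constant - 0.05) / 0.05
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
  expect_error(dtnb_rate(1:3, 1:3), ">= 5")
})

test_that("rate ratio orders a fast agent above a slow one", {
  tt <- seq(0, 200, by = 4)
  fast <- dtnb_rate(tt, 0.02 + 0.5 * (1 - exp(-0.05 * tt)))
  slow <- dtnb_rate(tt, 0.02 + 0.5 * (1 - exp(-0.01 * tt)))
  expect_rel_equal(kinetics_rate_ratio(fast, slow), 5, 0.01)
})

test_that("acute endogenous clearance: percent decrease and flags", {
  r <- acute_endogenous_clearance(c(9, 10, 11), c(4, 5, 6))
  expect_equal(r$percent_decrease, 50)
  same <- acute_endogenous_clearance(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$percent_decrease, 0)
  expect_gt(same$test$p, 0.99)
  z <- acute_endogenous_clearance(c(0, 0), c(1, 2))
  expect_true(is.na(z$percent_decrease))
  expect_match(z$flag, "zero vehicle")
})

test_that("a planted 40% clearance is detected with power > 80% (200 seeds)", {
  hits <- vapply(1:200, function(s) {
    lv <- simulate_lavage_experiment(c(12L, 13L), c(100, 60), seed = s)
    veh <- lv$counts$total[lv$counts$group == "group1"]
    trt <- lv$counts$total[lv$counts$group == "group2"]
    acute_endogenous_clearance(veh, trt)$test$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.80)
})

test_that("survival chi-square matches hand computation and is order-invariant", {
  expect_equal(survival_chisq(c(5, 5), c(20, 20))$chi2, 0)
  r <- survival_chisq(c(10, 0), c(20, 20))
  expect_equal(r$chi2, 40 / 3)
  expect_equal(r$df, 1L)
  r2 <- survival_chisq(c(0, 10), c(20, 20))
  expect_equal(r2$chi2, r$chi2)
  expect_match(survival_chisq(c(1, 0), c(30, 30))$warning, "expected")
  expect_error(survival_chisq(c(5), c(10)), ">= 2 groups")
})

test_that("linear-regime viscosity: plateau detection and recovery", {
  expect_equal(linear_regime_viscosity(1:6, rep(2, 6), frequency = 1)$complex_viscosity, 2)
  sweep_G <- c(rep(2, 6), 1.6, 1.2, 0.9)
  r <- linear_regime_viscosity(seq_along(sweep_G), sweep_G, frequency = 1)
  expect_equal(r$complex_viscosity, 2)
  expect_identical(r$plateau_points, 1:6)
  thinning <- 2 * 0.8^(0:7)
  expect_error(linear_regime_viscosity(1:8, thinning, 1), "no linear regime")
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    G <- c(rep(2, 8) * (1 + rnorm(8, sd = 0.05)), 1.4, 1.0)
    abs(linear_regime_viscosity(1:10, G, 1)$complex_viscosity - 2) / 2
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("viscosity-mass regression: exact line, permutation separation, coverage", {
  x <- c(1, 2, 3, 4)
  r <- viscosity_mass_regression(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$r, 1)
  set.seed(3)
  exceed <- sum(vapply(1:500, function(i) {
    abs(viscosity_mass_regression(x, sample(2 * x + 1))$r) > r$r
  }, logical(1)))
  expect_identical(exceed, 0L)   # no shuffle beats the exact line
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    xx <- 1:10
    yy <- 3 * xx + rnorm(10)
    fit <- stats::lm(yy ~ xx)
    est <- viscosity_mass_regression(xx, yy)
    abs(est$slope - 3) <= 2 * summary(fit)$coefficients[2, 2]
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_error(viscosity_mass_regression(c(1, 1, 1), 1:3), "zero variance")
})

test_that("group_compare: identical groups are never significant", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_gte(group_compare(g, "welch_t")$p, 0.99)
  expect_gte(group_compare(g, "mann_whitney")$p, 0.99)
  expect_gte(group_compare(c(g, list(c = c(1, 2, 3))), "anova_holm_sidak")$p, 0.99)
})

test_that("Mann-Whitney exact p on fully separated triplets is 1/20", {
  r <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                     method = "mann_whitney", alternative = "less")
  expect_equal(unname(r$statistic), 0)   # U = 0
  expect_equal(r$p, 0.05)               # 1 of choose(6,3)=20 orderings
})

test_that("Holm-Sidak adjustment matches the hand formula on a small case", {
  p <- c(0.01, 0.04, 0.03)
  adj <- p_adjust_holm_sidak(p)
  expect_equal(adj[1], 1 - (1 - 0.01)^3)
  expect_equal(adj[3], max(1 - (1 - 0.01)^3, 1 - (1 - 0.03)^2))
  expect_equal(adj[2], max(1 - (1 - 0.03)^2, 1 - (1 - 0.04)^1))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("reports carry audit fields", {
  r <- group_compare(list(a = rnorm(5), b = rnorm(5)), "welch_t")
  expect_identical(r$method, "welch_t")
  expect_identical(r$groups, c("a", "b"))
  expect_identical(r$alternative, "two.sided")
})
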