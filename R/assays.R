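# Endpoint assays: standard-curve interpolation, reduction kinetics, acute
# endogenous clearance, survival chi-square, stress-sweep viscosity,
# viscosity-vs-mass regression, and the shared group-comparison dispatcher.

#' Interpolate unknown concentrations along a linear standard curve
#'
#' Least-squares line through the standards; duplicates of each unknown are
#' averaged before inversion `C = (A - intercept) / slope`. Unknowns outside
#' the calibrated range are flagged as extrapolated.
#'
#' @param standards data.frame with columns `conc` and `absorbance`
#'   (>= 3 distinct standards)
#' @param unknowns numeric vector (one well per sample), a matrix
#'   (samples x replicate wells), or a list of replicate vectors
#' @return list: `concentrations` data.frame (`sample`, `mean_absorbance`,
#'   `concentration`, `extrapolated`) and `curve` (`slope`, `intercept`,
#'   `r_squared`, `range`)
#' @export
standard_curve_concentration <- function(standards, unknowns) {
  if (!all(c("conc", "absorbance") %in% names(standards)))
    stop_invalid("standards need columns `conc` and `absorbance`")
  if (length(unique(standards$conc)) < 3L)
    stop_invalid("need >= 3 distinct standards")
  fit <- stats::lm(absorbance ~ conc, data = standards)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < 1e-12) stop_invalid("degenerate standard curve: slope ~ 0")
  sst <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  a_mean <- if (is.matrix(unknowns)) rowMeans(unknowns)
            else if (is.list(unknowns)) vapply(unknowns, mean, numeric(1))
            else unknowns
  conc <- (a_mean - intercept) / slope
  rng <- range(standards$conc)
  out <- data.frame(sample = if (!is.null(names(a_mean))) names(a_mean)
                             else paste0("unk", seq_along(a_mean)),
                    mean_absorbance = unname(a_mean),
                    concentration = unname(conc),
                    extrapolated = unname(conc < rng[1] | conc > rng[2]))
  list(concentrations = out,
       curve = list(slope = slope, intercept = intercept, r_squared = r2,
                    range = rng))
}

#' Fit mono-exponential product-formation kinetics
#'
#' `A(t) = baseline + amplitude * (1 - exp(-k t))` — pseudo-first-order
#' approach to plateau under substrate excess — fitted by nonlinear least
#' squares. A flat series returns `k = 0, amplitude = 0` rather than failing.
#'
#' @param times time points, s (>= 5)
#' @param absorbance readings (same length)
#' @return object of class `kinetics_fit`: `rate_constant` (1/s),
#'   `amplitude`, `baseline`, `rmse`
#' @export
dtnb_rate <- function(times, absorbance) {
  if (length(times) < 5L || length(times) != length(absorbance))
    stop_invalid("need >= 5 matched (time, absorbance) points")
  if (stats::sd(absorbance) < 1e-12) {
    return(structure(list(rate_constant = 0, amplitude = 0,
                          baseline = mean(absorbance), rmse = 0),
                     class = "kinetics_fit"))
  }
  b0 <- min(absorbance); a0 <- max(absorbance) - b0
  # crude rate guess from the time to reach half amplitude
  t_half <- times[which(absorbance - b0 >= a0 / 2)[1]]
  k0 <- if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1 / max(times)
  df <- data.frame(t = times, A = absorbance)
  fit <- tryCatch(
    stats::nls(A ~ b + a * (1 - exp(-k * t)), data = df,
               start = list(b = b0, a = a0, k = k0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    sse <- function(p) {
      pred <- p[1] + p[2] * (1 - exp(-exp(p[3]) * times))
      sum((absorbance - pred)^2)
    }
    best <- NULL
    for (lk in log(k0) + c(-2, 0, 2)) {
      o <- stats::optim(c(b0, a0, lk), sse, control = list(maxit = 2000))
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best))
      stop_invalid("kinetics fit failed (starts: b=%.3g a=%.3g k=%.3g)",
                   b0, a0, k0)
    p <- c(best$par[1], best$par[2], exp(best$par[3]))
    resid <- absorbance - (p[1] + p[2] * (1 - exp(-p[3] * times)))
  } else {
    p <- stats::coef(fit)[c("b", "a", "k")]
    resid <- stats::residuals(fit)
  }
  structure(list(rate_constant = max(unname(p[3]), 0),
                 amplitude = unname(p[2]), baseline = unname(p[1]),
                 rmse = sqrt(mean(resid^2))),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> k = %s /s, amplitude = %s, baseline = %s\n",
              fmt_num(x$rate_constant), fmt_num(x$amplitude),
              fmt_num(x$baseline)))
  invisible(x)
}

#' Rate ratio between two kinetics fits
#'
#' @param fit_a,fit_b [dtnb_rate()] fits (e.g. mucolytic vs reference agent)
#' @return `fit_a$rate_constant / fit_b$rate_constant`
#' @export
kinetics_rate_ratio <- function(fit_a, fit_b) {
  fit_a$rate_constant / fit_b$rate_constant
}

#' Acute endogenous clearance from lavage leukocyte counts
#'
#' Percent decrease of the treated-arm mean relative to the vehicle arm,
#' with a two-sided two-sample comparison (Welch t by default).
#'
#' @param vehicle,treated per-animal counts (>= 2 each)
#' @param test "welch_t" (default) or "mann_whitney"
#' @return list: `percent_decrease`, `test` report (statistic, p, method),
#'   `flag`
#' @export
acute_endogenous_clearance <- function(vehicle, treated,
                                       test = c("welch_t", "mann_whitney")) {
  test <- match.arg(test)
  if (length(vehicle) < 2L || length(treated) < 2L)
    stop_invalid("need >= 2 animals per arm")
  mv <- mean(vehicle)
  flag <- "ok"
  pct <- if (mv == 0) { flag <- "undefined: zero vehicle mean"; NA_real_ }
         else 100 * (mv - mean(treated)) / mv
  rep <- group_compare(list(vehicle = vehicle, treated = treated),
                       method = if (test == "welch_t") "welch_t" else "mann_whitney")
  list(percent_decrease = pct, test = rep, flag = flag)
}

#' Pearson chi-square test on survival counts
#'
#' Groups x {died, survived} contingency table; df = groups - 1. A warning
#' string is attached when any expected cell is below 1.
#'
#' @param deaths deaths per group
#' @param totals animals per group (> 0)
#' @return list: `chi2`, `df`, `p`, `warning` (NULL or text)
#' @export
survival_chisq <- function(deaths, totals) {
  if (length(deaths) < 2L || length(deaths) != length(totals))
    stop_invalid("need >= 2 groups of matched (deaths, totals)")
  if (any(totals <= 0)) stop_invalid("group totals must be > 0")
  if (any(deaths < 0) || any(deaths > totals))
    stop_invalid("deaths must lie in [0, total] for every group")
  tab <- cbind(died = deaths, survived = totals - deaths)
  expctd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expctd < 1))
    "expected cell count < 1; chi-square approximation is unreliable" else NULL
  chi2 <- sum((tab - expctd)^2 / expctd)
  df <- length(deaths) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), warning = warn)
}

#' Complex viscosity from the linear regime of a stress sweep
#'
#' The linear regime is the leading run of the sweep in which the modulus
#' magnitude stays within `tolerance` of its running median; the run ends at
#' the first *sustained* departure (two consecutive points out of tolerance
#' on the same side, or a final out-of-tolerance point). An isolated noisy
#' point does not end the plateau — shear thinning is a one-sided, sustained
#' drop, which is what the termination rule looks for. Complex viscosity =
#' plateau modulus / angular frequency.
#'
#' @param stress applied stresses, Pa, sorted ascending (>= 5 points)
#' @param modulus_magnitude |G*| at each stress, Pa
#' @param frequency angular frequency of the sweep, rad/s
#' @param tolerance relative deviation defining the plateau (default 0.10)
#' @return list: `complex_viscosity` (Pa s), `plateau_modulus` (Pa),
#'   `plateau_points` (indices)
#' @export
linear_regime_viscosity <- function(stress, modulus_magnitude, frequency,
                                    tolerance = 0.10) {
  if (length(stress) < 5L || length(stress) != length(modulus_magnitude))
    stop_invalid("need >= 5 matched (stress, modulus) points")
  if (is.unsorted(stress)) stop_invalid("sweep must be sorted by stress")
  assert_positive(frequency, "frequency")
  G <- modulus_magnitude
  n <- length(G)
  run <- 1L
  for (i in 2:n) {
    # running median over at least 3 points; a 2-point "median" is the
    # midpoint and flags ordinary noise as departure from linearity
    med <- stats::median(G[1:max(i, 3L)])
    dev_i <- (G[i] - med) / med
    if (abs(dev_i) >= tolerance) {
      if (i == n) break
      dev_next <- (G[i + 1] - med) / med
      if (abs(dev_next) >= tolerance && sign(dev_next) == sign(dev_i)) break
      run <- i  # isolated excursion: keep the point, continue the run
    } else {
      run <- i
    }
  }
  if (run < 3L) stop_invalid("no linear regime: leading plateau shorter than 3 points")
  plateau <- mean(G[1:run])
  list(complex_viscosity = plateau / frequency, plateau_modulus = plateau,
       plateau_points = seq_len(run))
}

#' Linear regression of complex viscosity on molecular mass
#'
#' Ordinary least squares with Pearson correlation and its p-value.
#'
#' @param molecular_mass predictor (>= 3 values, non-constant)
#' @param complex_viscosity response
#' @return list: `slope`, `intercept`, `r`, `p`
#' @export
viscosity_mass_regression <- function(molecular_mass, complex_viscosity) {
  if (length(molecular_mass) < 3L ||
      length(molecular_mass) != length(complex_viscosity))
    stop_invalid("need >= 3 matched (mass, viscosity) pairs")
  if (stats::sd(molecular_mass) < 1e-300)
    stop_invalid("zero variance in molecular mass")
  fit <- stats::lm(complex_viscosity ~ molecular_mass)
  ct <- stats::cor.test(molecular_mass, complex_viscosity)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value)
}

#' Compare groups by the study's shared statistical tests
#'
#' Dispatches to Welch's t-test, the Mann–Whitney test, or one-way ANOVA
#' with Holm–Šidák-adjusted pairwise comparisons against a reference group.
#' The report records the method and all parameters (audit contract).
#'
#' @param groups named list of numeric vectors (>= 2 groups)
#' @param method "welch_t", "mann_whitney", or "anova_holm_sidak"
#' @param reference reference group for the ANOVA pairwise path (default the
#'   first group)
#' @param alternative for the two-sample paths (default "two.sided")
#' @return list report: `method`, `statistic`, `p`, and for the ANOVA path
#'   `pairwise` (data.frame with `p_adj`); `note` records tie handling
#' @export
group_compare <- function(groups,
                          method = c("welch_t", "mann_whitney", "anova_holm_sidak"),
                          reference = names(groups)[1],
                          alternative = "two.sided") {
  method <- match.arg(method)
  if (length(groups) < 2L) stop_invalid("need >= 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  note <- NULL
  if (method %in% c("welch_t", "mann_whitney") && length(groups) != 2L)
    stop_invalid("%s requires exactly 2 groups", method)
  if (method == "welch_t") {
    ht <- if (stats::sd(groups[[1]]) < 1e-300 && stats::sd(groups[[2]]) < 1e-300 &&
              isTRUE(all.equal(mean(groups[[1]]), mean(groups[[2]]))))
      list(t = 0, df = length(unlist(groups)) - 2, p = 1)
    else {
      tt <- stats::t.test(groups[[1]], groups[[2]], alternative = alternative)
      list(t = unname(tt$statistic), df = unname(tt$parameter),
           p = unname(tt$p.value))
    }
    return(list(method = method, statistic = ht$t, df = ht$df, p = ht$p,
                alternative = alternative, groups = names(groups), note = note))
  }
  if (method == "mann_whitney") {
    a <- groups[[1]]; b <- groups[[2]]
    ties <- any(duplicated(c(a, b)))
    if (length(unique(c(a, b))) == 1L) {
      return(list(method = method, statistic = length(a) * length(b) / 2,
                  p = 1, alternative = alternative, groups = names(groups),
                  note = "all values tied; p set to 1"))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = alternative, exact = !ties))
    if (ties) note <- "ties present; normal approximation used"
    return(list(method = method, statistic = unname(wt$statistic),
                p = unname(wt$p.value), alternative = alternative,
                groups = names(groups), note = note))
  }
  # anova_holm_sidak
  v <- unlist(groups, use.names = FALSE)
  gr <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  an <- oneway_anova(v, gr)
  others <- setdiff(names(groups), reference)
  pw <- do.call(rbind, lapply(others, function(nm) {
    ht <- safe_welch(groups[[nm]], groups[[reference]])
    data.frame(group = nm, t = ht$t, df = ht$df, p_raw = ht$p)
  }))
  pw$p_adj <- p_adjust_holm_sidak(pw$p_raw)
  list(method = method, statistic = an$F, df1 = an$df1, df2 = an$df2,
       p = an$p, pairwise = pw, reference = reference,
       groups = names(groups), note = note)
}
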