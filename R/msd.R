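# Mean squared displacement: drift correction, per-bead and ensemble curves,
# scaling fits, dose-response testing.
#
# The per-bead curve is the overlapping-window time average
#   dr2(tau) = 1/(N - tau) * sum_{i=1..N-tau} (x_i+tau - x_i)^2 + (y_i+tau - y_i)^2
# evaluated at integer frame lags; n_terms(tau) = N - tau. The ensemble curve
# is the equal-weighted per-bead mean at each lag (pooled n_terms weighting
# available), with sem = sd across beads / sqrt(n_beads).

#' MSD curve container
#'
#' @param df data.frame with columns `lag_frames`, `lag_s`, `msd_um2`,
#'   `n_terms`, and (for ensemble curves) `n_beads`, `sem`
#' @param dt frame interval, seconds
#' @return object of class `msd_curve` (a data.frame)
#' @export
msd_curve <- function(df, dt) {
  need <- c("lag_frames", "lag_s", "msd_um2", "n_terms")
  if (!all(need %in% names(df)))
    stop_invalid("msd data must have columns %s", paste(need, collapse = ", "))
  if (any(df$msd_um2 < -1e-12)) stop_invalid("msd must be non-negative")
  structure(as.data.frame(df), dt = dt, class = c("msd_curve", "data.frame"))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, dt = %g s, msd[1] = %s um^2\n",
              nrow(x), attr(x, "dt"), fmt_num(x$msd_um2[1])))
  invisible(x)
}

#' Write / read an MSD curve as CSV
#' @param msd an [msd_curve()]
#' @param path CSV path
#' @export
write_msd <- function(msd, path) {
  utils::write.csv(as.data.frame(msd), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  df <- utils::read.csv(path)
  msd_curve(df, dt = if (nrow(df)) df$lag_s[1] / df$lag_frames[1] else 1)
}

check_uniform_times <- function(t_s) {
  if (length(t_s) < 2L) stop_invalid("trajectory must have N >= 2 frames")
  dts <- diff(t_s)
  if (any(dts <= 0)) stop_invalid("times must be strictly increasing")
  if (diff(range(dts)) > 1e-9 * max(abs(dts)))
    stop_invalid("times must be uniformly spaced (1e-9 relative tolerance)")
  dts[1]
}

#' Estimate and subtract linear drift from a trajectory ensemble
#'
#' Drift is the per-axis least-squares slope of the ensemble-mean position
#' against time; it is subtracted (about the first time point) from every
#' trajectory. Applying the correction twice is a no-op.
#'
#' @param trajectories a [trajectory_set()] with >= 2 distinct frames
#' @return list with `trajectories` (corrected) and `drift_estimate`
#'   (um/s 2-vector, x then y)
#' @export
correct_linear_drift <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  df <- as.data.frame(trajectories)
  if (nrow(df) == 0L) stop_invalid("empty trajectory set")
  mx <- tapply(df$x_um, df$t_s, mean)
  my <- tapply(df$y_um, df$t_s, mean)
  tt <- as.numeric(names(mx))
  if (length(tt) < 2L)
    stop_invalid("drift estimation needs >= 2 frames of ensemble overlap")
  vx <- stats::cov(tt, mx) / stats::var(tt)
  vy <- stats::cov(tt, my) / stats::var(tt)
  t0 <- min(df$t_s)
  df$x_um <- df$x_um - vx * (df$t_s - t0)
  df$y_um <- df$y_um - vy * (df$t_s - t0)
  list(trajectories = trajectory_set(df, dt = attr(trajectories, "dt"),
                                     truth = attr(trajectories, "ground_truth")),
       drift_estimate = c(vx, vy))
}

#' Per-bead mean squared displacement (overlapping windows)
#'
#' @param trajectory a single-bead data.frame (`t_s`, `x_um`, `y_um`) or a
#'   [trajectory_set()] containing exactly one bead
#' @param max_lag largest lag in frames; default `floor((N - 1) / 4)`
#'   (variance at longer lags is the field's reason to stop there)
#' @return an [msd_curve()] with `n_terms = N - tau`
#' @export
compute_msd <- function(trajectory, max_lag = NULL) {
  df <- as.data.frame(trajectory)
  if ("bead_id" %in% names(df) && length(unique(df$bead_id)) != 1L)
    stop_invalid("compute_msd expects a single bead; see ensemble_msd()")
  dt <- check_uniform_times(df$t_s)
  N <- nrow(df)
  if (is.null(max_lag)) max_lag <- max(1L, (N - 1L) %/% 4L)
  max_lag <- assert_count(max_lag, "max_lag")
  if (max_lag >= N) stop_invalid("max_lag (%d) must be < N (%d)", max_lag, N)
  x <- df$x_um; y <- df$y_um
  msd <- vapply(seq_len(max_lag), function(tau) {
    dx <- x[(1L + tau):N] - x[1:(N - tau)]
    dy <- y[(1L + tau):N] - y[1:(N - tau)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  msd_curve(data.frame(lag_frames = seq_len(max_lag),
                       lag_s = seq_len(max_lag) * dt,
                       msd_um2 = msd,
                       n_terms = N - seq_len(max_lag)), dt = dt)
}

#' Ensemble mean squared displacement across beads
#'
#' @param trajectories a [trajectory_set()]
#' @param max_lag largest lag in frames; default N/4 of the longest bead
#' @param weighting "equal" (per-bead equal weight, default) or "pooled"
#'   (beads weighted by their n_terms at each lag)
#' @return an [msd_curve()] with `n_beads` and `sem` columns
#' @export
ensemble_msd <- function(trajectories, max_lag = NULL, weighting = c("equal", "pooled")) {
  weighting <- match.arg(weighting)
  beads <- split_beads(trajectories)
  if (length(beads) == 0L) stop_invalid("empty trajectory set")
  lens <- vapply(beads, nrow, integer(1))
  if (is.null(max_lag)) max_lag <- max(1L, (max(lens) - 1L) %/% 4L)
  max_lag <- assert_count(max_lag, "max_lag")
  usable <- lens > max_lag
  if (!any(usable))
    stop_invalid("no trajectory longer than max_lag = %d", max_lag)
  curves <- lapply(beads[usable], compute_msd, max_lag = max_lag)
  dt <- attr(curves[[1]], "dt")
  M <- vapply(curves, function(cv) cv$msd_um2[seq_len(max_lag)], numeric(max_lag))
  M <- matrix(M, nrow = max_lag)
  W <- vapply(curves, function(cv) cv$n_terms[seq_len(max_lag)], numeric(max_lag))
  W <- matrix(W, nrow = max_lag)
  if (weighting == "equal") {
    mu <- rowMeans(M)
  } else {
    mu <- rowSums(M * W) / rowSums(W)
  }
  nb <- ncol(M)
  sem <- if (nb > 1L) apply(M, 1, stats::sd) / sqrt(nb) else rep(0, max_lag)
  msd_curve(data.frame(lag_frames = seq_len(max_lag),
                       lag_s = seq_len(max_lag) * dt,
                       msd_um2 = mu,
                       n_terms = rowMeans(W),
                       n_beads = nb,
                       sem = sem), dt = dt)
}

#' Fit a power-law scaling to an MSD curve
#'
#' Least-squares line on log lag (seconds) versus log MSD:
#' the slope is the anomalous exponent and `exp(intercept) / 4` the apparent
#' diffusion coefficient (2-D convention `msd = 4 D tau^alpha`).
#'
#' @param msd an [msd_curve()]
#' @param fit_range c(min, max) lag in frames; default the full curve.
#'   Choose a range starting above the localization-noise floor
#'   (a stationary noisy bead has flat MSD `4 sigma_loc^2`).
#' @return list with `anomalous_exponent`, `apparent_D` (um^2/s)
#' @export
fit_scaling <- function(msd, fit_range = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  df <- as.data.frame(msd)
  if (!is.null(fit_range)) {
    df <- df[df$lag_frames >= fit_range[1] & df$lag_frames <= fit_range[2], ]
  }
  if (nrow(df) < 2L) stop_invalid("fit_range leaves < 2 lags")
  if (any(df$msd_um2 <= 0))
    stop_invalid("msd must be strictly positive over the fit range")
  lx <- log(df$lag_s); ly <- log(df$msd_um2)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  intercept <- mean(ly) - slope * mean(lx)
  list(anomalous_exponent = slope, apparent_D = exp(intercept) / 4)
}

#' MSD value at a reference lag
#'
#' @param msd an [msd_curve()]
#' @param lag_s reference lag in seconds (nearest available lag is used)
#' @return MSD in um^2
#' @export
msd_at <- function(msd, lag_s) {
  stopifnot(inherits(msd, "msd_curve"))
  msd$msd_um2[which.min(abs(msd$lag_s - lag_s))]
}

# Closed-form one-way ANOVA; returns F, df, p. SSB == 0 is reported as
# F = 0, p = 1 (identical groups are "no evidence", not NaN).
oneway_anova <- function(values, groups) {
  g <- split(values, groups)
  k <- length(g)
  n <- length(values)
  gm <- mean(values)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- k - 1L; df2 <- n - k
  if (ssb <= 1e-300) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Dose-response comparison of MSD across treatment groups
#'
#' One-way ANOVA on per-replicate MSD values at a reference lag, followed by
#' pairwise Welch comparisons of each group against the vehicle with
#' Holm–Šidák family-wise adjustment.
#'
#' @param groups named list; each element either a numeric vector of
#'   per-replicate MSD values at the reference lag, or a list of
#'   [msd_curve()]s from which values are read via [msd_at()]
#' @param reference_lag lag in seconds (needed when curves are supplied)
#' @param reference name of the vehicle group (default the first)
#' @return list: `anova` (F, df1, df2, p), `pairwise` data.frame
#'   (group, t, df, p_raw, p_adj), `reference_lag`, `reference`
#' @export
msd_dose_response <- function(groups, reference_lag = NULL,
                              reference = names(groups)[1]) {
  if (length(groups) < 2L) stop_invalid("need >= 2 groups")
  vals <- lapply(groups, function(g) {
    if (is.numeric(g)) return(g)
    if (is.null(reference_lag))
      stop_invalid("reference_lag is required when MSD curves are supplied")
    vapply(g, msd_at, numeric(1), lag_s = reference_lag)
  })
  if (any(vapply(vals, length, integer(1)) < 2L))
    stop_invalid("every group needs >= 2 replicates")
  v <- unlist(vals, use.names = FALSE)
  gr <- factor(rep(names(vals), vapply(vals, length, integer(1))),
               levels = names(vals))
  an <- oneway_anova(v, gr)
  others <- setdiff(names(vals), reference)
  pw <- lapply(others, function(nm) {
    ht <- safe_welch(vals[[nm]], vals[[reference]])
    data.frame(group = nm, t = ht$t, df = ht$df, p_raw = ht$p)
  })
  pw <- do.call(rbind, pw)
  pw$p_adj <- p_adjust_holm_sidak(pw$p_raw)
  list(anova = an, pairwise = pw,
       reference_lag = reference_lag, reference = reference)
}

# Welch t-test that degrades gracefully on zero-variance input.
safe_welch <- function(a, b, var_equal = FALSE) {
  if (stats::sd(a) < 1e-300 && stats::sd(b) < 1e-300) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
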