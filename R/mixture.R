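# Histogram statistics for SHG percent-area distributions: least chi-square
# Gaussian mixture fitting with peak-count selection, and the large-df
# rejection-region t comparison.

# min_bins guards the bin-rule output: FD collapses on strongly bimodal data
# (huge IQR -> coarse bins), and every candidate k needs nb - 3k >= 1 dof.
hist_counts <- function(values, bin_rule, min_bins = 12L) {
  if (is.numeric(bin_rule)) {
    nb <- assert_count(bin_rule, "bin_rule")
  } else {
    nb <- switch(match.arg(bin_rule, c("fd", "sturges")),
                 fd = grDevices::nclass.FD(values),
                 sturges = grDevices::nclass.Sturges(values))
  }
  nb <- max(nb, min_bins)
  h <- graphics::hist(values, breaks = nb, plot = FALSE)
  if (length(h$counts) < min_bins) {
    brk <- seq(min(values), max(values), length.out = min_bins + 1L)
    brk[1] <- brk[1] - 1e-9; brk[min_bins + 1L] <- brk[min_bins + 1L] + 1e-9
    h <- graphics::hist(values, breaks = brk, plot = FALSE)
  }
  list(counts = h$counts, mids = h$mids, width = diff(h$breaks[1:2]))
}

# Component sd is parameterized as width + exp(p): a "peak" narrower than
# one histogram bin is bin noise, not a component, and allowing it lets the
# optimizer erase single-bin residuals with spikes.
gauss_sum <- function(x, par, width) {
  k <- length(par) / 3
  f <- numeric(length(x))
  for (j in seq_len(k)) {
    mu <- par[3 * j - 2]; sd <- width + exp(par[3 * j - 1]); A <- exp(par[3 * j])
    f <- f + A * exp(-(x - mu)^2 / (2 * sd^2))
  }
  f
}

# chi2 = sum (obs - fit)^2 / max(fit, 1): bins with tiny fitted expectation
# are floored in the denominator to avoid blow-ups.
mixture_chi2 <- function(par, mids, counts, width) {
  f <- gauss_sum(mids, par, width)
  sum((counts - f)^2 / pmax(f, 1))
}

# quantile-sliced starting values for k components
mixture_start <- function(values, k, width) {
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1))
  par <- numeric(0)
  for (j in seq_len(k)) {
    v <- values[values >= qs[j] & values <= qs[j + 1]]
    if (length(v) < 2L) v <- values
    mu <- mean(v)
    sd <- max(stats::sd(v), 1.5 * width)
    A <- length(v) * width / (sd * sqrt(2 * pi))
    par <- c(par, mu, log(max(sd - width, width / 4)), log(max(A, 1e-6)))
  }
  par
}

fit_k_components <- function(values, k, mids, counts, width, prev = NULL) {
  starts <- list(mixture_start(values, k, width))
  if (!is.null(prev)) {
    # nested start: previous best solution plus one component at the bin
    # with the largest positive residual — keeps chi2(k) non-increasing
    f <- gauss_sum(mids, prev, width)
    j <- which.max(counts - f)
    extra <- c(mids[j], log(max(stats::sd(values) / 4, width / 2)),
               log(max(counts[j] - f[j], 1)))
    starts <- c(starts, list(c(prev, extra)))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, mixture_chi2, mids = mids, counts = counts,
                   width = width, method = "Nelder-Mead",
                   control = list(maxit = 3000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit <- tryCatch(
      stats::optim(fit$par, mixture_chi2, mids = mids, counts = counts,
                   width = width, method = "BFGS",
                   control = list(maxit = 500)),
      error = function(e) fit)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best
}

#' Fit a least chi-square Gaussian mixture to a percent-area histogram
#'
#' For k = 1..`max_peaks`, a k-component Gaussian sum is fitted to the bin
#' counts by nonlinear least squares minimizing
#' `chi2 = sum (obs - fit)^2 / max(fit, 1)`. The selected peak count is the
#' smallest k whose reduced chi2 is not improved by more than
#' `improvement` (default 15%) by k + 1.
#'
#' @param values numeric vector of percent areas (>= 30 values)
#' @param max_peaks maximum component count to try (default 3)
#' @param bin_rule "fd" (Freedman–Diaconis, default), "sturges", or a bin count
#' @param improvement relative reduced-chi2 improvement required to accept an
#'   extra peak (default 0.15)
#' @param adequacy reduced-chi2 level at or below which a fit is accepted
#'   outright, without consulting k + 1 (default 1.5). For Poisson-like bin
#'   counts an adequate model has reduced chi2 near 1; improvements beyond
#'   that are fits to noise, and the 15% rule alone cannot tell them apart.
#' @return object of class `mixture_fit`: `n_peaks`, `means`, `sds`,
#'   `weights` (component masses in counts, summing approximately to the
#'   histogram mass), `chi2`, `dof`, `chi2_trace` (per-k), and the histogram
#' @export
fit_gaussian_mixture_histogram <- function(values, max_peaks = 3,
                                           bin_rule = "fd",
                                           improvement = 0.15,
                                           adequacy = 1.5) {
  if (length(values) < 30L)
    stop_invalid("need >= 30 values to fit a histogram (got %d)", length(values))
  max_peaks <- assert_count(max_peaks, "max_peaks")
  h <- hist_counts(values, bin_rule, min_bins = 3L * max_peaks + 3L)
  nb <- length(h$counts)
  fits <- vector("list", max_peaks)
  chi2s <- rep(NA_real_, max_peaks)
  prev <- NULL
  for (k in seq_len(max_peaks)) {
    if (nb - 3 * k < 1L) break   # not enough bins for this many components
    fit <- fit_k_components(values, k, h$mids, h$counts, h$width, prev)
    if (is.null(fit)) { warning(sprintf("k = %d fit failed; skipped", k)); next }
    fits[[k]] <- fit
    chi2s[k] <- fit$value
    prev <- fit$par
  }
  ks <- which(!is.na(chi2s))
  if (length(ks) == 0L) stop_invalid("mixture fitting failed at every k")
  red <- chi2s[ks] / (nb - 3 * ks)
  sel <- ks[length(ks)]
  for (i in seq_along(ks)) {
    if (red[i] <= adequacy) { sel <- ks[i]; break }
    if (i == length(ks)) { sel <- ks[i]; break }
    if ((red[i] - red[i + 1]) <= improvement * red[i]) { sel <- ks[i]; break }
  }
  par <- fits[[sel]]$par
  k <- length(par) / 3
  mu <- par[seq(1, length(par), 3)]
  sd <- h$width + exp(par[seq(2, length(par), 3)])
  A <- exp(par[seq(3, length(par), 3)])
  o <- order(mu)
  structure(list(n_peaks = k,
                 means = mu[o], sds = sd[o],
                 weights = (A * sd * sqrt(2 * pi) / h$width)[o],
                 chi2 = chi2s[sel], dof = nb - 3 * sel,
                 chi2_trace = data.frame(k = ks, chi2 = chi2s[ks],
                                         reduced_chi2 = red),
                 histogram = h),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d peak(s): means %s; chi2 = %s (dof %d)\n",
              x$n_peaks, paste(fmt_num(x$means), collapse = ", "),
              fmt_num(x$chi2), x$dof))
  invisible(x)
}

#' Rejection-region two-sample t comparison
#'
#' Two-sample t statistic (Welch by default) compared against the upper-alpha
#' critical value of the reference distribution; for df > 100 the large-df
#' normal limit is used, which at alpha = 0.001 gives the classical
#' rejection region \[3.09, Inf).
#'
#' @param groupA,groupB numeric vectors (>= 2 values each)
#' @param alpha one-sided significance level (default 0.001)
#' @param var_equal pooled-variance t instead of Welch (default FALSE)
#' @return list: `t_statistic`, `df`, `critical_value`, `decision` (logical),
#'   `alpha`, `flag`
#' @export
rejection_region_test <- function(groupA, groupB, alpha = 0.001,
                                  var_equal = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop_invalid("each group needs >= 2 values")
  assert_positive(alpha, "alpha")
  ht <- safe_welch(groupA, groupB, var_equal = var_equal)
  flag <- "ok"
  if (ht$t == 0 && ht$p == 1 &&
      stats::sd(groupA) < 1e-300 && stats::sd(groupB) < 1e-300)
    flag <- "undefined: zero variance in both groups with equal means"
  crit <- if (is.finite(ht$df) && ht$df > 100) stats::qnorm(1 - alpha)
          else stats::qt(1 - alpha, df = ht$df)
  list(t_statistic = ht$t, df = ht$df, critical_value = crit,
       decision = is.finite(ht$t) && ht$t >= crit || ht$t == Inf,
       alpha = alpha, flag = flag)
}
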