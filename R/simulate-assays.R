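# Synthetic plate assays and lavage/survival experiments.

#' Simulate a colorimetric plate read against a linear standard curve
#'
#' Absorbance = intercept + slope * concentration, with multiplicative
#' Gaussian noise of the stated coefficient of variation. Standards and
#' unknowns are generated and labeled; duplicate plating is the default.
#'
#' @param true_concentrations unknown sample concentrations (>= 0)
#' @param curve_slope absorbance per concentration unit
#' @param curve_intercept absorbance at zero concentration
#' @param replicate_cv multiplicative noise CV (fraction, >= 0)
#' @param n_replicates wells per sample (default 2, "plated in duplicate")
#' @param standard_concentrations standards for the curve
#' @param seed RNG seed
#' @return object of class `plate_data`: data.frame with `well_type`
#'   (standard/unknown), `sample_id`, `replicate`, `conc_true`, `absorbance`,
#'   plus the [ground_truth()] as an attribute
#' @export
simulate_plate_assay <- function(true_concentrations, curve_slope,
                                 curve_intercept, replicate_cv = 0,
                                 n_replicates = 2,
                                 standard_concentrations = c(0, 2.5, 5, 10, 20, 40),
                                 seed) {
  if (any(!is.finite(true_concentrations)) || any(true_concentrations < 0))
    stop_invalid("concentrations must be non-negative")
  assert_scalar_number(curve_slope, "curve_slope")
  assert_scalar_number(curve_intercept, "curve_intercept")
  assert_non_negative(replicate_cv, "replicate_cv")
  n_replicates <- assert_count(n_replicates, "n_replicates")
  seed <- assert_seed(seed)

  conc <- c(standard_concentrations, true_concentrations)
  type <- rep(c("standard", "unknown"),
              c(length(standard_concentrations), length(true_concentrations)))
  id <- c(paste0("std", seq_along(standard_concentrations)),
          paste0("unk", seq_along(true_concentrations)))
  df <- data.frame(
    well_type = rep(type, each = n_replicates),
    sample_id = rep(id, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(conc)),
    conc_true = rep(conc, each = n_replicates))
  clean <- curve_intercept + curve_slope * df$conc_true
  df$absorbance <- if (replicate_cv > 0) {
    with_seed(seed, clean * (1 + replicate_cv * stats::rnorm(nrow(df))))
  } else clean
  structure(df,
            ground_truth = ground_truth(curve_slope = curve_slope,
                                        curve_intercept = curve_intercept,
                                        replicate_cv = replicate_cv,
                                        seed = seed),
            class = c("plate_data", "data.frame"))
}

#' Simulate a lavage leukocyte experiment with survival outcomes
#'
#' Per-animal total leukocyte counts are negative-binomial around the group
#' mean (overdispersed, as lavage counts are in practice); `poisson = TRUE`
#' gives the equidispersed limit. Differential counts split each total
#' multinomially into macrophages / lymphocytes / neutrophils.
#'
#' @param group_sizes animals per group (named or not)
#' @param group_means mean total leukocyte count per group
#' @param dispersion negative-binomial size parameter (> 0); default 10,
#'   moderate overdispersion typical of lavage totals
#' @param deaths_per_group deaths observed per group (<= group size)
#' @param differential_probs multinomial split, default c(0.7, 0.1, 0.2)
#' @param poisson use Poisson counts instead (dispersion ignored)
#' @param seed RNG seed
#' @return list: `counts` data.frame (group, animal, total, macrophages,
#'   lymphocytes, neutrophils), `survival` data.frame (group, deaths, total),
#'   and `ground_truth`
#' @export
simulate_lavage_experiment <- function(group_sizes, group_means, dispersion = 10,
                                       deaths_per_group = NULL,
                                       differential_probs = c(0.7, 0.1, 0.2),
                                       poisson = FALSE, seed) {
  if (length(group_sizes) != length(group_means))
    stop_invalid("group_sizes and group_means must have equal length")
  if (any(group_sizes < 1)) stop_invalid("all group sizes must be >= 1")
  if (!poisson) assert_positive(dispersion, "dispersion")
  if (is.null(deaths_per_group)) deaths_per_group <- rep(0L, length(group_sizes))
  if (any(deaths_per_group > group_sizes))
    stop_invalid("deaths cannot exceed group size")
  seed <- assert_seed(seed)
  gnames <- names(group_sizes)
  if (is.null(gnames)) gnames <- paste0("group", seq_along(group_sizes))

  counts <- with_seed(seed, {
    rows <- lapply(seq_along(group_sizes), function(g) {
      n <- group_sizes[g]
      tot <- if (poisson) stats::rpois(n, group_means[g])
             else stats::rnbinom(n, size = dispersion, mu = group_means[g])
      diffm <- t(vapply(tot, function(tc)
        as.numeric(stats::rmultinom(1, tc, differential_probs)),
        numeric(3)))
      data.frame(group = gnames[g], animal = paste0(gnames[g], "_", seq_len(n)),
                 total = tot, macrophages = diffm[, 1],
                 lymphocytes = diffm[, 2], neutrophils = diffm[, 3])
    })
    do.call(rbind, rows)
  })
  list(counts = counts,
       survival = data.frame(group = gnames,
                             deaths = as.integer(deaths_per_group),
                             total = as.integer(group_sizes)),
       ground_truth = ground_truth(group_means = group_means,
                                   dispersion = if (poisson) Inf else dispersion,
                                   seed = seed))
}
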