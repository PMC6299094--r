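#' @keywords internal
"_PACKAGE"

# Argument checks ------------------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  invisible(x)
}

assert_positive <- function(x, name) {
  assert_scalar_number(x, name)
  if (x <= 0) stop_invalid("`%s` must be > 0 (got %g)", name, x)
  invisible(x)
}

assert_non_negative <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0) stop_invalid("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name)
  if (x < min || x != round(x))
    stop_invalid("`%s` must be an integer >= %d (got %g)", name, min, x)
  invisible(as.integer(x))
}

assert_seed <- function(seed) {
  if (missing(seed) || is.null(seed))
    stop_invalid("a `seed` must be supplied for reproducibility")
  assert_count(seed, "seed", min = 0L)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Deterministic fan-out of a master seed into per-stage child seeds.
# Documented rule: child_k = (seed * 7919 + 1000003 * k) mod (2^31 - 1).
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 1000003 * as.double(k)) %% 2147483647)
}

# Number of frames acquired in `duration_s` seconds at `frame_rate` frames/s.
#' Frame-count bookkeeping for a timed acquisition
#'
#' @param duration_s acquisition duration in seconds
#' @param frame_rate acquisition rate in frames per second
#' @return integer frame count (`round(duration_s * frame_rate)`)
#' @examples
#' n_frames_for(30, 60)  # 1800
#' @export
n_frames_for <- function(duration_s, frame_rate) {
  assert_positive(duration_s, "duration_s")
  assert_positive(frame_rate, "frame_rate")
  as.integer(round(duration_s * frame_rate))
}

# Statistics helpers ----------------------------------------------------------

#' Holm–Šidák step-down adjustment of p-values
#'
#' Orders p ascending; adjusted p_(i) = 1 - (1 - p_(i))^(m - i + 1), enforced
#' monotone non-decreasing, returned in the original order.
#'
#' @param p numeric vector of raw p-values
#' @return adjusted p-values in the input order
#' @export
p_adjust_holm_sidak <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_invalid("`p` must be p-values in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Weighted variance (used by the kymograph orientation search).
weighted_var <- function(x, w) {
  ok <- w > 0
  x <- x[ok]; w <- w[ok]
  if (length(x) < 2L) return(0)
  mu <- sum(w * x) / sum(w)
  sum(w * (x - mu)^2) / sum(w)
}

fmt_num <- function(x) formatC(x, digits = 4, format = "g")
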