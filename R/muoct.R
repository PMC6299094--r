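# Functional metrics from B-scan time series: ASL/PCL depths, ciliary beat
# frequency, mucociliary transport rate.
#
# The source protocol measured depths "directly" (manual calipers); the
# operationalization here is: epithelium = maximum of the time-averaged depth
# profile; cilia-tip interface = top of the contiguous band of elevated
# temporal variance abutting the epithelium; air-mucus interface = shallowest
# row whose mean intensity exceeds background by a threshold fraction of the
# epithelial peak. Thresholds are arguments with documented defaults.

time_mean_image <- function(stack) colMeans(stack$frames, dims = 1)

time_var_image <- function(stack) {
  m1 <- colMeans(stack$frames, dims = 1)
  m2 <- colMeans(stack$frames^2, dims = 1)
  pmax(m2 - m1^2, 0)
}

# Per-row oscillation score: peak / median of the column-averaged temporal
# power spectrum inside the physiological frequency band. The ciliary band
# beats narrowband all the time, so its score is large; broadband noise
# averages to a flat spectrum (score ~ 1), and a transiting particulate
# spreads its power over many low harmonics. Raw temporal variance cannot
# separate these (noise clipping and particulate duty cycles both bias it).
row_oscillation_score <- function(stack, rows, search_band = c(2, 30)) {
  d <- dim(stack$frames)
  n <- d[1]
  freq <- (0:(n - 1)) * stack$frame_rate / n
  inb <- freq >= search_band[1] & freq <= search_band[2]
  pos <- freq > 0 & freq <= stack$frame_rate / 2
  vapply(rows, function(r) {
    X <- stack$frames[, r, ]
    X <- sweep(X, 2, colMeans(X))
    P <- rowMeans(Mod(stats::mvfft(X))^2)
    med <- stats::median(P[pos])
    if (max(P[inb]) <= 0) return(0)
    max(P[inb]) / (med + 1e-12 * max(P[inb]))
  }, numeric(1))
}

#' Measure airway-surface-liquid and periciliary layer depths
#'
#' @param stack an [image_stack()] of B-scans (depth x lateral per frame)
#' @param var_frac cilia-band threshold: fraction of the peak above-median
#'   oscillation-score excess a row must exceed to count as ciliary
#'   (default 0.2). The score is the narrowband peak-to-median temporal
#'   power ratio, which sees the always-on ciliary beat but neither
#'   broadband noise nor the brief transits of advected particulates.
#' @param intensity_frac air-mucus threshold: fraction of the
#'   background-to-epithelium intensity range (default 0.15)
#' @return list with `asl_depth` and `pcl_depth` (um), the interface row
#'   indices (`epithelial_row`, `cilia_tip_row`, `air_mucus_row`) and a
#'   per-metric `flags` character vector ("ok" or "unmeasurable")
#' @export
measure_layer_depths <- function(stack, var_frac = 0.2, intensity_frac = 0.15) {
  stopifnot(inherits(stack, "image_stack"))
  if (dim(stack$frames)[1] < 1L) stop_invalid("stack has no frames")
  ps <- stack$pixel_size
  mimg <- time_mean_image(stack)
  profile <- rowMeans(mimg)
  epi_row <- which.max(profile)
  flags <- c(asl = "ok", pcl = "ok")
  if (epi_row <= 1L)
    return(list(asl_depth = NA_real_, pcl_depth = NA_real_,
                epithelial_row = epi_row, cilia_tip_row = NA_integer_,
                air_mucus_row = NA_integer_,
                flags = c(asl = "unmeasurable", pcl = "unmeasurable")))
  above <- seq_len(epi_row - 1L)

  # PCL: contiguous run of oscillatory rows ending at the epithelium.
  score <- rep(0, epi_row)
  if (dim(stack$frames)[1] >= 8L) {
    score[above] <- row_oscillation_score(stack, above)
  }
  excess <- pmax(score - stats::median(score[above]), 0)
  vthr <- var_frac * max(excess[above])
  cilia_tip <- NA_integer_
  if (is.finite(vthr) && vthr > 0) {
    r <- epi_row - 1L
    while (r >= 1L && excess[r] > vthr) r <- r - 1L
    if (r < epi_row - 1L) cilia_tip <- r + 1L
  }
  if (is.na(cilia_tip)) flags["pcl"] <- "unmeasurable"
  pcl_depth <- if (is.na(cilia_tip)) NA_real_ else (epi_row - cilia_tip) * ps

  # ASL: shallowest row whose mean intensity clears background.
  bg <- min(profile[above])
  ithr <- bg + intensity_frac * (profile[epi_row] - bg)
  hit <- which(profile[above] > ithr)
  air_mucus <- if (length(hit)) hit[1] else NA_integer_
  if (is.na(air_mucus)) flags["asl"] <- "unmeasurable"
  asl_depth <- if (is.na(air_mucus)) NA_real_ else (epi_row - air_mucus) * ps

  list(asl_depth = asl_depth, pcl_depth = pcl_depth,
       epithelial_row = epi_row, cilia_tip_row = cilia_tip,
       air_mucus_row = air_mucus, flags = flags)
}

#' Estimate ciliary beat frequency by Fourier analysis
#'
#' Per-pixel reflectance time series within the ciliary band are
#' mean-detrended, Hann-windowed and periodogram-averaged across pixels
#' (Welch-style across space); the CBF is the frequency of maximum averaged
#' power inside the physiological search band.
#'
#' @param stack an [image_stack()]
#' @param band integer rows of the ciliary band; default the PCL detected by
#'   [measure_layer_depths()]
#' @param search_band frequency window in Hz (default 2–30)
#' @param snr_threshold minimum peak-to-median power ratio within the search
#'   band below which the metric is flagged unmeasurable (default 5)
#' @return list with `cbf` (Hz, NA if unmeasurable), `flag`, `resolution`
#'   (Hz, = frame_rate / n_frames), and `spectrum` (data.frame freq_hz, power)
#' @export
estimate_cbf <- function(stack, band = NULL, search_band = c(2, 30),
                         snr_threshold = 5) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (d[1] < 256L) stop_invalid("estimate_cbf needs >= 256 frames (got %d)", d[1])
  if (is.null(band)) {
    ld <- measure_layer_depths(stack)
    if (is.na(ld$cilia_tip_row))
      return(list(cbf = NA_real_, flag = "unmeasurable",
                  resolution = stack$frame_rate / d[1], spectrum = NULL))
    band <- ld$cilia_tip_row:(ld$epithelial_row - 1L)
  }
  n <- d[1]
  X <- matrix(stack$frames[, band, , drop = FALSE], nrow = n)
  X <- sweep(X, 2, colMeans(X))                 # detrend (remove DC)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hann
  P <- rowMeans(Mod(stats::mvfft(X * w))^2)     # averaged periodogram
  freq <- (0:(n - 1)) * stack$frame_rate / n
  inb <- which(freq >= search_band[1] & freq <= search_band[2])
  spec <- data.frame(freq_hz = freq[inb], power = P[inb])
  peak <- which.max(spec$power)
  snr <- spec$power[peak] / stats::median(spec$power)
  if (!is.finite(snr) || snr < snr_threshold)
    return(list(cbf = NA_real_, flag = "unmeasurable",
                resolution = stack$frame_rate / n, spectrum = spec))
  list(cbf = spec$freq_hz[peak], flag = "ok",
       resolution = stack$frame_rate / n, spectrum = spec)
}

#' Build a kymograph from the mucus band above the epithelium
#'
#' Per frame, intensities within the band up to `band_um` above the
#' epithelial surface are max-projected across depth onto the lateral axis;
#' projected rows are stacked in time order (one row per frame).
#'
#' @param stack an [image_stack()]
#' @param epithelial_row epithelial surface row, from [measure_layer_depths()]
#' @param band_um band height above the epithelium, um (default 50)
#' @return object of class `kymograph`: list(matrix time x lateral, `dt`
#'   s/row, `dx` um/column, `band` rows used)
#' @export
build_kymograph <- function(stack, epithelial_row, band_um = 50) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  epithelial_row <- assert_count(epithelial_row, "epithelial_row")
  r0 <- epithelial_row - round(band_um / stack$pixel_size)
  if (r0 < 1L || epithelial_row > d[2])
    stop_invalid("depth band [%d, %d] falls outside the image (1..%d)",
                 r0, epithelial_row - 1L, d[2])
  band <- r0:(epithelial_row - 1L)
  K <- apply(stack$frames[, band, , drop = FALSE], c(1, 3), max)
  structure(list(matrix = K, dt = 1 / stack$frame_rate,
                 dx = stack$pixel_size, band = band),
            class = "kymograph")
}

#' Estimate the mucociliary transport rate from a kymograph
#'
#' Streak orientation is found by maximizing the directional image variance
#' over a grid of projection angles (Radon-style binned projection); the rate
#' is `tan(best_angle) * dx / dt`. Confidence is the peak-to-median variance
#' ratio over the grid.
#'
#' @param kymo a [build_kymograph()] result (>= 10 rows)
#' @param angle_range degrees, default c(-80, 80)
#' @param angle_step grid step in degrees (<= 0.25; default 0.25)
#' @param confidence_threshold minimum peak/median variance ratio (default 2)
#' @return list with `mct_rate` (um/s, NA if unmeasurable), `angle_deg`,
#'   `confidence`, `flag`
#' @export
estimate_mct_rate <- function(kymo, angle_range = c(-80, 80),
                              angle_step = 0.25, confidence_threshold = 2) {
  stopifnot(inherits(kymo, "kymograph"))
  K <- kymo$matrix
  if (nrow(K) < 10L) stop_invalid("kymograph needs >= 10 rows (got %d)", nrow(K))
  if (angle_step > 0.25) stop_invalid("angle_step must be <= 0.25 degrees")
  K <- K - mean(K)
  nT <- nrow(K); nL <- ncol(K)
  i <- 0:(nT - 1)
  jmat <- matrix(rep(0:(nL - 1), each = nT), nT, nL)
  kv <- as.vector(K)
  angles <- seq(angle_range[1], angle_range[2], by = angle_step)
  vars <- vapply(angles, function(a) {
    s <- tan(a * pi / 180)
    bin <- as.integer(round(jmat - s * i))      # recycled down columns
    bin <- bin - min(bin) + 1L
    cnt <- tabulate(bin)
    tot <- rowsum(kv, bin)
    weighted_var(tot[, 1] / cnt[cnt > 0], cnt[cnt > 0])
  }, numeric(1))
  best <- which.max(vars)
  confidence <- vars[best] / stats::median(vars)
  if (!is.finite(confidence) || confidence < confidence_threshold)
    return(list(mct_rate = NA_real_, angle_deg = NA_real_,
                confidence = confidence, flag = "unmeasurable"))
  slope <- tan(angles[best] * pi / 180)         # columns per row = px/frame
  list(mct_rate = slope * kymo$dx / kymo$dt, angle_deg = angles[best],
       confidence = confidence, flag = "ok")
}

#' All four functional metrics from one B-scan stack
#'
#' Convenience driver: layer depths, CBF (over the detected ciliary band) and
#' MCT rate (kymograph over the 50 um band above the epithelium).
#'
#' @param stack an [image_stack()]
#' @param roi_id identifier carried into the output row
#' @return one-row data.frame: `roi_id`, `asl_depth_um`, `pcl_depth_um`,
#'   `mucus_depth_um`, `cbf_hz`, `mct_rate_um_s` plus per-metric flags
#' @export
muoct_metrics <- function(stack, roi_id = "roi1") {
  ld <- measure_layer_depths(stack)
  cb <- estimate_cbf(stack)
  mct <- list(mct_rate = NA_real_, flag = "unmeasurable")
  if (!is.na(ld$epithelial_row)) {
    km <- tryCatch(build_kymograph(stack, ld$epithelial_row),
                   error = function(e) NULL)
    if (!is.null(km)) mct <- estimate_mct_rate(km)
  }
  data.frame(roi_id = roi_id,
             asl_depth_um = ld$asl_depth, pcl_depth_um = ld$pcl_depth,
             mucus_depth_um = ld$asl_depth - ld$pcl_depth,
             cbf_hz = cb$cbf, mct_rate_um_s = mct$mct_rate,
             flag_asl = ld$flags[["asl"]], flag_pcl = ld$flags[["pcl"]],
             flag_cbf = cb$flag, flag_mct = mct$flag,
             stringsAsFactors = FALSE)
}
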