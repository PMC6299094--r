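# Synthetic microbead trajectories and rendered movies.
#
# The generative model matches what passive microrheology assumes: per-axis
# increments are stationary Gaussian with E[dr^2(tau)] = 4 D (tau dt)^alpha in
# 2-D. alpha = 1 gives ordinary Brownian motion (iid increments of variance
# 2 D dt per axis); alpha != 1 gives fractional Gaussian increments with
# Hurst index alpha/2, the standard viscoelastic null. Optional linear drift
# adds v dt per frame, and localization noise adds iid Gaussian jitter to
# every stored coordinate.

#' Trajectory set
#'
#' Tidy container for per-bead, time-ordered 2-D positions: one row per
#' (bead, frame), columns `bead_id`, `frame`, `t_s`, `x_um`, `y_um`.
#' `dt` and any generating [ground_truth()] ride along as attributes.
#'
#' @param df data.frame with the five columns above
#' @param dt frame interval in seconds
#' @param truth optional [ground_truth()]
#' @return object of class `trajectory_set` (a data.frame)
#' @export
trajectory_set <- function(df, dt, truth = NULL) {
  need <- c("bead_id", "frame", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop_invalid("trajectory data must have columns %s", paste(need, collapse = ", "))
  assert_positive(dt, "dt")
  structure(as.data.frame(df), dt = dt, ground_truth = truth,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d beads, %d rows, dt = %g s\n",
              length(unique(x$bead_id)), nrow(x), attr(x, "dt")))
  invisible(x)
}

split_beads <- function(ts) split(as.data.frame(ts), ts$bead_id)

#' Write / read trajectories as CSV
#'
#' Columns `bead_id, frame, t_s, x_um, y_um`; `dt` is recoverable from `t_s`.
#'
#' @param ts a [trajectory_set()]
#' @param path CSV file path
#' @return `path` (write) or a [trajectory_set()] (read)
#' @export
write_trajectories <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  dts <- diff(sort(unique(df$t_s)))
  trajectory_set(df, dt = if (length(dts)) min(dts) else 1)
}

# fGn increment covariance at integer lag k, per axis:
# gamma(k) = D dt^alpha (|k+1|^a - 2|k|^a + |k-1|^a); gamma(0) = 2 D dt^alpha.
fgn_autocov <- function(k, D, dt, alpha) {
  D * dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha + abs(k - 1)^alpha)
}

# m x n matrix of fractional Gaussian increments (columns independent).
fgn_increments <- function(m, n, D, dt, alpha) {
  if (D == 0) return(matrix(0, m, n))
  if (alpha == 1) return(matrix(stats::rnorm(m * n, sd = sqrt(2 * D * dt)), m, n))
  if (alpha == 2) {
    # Perfectly persistent limit: one velocity draw per column.
    v <- stats::rnorm(n, sd = sqrt(2 * D) * dt)
    return(matrix(rep(v, each = m), m, n))
  }
  C <- stats::toeplitz(fgn_autocov(0:(m - 1), D, dt, alpha))
  R <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-10 * C[1, 1], m)))
  crossprod(R, matrix(stats::rnorm(m * n), m, n))
}

#' Simulate 2-D bead trajectories with known ground truth
#'
#' Brownian or fractional-Gaussian bead motion with optional linear drift and
#' localization noise; the generating parameters are attached as a
#' [ground_truth()]. Identical seeds reproduce identical output.
#'
#' @param n_beads number of beads (>= 1)
#' @param n_frames frames per trajectory (>= 2)
#' @param dt frame interval, seconds
#' @param diffusion_coeff D, um^2/s
#' @param anomalous_exponent alpha in (0, 2]; 1 = Brownian
#' @param drift_velocity 2-vector (vx, vy), um/s
#' @param localization_sigma static localization error sd, um
#' @param seed RNG seed (required)
#' @param origins optional `n_beads` x 2 matrix of starting positions (um);
#'   default all at the origin
#' @return a [trajectory_set()] with the truth attached
#' @export
simulate_trajectories <- function(n_beads, n_frames, dt, diffusion_coeff,
                                  anomalous_exponent = 1,
                                  drift_velocity = c(0, 0),
                                  localization_sigma = 0, seed,
                                  origins = NULL) {
  n_beads <- assert_count(n_beads, "n_beads")
  n_frames <- assert_count(n_frames, "n_frames", min = 2L)
  assert_positive(dt, "dt")
  assert_non_negative(diffusion_coeff, "diffusion_coeff")
  assert_scalar_number(anomalous_exponent, "anomalous_exponent")
  if (anomalous_exponent <= 0 || anomalous_exponent > 2)
    stop_invalid("anomalous_exponent must lie in (0, 2]")
  if (length(drift_velocity) != 2L || any(!is.finite(drift_velocity)))
    stop_invalid("drift_velocity must be a finite 2-vector (um/s)")
  assert_non_negative(localization_sigma, "localization_sigma")
  seed <- assert_seed(seed)
  if (is.null(origins)) origins <- matrix(0, n_beads, 2)
  origins <- matrix(origins, ncol = 2)
  if (nrow(origins) != n_beads) stop_invalid("`origins` must be n_beads x 2")

  m <- n_frames - 1L
  tt <- (seq_len(n_frames) - 1L) * dt
  pos <- with_seed(seed, {
    dx <- fgn_increments(m, n_beads, diffusion_coeff, dt, anomalous_exponent)
    dy <- fgn_increments(m, n_beads, diffusion_coeff, dt, anomalous_exponent)
    x <- rbind(0, apply(dx, 2, cumsum)) +
      outer(tt, rep(drift_velocity[1], n_beads)) +
      matrix(origins[, 1], n_frames, n_beads, byrow = TRUE)
    y <- rbind(0, apply(dy, 2, cumsum)) +
      outer(tt, rep(drift_velocity[2], n_beads)) +
      matrix(origins[, 2], n_frames, n_beads, byrow = TRUE)
    if (localization_sigma > 0) {
      x <- x + matrix(stats::rnorm(n_frames * n_beads, sd = localization_sigma),
                      n_frames, n_beads)
      y <- y + matrix(stats::rnorm(n_frames * n_beads, sd = localization_sigma),
                      n_frames, n_beads)
    }
    list(x = x, y = y)
  })

  truth <- ground_truth(
    diffusion_coeff = diffusion_coeff,
    anomalous_exponent = anomalous_exponent,
    drift_velocity = drift_velocity,
    localization_sigma = localization_sigma,
    seed = seed)
  df <- data.frame(
    bead_id = rep(seq_len(n_beads), each = n_frames),
    frame = rep(seq_len(n_frames), n_beads),
    t_s = rep(tt, n_beads),
    x_um = as.vector(pos$x),
    y_um = as.vector(pos$y))
  trajectory_set(df, dt = dt, truth = truth)
}

#' Render a trajectory set as a synthetic fluorescence movie
#'
#' Each frame is a sum of isotropic Gaussian spots centred at that frame's
#' bead positions (um -> pixel via `pixel_size`; pixel i spans
#' `[(i-1), i] * pixel_size`, so continuous pixel coordinate =
#' position/pixel_size + 0.5) plus additive Gaussian noise clipped at zero.
#'
#' @param trajectories a [trajectory_set()]
#' @param image_shape c(rows, cols) in pixels
#' @param psf_sigma Gaussian spot sd, pixels
#' @param peak_intensity spot peak, arbitrary units
#' @param background_noise_sigma additive noise sd, arbitrary units
#' @param pixel_size um per pixel
#' @param seed RNG seed for the noise
#' @return an [image_stack()]; metadata records the generating truth
#' @export
render_bead_movie <- function(trajectories, image_shape, psf_sigma,
                              peak_intensity, background_noise_sigma,
                              pixel_size, seed) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  image_shape <- c(assert_count(image_shape[1], "image_shape[1]"),
                   assert_count(image_shape[2], "image_shape[2]"))
  assert_positive(psf_sigma, "psf_sigma")
  assert_positive(peak_intensity, "peak_intensity")
  assert_non_negative(background_noise_sigma, "background_noise_sigma")
  assert_positive(pixel_size, "pixel_size")
  seed <- assert_seed(seed)

  df <- as.data.frame(trajectories)
  col <- df$x_um / pixel_size + 0.5
  row <- df$y_um / pixel_size + 0.5
  bad <- which(col < 0.5 | col > image_shape[2] + 0.5 |
               row < 0.5 | row > image_shape[1] + 0.5)
  if (length(bad)) {
    stop_invalid("position out of frame: bead %s at frame %d (%.2f, %.2f px)",
                 df$bead_id[bad[1]], df$frame[bad[1]], col[bad[1]], row[bad[1]])
  }
  frames_idx <- sort(unique(df$frame))
  n_frames <- length(frames_idx)
  half <- ceiling(4 * psf_sigma)
  frames <- array(0, dim = c(n_frames, image_shape[1], image_shape[2]))
  by_frame <- split(seq_len(nrow(df)), df$frame)
  for (t in seq_len(n_frames)) {
    img <- matrix(0, image_shape[1], image_shape[2])
    for (i in by_frame[[as.character(frames_idx[t])]]) {
      r0 <- max(1L, floor(row[i]) - half); r1 <- min(image_shape[1], floor(row[i]) + half)
      c0 <- max(1L, floor(col[i]) - half); c1 <- min(image_shape[2], floor(col[i]) + half)
      rr <- r0:r1; cc <- c0:c1
      img[rr, cc] <- img[rr, cc] + peak_intensity *
        exp(-(outer((rr - row[i])^2, (cc - col[i])^2, "+")) / (2 * psf_sigma^2))
    }
    frames[t, , ] <- img
  }
  if (background_noise_sigma > 0) {
    frames <- with_seed(seed, {
      frames + array(stats::rnorm(length(frames), sd = background_noise_sigma),
                     dim = dim(frames))
    })
    frames[frames < 0] <- 0
  }
  dt <- attr(trajectories, "dt")
  image_stack(frames, pixel_size = pixel_size, frame_rate = 1 / dt,
              metadata = list(seed = seed,
                              n_beads = length(unique(df$bead_id)),
                              psf_sigma = psf_sigma,
                              ground_truth = attr(trajectories, "ground_truth")))
}

#' Default microbead acquisition settings
#'
#' The fixture acquisition: 30 s movies at 60 frames/s (N = 1800 frames),
#' 1 um beads.
#'
#' @return list with `duration_s`, `frame_rate`, `n_frames`, `dt`,
#'   `bead_diameter_um`
#' @export
microrheology_defaults <- function() {
  list(duration_s = 30, frame_rate = 60,
       n_frames = n_frames_for(30, 60), dt = 1 / 60,
       bead_diameter_um = 1)
}
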