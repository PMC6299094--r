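# Synthetic B-scan time series emulating micro-OCT of the airway surface.
#
# The phantom is a 2-D (depth x lateral) intensity model per frame: from the
# bottom, a bright epithelial surface line; a periciliary band of thickness
# pcl_depth whose reflectance oscillates sinusoidally at the ciliary beat
# frequency; a mucus layer completing the airway-surface-liquid thickness to
# asl_depth; and bright particulates inside the mucus advected laterally at
# the transport rate (wrapping at the frame edge). Speckle is approximated by
# additive Gaussian noise clipped at zero — enough to exercise the
# estimators, not an optics simulation.

# Nominal phantom intensities (arbitrary units). The analyzers make no use of
# these constants; they only assume epithelium > mucus > background.
.muoct_levels <- list(epithelium = 200, submucosa = 80, mucus = 70,
                      pcl_base = 60, pcl_amplitude = 40, particulate = 150)

#' Simulate a micro-OCT B-scan time series with known ground truth
#'
#' @param asl_depth airway-surface-liquid depth (air interface to epithelium), um
#' @param pcl_depth periciliary layer depth, um; `asl_depth >= pcl_depth >= 0`
#' @param cbf ciliary beat frequency, Hz; must be below `frame_rate / 2`
#' @param mct_rate mucociliary transport rate, um/s (sign = direction)
#' @param frame_rate frames per second (nominally 100)
#' @param n_frames number of frames
#' @param lines_per_frame lateral A-lines per frame (nominally 256)
#' @param pixel_size um per pixel (isotropic)
#' @param noise_sigma additive noise sd, arbitrary units
#' @param seed RNG seed
#' @param n_particulates number of advected mucus particulates
#' @return an [image_stack()] with the [ground_truth()] in its metadata
#' @export
simulate_muoct_stack <- function(asl_depth, pcl_depth, cbf, mct_rate,
                                 frame_rate = 100, n_frames = 512,
                                 lines_per_frame = 256, pixel_size = 1,
                                 noise_sigma = 0, seed,
                                 n_particulates = max(3L, lines_per_frame %/% 32L)) {
  assert_non_negative(asl_depth, "asl_depth")
  assert_non_negative(pcl_depth, "pcl_depth")
  if (asl_depth < pcl_depth)
    stop_invalid("asl_depth (%g) must be >= pcl_depth (%g)", asl_depth, pcl_depth)
  assert_non_negative(cbf, "cbf")
  assert_positive(frame_rate, "frame_rate")
  if (cbf >= frame_rate / 2)
    stop_invalid("cbf (%g Hz) must be below the Nyquist limit %g Hz",
                 cbf, frame_rate / 2)
  assert_scalar_number(mct_rate, "mct_rate")
  n_frames <- assert_count(n_frames, "n_frames", min = 2L)
  lines_per_frame <- assert_count(lines_per_frame, "lines_per_frame", min = 8L)
  assert_positive(pixel_size, "pixel_size")
  assert_non_negative(noise_sigma, "noise_sigma")
  seed <- assert_seed(seed)

  lv <- .muoct_levels
  pcl_px <- as.integer(round(pcl_depth / pixel_size))
  asl_px <- as.integer(round(asl_depth / pixel_size))
  n_above <- as.integer(max(ceiling(50 / pixel_size), asl_px)) + 4L
  n_depth <- n_above + 4L
  epi_row <- n_above + 1L
  lat <- lines_per_frame

  base <- matrix(0, n_depth, lat)
  base[epi_row, ] <- lv$epithelium
  if (epi_row < n_depth) base[(epi_row + 1L):n_depth, ] <- lv$submucosa
  mucus_rows <- if (asl_px > pcl_px) (epi_row - asl_px):(epi_row - pcl_px - 1L) else integer(0)
  if (length(mucus_rows)) base[mucus_rows, ] <- lv$mucus
  pcl_rows <- if (pcl_px > 0) (epi_row - pcl_px):(epi_row - 1L) else integer(0)

  # Particulates live in the mucus layer; lateral advection wraps.
  have_particles <- length(mucus_rows) > 0 && n_particulates > 0
  frames <- with_seed(seed, {
    if (have_particles) {
      p_row <- sample(mucus_rows, n_particulates, replace = TRUE)
      p_col0 <- stats::runif(n_particulates, 1, lat)
    }
    lateral_phase <- 0.3 * seq_len(lat)  # fixed phase ramp across the surface
    step_px <- mct_rate / frame_rate / pixel_size
    arr <- array(0, dim = c(n_frames, n_depth, lat))
    for (t in seq_len(n_frames)) {
      img <- base
      if (length(pcl_rows)) {
        osc <- lv$pcl_base + lv$pcl_amplitude *
          sin(2 * pi * cbf * (t - 1) / frame_rate + lateral_phase)
        img[pcl_rows, ] <- matrix(osc, length(pcl_rows), lat, byrow = TRUE)
      }
      if (have_particles) {
        cols <- ((p_col0 + (t - 1) * step_px - 1) %% lat) + 1
        for (p in seq_len(n_particulates)) {
          cc <- (round(cols[p]) + (-2:2) - 1) %% lat + 1
          w <- exp(-((-2:2) + round(cols[p]) - cols[p])^2 / (2 * 1.2^2))
          rr <- p_row[p] + (-1:1)
          rr_ok <- rr >= 1 & rr <= n_depth
          img[rr[rr_ok], cc] <- img[rr[rr_ok], cc] +
            lv$particulate * outer(exp(-(-1:1)[rr_ok]^2 / (2 * 1.2^2)), w)
        }
      }
      arr[t, , ] <- img
    }
    if (noise_sigma > 0) {
      arr <- arr + array(stats::rnorm(length(arr), sd = noise_sigma), dim = dim(arr))
      arr[arr < 0] <- 0
    }
    arr
  })

  truth <- ground_truth(asl_depth = asl_px * pixel_size,
                        pcl_depth = pcl_px * pixel_size,
                        cbf = cbf, mct_rate = mct_rate, seed = seed)
  image_stack(frames, pixel_size = pixel_size, frame_rate = frame_rate,
              metadata = list(seed = seed, epithelial_row = epi_row,
                              ground_truth = truth))
}
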