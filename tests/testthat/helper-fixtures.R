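# Shared fixture builders. Everything is generated in code at test time.

# n starting positions on a grid with a safety margin, inside a box of
# side_um micrometres.
grid_origins <- function(n, side_um, margin_um) {
  per <- ceiling(sqrt(n))
  g <- seq(margin_um, side_um - margin_um, length.out = per)
  as.matrix(expand.grid(x = g, y = g))[seq_len(n), , drop = FALSE]
}

# Simulate + render + track one small bead movie; returns the linked set.
chain_movie_tracks <- function(n_beads, n_frames, D, drift, seed,
                               pixel_size = 0.3, side_px = 104,
                               noise = 4, loc_sigma = 0) {
  side_um <- side_px * pixel_size
  ts <- simulate_trajectories(
    n_beads, n_frames, dt = 1 / 60, diffusion_coeff = D,
    drift_velocity = drift, localization_sigma = loc_sigma, seed = seed,
    origins = grid_origins(n_beads, side_um, margin_um = 6))
  mv <- render_bead_movie(ts, c(side_px, side_px), psf_sigma = 1.2,
                          peak_intensity = 100, background_noise_sigma = noise,
                          pixel_size = pixel_size, seed = seed + 1L)
  detect_and_link(mv, expected_diameter = 7, intensity_percentile = 99,
                  max_displacement = 4, min_length = max(10L, n_frames - 20L))
}

# Hand-built B-scan stack: bright epithelium at `epi_row`, a sinusoidal band,
# everything else dark. For CBF tests that want full control of the signal.
sinusoid_stack <- function(n_frames, freqs, amps, band_rows = 10:12,
                           epi_row = 16, n_depth = 20, n_lat = 32,
                           frame_rate = 100, offset = 50) {
  arr <- array(0, dim = c(n_frames, n_depth, n_lat))
  tt <- (seq_len(n_frames) - 1) / frame_rate
  sig <- offset + rowSums(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * tt), numeric(n_frames)))
  for (r in band_rows) arr[, r, ] <- sig
  arr[, epi_row, ] <- 200
  image_stack(arr, pixel_size = 1, frame_rate = frame_rate)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / abs(y), tol)
}
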