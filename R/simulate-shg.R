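# Synthetic second-harmonic-generation fields: oriented thick fiber segments
# on a dark background, blurred and noised, with the true foreground mask
# kept so area-fraction estimators can be scored against ground truth.

draw_segment <- function(mask, length_px, width_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
  th <- stats::runif(1, 0, pi)
  ux <- cos(th); uy <- sin(th)
  half <- length_px / 2
  x0 <- cx - half * ux; y0 <- cy - half * uy
  x1 <- cx + half * ux; y1 <- cy + half * uy
  r0 <- max(1L, floor(min(y0, y1) - width_px)); r1 <- min(nr, ceiling(max(y0, y1) + width_px))
  c0 <- max(1L, floor(min(x0, x1) - width_px)); c1 <- min(nc, ceiling(max(x0, x1) + width_px))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  px <- matrix(rep(cc, each = length(rr)), length(rr))
  py <- matrix(rep(rr, length(cc)), length(rr))
  # distance from pixel centres to the segment
  vx <- x1 - x0; vy <- y1 - y0
  tproj <- ((px - x0) * vx + (py - y0) * vy) / (vx^2 + vy^2)
  tproj <- pmin(pmax(tproj, 0), 1)
  d2 <- (px - (x0 + tproj * vx))^2 + (py - (y0 + tproj * vy))^2
  sub <- mask[rr, cc]
  sub[d2 <= (width_px / 2)^2] <- TRUE
  mask[rr, cc] <- sub
  mask
}

blur3 <- function(img) {
  k <- c(0.25, 0.5, 0.25)
  pad <- rbind(img[1, ], img, img[nrow(img), ])
  v <- k[1] * pad[1:nrow(img), ] + k[2] * pad[2:(nrow(img) + 1), ] +
    k[3] * pad[3:(nrow(img) + 2), ]
  pad <- cbind(v[, 1], v, v[, ncol(v)])
  k[1] * pad[, 1:ncol(img)] + k[2] * pad[, 2:(ncol(img) + 1)] +
    k[3] * pad[, 3:(ncol(img) + 2)]
}

#' Simulate a set of SHG collagen fields with known area fractions
#'
#' Each field's true foreground fraction is drawn from
#' `Normal(collagen_fraction, between_field_sd)` truncated to \[0, 100\];
#' oriented thick segments are added until the mask reaches that fraction,
#' then the signal is blurred and Gaussian noise added. Truth masks are kept.
#'
#' @param n_fields number of fields (>= 1)
#' @param collagen_fraction target mean foreground percentage in \[0, 100\]
#' @param fiber_count nominal fibers per field (sets segment length)
#' @param fiber_width fiber width in pixels
#' @param image_shape c(rows, cols), default c(128, 128)
#' @param between_field_sd field-to-field sd of the true fraction, percentage
#'   points
#' @param noise_sigma additive noise sd (signal level is 150 a.u.)
#' @param seed RNG seed
#' @return object of class `shg_field_set`: list of `fields` (matrices),
#'   `masks` (logical truth), `true_fractions` (%), and the [ground_truth()]
#' @export
simulate_shg_field_set <- function(n_fields, collagen_fraction, fiber_count = 12,
                                   fiber_width = 3, image_shape = c(128, 128),
                                   between_field_sd = 0, noise_sigma = 10,
                                   seed) {
  n_fields <- assert_count(n_fields, "n_fields")
  assert_scalar_number(collagen_fraction, "collagen_fraction")
  if (collagen_fraction < 0 || collagen_fraction > 100)
    stop_invalid("collagen_fraction must lie in [0, 100]")
  fiber_count <- assert_count(fiber_count, "fiber_count")
  assert_positive(fiber_width, "fiber_width")
  assert_non_negative(between_field_sd, "between_field_sd")
  assert_non_negative(noise_sigma, "noise_sigma")
  seed <- assert_seed(seed)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  npix <- nr * nc

  signal <- 150
  out <- with_seed(seed, {
    fields <- vector("list", n_fields)
    masks <- vector("list", n_fields)
    truef <- numeric(n_fields)
    for (f in seq_len(n_fields)) {
      target <- collagen_fraction
      if (between_field_sd > 0)
        target <- min(100, max(0, stats::rnorm(1, collagen_fraction, between_field_sd)))
      mask <- matrix(FALSE, nr, nc)
      if (target >= 100) {
        mask[] <- TRUE
      } else if (target > 0) {
        seg_len <- (target / 100 * npix) / fiber_count / fiber_width
        if (seg_len < 1)
          stop_invalid(paste("infeasible fraction for given fiber geometry:",
                             "segment length %.2f px < 1"), seg_len)
        per_fiber_pp <- 100 * seg_len * fiber_width / npix
        for (i in seq_len(50L * fiber_count)) {
          gap <- target - 100 * mean(mask)
          if (gap <= 0) break
          # shorten the closing fiber so the mask does not overshoot target
          mask <- draw_segment(mask, seg_len * min(1, gap / per_fiber_pp),
                               fiber_width)
        }
      }
      truef[f] <- 100 * mean(mask)
      img <- blur3(mask * signal)
      if (noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(npix, sd = noise_sigma), nr, nc)
        img[img < 0] <- 0
      }
      fields[[f]] <- img
      masks[[f]] <- mask
    }
    list(fields = fields, masks = masks, truef = truef)
  })

  structure(list(fields = out$fields, masks = out$masks,
                 true_fractions = out$truef,
                 ground_truth = ground_truth(
                   collagen_fraction = collagen_fraction,
                   between_field_sd = between_field_sd, seed = seed)),
            class = "shg_field_set")
}

#' @export
print.shg_field_set <- function(x, ...) {
  cat(sprintf("<shg_field_set> %d fields, true fraction %.1f%% (mean)\n",
              length(x$fields), mean(x$true_fractions)))
  invisible(x)
}

#' Systematic uniform random sampling of imaging fields
#'
#' Random start, fixed stride over the serialized grid (row-major), the
#' standard stereological design: every grid position has the same inclusion
#' probability `n_fields / total`.
#'
#' @param grid_shape c(rows, cols) of candidate field positions
#' @param n_fields number of fields to sample (<= total positions)
#' @param seed RNG seed
#' @return data.frame with `index`, `row`, `col`
#' @export
sample_fields_uniform <- function(grid_shape, n_fields, seed) {
  nr <- assert_count(grid_shape[1], "grid_shape[1]")
  nc <- assert_count(grid_shape[2], "grid_shape[2]")
  n_fields <- assert_count(n_fields, "n_fields")
  total <- nr * nc
  if (n_fields > total)
    stop_invalid("n_fields (%d) exceeds grid positions (%d)", n_fields, total)
  seed <- assert_seed(seed)
  stride <- total %/% n_fields
  start <- with_seed(seed, sample.int(stride, 1L))
  idx <- start + stride * (seq_len(n_fields) - 1L)
  data.frame(index = idx,
             row = (idx - 1L) %/% nc + 1L,
             col = (idx - 1L) %% nc + 1L)
}
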