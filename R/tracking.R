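# Spot detection and frame-to-frame linking for bead movies.
#
# Detection: local maxima above an intensity percentile, refined to
# sub-pixel centroids on a background-subtracted window. Linking: greedy
# nearest-neighbour assignment within a per-step displacement bound, with
# optional gap memory; gapped frames are filled by linear interpolation so
# downstream lag arithmetic sees uniform sampling. Optimal (Hungarian)
# assignment is deliberately out of scope at fixture densities.

local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & img >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  ok
}

detect_spots <- function(img, expected_diameter, intensity_percentile) {
  thr <- stats::quantile(img, intensity_percentile / 100, names = FALSE)
  cand <- which(local_maxima(img) & img > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  # Non-maximum suppression within one spot diameter, brightest first.
  o <- order(img[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep)) {
      d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
      if (min(d2) < expected_diameter^2) next
    }
    keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]
  w <- (expected_diameter - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(cand), 2)
  for (i in seq_len(nrow(cand))) {
    rr <- max(1L, cand[i, 1] - w):min(nrow(img), cand[i, 1] + w)
    cc <- max(1L, cand[i, 2] - w):min(ncol(img), cand[i, 2] + w)
    patch <- img[rr, cc, drop = FALSE] - min(img[rr, cc])
    m <- sum(patch)
    if (m <= 0) { out[i, ] <- cand[i, ]; next }
    out[i, 1] <- sum(rowSums(patch) * rr) / m
    out[i, 2] <- sum(colSums(patch) * cc) / m
  }
  colnames(out) <- c("row", "col")
  out
}

#' Detect beads and link them into trajectories
#'
#' @param movie an [image_stack()] bead movie
#' @param expected_diameter odd spot diameter in pixels (>= 3)
#' @param intensity_percentile detection threshold percentile (default 95)
#' @param max_displacement maximum per-step link distance, pixels (>= 1)
#' @param memory frames a bead may vanish and still be re-linked (default 0)
#' @param min_length trajectories shorter than this are dropped (default 10)
#' @return a [trajectory_set()] with positions in um
#' @export
detect_and_link <- function(movie, expected_diameter, intensity_percentile = 95,
                            max_displacement, memory = 0L, min_length = 10L) {
  stopifnot(inherits(movie, "image_stack"))
  d <- dim(movie$frames)
  if (d[1] < 1L) stop_invalid("movie has no frames")
  expected_diameter <- assert_count(expected_diameter, "expected_diameter", min = 3L)
  if (expected_diameter %% 2L == 0L)
    stop_invalid("expected_diameter must be odd")
  assert_scalar_number(max_displacement, "max_displacement")
  if (max_displacement < 1) stop_invalid("max_displacement must be >= 1 pixel")
  memory <- assert_count(memory, "memory", min = 0L)
  min_length <- assert_count(min_length, "min_length", min = 1L)

  tracks <- list()  # each: list(rows, cols, frames, last_row, last_col, last_frame)
  n_det <- 0L
  for (t in seq_len(d[1])) {
    det <- detect_spots(movie$frames[t, , ], expected_diameter,
                        intensity_percentile)
    n_det <- n_det + nrow(det)
    if (nrow(det) == 0L) next
    active <- which(vapply(tracks, function(tr) t - tr$last_frame <= memory + 1L,
                           logical(1)))
    assigned_det <- rep(FALSE, nrow(det))
    if (length(active)) {
      lr <- vapply(tracks[active], `[[`, numeric(1), "last_row")
      lc <- vapply(tracks[active], `[[`, numeric(1), "last_col")
      D <- sqrt(outer(lr, det[, 1], "-")^2 + outer(lc, det[, 2], "-")^2)
      ord <- order(D)
      used_tr <- rep(FALSE, length(active))
      for (idx in ord) {
        if (D[idx] > max_displacement) break
        ti <- (idx - 1L) %% length(active) + 1L
        di <- (idx - 1L) %/% length(active) + 1L
        if (used_tr[ti] || assigned_det[di]) next
        k <- active[ti]
        tracks[[k]]$rows <- c(tracks[[k]]$rows, det[di, 1])
        tracks[[k]]$cols <- c(tracks[[k]]$cols, det[di, 2])
        tracks[[k]]$frames <- c(tracks[[k]]$frames, t)
        tracks[[k]]$last_row <- det[di, 1]
        tracks[[k]]$last_col <- det[di, 2]
        tracks[[k]]$last_frame <- t
        used_tr[ti] <- TRUE; assigned_det[di] <- TRUE
      }
    }
    for (di in which(!assigned_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        rows = det[di, 1], cols = det[di, 2], frames = t,
        last_row = det[di, 1], last_col = det[di, 2], last_frame = t)
    }
  }
  if (n_det == 0L) warning("no spots detected; returning an empty trajectory set")

  dt <- 1 / movie$frame_rate
  ps <- movie$pixel_size
  rows <- list()
  bead <- 0L
  for (tr in tracks) {
    if (length(tr$frames) < min_length) next
    bead <- bead + 1L
    fr <- tr$frames[1]:tr$frames[length(tr$frames)]
    # fill gaps by linear interpolation (only present when memory > 0)
    r <- stats::approx(tr$frames, tr$rows, xout = fr)$y
    cl <- stats::approx(tr$frames, tr$cols, xout = fr)$y
    rows[[bead]] <- data.frame(
      bead_id = bead, frame = fr, t_s = (fr - 1L) * dt,
      x_um = (cl - 0.5) * ps, y_um = (r - 0.5) * ps)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bead_id = integer(0), frame = integer(0), t_s = numeric(0),
               x_um = numeric(0), y_um = numeric(0))
  trajectory_set(df, dt = dt, truth = movie$metadata$ground_truth)
}
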