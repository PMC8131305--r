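#' Pyramidal KLT tracker parameters
#'
#' @param window_px side of the square tracking window (odd, >= 5).
#' @param pyramid_levels number of pyramid levels (>= 1).
#' @param max_iterations iteration cap per level.
#' @param convergence_eps_px stop when the update falls below this (px).
#' @param fb_error_max_px forward-backward validation bound: a marker is
#'   invalidated when re-tracking it backwards misses its origin by more
#'   than this distance.
#' @return An object of class `klt_params`.
#' @export
klt_params <- function(window_px = 21, pyramid_levels = 3,
                       max_iterations = 30, convergence_eps_px = 0.01,
                       fb_error_max_px = 1.0) {
  if (window_px < 5 || window_px %% 2 == 0)
    stopf("window_px must be odd and >= 5")
  if (pyramid_levels < 1) stopf("pyramid_levels must be >= 1")
  if (fb_error_max_px <= 0) stopf("fb_error_max_px must be > 0")
  structure(list(window_px = as.integer(window_px),
                 pyramid_levels = as.integer(pyramid_levels),
                 max_iterations = as.integer(max_iterations),
                 convergence_eps_px = convergence_eps_px,
                 fb_error_max_px = fb_error_max_px), class = "klt_params")
}

build_pyramid <- function(frame, levels) {
  p <- vector("list", levels)
  p[[1]] <- frame
  for (l in seq_len(levels - 1)) p[[l + 1]] <- cpp_downsample2(p[[l]])
  p
}

#' Track markers through a sequence with pyramidal KLT
#'
#' Iterative Lucas-Kanade over an image pyramid. Each marker is anchored
#' to its template in the track-start frame: in every new frame the
#' solver starts from the marker's previous position and registers the
#' birth-frame window to the current frame, so frame-to-frame random-walk
#' drift cannot accumulate. Forward-backward validation re-tracks the
#' found position back to the template frame and invalidates the marker
#' when the round trip misses its origin by more than `fb_error_max_px`
#' (or when its window leaves the frame). Once lost, a marker stays lost
#' (until a re-detection event at the pipeline level). Deterministic.
#'
#' @param seq a (stabilized) [frame_sequence()].
#' @param markers a `marker_set` from [select_markers()].
#' @param params a [klt_params()].
#' @param error_on_total_loss raise a tracking-failure error naming the
#'   frame when every marker is lost (default TRUE).
#' @return Object of class `trajectory_set`: matrices `x`, `y` (frames x
#'   markers, sub-pixel positions), logical `valid`, `baseline` (the
#'   input marker set), `fps`, `timestamps`.
#' @export
track_markers <- function(seq, markers, params = klt_params(),
                          error_on_total_loss = TRUE) {
  if (nrow(markers) < 1) stopf("need at least one marker to track")
  n <- length(seq$frames)
  m <- nrow(markers)
  X <- matrix(NA_real_, n, m); Y <- matrix(NA_real_, n, m)
  V <- matrix(FALSE, n, m)
  X[1, ] <- markers$x; Y[1, ] <- markers$y; V[1, ] <- TRUE
  hw <- (params$window_px - 1L) %/% 2L
  dims <- frame_dim(seq)
  pyr0 <- build_pyramid(seq$frames[[1]], params$pyramid_levels)
  base <- cbind(markers$x, markers$y)
  for (t in seq_len(n - 1)) {
    pyrJ <- build_pyramid(seq$frames[[t + 1]], params$pyramid_levels)
    act <- which(V[t, ])
    if (length(act) == 0) {
      if (error_on_total_loss)
        stopf("all markers lost at frame %d", t, class = "tracking_failure")
      next
    }
    pts <- base[act, , drop = FALSE]
    init <- cbind(X[t, act] - pts[, 1], Y[t, act] - pts[, 2])
    fwd <- cpp_klt_pair(pyr0, pyrJ, pts, hw, params$max_iterations,
                        params$convergence_eps_px, init)
    bwd <- cpp_klt_pair(pyrJ, pyr0, fwd[, 1:2, drop = FALSE], hw,
                        params$max_iterations, params$convergence_eps_px,
                        -(fwd[, 1:2, drop = FALSE] - pts))
    fb <- sqrt((bwd[, 1] - pts[, 1])^2 + (bwd[, 2] - pts[, 2])^2)
    ok <- fwd[, 3] > 0 & bwd[, 3] > 0 & fb <= params$fb_error_max_px &
      fwd[, 1] >= 0 & fwd[, 1] <= dims[2] - 1 &
      fwd[, 2] >= 0 & fwd[, 2] <= dims[1] - 1
    V[t + 1, act[ok]] <- TRUE
    X[t + 1, act[ok]] <- fwd[ok, 1]
    Y[t + 1, act[ok]] <- fwd[ok, 2]
  }
  structure(list(x = X, y = Y, valid = V, baseline = markers, fps = seq$fps,
                 timestamps = seq$timestamps), class = "trajectory_set")
}

#' Per-frame, per-marker displacement magnitudes
#'
#' Euclidean distance of every valid marker position from its baseline
#' (track-start) position; invalid entries are `NA`.
#'
#' @param traj a `trajectory_set` from [track_markers()].
#' @return Numeric matrix (frames x markers) of displacements in px.
#' @export
displacement_magnitudes <- function(traj) {
  d <- sqrt(sweep(traj$x, 2, traj$baseline$x)^2 +
            sweep(traj$y, 2, traj$baseline$y)^2)
  d[!traj$valid] <- NA_real_
  d
}

#' Savitzky-Golay smoothing of marker trajectories
#'
#' Applies the Savitzky-Golay filter to every marker's x(t) and y(t)
#' coordinate track (the contiguous valid stretch of each marker),
#' suppressing tracking noise and heartbeat-rate ripple before any
#' scalar displacement is computed. Stretches shorter than the window
#' are left unsmoothed.
#'
#' @param traj a `trajectory_set`.
#' @param window_frames odd Savitzky-Golay window.
#' @param polyorder polynomial order.
#' @return A `trajectory_set` with smoothed positions.
#' @export
smooth_trajectories <- function(traj, window_frames = 11, polyorder = 3) {
  for (m in seq_len(ncol(traj$x))) {
    run <- which(traj$valid[, m])
    if (length(run) < window_frames) next
    traj$x[run, m] <- as.numeric(
      signal::sgolayfilt(traj$x[run, m], p = polyorder, n = window_frames))
    traj$y[run, m] <- as.numeric(
      signal::sgolayfilt(traj$y[run, m], p = polyorder, n = window_frames))
  }
  traj
}

#' Export trajectories as CSV
#'
#' Long format: `frame, marker_id, x, y, valid`.
#'
#' @param traj a `trajectory_set`.
#' @param path CSV path.
#' @export
write_trajectories <- function(traj, path) {
  n <- nrow(traj$x); m <- ncol(traj$x)
  out <- data.frame(frame = rep(seq_len(n), m),
                    marker_id = rep(traj$baseline$marker_id, each = n),
                    x = as.vector(traj$x), y = as.vector(traj$y),
                    valid = as.vector(traj$valid))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
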