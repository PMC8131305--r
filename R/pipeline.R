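#' Run the full eSR detection pipeline on a sequence
#'
#' Orchestrates the detector: stabilize against the reference ROI,
#' seed MSER markers in the tendon ROI on the first stabilized frame,
#' track them with pyramidal KLT, Savitzky-Golay-smooth the marker
#' trajectories, collapse them into the scalar displacement signal
#' (length of the median displacement vector), and classify every
#' stimulus against the pooled noise floor. If more than half the
#' markers are invalid at a stimulus onset, markers are re-detected on
#' that frame and tracking continues with fresh baselines.
#'
#' @param seq a [frame_sequence()].
#' @param tendon_roi,ref_roi [roi()]s for the stapedius tendon and the
#'   promontory reference patch.
#' @param stimuli stimulus-event data frame with `onset_s` (see
#'   [align_stimuli()]).
#' @param mser an [mser_params()].
#' @param klt a [klt_params()].
#' @param detector a [detector_params()].
#' @param search_radius_px stabilizer search radius.
#' @param quality_floor stabilizer confidence floor.
#' @return Object of class `esr_analysis` with elements `detections`,
#'   `signal` (raw), `smoothed`, `stabilization` (shift trace + QC),
#'   `markers`, `trajectories` (list of segments), `stimuli`, `params`.
#' @export
analyze_sequence <- function(seq, tendon_roi, ref_roi, stimuli,
                             mser = mser_params(), klt = klt_params(),
                             detector = detector_params(),
                             search_radius_px = 20, quality_floor = 0.5) {
  stab <- stabilize_sequence(seq, ref_roi, search_radius_px, quality_floor)
  sseq <- stab$sequence
  n <- length(sseq$frames)
  onset_frames <- sort(unique(pmax(1L, pmin(n, as.integer(
    floor(stimuli$onset_s * seq$fps)) + 1L))))

  segments <- list()
  start <- 1L
  repeat {
    markers <- select_markers(
      detect_regions(sseq$frames[[start]], tendon_roi, mser))
    if (nrow(markers) < detector$min_markers)
      stopf("only %d markers found at frame %d (need >= %d)",
            nrow(markers), start, detector$min_markers,
            class = "tracking_failure")
    sub <- frame_sequence(sseq$frames[start:n], fps = sseq$fps,
                          timestamps = sseq$timestamps[start:n])
    traj <- track_markers(sub, markers, klt, error_on_total_loss = FALSE)
    # check marker coverage at each stimulus onset within this segment
    redetect_at <- NA_integer_
    for (f in onset_frames[onset_frames > start]) {
      if (mean(traj$valid[f - start + 1L, ]) < 0.5) { redetect_at <- f; break }
    }
    seg_end <- if (is.na(redetect_at)) n else redetect_at
    segments[[length(segments) + 1L]] <-
      list(traj = traj, start = start, end = seg_end, markers = markers)
    if (is.na(redetect_at)) break
    start <- redetect_at
  }

  # assemble full-length trajectory sets (NA outside each segment)
  full <- lapply(segments, function(s) {
    m <- ncol(s$traj$x)
    X <- matrix(NA_real_, n, m); Y <- matrix(NA_real_, n, m)
    V <- matrix(FALSE, n, m)
    rng <- s$start:s$end
    X[rng, ] <- s$traj$x[seq_along(rng), ]
    Y[rng, ] <- s$traj$y[seq_along(rng), ]
    V[rng, ] <- s$traj$valid[seq_along(rng), ]
    structure(list(x = X, y = Y, valid = V, baseline = s$markers,
                   fps = sseq$fps, timestamps = sseq$timestamps),
              class = "trajectory_set")
  })

  smoothed_traj <- lapply(full, smooth_trajectories,
                          window_frames = detector$savgol_window_frames,
                          polyorder = detector$savgol_polyorder)
  mc <- median_components(smoothed_traj)
  rv <- response_vectors(mc, stimuli, detector)
  total <- colSums(rv)
  axis <- estimate_motion_axis(smoothed_traj, stimuli, detector)
  sig <- build_signal(full, detector, direction = axis)
  sm <- savgol_smooth(build_signal(smoothed_traj, detector, direction = axis),
                      detector$savgol_window_frames,
                      detector$savgol_polyorder)
  # per-stimulus leave-one-out axis: stimulus k is classified on the
  # projection whose direction was estimated from the other stimuli only,
  # so its own window noise cannot pick its projection axis
  det <- vector("list", nrow(stimuli))
  for (k in seq_len(nrow(stimuli))) {
    u <- if (nrow(stimuli) > 1) total - rv[k, ] else total
    nrm <- sqrt(sum(u^2))
    u <- if (is.finite(nrm) && nrm > 0) u / nrm else c(1, 0)
    sk <- finalize_signal(mc$mx * u[1] + mc$my * u[2], mc$used, detector,
                          mc$fps, mc$timestamps)
    sk <- savgol_smooth(sk, detector$savgol_window_frames,
                        detector$savgol_polyorder)
    nf <- pooled_floor_for(sk, stimuli, detector)
    det[[k]] <- detect_reflex(sk, stimuli[k, ], detector, pooled_floor = nf)
  }
  det <- do.call(rbind, det)
  structure(list(detections = det, signal = sig, smoothed = sm,
                 motion_axis = axis,
                 stabilization = stab,
                 markers = segments[[1]]$markers,
                 trajectories = full, stimuli = stimuli,
                 params = list(mser = mser, klt = klt, detector = detector)),
            class = "esr_analysis")
}

#' @export
print.esr_analysis <- function(x, ...) {
  cat(sprintf("<esr_analysis> %d stimuli, %d detected (%.1f%%)\n",
              nrow(x$detections), sum(x$detections$detected),
              100 * mean(x$detections$detected)))
  cat(sprintf("  markers: %d | median noise floor: %.3f px | shift RMS: %.2f px\n",
              nrow(x$markers), median(x$detections$noise_floor_px),
              sqrt(mean(x$stabilization$shifts$dx^2 +
                        x$stabilization$shifts$dy^2))))
  invisible(x)
}

#' @export
summary.esr_analysis <- function(object, ...) {
  d <- object$detections
  by_el <- if (nrow(d)) stats::aggregate(detected ~ electrode, d, mean) else NULL
  out <- list(n_stimuli = nrow(d), n_detected = sum(d$detected),
              rate = mean(d$detected),
              median_noise_floor_px = median(d$noise_floor_px),
              median_motion_vector_px = median(d$motion_vector_length_px),
              by_electrode = by_el)
  class(out) <- "summary.esr_analysis"
  out
}

#' @export
print.summary.esr_analysis <- function(x, ...) {
  cat(sprintf("eSR analysis: %d/%d stimuli detected (%.1f%%)\n",
              x$n_detected, x$n_stimuli, 100 * x$rate))
  cat(sprintf("median noise floor %.3f px, median motion vector %.3f px\n",
              x$median_noise_floor_px, x$median_motion_vector_px))
  if (!is.null(x$by_electrode)) {
    for (i in seq_len(nrow(x$by_electrode)))
      cat(sprintf("  %s: %.1f%%\n", x$by_electrode$electrode[i],
                  100 * x$by_electrode$detected[i]))
  }
  invisible(x)
}

#' Plot the smoothed displacement signal with stimulus verdicts
#'
#' @param x an `esr_analysis`.
#' @param ... passed to `plot`.
#' @export
plot.esr_analysis <- function(x, ...) {
  t <- x$smoothed$timestamps
  plot(t, x$smoothed$values, type = "l", xlab = "time (s)",
       ylab = "tendon displacement (px)", ...)
  lines(t, x$signal$values, col = gray(0.8))
  lines(t, x$smoothed$values)
  d <- x$detections
  abline(v = d$onset_s, col = ifelse(d$detected, "forestgreen", "firebrick"),
         lty = 3)
  points(d$onset_s + d$latency_s, d$motion_vector_length_px +
           vapply(seq_len(nrow(d)), function(k) {
             i <- which(t > d$onset_s[k] - 0.5 & t <= d$onset_s[k])
             median(x$smoothed$values[i])
           }, numeric(1)),
         pch = ifelse(d$detected, 19, 1), col = "forestgreen")
  legend("topleft", bty = "n", lty = c(1, 3, 3), pch = c(NA, NA, NA),
         col = c("black", "forestgreen", "firebrick"),
         legend = c("smoothed signal", "detected stimulus", "undetected"))
  invisible(x)
}
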