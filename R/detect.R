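#' Reflex detector parameters
#'
#' @param slow_window_s width of the running-median high-pass applied to
#'   the smoothed signal before thresholding (0 disables). The running
#'   median tracks drift slower than this window -- respiratory residuals
#'   and interpolation bias -- while reflex peaks, an order of magnitude
#'   briefer, pass through unattenuated.
#' @param savgol_window_frames Savitzky-Golay window (odd number of
#'   frames, greater than the polynomial order). The default, 11 frames
#'   at 50 fps (220 ms), flattens heartbeat-rate (~1 Hz) residuals while
#'   preserving reflex peaks with ~50 ms rise times.
#' @param savgol_polyorder local polynomial order.
#' @param baseline_window_s pre-onset window used for the noise floor.
#' @param response_window_s post-onset window searched for the peak.
#'   Stapedius reflex latencies are tens of milliseconds and the twitch
#'   peaks well under 250 ms after the stimulus; 0.3 s covers that with
#'   margin, and every additional sample in the window raises the
#'   false-alarm probability of the max-over-window statistic.
#' @param threshold_k detection threshold in multiples of the noise
#'   floor.
#' @param noise_floor_min_px lower clip for the noise-floor estimate
#'   (px). On nearly noise-free input the baseline MAD collapses to the
#'   16-bit quantization ripple, far below what the tracker can actually
#'   resolve; the floor is therefore never taken below the tracker's
#'   resolution limit (default half the KLT convergence tolerance).
#' @param min_markers minimal number of valid markers per frame.
#' @param max_gap_frames longest run of low-coverage frames bridged by
#'   linear interpolation before a coverage error is raised.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(savgol_window_frames = 11, savgol_polyorder = 3,
                            baseline_window_s = 0.5, response_window_s = 0.3,
                            threshold_k = 3, min_markers = 3,
                            max_gap_frames = 5, slow_window_s = 2,
                            noise_floor_min_px = 0.005) {
  if (savgol_window_frames %% 2 == 0 ||
      savgol_window_frames <= savgol_polyorder)
    stopf("savgol window must be odd and exceed the polynomial order")
  if (baseline_window_s <= 0 || response_window_s <= 0)
    stopf("windows must be > 0")
  if (threshold_k <= 0) stopf("threshold_k must be > 0")
  structure(list(savgol_window_frames = as.integer(savgol_window_frames),
                 savgol_polyorder = as.integer(savgol_polyorder),
                 baseline_window_s = baseline_window_s,
                 response_window_s = response_window_s,
                 threshold_k = threshold_k,
                 min_markers = as.integer(min_markers),
                 max_gap_frames = as.integer(max_gap_frames),
                 slow_window_s = slow_window_s,
                 noise_floor_min_px = noise_floor_min_px),
            class = "detector_params")
}

#' Build the scalar tendon displacement signal
#'
#' Collapses the per-marker trajectories into one per-frame scalar
#' displacement in px (the median is robust to single-marker tracking
#' glitches in either construction):
#'
#' * `"axis_projection"` (the pipeline default): signed projection of
#'   the component-wise median displacement vector onto the tendon's
#'   motion axis. The stapedius tendon twitches along one anatomical
#'   direction, so this captures the full motion-vector length while
#'   leaving zero-mean tracking noise *signed* and Gaussian-tailed --
#'   which is what makes a `k` x MAD threshold behave like a true
#'   k-sigma rule. The axis comes from `direction` when supplied
#'   (typically the stimulus-triggered average response vector, see
#'   [estimate_motion_axis()]); otherwise from the leading eigenvector
#'   of the drift-corrected component covariance, oriented so the
#'   largest excursion is positive. Values may be negative.
#' * `"vector_median"`: length of the component-wise median
#'   displacement vector. Non-negative; rectification biases the
#'   baseline upward by roughly the noise of the median vector.
#' * `"magnitude_median"`: median of the per-marker displacement
#'   magnitudes. Simplest and insensitive to markers moving in opposite
#'   directions, but rectifies noise at full per-marker amplitude,
#'   which masks twitches smaller than about twice the per-marker
#'   tracking noise.
#'
#' Frames with fewer than `min_markers` valid markers are marked
#' missing and bridged by linear interpolation up to `max_gap_frames`
#' consecutive frames; lower coverage raises a signal-coverage error.
#'
#' @param traj a `trajectory_set`, or a list of them from sequential
#'   re-detection segments (concatenated marker columns).
#' @param params a [detector_params()].
#' @param method signal construction, see above.
#' @param direction optional unit 2-vector giving the projection axis
#'   (and its sign) for `"axis_projection"`.
#' @return Object of class `displacement_signal`: `values` (px, one per
#'   frame), `fps`, `timestamps`, `n_markers_used`.
#' @export
build_signal <- function(traj, params = detector_params(),
                         method = c("axis_projection", "vector_median",
                                    "magnitude_median"), direction = NULL) {
  method <- match.arg(method)
  if (inherits(traj, "trajectory_set")) traj <- list(traj)
  if (method == "magnitude_median") {
    d <- do.call(cbind, lapply(traj, displacement_magnitudes))
    used <- rowSums(!is.na(d))
    vals <- apply(d, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) median(r) else NA_real_
    })
  } else {
    dx <- do.call(cbind, lapply(traj, function(s) {
      o <- sweep(s$x, 2, s$baseline$x); o[!s$valid] <- NA_real_; o
    }))
    dy <- do.call(cbind, lapply(traj, function(s) {
      o <- sweep(s$y, 2, s$baseline$y); o[!s$valid] <- NA_real_; o
    }))
    used <- rowSums(!is.na(dx))
    mx <- apply(dx, 1, median, na.rm = TRUE)
    my <- apply(dy, 1, median, na.rm = TRUE)
    mx[used == 0] <- NA_real_; my[used == 0] <- NA_real_
    if (method == "vector_median") {
      vals <- sqrt(mx^2 + my^2)
    } else if (!is.null(direction)) {
      u <- direction / sqrt(sum(direction^2))
      vals <- mx * u[1] + my * u[2]
    } else {
      fps1 <- traj[[1]]$fps
      cx <- mx - slow_baseline(mx, fps1)
      cy <- my - slow_baseline(my, fps1)
      ok <- !is.na(cx)
      cv <- stats::cov(cbind(cx[ok], cy[ok]))
      u <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      vals <- mx * u[1] + my * u[2]
      # orient the axis so the dominant excursion is positive
      if (max(vals, na.rm = TRUE) < -min(vals, na.rm = TRUE)) vals <- -vals
    }
  }
  finalize_signal(vals, used, params, traj[[1]]$fps, traj[[1]]$timestamps)
}

# coverage checks + gap interpolation shared by all signal constructions
finalize_signal <- function(vals, used, params, fps, timestamps) {
  vals[used < params$min_markers] <- NA_real_
  ok <- !is.na(vals)
  if (mean(ok) < 0.9)
    stopf("only %.0f%% of frames have >= %d valid markers",
          100 * mean(ok), params$min_markers, class = "signal_coverage_error")
  if (!all(ok)) {
    r <- rle(!ok)
    if (max(r$lengths[r$values]) > params$max_gap_frames)
      stopf("gap of %d low-coverage frames exceeds the %d-frame limit",
            max(r$lengths[r$values]), params$max_gap_frames,
            class = "signal_coverage_error")
    vals <- approx(which(ok), vals[ok], xout = seq_along(vals), rule = 2)$y
  }
  structure(list(values = vals, fps = fps, timestamps = timestamps,
                 n_markers_used = used), class = "displacement_signal")
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: within every window the
#' signal is replaced by the value of the best-fitting polynomial of the
#' given order, which reproduces any polynomial of degree up to
#' `polyorder` exactly while suppressing broadband noise and
#' heartbeat-rate ripple.
#'
#' @param x numeric vector or a `displacement_signal`.
#' @param window_frames odd window length, at most the signal length.
#' @param polyorder polynomial order, below `window_frames`.
#' @return Same type as the input, smoothed.
#' @export
savgol_smooth <- function(x, window_frames = 11, polyorder = 3) {
  v <- if (inherits(x, "displacement_signal")) x$values else x
  if (window_frames %% 2 == 0 || window_frames <= polyorder ||
      window_frames > length(v))
    stopf("savgol window must be odd, > polyorder and <= signal length")
  sm <- as.numeric(signal::sgolayfilt(v, p = polyorder, n = window_frames))
  if (inherits(x, "displacement_signal")) { x$values <- sm; x } else sm
}

# per-frame median displacement components across markers/segments
median_components <- function(traj) {
  if (inherits(traj, "trajectory_set")) traj <- list(traj)
  dx <- do.call(cbind, lapply(traj, function(s) {
    o <- sweep(s$x, 2, s$baseline$x); o[!s$valid] <- NA_real_; o
  }))
  dy <- do.call(cbind, lapply(traj, function(s) {
    o <- sweep(s$y, 2, s$baseline$y); o[!s$valid] <- NA_real_; o
  }))
  used <- rowSums(!is.na(dx))
  mx <- apply(dx, 1, median, na.rm = TRUE)
  my <- apply(dy, 1, median, na.rm = TRUE)
  mx[used == 0] <- NA_real_; my[used == 0] <- NA_real_
  list(mx = mx, my = my, used = used,
       fps = traj[[1]]$fps, timestamps = traj[[1]]$timestamps)
}

#' Estimate the tendon's motion axis from the stimulus-triggered response
#'
#' Averages the drift-corrected median displacement vector over the
#' response windows of all stimuli, subtracts the corresponding baseline
#' average, and returns the resulting mean response vector normalized to
#' unit length. With real reflexes present this is the twitch direction
#' (with the correct sign); averaging over all stimuli keeps the
#' direction estimate nearly independent of any single window's noise,
#' so projecting onto it does not meaningfully inflate the false-alarm
#' rate of the downstream threshold.
#'
#' @param traj a `trajectory_set` or list of them (smoothed).
#' @param stimuli stimulus events with `onset_s`.
#' @param params a [detector_params()].
#' @return Unit 2-vector (x, y).
#' @export
estimate_motion_axis <- function(traj, stimuli, params = detector_params()) {
  mc <- median_components(traj)
  rv <- response_vectors(mc, stimuli, params)
  nrm <- sqrt(sum(colSums(rv)^2))
  if (!is.finite(nrm) || nrm <= 0) return(c(1, 0))
  colSums(rv) / nrm
}

# one response-minus-baseline mean displacement vector per stimulus
response_vectors <- function(mc, stimuli, params) {
  cx <- mc$mx - slow_baseline(mc$mx, mc$fps)
  cy <- mc$my - slow_baseline(mc$my, mc$fps)
  t <- mc$timestamps
  out <- matrix(0, nrow(stimuli), 2)
  for (k in seq_len(nrow(stimuli))) {
    on <- stimuli$onset_s[k]
    ri <- which(t > on & t <= on + params$response_window_s)
    bi <- which(t > on - params$baseline_window_s & t <= on)
    if (length(ri) == 0 || length(bi) == 0) next
    out[k, 1] <- mean(cx[ri], na.rm = TRUE) - mean(cx[bi], na.rm = TRUE)
    out[k, 2] <- mean(cy[ri], na.rm = TRUE) - mean(cy[bi], na.rm = TRUE)
  }
  out
}

# running-median estimate of the slow (drift) component of a series
slow_baseline <- function(values, fps, slow_window_s = 2) {
  if (is.null(slow_window_s) || slow_window_s <= 0)
    return(rep(0, length(values)))
  v <- values
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    if (length(ok) < 2) return(rep(median(v, na.rm = TRUE), length(v)))
    v <- approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  }
  k <- as.integer(round(slow_window_s * fps))
  if (k %% 2 == 0) k <- k + 1L
  if (k >= length(v)) return(rep(median(v), length(v)))
  as.numeric(stats::runmed(v, k, endrule = "median"))
}

# running-median high-pass: removes components slower than the window
slow_highpass <- function(values, fps, slow_window_s) {
  values - slow_baseline(values, fps, slow_window_s)
}

#' Robust noise floor of a displacement signal
#'
#' `1.4826 x` the median absolute deviation of the baseline samples
#' (median-subtracted, so constant offsets do not contribute): the
#' robust Gaussian-equivalent SD of the pre-stimulus background noise.
#'
#' @param values numeric signal values.
#' @param baseline_idx integer indices of baseline (pre-stimulus)
#'   samples; at least 20 required.
#' @return Noise floor in px.
#' @export
noise_floor <- function(values, baseline_idx) {
  s <- values[baseline_idx]
  s <- s[!is.na(s)]
  if (length(s) < 20)
    stopf("need >= 20 baseline samples, got %d", length(s),
          class = "noise_estimation_error")
  mad(s)  # stats::mad already scales by 1.4826 about the median
}

#' Decide whether one stimulus elicited a reflex
#'
#' The baseline median over `(onset - baseline_window_s, onset]` is
#' subtracted; the peak of the smoothed displacement signal within
#' `(onset, onset + response_window_s]` is compared against
#' `threshold_k x` the noise floor estimated from the baseline window.
#' A peak exceeding the background noise is registered as an eSR.
#'
#' @param signal a smoothed `displacement_signal`.
#' @param stim one-row data frame (or list) with at least `onset_s`;
#'   `stimulus_id`, `electrode`, `level` are carried through.
#' @param params a [detector_params()].
#' @param pooled_floor optional pre-computed noise floor (px). After
#'   Savitzky-Golay smoothing, samples within one baseline window are
#'   strongly correlated, so a floor estimated from a single window has
#'   very few effective degrees of freedom; [detect_reflexes()] therefore
#'   pools the baseline segments of all stimuli in a run into one robust
#'   floor and passes it here. `NULL` falls back to the single-window
#'   estimate.
#' @return One-row data frame: `stimulus_id, electrode, level, onset_s,
#'   detected, motion_vector_length_px, latency_s, noise_floor_px,
#'   threshold_px`.
#' @export
detect_reflex <- function(signal, stim, params = detector_params(),
                          pooled_floor = NULL) {
  t <- signal$timestamps
  on <- stim$onset_s
  base_idx <- which(t > on - params$baseline_window_s & t <= on)
  resp_idx <- which(t > on & t <= on + params$response_window_s)
  if (length(base_idx) == 0 || length(resp_idx) == 0 ||
      on - params$baseline_window_s < t[1] - 1e-9 ||
      on + params$response_window_s > t[length(t)] + 1e-9)
    stopf("baseline/response window out of range for onset %.3f s", on,
          class = "window_error")
  hp_active <- !is.null(params$slow_window_s) && params$slow_window_s > 0
  v <- slow_highpass(signal$values, signal$fps, params$slow_window_s)
  nf <- pooled_floor %||% noise_floor(v, base_idx)
  nf <- max(nf, params$noise_floor_min_px %||% 0)
  # with the high-pass active, the running median of baseline-dominated
  # samples is already subtracted; re-subtracting a short-window median
  # would only add its own estimation noise to the peak
  m <- if (hp_active) 0 else median(v[base_idx], na.rm = TRUE)
  resp <- v[resp_idx] - m
  peak_i <- which.max(resp)
  peak <- resp[peak_i]
  thr <- params$threshold_k * nf
  data.frame(stimulus_id = stim$stimulus_id %||% NA,
             electrode = stim$electrode %||% NA_character_,
             level = stim$level %||% NA_real_,
             onset_s = on, detected = peak > thr,
             motion_vector_length_px = peak,
             latency_s = t[resp_idx[peak_i]] - on,
             noise_floor_px = nf, threshold_px = thr)
}

#' Classify every stimulus in a schedule
#'
#' The noise floor is estimated once from the pooled pre-onset baseline
#' segments of all stimuli (each local to its stimulus, none overlapping
#' a response window), which gives the robust floor enough effective
#' degrees of freedom despite the smoothing-induced correlation; the
#' baseline median stays local to each stimulus.
#'
#' @param signal a smoothed `displacement_signal`.
#' @param stimuli data frame of stimulus events with `onset_s`.
#' @param params a [detector_params()].
#' @param pool_noise_floor estimate one pooled floor for the whole run
#'   (default) instead of per-stimulus single-window floors.
#' @return Data frame with one [detect_reflex()] row per stimulus.
#' @export
detect_reflexes <- function(signal, stimuli, params = detector_params(),
                            pool_noise_floor = TRUE) {
  nf <- if (pool_noise_floor && nrow(stimuli) > 1)
    pooled_floor_for(signal, stimuli, params) else NULL
  do.call(rbind, lapply(seq_len(nrow(stimuli)), function(k)
    detect_reflex(signal, stimuli[k, ], params, pooled_floor = nf)))
}

# robust noise floor pooled over the baseline windows of all stimuli,
# clipped below at the tracker resolution limit
pooled_floor_for <- function(signal, stimuli, params) {
  t <- signal$timestamps
  idx <- sort(unique(unlist(lapply(stimuli$onset_s, function(on)
    which(t > on - params$baseline_window_s & t <= on)))))
  v <- slow_highpass(signal$values, signal$fps, params$slow_window_s)
  max(noise_floor(v, idx), params$noise_floor_min_px %||% 0)
}

#' Estimate the reflex threshold (eSRT) from a level sweep
#'
#' The eSRT is the lowest stimulation level at which a reflex was
#' detected; the dynamic range runs from there to the highest level
#' tested. The estimate is flagged non-monotone when any higher tested
#' level went undetected. When no level elicited a reflex, the result
#' records an absent reflex (`reflex_present = FALSE`).
#'
#' @param detections detection data frame for one electrode, with
#'   columns `level` and `detected`; at least two distinct levels.
#' @return Object of class `esrt_estimate`: `electrode, reflex_present,
#'   esrt_level, dynamic_range, monotone, levels_tested`.
#' @export
estimate_esrt <- function(detections) {
  if (nrow(detections) == 0) stopf("no detection records supplied")
  if (length(unique(detections$level)) < 2)
    stopf("need at least 2 distinct stimulation levels")
  d <- detections[order(detections$level), ]
  electrode <- if ("electrode" %in% names(d)) unique(d$electrode)[1] else NA
  if (!any(d$detected))
    return(structure(list(electrode = electrode, reflex_present = FALSE,
                          esrt_level = NA_real_,
                          dynamic_range = c(NA_real_, max(d$level)),
                          monotone = NA, levels_tested = sort(unique(d$level))),
                     class = "esrt_estimate"))
  esrt <- min(d$level[d$detected])
  above <- d[d$level > esrt, ]
  monotone <- all(above$detected)
  structure(list(electrode = electrode, reflex_present = TRUE,
                 esrt_level = esrt,
                 dynamic_range = c(esrt, max(d$level)),
                 monotone = monotone, levels_tested = sort(unique(d$level))),
            class = "esrt_estimate")
}

#' @export
print.esrt_estimate <- function(x, ...) {
  if (!x$reflex_present) {
    cat(sprintf("<esrt> electrode %s: no reflex detected at any tested level\n",
                x$electrode))
  } else {
    cat(sprintf(
      "<esrt> electrode %s: eSRT %g, dynamic range [%g, %g], monotone: %s\n",
      x$electrode, x$esrt_level, x$dynamic_range[1], x$dynamic_range[2],
      x$monotone))
  }
  invisible(x)
}
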