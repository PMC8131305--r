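fake_traj <- function(x, y = NULL, valid = NULL, fps = 50) {
  n <- nrow(x); m <- ncol(x)
  y <- y %||% matrix(0, n, m)
  valid <- valid %||% matrix(TRUE, n, m)
  structure(list(x = x, y = y, valid = valid,
                 baseline = data.frame(marker_id = seq_len(m),
                                       x = x[1, ], y = y[1, ]),
                 fps = fps, timestamps = (seq_len(n) - 1) / fps),
            class = "trajectory_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the magnitude-median signal takes the per-frame median", {
  # 3 markers displaced by (1, 2, 9) px at one frame: median 2
  x <- matrix(0, 3, 3)
  x[2, ] <- c(1, 2, 9)
  sig <- build_signal(fake_traj(x), detector_params(min_markers = 3),
                      method = "magnitude_median")
  expect_equal(sig$values[2], 2)
  expect_equal(sig$values[1], 0)
  # static markers -> all-zero signal
  sig0 <- build_signal(fake_traj(matrix(5, 10, 3)),
                       detector_params(min_markers = 3),
                       method = "magnitude_median")
  expect_true(all(sig0$values == 0))
})

test_that("low marker coverage raises a signal-coverage error", {
  x <- matrix(0, 20, 3)
  v <- matrix(TRUE, 20, 3)
  v[6:20, 2:3] <- FALSE  # only 1 valid marker for 75% of frames
  expect_error(build_signal(fake_traj(x, valid = v),
                            detector_params(min_markers = 3)),
               class = "signal_coverage_error")
  # a short gap is interpolated instead
  v2 <- matrix(TRUE, 40, 3)
  v2[10:12, 2:3] <- FALSE
  sig <- build_signal(fake_traj(x = matrix(0, 40, 3), valid = v2),
                      detector_params(min_markers = 3))
  expect_length(sig$values, 40)
  expect_false(anyNA(sig$values))
})

test_that("Savitzky-Golay reproduces polynomials and constants", {
  expect_equal(savgol_smooth(rep(2.5, 40), 11, 3), rep(2.5, 40))
  t2 <- (1:40)^2
  expect_equal(savgol_smooth(t2, 11, 3)[6:35], t2[6:35], tolerance = 1e-9)
  expect_error(savgol_smooth(1:40, 10, 3), "odd")
  expect_error(savgol_smooth(1:40, 11, 11), "odd|polyorder")
  expect_error(savgol_smooth(1:5, 11, 3), "length")
})

test_that("Savitzky-Golay attenuates a twitch peak < 15% (coefficient oracle)", {
  fps <- 50
  t <- seq(0, 2, by = 1 / fps)
  tw <- twitch_model()
  w <- stapetrack:::twitch_waveform(tw, t - 0.5)  # unit-peak twitch
  hb <- 0.8 * sin(2 * pi * 1.1 * t)               # heartbeat ripple
  sm <- savgol_smooth(w + hb, 11, 3)
  # independent oracle: central SG coefficients from the projection matrix
  A <- outer(-5:5, 0:3, `^`)
  h <- (A %*% solve(t(A) %*% A, t(A)))[6, ]
  oracle <- as.numeric(stats::filter(w + hb, rev(h), sides = 2))
  inner <- 6:(length(t) - 5)
  expect_equal(sm[inner], oracle[inner], tolerance = 1e-9)
  # peak attenuation of the twitch alone
  smw <- savgol_smooth(w, 11, 3)
  expect_lt(1 - max(smw) / max(w), 0.15)
})

test_that("noise floor is the scaled MAD of the baseline", {
  expect_equal(noise_floor(rep(0, 30), 1:30), 0)
  expect_equal(noise_floor(rep(4.2, 30), 1:30), 0)  # offset removed
  set.seed(42)
  x <- rnorm(500, sd = 0.2)
  est <- noise_floor(x, 1:500)
  expect_lt(abs(est - sd(x)) / sd(x), 0.1)  # sample-SD oracle
  expect_error(noise_floor(rnorm(10), 1:10),
               class = "noise_estimation_error")
})

test_that("detect_reflex applies the k x floor rule with exact bookkeeping", {
  fps <- 50
  n <- 120
  sig <- structure(list(values = rep(0, n), fps = fps,
                        timestamps = (seq_len(n) - 1) / fps,
                        n_markers_used = rep(5, n)),
                   class = "displacement_signal")
  p <- detector_params()
  stim <- data.frame(stimulus_id = 1, electrode = "middle", level = 20,
                     onset_s = 1.0)
  d0 <- detect_reflex(sig, stim, p)
  expect_false(d0$detected)
  expect_equal(d0$motion_vector_length_px, 0)
  # windows out of range
  expect_error(detect_reflex(sig, data.frame(onset_s = 0.1), p),
               class = "window_error")
  expect_error(detect_reflex(sig, data.frame(onset_s = 2.3), p),
               class = "window_error")
  # a clear synthetic peak: detected, with consistent fields
  v <- rnorm(n, sd = 0.02)
  v[55:60] <- v[55:60] + c(0.2, 0.5, 0.8, 0.6, 0.4, 0.2)
  sig$values <- v
  d1 <- detect_reflex(sig, stim, p)
  expect_true(d1$detected)
  expect_equal(d1$threshold_px, p$threshold_k * d1$noise_floor_px)
  expect_identical(d1$detected,
                   d1$motion_vector_length_px > d1$threshold_px)
  expect_gt(d1$latency_s, 0)
  expect_lte(d1$latency_s, p$response_window_s)
})

test_that("an end-to-end twitch at SNR 6 is detected with correct latency", {
  r <- stapetrack:::run_synthetic_batch(31, levels = rep(0, 6))
  floor_raw <- mad(r$analysis$signal$values)
  amp <- 6 * floor_raw
  r2 <- stapetrack:::run_synthetic_batch(
    32, levels = rep(40, 6),
    saturation_amp_px = amp / stats::plogis(0.5 * 20))
  d <- r2$analysis$detections
  expect_true(all(d$detected))
  # latency within +-40 ms of the ground-truth peak delay
  true_delay <- r2$truth$stimuli$peak_time_s - r2$truth$stimuli$onset_s
  expect_true(all(abs(d$latency_s - true_delay) <= 0.04 + 1e-9))
})

test_that("thresholding consistency holds on every pipeline output", {
  r <- stapetrack:::run_synthetic_batch(33, levels = c(0, 15, 25, 40))
  d <- r$analysis$detections
  expect_identical(d$detected, d$motion_vector_length_px > d$threshold_px)
  expect_equal(d$threshold_px, 3 * d$noise_floor_px)
})

test_that("motion vector length is non-decreasing in true amplitude (noise-free)", {
  nuis <- nuisance_model(heartbeat_amp_px = 0, respiration_amp_px = 0,
                         jitter_sd_px = 0, sensor_noise_sd = 0)
  r <- stapetrack:::run_synthetic_batch(34, levels = c(14, 18, 22, 26, 40),
                                        nuisance = nuis)
  d <- r$analysis$detections[order(r$analysis$detections$level), ]
  expect_true(all(diff(d$motion_vector_length_px) > -0.02))
  # and amplitudes track the ground truth
  expect_equal(d$motion_vector_length_px[5], 3, tolerance = 0.3)
})

test_that("estimate_esrt finds the lowest detected level and flags gaps", {
  d1 <- data.frame(level = c(10, 15, 20, 25),
                   detected = c(FALSE, FALSE, TRUE, TRUE),
                   electrode = "middle")
  e1 <- estimate_esrt(d1)
  expect_equal(e1$esrt_level, 20)
  expect_true(e1$monotone)
  expect_equal(e1$dynamic_range, c(20, 25))
  d2 <- data.frame(level = c(10, 20, 25, 30),
                   detected = c(FALSE, TRUE, FALSE, TRUE),
                   electrode = "middle")
  e2 <- estimate_esrt(d2)
  expect_equal(e2$esrt_level, 20)
  expect_false(e2$monotone)
  # absent reflex mirrors patients without detectable responses
  d3 <- data.frame(level = c(10, 20), detected = c(FALSE, FALSE),
                   electrode = "basal")
  e3 <- estimate_esrt(d3)
  expect_false(e3$reflex_present)
  expect_true(is.na(e3$esrt_level))
  expect_error(estimate_esrt(d3[0, ]), "no detection")
  expect_error(estimate_esrt(data.frame(level = c(10, 10),
                                        detected = c(TRUE, TRUE))),
               "distinct")
})

test_that("detector parameter invariants are enforced", {
  expect_error(detector_params(savgol_window_frames = 10), "odd")
  expect_error(detector_params(savgol_window_frames = 3,
                               savgol_polyorder = 3), "odd")
  expect_error(detector_params(baseline_window_s = 0), "windows")
  expect_error(detector_params(threshold_k = 0), "threshold_k")
})
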