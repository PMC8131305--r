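track_fixture <- function(seed = 2, nuisance = NULL, duration_s = 0.5, ...) {
  nuisance <- nuisance %||% nuisance_model(heartbeat_amp_px = 0,
                                           respiration_amp_px = 0,
                                           jitter_sd_px = 0,
                                           sensor_noise_sd = 0)
  sim <- quiet_sim(seed = seed, nuisance = nuisance,
                   duration_s = duration_s, ...)
  markers <- select_markers(detect_regions(sim$sequence$frames[[1]],
                                           tendon_roi(scene_spec(texture_seed = seed))))
  list(sim = sim, markers = markers)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("static sequences give constant trajectories", {
  fx <- track_fixture(seed = 2)
  traj <- track_markers(fx$sim$sequence, fx$markers)
  expect_true(all(traj$valid))
  dev <- abs(sweep(traj$x, 2, fx$markers$x)) +
         abs(sweep(traj$y, 2, fx$markers$y))
  expect_lt(max(dev), 0.05)
  expect_lt(max(displacement_magnitudes(traj)), 0.05)
})

test_that("a global 1 px/frame translation is tracked to 1.0 +- 0.2 px", {
  fx <- track_fixture(seed = 3, duration_s = 0.2)
  base <- fx$sim$sequence$frames[[1]]
  frames <- lapply(0:7, function(i) stapetrack:::cpp_translate(base, i, 0))
  seq <- frame_sequence(frames, fps = 50)
  traj <- track_markers(seq, fx$markers)
  steps <- diff(traj$x[, traj$valid[8, ], drop = FALSE])
  expect_true(all(abs(steps - 1) < 0.2))
})

test_that("a rendered 3 px twitch produces a 3.0 +- 0.3 px marker excursion", {
  fx <- track_fixture(seed = 4, duration_s = 1.6, onsets = 0.5, levels = 40)
  traj <- track_markers(fx$sim$sequence, fx$markers)
  d <- displacement_magnitudes(traj)
  peak <- apply(d, 2, max)
  expect_true(all(abs(peak - 3) < 0.3))
  # per-frame magnitudes follow the ground-truth twitch trace
  truth <- fx$sim$truth$frames$tendon_disp_px
  med <- apply(d, 1, median)
  expect_lt(max(abs(med - truth)), 0.3)
})

test_that("displacement magnitudes are baseline-relative Euclidean norms", {
  traj <- structure(list(
    x = rbind(c(0, 10), c(3, 10)), y = rbind(c(0, 5), c(4, 5)),
    valid = matrix(TRUE, 2, 2),
    baseline = data.frame(marker_id = 1:2, x = c(0, 10), y = c(0, 5)),
    fps = 50, timestamps = c(0, 0.02)), class = "trajectory_set")
  d <- displacement_magnitudes(traj)
  expect_equal(d[1, ], c(0, 0))
  expect_equal(d[2, ], c(5, 0))  # 3-4-5 triangle
  traj$valid[2, 2] <- FALSE
  expect_true(is.na(displacement_magnitudes(traj)[2, 2]))
})

test_that("sub-pixel accuracy on noise-free pure translation is < 0.2 px RMS", {
  res <- validation_tracking_accuracy(seed = 5, n_frames = 40)
  expect_lt(res$rms_error_px, 0.2)
})

test_that("tracking is deterministic and forward-backward consistent", {
  nuis <- nuisance_model(heartbeat_amp_px = 0.8, respiration_amp_px = 0,
                         jitter_sd_px = 0.1, sensor_noise_sd = 0.02)
  fx <- track_fixture(seed = 6, nuisance = nuis, duration_s = 0.4)
  t1 <- track_markers(fx$sim$sequence, fx$markers)
  t2 <- track_markers(fx$sim$sequence, fx$markers)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$valid, t2$valid)
  # forward-backward: re-track each valid frame's positions back to frame 1
  p <- klt_params()
  pyr1 <- stapetrack:::build_pyramid(fx$sim$sequence$frames[[1]], 3)
  n <- nrow(t1$x)
  pyrN <- stapetrack:::build_pyramid(fx$sim$sequence$frames[[n]], 3)
  act <- which(t1$valid[n, ])
  pts <- cbind(t1$x[n, act], t1$y[n, act])
  init <- cbind(fx$markers$x[act] - pts[, 1], fx$markers$y[act] - pts[, 2])
  back <- stapetrack:::cpp_klt_pair(pyrN, pyr1, pts, 10L, 30L, 0.01, init)
  fb <- sqrt((back[, 1] - fx$markers$x[act])^2 +
             (back[, 2] - fx$markers$y[act])^2)
  expect_true(all(fb <= p$fb_error_max_px))
})

test_that("markers whose window leaves the frame are invalidated, not moved", {
  fx <- track_fixture(seed = 7, duration_s = 0.2)
  base <- fx$sim$sequence$frames[[1]]
  # walk the scene off the frame edge quickly
  frames <- lapply(0:9, function(i) stapetrack:::cpp_translate(base, 8 * i, 0))
  traj <- track_markers(frame_sequence(frames, fps = 50), fx$markers,
                        error_on_total_loss = FALSE)
  expect_true(any(!traj$valid[10, ]))
  # validity is prefix-monotone: once lost, stays lost
  for (m in seq_len(ncol(traj$valid))) {
    v <- traj$valid[, m]
    expect_true(all(diff(as.integer(v)) <= 0) || all(v))
  }
})

test_that("total marker loss raises a tracking failure naming the frame", {
  fx <- track_fixture(seed = 8, duration_s = 0.1)
  base <- fx$sim$sequence$frames[[1]]
  frames <- c(list(base), lapply(1:4, function(i)
    matrix(runif(length(base)), nrow(base))))
  expect_error(track_markers(frame_sequence(frames, fps = 50), fx$markers),
               "frame", class = "tracking_failure")
})

test_that("trajectory CSV export is long-format and complete", {
  fx <- track_fixture(seed = 9, duration_s = 0.1)
  traj <- track_markers(fx$sim$sequence, fx$markers)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(traj, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(traj$x) * ncol(traj$x))
  expect_equal(names(back), c("frame", "marker_id", "x", "y", "valid"))
})

test_that("klt_params validates its invariants", {
  expect_error(klt_params(window_px = 10), "odd")
  expect_error(klt_params(window_px = 3), "odd")
  expect_error(klt_params(pyramid_levels = 0), "pyramid")
  expect_error(klt_params(fb_error_max_px = 0), "fb_error")
})
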