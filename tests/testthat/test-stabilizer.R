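make_textured <- function(seed = 2, h = 96, w = 168) {
  sim <- quiet_sim(seed = seed, duration_s = 0.06)
  sim$sequence$frames[[1]]
}

test_that("estimate_shift recovers applied translations", {
  base <- make_textured()
  templ <- base[31:66, 19:58]  # the reference patch region
  # self-registration
  e0 <- estimate_shift(base, templ, 18, 30, 10)
  expect_equal(c(e0$dx, e0$dy), c(0, 0), tolerance = 1e-6)
  expect_gt(e0$quality, 0.999)
  # integer roll
  rolled <- base[c(3:96, 1:2), c(166:168, 1:165)]  # shift +3 x, -2 y
  e1 <- estimate_shift(rolled, templ, 18, 30, 10)
  expect_lt(abs(e1$dx - 3), 0.1)
  expect_lt(abs(e1$dy - (-2)), 0.1)
  # sub-pixel shift via bilinear resampling
  sub <- stapetrack:::cpp_translate(base, 0.5, 0.5)
  e2 <- estimate_shift(sub, templ, 18, 30, 10)
  expect_lt(abs(e2$dx - 0.5), 0.2)
  expect_lt(abs(e2$dy - 0.5), 0.2)
})

test_that("zero-variance template is a degenerate-template error", {
  base <- make_textured()
  expect_error(estimate_shift(base, matrix(0.5, 20, 20), 10, 10, 5),
               "degenerate")
})

test_that("a static sequence stabilizes to itself with zero shifts", {
  sim <- quiet_sim(seed = 3, duration_s = 0.1)
  st <- stabilize_sequence(sim$sequence, reference_roi(scene_spec()))
  expect_true(all(abs(st$shifts$dx) < 1e-6))
  expect_true(all(abs(st$shifts$dy) < 1e-6))
  expect_equal(st$sequence$frames, sim$sequence$frames)
})

test_that("heartbeat-only global motion is removed below 0.3 px RMS", {
  nuis <- nuisance_model(respiration_amp_px = 0, jitter_sd_px = 0,
                         sensor_noise_sd = 0)
  sim <- quiet_sim(seed = 6, duration_s = 2, nuisance = nuis)
  st <- stabilize_sequence(sim$sequence, reference_roi(scene_spec()),
                           search_radius_px = 8)
  tr <- sim$truth$frames
  ex <- st$shifts$dx - (tr$nuisance_dx - tr$nuisance_dx[1])
  ey <- st$shifts$dy - (tr$nuisance_dy - tr$nuisance_dy[1])
  expect_lt(sqrt(mean(ex^2 + ey^2)), 0.3)
  # tendon centroid is steady after stabilization
  cents <- t(sapply(st$sequence$frames, function(f)
    centroid_oracle(f, 70, 26, 150, 70, 0.55)))
  expect_lt(sd(cents[, 1]), 0.2)
  expect_lt(sd(cents[, 2]), 0.2)
})

test_that("heartbeat is removed while the twitch survives in the tendon", {
  nuis <- nuisance_model(respiration_amp_px = 0, jitter_sd_px = 0,
                         sensor_noise_sd = 0)
  # low-texture scene so the thresholded-centroid oracle reads the tendon
  scene <- scene_spec(bg_contrast = 0.02, tendon_contrast = 0.01,
                      spot_amp = 0, texture_seed = 8)
  sim <- quiet_sim(seed = 8, onsets = 1.0, levels = 40, nuisance = nuis,
                   duration_s = 2, scene = scene)
  st <- stabilize_sequence(sim$sequence, reference_roi(scene),
                           search_radius_px = 8)
  tr <- sim$truth$frames
  ex <- st$shifts$dx - (tr$nuisance_dx - tr$nuisance_dx[1])
  ey <- st$shifts$dy - (tr$nuisance_dy - tr$nuisance_dy[1])
  expect_lt(sqrt(mean(ex^2 + ey^2)), 0.3)
  peak_frame <- which.max(tr$tendon_disp_px)
  c0 <- centroid_oracle(st$sequence$frames[[1]], 70, 26, 150, 70, 0.55)
  c1 <- centroid_oracle(st$sequence$frames[[peak_frame]], 70, 26, 150, 70, 0.55)
  expect_gt(sqrt(sum((c1 - c0)^2)), 2)  # ~3 px twitch preserved
})

test_that("recovered shifts are equivariant under constant pre-translation", {
  sim <- quiet_sim(seed = 9, duration_s = 0.2,
                   nuisance = nuisance_model(heartbeat_amp_px = 0.4,
                                             respiration_amp_px = 0,
                                             jitter_sd_px = 0,
                                             sensor_noise_sd = 0))
  ref <- reference_roi(scene_spec())
  st0 <- stabilize_sequence(sim$sequence, ref, search_radius_px = 8)
  moved <- frame_sequence(lapply(sim$sequence$frames, function(f)
    stapetrack:::cpp_translate(f, 2, -1)), fps = 50)
  # keep the template identical: cut it from the *unshifted* first frame by
  # translating the reference frame back
  st1 <- stabilize_sequence(
    frame_sequence(c(sim$sequence$frames[1], moved$frames[-1]), fps = 50),
    ref, search_radius_px = 8)
  expect_lt(max(abs(st1$shifts$dx[-1] - (st0$shifts$dx[-1] + 2))), 0.1)
  expect_lt(max(abs(st1$shifts$dy[-1] - (st0$shifts$dy[-1] - 1))), 0.1)
})

test_that("low-quality frames get interpolated shifts and are flagged", {
  sim <- quiet_sim(seed = 10, duration_s = 0.2)
  frames <- sim$sequence$frames
  # corrupt one frame beyond recognition
  frames[[5]] <- matrix(runif(length(frames[[5]])), nrow(frames[[5]]))
  st <- stabilize_sequence(frame_sequence(frames, fps = 50),
                           reference_roi(scene_spec()), search_radius_px = 8)
  expect_true(st$shifts$interpolated[5])
  expect_lt(abs(st$shifts$dx[5]), 0.2)  # interpolated from static neighbours
})

test_that("stabilization preserves frame dimensions and exports CSV", {
  sim <- quiet_sim(seed = 11, duration_s = 0.1,
                   nuisance = nuisance_model(heartbeat_amp_px = 0.5,
                                             respiration_amp_px = 0,
                                             jitter_sd_px = 0,
                                             sensor_noise_sd = 0))
  st <- stabilize_sequence(sim$sequence, reference_roi(scene_spec()),
                           search_radius_px = 8)
  expect_equal(dim(st$sequence$frames[[1]]), dim(sim$sequence$frames[[1]]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_shift_trace(st, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("frame", "dx", "dy", "quality"))
  expect_equal(nrow(back), length(sim$sequence$frames))
})
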