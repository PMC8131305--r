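# shared fixture builders (everything is generated in code at test time)

# a quiet scene render: no nuisance unless asked for
quiet_sim <- function(seed = 1, levels = numeric(0), onsets = numeric(0),
                      nuisance = nuisance_model(heartbeat_amp_px = 0,
                                                respiration_amp_px = 0,
                                                jitter_sd_px = 0,
                                                sensor_noise_sd = 0),
                      twitch = twitch_model(), duration_s = NULL,
                      scene = scene_spec(texture_seed = seed), ...) {
  sched <- if (length(onsets)) stimulus_schedule(onsets, levels)
           else stimulus_schedule(numeric(0), numeric(0))
  synthesize_sequence(scene, sched, nuisance, twitch,
                      duration_s = duration_s, seed = seed, ...)
}

# a flat image with one or more bright disks, for marker-engine oracles
disk_image <- function(w = 100, h = 80, centers, radius = 6, bg = 0.1,
                       fg = 0.8) {
  img <- matrix(bg, h, w)
  for (ci in seq_len(nrow(centers))) {
    cx <- centers[ci, 1]; cy <- centers[ci, 2]
    for (y in 0:(h - 1)) for (x in 0:(w - 1))
      if ((x - cx)^2 + (y - cy)^2 <= radius^2) img[y + 1, x + 1] <- fg
  }
  img
}

# independent centroid oracle: intensity-weighted centroid of pixels above
# a mid threshold inside a window (0-based coordinates)
centroid_oracle <- function(img, x0, y0, x1, y1, thr) {
  sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  w <- pmax(sub - thr, 0)
  xs <- matrix(rep(x0:x1, each = nrow(sub)), nrow(sub))
  ys <- matrix(rep(y0:y1, ncol(sub)), nrow(sub))
  c(sum(w * xs) / sum(w), sum(w * ys) / sum(w))
}
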