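#' Synthetic middle-ear scene description
#'
#' Describes the rendered scene: a textured background (the surgical
#' field, including the promontory reference patch) and an elliptical
#' stapedius-tendon region that twitches in response to stimulation. The
#' default geometry mimics a 14 x 8 mm field of view imaged at low
#' resolution; `mm_per_px` is metadata only.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param tendon_ellipse list with `center` (x, y), `axes` (semi-major,
#'   semi-minor, px) and `orientation` (radians).
#' @param reference_patch promontory stand-in rectangle, named vector
#'   `c(x, y, width, height)`; must not overlap the tendon ellipse.
#' @param texture_seed integer seed for the background/tendon textures
#'   (kept separate from the per-run noise seed so the same anatomy can
#'   be rendered under different noise draws).
#' @param mm_per_px millimetres per pixel; defaults to a 14 mm wide field.
#' @param bg_mean,bg_contrast background texture mean level and SD of the
#'   band-limited component.
#' @param tendon_mean,tendon_contrast tendon texture mean level and SD of
#'   the band-limited component.
#' @param texture_sigma_px Gaussian correlation length of the textures.
#' @param spot_amp,spot_density,spot_sigma_px amplitude, per-pixel density
#'   and radius of discrete spot features (specular highlights, fibrous
#'   speckle) that give MSER stable regions to latch onto; `spot_amp` is
#'   the peak intensity excursion of a full-strength spot.
#' @param edge_softness_px width of the tendon's soft edge.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(frame_width = 168, frame_height = 96,
                       tendon_ellipse = list(center = c(110, 48),
                                             axes = c(40, 20),
                                             orientation = 0.15),
                       reference_patch = c(x = 18, y = 30, width = 40,
                                           height = 36),
                       texture_seed = 1L,
                       mm_per_px = 14 / frame_width,
                       bg_mean = 0.45, bg_contrast = 0.06,
                       tendon_mean = 0.68, tendon_contrast = 0.05,
                       texture_sigma_px = 1.6,
                       spot_amp = 0.28, spot_density = 1 / 45,
                       spot_sigma_px = 2.8, edge_softness_px = 0.75) {
  ce <- tendon_ellipse$center; ax <- tendon_ellipse$axes
  r <- max(ax)
  if (ce[1] - r < 0 || ce[2] - r < 0 || ce[1] + r > frame_width - 1 ||
      ce[2] + r > frame_height - 1)
    stopf("tendon ellipse does not fit inside the frame")
  rp <- reference_patch
  if (rp["x"] < 0 || rp["y"] < 0 ||
      rp["x"] + rp["width"] > frame_width ||
      rp["y"] + rp["height"] > frame_height)
    stopf("reference patch does not fit inside the frame")
  # conservative overlap check: patch rectangle vs ellipse bounding box
  if (!(rp["x"] + rp["width"] < ce[1] - r || rp["x"] > ce[1] + r ||
        rp["y"] + rp["height"] < ce[2] - r || rp["y"] > ce[2] + r))
    stopf("reference patch overlaps the tendon ellipse")
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 tendon_ellipse = tendon_ellipse,
                 reference_patch = rp, texture_seed = as.integer(texture_seed),
                 mm_per_px = mm_per_px, bg_mean = bg_mean,
                 bg_contrast = bg_contrast, tendon_mean = tendon_mean,
                 tendon_contrast = tendon_contrast,
                 texture_sigma_px = texture_sigma_px,
                 spot_amp = spot_amp, spot_density = spot_density,
                 spot_sigma_px = spot_sigma_px,
                 edge_softness_px = edge_softness_px),
            class = "scene_spec")
}

#' Default ROIs for a synthetic scene
#'
#' `tendon_roi()` is the tracking region: the largest axis-aligned
#' rectangle inscribed in the tendon ellipse (as a user would draw the
#' ROI onto the tendon itself, so every marker lies on moving tissue).
#' `reference_roi()` is the promontory patch used for stabilization.
#'
#' @param scene a [scene_spec()].
#' @return A [roi()].
#' @export
tendon_roi <- function(scene) {
  ce <- scene$tendon_ellipse$center
  ax <- scene$tendon_ellipse$axes
  th <- scene$tendon_ellipse$orientation
  # bounding-box half extents of the rotated ellipse
  wh <- sqrt((ax[1] * cos(th))^2 + (ax[2] * sin(th))^2)
  hh <- sqrt((ax[1] * sin(th))^2 + (ax[2] * cos(th))^2)
  # shrink until both corner types lie inside the ellipse
  efun <- function(px, py) {
    xr <- px * cos(th) + py * sin(th)
    yr <- -px * sin(th) + py * cos(th)
    (xr / ax[1])^2 + (yr / ax[2])^2
  }
  s <- 1 / sqrt(max(efun(wh, hh), efun(wh, -hh)))
  x0 <- ceiling(ce[1] - s * wh + 1); y0 <- ceiling(ce[2] - s * hh + 1)
  x1 <- floor(ce[1] + s * wh - 1); y1 <- floor(ce[2] + s * hh - 1)
  roi(x0, y0, x1 - x0 + 1, y1 - y0 + 1, "tendon")
}

#' @rdname tendon_roi
#' @export
reference_roi <- function(scene) {
  rp <- scene$reference_patch
  roi(rp[["x"]], rp[["y"]], rp[["width"]], rp[["height"]], "reference")
}

#' Nuisance (global) motion model
#'
#' Whole-frame motion superimposed on the scene: heartbeat-rate
#' oscillation, slow respiratory drift, and per-frame white camera
#' jitter, plus additive sensor noise on the rendered intensities.
#'
#' @param heartbeat_amp_px,heartbeat_freq_hz heartbeat oscillation
#'   amplitude (px) and rate (Hz).
#' @param respiration_amp_px,respiration_freq_hz respiratory drift
#'   amplitude (px) and rate (Hz).
#' @param jitter_sd_px SD of per-frame white translation jitter (px).
#' @param sensor_noise_sd SD of additive intensity noise on `[0, 1]`.
#' @return An object of class `nuisance_model`.
#' @export
nuisance_model <- function(heartbeat_amp_px = 0.8, heartbeat_freq_hz = 1.1,
                           respiration_amp_px = 2.0,
                           respiration_freq_hz = 0.25,
                           jitter_sd_px = 0.1, sensor_noise_sd = 0.01) {
  amps <- c(heartbeat_amp_px, respiration_amp_px, jitter_sd_px,
            sensor_noise_sd)
  if (any(amps < 0)) stopf("amplitudes and SDs must be >= 0")
  if (heartbeat_freq_hz <= 0 || respiration_freq_hz <= 0)
    stopf("frequencies must be > 0")
  structure(list(heartbeat_amp_px = heartbeat_amp_px,
                 heartbeat_freq_hz = heartbeat_freq_hz,
                 respiration_amp_px = respiration_amp_px,
                 respiration_freq_hz = respiration_freq_hz,
                 jitter_sd_px = jitter_sd_px,
                 sensor_noise_sd = sensor_noise_sd),
            class = "nuisance_model")
}

#' Stapedius twitch response model
#'
#' Amplitude grows with stimulation level as a logistic with a threshold
#' and a saturation plateau; the time course of one twitch is a
#' difference of exponentials (rise then decay) starting `latency_s`
#' after the stimulus.
#'
#' @param threshold_level stimulation level at the logistic midpoint.
#' @param saturation_amp_px maximal twitch displacement (px).
#' @param slope logistic growth rate per stimulation unit.
#' @param latency_s delay between stimulus onset and motion onset.
#' @param rise_tau_s,decay_tau_s rise/decay time constants (s).
#' @param direction unit 2-vector of tendon motion (normalized here).
#' @return An object of class `twitch_model`.
#' @export
twitch_model <- function(threshold_level = 20, saturation_amp_px = 3,
                         slope = 0.5, latency_s = 0.06, rise_tau_s = 0.05,
                         decay_tau_s = 0.2, direction = c(0.8, -0.6)) {
  if (saturation_amp_px < 0) stopf("saturation_amp_px must be >= 0")
  if (rise_tau_s <= 0 || decay_tau_s <= 0) stopf("time constants must be > 0")
  nd <- sqrt(sum(direction^2))
  if (nd <= 0) stopf("direction must be non-zero")
  structure(list(threshold_level = threshold_level,
                 saturation_amp_px = saturation_amp_px, slope = slope,
                 latency_s = latency_s, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, direction = direction / nd),
            class = "twitch_model")
}

#' Twitch amplitude as a function of stimulation level
#'
#' `saturation_amp_px * logistic(slope * (level - threshold_level))`:
#' non-decreasing in level, half the saturation amplitude exactly at the
#' threshold level, and bounded by the saturation amplitude.
#'
#' @param model a [twitch_model()].
#' @param level stimulation level(s), all non-negative.
#' @return Twitch displacement amplitude(s) in pixels.
#' @export
amplitude_at_level <- function(model, level) {
  if (any(level < 0)) stopf("stimulation level must be >= 0")
  model$saturation_amp_px * stats::plogis(model$slope * (level - model$threshold_level))
}

#' Build a stimulus schedule
#'
#' @param onsets_s stimulus onset times (s).
#' @param levels stimulation levels, recycled to the number of onsets.
#' @param electrode electrode position for every stimulus.
#' @param patient_id identifier written into the schedule.
#' @return Data frame with columns `stimulus_id, patient_id, electrode,
#'   level, onset_s`.
#' @export
stimulus_schedule <- function(onsets_s, levels, electrode = "middle",
                              patient_id = "synthetic") {
  n <- length(onsets_s)
  if (n == 0)
    return(data.frame(stimulus_id = integer(0), patient_id = character(0),
                      electrode = character(0), level = numeric(0),
                      onset_s = numeric(0)))
  data.frame(stimulus_id = seq_len(n), patient_id = patient_id,
             electrode = rep(electrode, length.out = n),
             level = rep(levels, length.out = n), onset_s = onsets_s)
}

# scattered flat-cored spots (specular highlights / fibrous speckle):
# randomly placed super-Gaussian bumps -- flat top, sharp edge -- with
# random sign and amplitude in [0.5, 1] of full strength
spot_texture <- function(h, w, density, sigma) {
  n <- max(1L, as.integer(round(density * h * w)))
  cx <- runif(n, 0, w - 1); cy <- runif(n, 0, h - 1)
  amp <- runif(n, 0.5, 1) * sample(c(-1, 1), n, replace = TRUE)
  x <- matrix(rep(0:(w - 1), each = h), h)
  y <- matrix(rep(0:(h - 1), w), h)
  out <- matrix(0, h, w)
  for (k in seq_len(n)) {
    r2 <- ((x - cx[k])^2 + (y - cy[k])^2) / (2 * sigma^2)
    out <- out + amp[k] * exp(-r2^3)
  }
  out
}

# band-limited texture: white noise smoothed by a circular Gaussian, then
# standardized to zero mean / unit SD
band_limited_texture <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  circ_conv <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), -half:half, function(i, o) ((i + o - 1) %% n) + 1)
    as.numeric(matrix(v[idx], n) %*% k)
  }
  z <- apply(z, 2, circ_conv)
  z <- t(apply(z, 1, circ_conv))
  (z - mean(z)) / sd(z)
}

soft_ellipse_mask <- function(scene) {
  ce <- scene$tendon_ellipse$center
  ax <- scene$tendon_ellipse$axes
  th <- scene$tendon_ellipse$orientation
  x <- matrix(rep(0:(scene$frame_width - 1), each = scene$frame_height),
              scene$frame_height)
  y <- matrix(rep(0:(scene$frame_height - 1), scene$frame_width),
              scene$frame_height)
  xr <- (x - ce[1]) * cos(th) + (y - ce[2]) * sin(th)
  yr <- -(x - ce[1]) * sin(th) + (y - ce[2]) * cos(th)
  r <- sqrt((xr / ax[1])^2 + (yr / ax[2])^2)
  # signed distance from the ellipse edge, approximately in pixels
  d <- (r - 1) * min(ax)
  stats::plogis(-d / scene$edge_softness_px)
}

twitch_waveform <- function(model, t) {
  # unit-peak difference of exponentials, delayed by the latency
  s <- t - model$latency_s
  w <- ifelse(s > 0, (1 - exp(-s / model$rise_tau_s)) * exp(-s / model$decay_tau_s), 0)
  s_peak <- model$rise_tau_s * log(1 + model$decay_tau_s / model$rise_tau_s)
  peak <- (1 - exp(-s_peak / model$rise_tau_s)) * exp(-s_peak / model$decay_tau_s)
  w / peak
}

twitch_peak_delay <- function(model) {
  model$latency_s +
    model$rise_tau_s * log(1 + model$decay_tau_s / model$rise_tau_s)
}

#' Render a synthetic microscope sequence with ground truth
#'
#' Renders frames in which the whole scene is translated by the nuisance
#' trace (sub-pixel, bilinear) and the tendon layer is additionally
#' translated by the summed twitch waveforms of the scheduled stimuli.
#' Also produces the audio sync track (one tone burst per stimulus) and
#' the ground-truth record. Identical inputs and seed give bit-identical
#' output; rendered intensities are quantized to the 16-bit grid so that
#' a [write_frames()]/[read_frames()] round trip is exact.
#'
#' @param scene a [scene_spec()].
#' @param schedule data frame from [stimulus_schedule()] (may be empty).
#' @param nuisance a [nuisance_model()].
#' @param twitch a [twitch_model()].
#' @param fps frame rate (Hz).
#' @param duration_s total duration; defaults to the last onset + 1.5 s.
#' @param seed integer seed for jitter and sensor noise.
#' @param audio_rate_hz,burst_dur_s,burst_freq_hz sync-tone parameters.
#' @return List with elements `sequence` ([frame_sequence()]), `sync`
#'   ([sync_track()]) and `truth` (list of per-stimulus and per-frame
#'   ground-truth data frames).
#' @export
synthesize_sequence <- function(scene, schedule, nuisance = nuisance_model(),
                                twitch = twitch_model(), fps = 50,
                                duration_s = NULL, seed = 1L,
                                audio_rate_hz = 8000, burst_dur_s = 0.01,
                                burst_freq_hz = 1000) {
  if (fps <= 0) stopf("fps must be > 0")
  if (is.null(duration_s))
    duration_s <- if (nrow(schedule)) max(schedule$onset_s) + 1.5 else 2
  if (nrow(schedule) && any(schedule$onset_s < 0 | schedule$onset_s >= duration_s))
    stopf("schedule onsets must lie within the sequence duration")
  n <- max(2L, as.integer(ceiling(duration_s * fps)))
  t <- (seq_len(n) - 1) / fps

  # warn on overlapping twitch windows (amplitudes are summed)
  if (nrow(schedule) > 1) {
    win_end <- schedule$onset_s + twitch$latency_s + twitch$rise_tau_s +
      4 * twitch$decay_tau_s
    o <- order(schedule$onset_s)
    if (any(win_end[o][-nrow(schedule)] > schedule$onset_s[o][-1]))
      warning("overlapping twitch windows; amplitudes are summed")
  }

  h <- scene$frame_height; w <- scene$frame_width
  bg <- with_seed(scene$texture_seed, {
    b <- scene$bg_mean +
      scene$bg_contrast * band_limited_texture(h, w, scene$texture_sigma_px) +
      scene$spot_amp * spot_texture(h, w, scene$spot_density, scene$spot_sigma_px)
    tt <- scene$tendon_mean +
      scene$tendon_contrast * band_limited_texture(h, w, scene$texture_sigma_px) +
      scene$spot_amp * spot_texture(h, w, scene$spot_density, scene$spot_sigma_px)
    list(bg = b, tendon = tt)
  })
  mask <- soft_ellipse_mask(scene)

  truth_stim <- NULL
  twitch_x <- numeric(n); twitch_y <- numeric(n); twitch_disp <- numeric(n)
  if (nrow(schedule)) {
    amp <- amplitude_at_level(twitch, schedule$level)
    for (k in seq_len(nrow(schedule)))
      twitch_disp <- twitch_disp + amp[k] * twitch_waveform(twitch, t - schedule$onset_s[k])
    twitch_x <- twitch$direction[1] * twitch_disp
    twitch_y <- twitch$direction[2] * twitch_disp
    truth_stim <- data.frame(stimulus_id = schedule$stimulus_id,
                             onset_s = schedule$onset_s,
                             level = schedule$level,
                             true_amp_px = amp,
                             peak_time_s = schedule$onset_s + twitch_peak_delay(twitch))
  } else {
    truth_stim <- data.frame(stimulus_id = integer(0), onset_s = numeric(0),
                             level = numeric(0), true_amp_px = numeric(0),
                             peak_time_s = numeric(0))
  }

  frames <- with_seed(seed, {
    ph <- runif(2, 0, 2 * pi)
    hb <- nuisance$heartbeat_amp_px * sin(2 * pi * nuisance$heartbeat_freq_hz * t + ph[1])
    rs <- nuisance$respiration_amp_px * sin(2 * pi * nuisance$respiration_freq_hz * t + ph[2])
    # heartbeat mostly vertical, respiration mostly horizontal
    ndx <- 0.35 * hb + 0.95 * rs + rnorm(n, 0, nuisance$jitter_sd_px)
    ndy <- 0.94 * hb + 0.31 * rs + rnorm(n, 0, nuisance$jitter_sd_px)
    fr <- vector("list", n)
    for (i in seq_len(n))
      fr[[i]] <- cpp_render_frame(bg$bg, bg$tendon, mask, ndx[i], ndy[i],
                                  twitch_x[i], twitch_y[i],
                                  nuisance$sensor_noise_sd)
    attr(fr, "nuisance_dx") <- ndx
    attr(fr, "nuisance_dy") <- ndy
    fr
  })
  ndx <- attr(frames, "nuisance_dx"); ndy <- attr(frames, "nuisance_dy")
  attributes(frames) <- NULL

  # sync audio: one tone burst per scheduled stimulus
  ns <- as.integer(ceiling(duration_s * audio_rate_hz))
  samples <- numeric(ns)
  if (nrow(schedule)) {
    nb <- as.integer(round(burst_dur_s * audio_rate_hz))
    tb <- (seq_len(nb) - 1) / audio_rate_hz
    for (on in schedule$onset_s) {
      i0 <- as.integer(round(on * audio_rate_hz))
      idx <- i0 + seq_len(nb)
      idx <- idx[idx <= ns]
      samples[idx] <- samples[idx] + 0.8 * sin(2 * pi * burst_freq_hz * tb[seq_along(idx)])
    }
  }

  list(sequence = frame_sequence(frames, fps = fps),
       sync = sync_track(pmin(pmax(samples, -1), 1), audio_rate_hz),
       truth = list(
         stimuli = truth_stim,
         frames = data.frame(frame = seq_len(n), time_s = t,
                             nuisance_dx = ndx, nuisance_dy = ndy,
                             tendon_dx = twitch_x, tendon_dy = twitch_y,
                             tendon_disp_px = abs(twitch_disp))))
}

#' Write a complete synthetic fixture set to disk
#'
#' Writes the frame stack, WAV sync track, stimulus schedule CSV and
#' ground-truth CSVs produced by [synthesize_sequence()].
#'
#' @param sim result of [synthesize_sequence()].
#' @param schedule the schedule used to generate it.
#' @param dir output directory.
#' @export
write_fixture_set <- function(sim, schedule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(sim$sequence, file.path(dir, "frames"))
  write_wav(sim$sync, file.path(dir, "sync.wav"))
  write_stimulus_log(schedule, file.path(dir, "schedule.csv"))
  utils::write.csv(sim$truth$stimuli, file.path(dir, "truth_stimuli.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$frames, file.path(dir, "truth_frames.csv"),
                   row.names = FALSE)
  invisible(dir)
}
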