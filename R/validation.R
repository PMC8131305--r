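#' Synthetic validation studies
#'
#' Self-contained simulation studies that exercise the whole pipeline on
#' ground-truthed synthetic scenes: detector operating point
#' (sensitivity/specificity), reflex-threshold recovery over level
#' sweeps, heartbeat rejection, sub-pixel tracking accuracy and
#' stabilization quality. Each is deterministic given its seed and is
#' used both by the test suite and by the acceptance script.
#'
#' @name validation
NULL

# default stimulus train for one synthetic run: onsets every 1.2 s
study_schedule <- function(n, levels, electrode = "middle") {
  stimulus_schedule(onsets_s = 0.8 + 1.2 * (seq_len(n) - 1), levels = levels,
                    electrode = electrode)
}

run_synthetic_batch <- function(seed, levels, saturation_amp_px = 3,
                                nuisance = nuisance_model(),
                                twitch = twitch_model(),
                                detector = detector_params(),
                                search_radius_px = 8) {
  twitch$saturation_amp_px <- saturation_amp_px
  scene <- scene_spec(texture_seed = seed)
  sched <- study_schedule(length(levels), levels)
  sim <- synthesize_sequence(scene, sched, nuisance, twitch, seed = seed)
  ana <- analyze_sequence(sim$sequence, tendon_roi(scene),
                          reference_roi(scene), sched, detector = detector,
                          search_radius_px = search_radius_px)
  list(analysis = ana, truth = sim$truth, scene = scene)
}

#' @describeIn validation Detector operating point over seeded synthetic
#'   stimuli. Scenes are processed in batches; on every scene a
#'   stimulus-free calibration run measures that scene's raw
#'   displacement-signal noise floor, defines the twitch amplitude as
#'   `snr` times it, and contributes the calibration stimuli as true
#'   negatives and the twitch run as true positives.
#' @param n_stimuli total number of stimuli (half negatives, half
#'   positives).
#' @param seed integer seed.
#' @param snr twitch amplitude in multiples of the scene's raw-signal
#'   noise floor.
#' @param batch_size stimuli per rendered sequence.
#' @export
validation_operating_point <- function(n_stimuli = 200, seed = 1, snr = 5,
                                       batch_size = 10) {
  n_scenes <- ceiling(n_stimuli / (2 * batch_size))
  pos <- neg <- 0L; pos_det <- neg_det <- 0L
  floors <- amps <- numeric(n_scenes)
  for (k in seq_len(n_scenes)) {
    s <- seed * 1000L + k
    calib <- run_synthetic_batch(s, levels = rep(0, batch_size))
    floor_k <- mad(calib$analysis$signal$values)
    amp <- snr * floor_k
    floors[k] <- floor_k; amps[k] <- amp
    neg <- neg + batch_size
    neg_det <- neg_det + sum(calib$analysis$detections$detected)
    # level 40 with threshold 20 puts the logistic at ~1: amplitude = amp
    twr <- run_synthetic_batch(s + 500000L, levels = rep(40, batch_size),
                               saturation_amp_px = amp / stats::plogis(0.5 * 20))
    pos <- pos + batch_size
    pos_det <- pos_det + sum(twr$analysis$detections$detected)
  }
  list(sensitivity = pos_det / pos, specificity = 1 - neg_det / neg,
       n_positive = pos, n_negative = neg,
       median_floor_px = median(floors), median_amp_px = median(amps))
}

#' @describeIn validation Reflex-threshold (eSRT) recovery on level
#'   sweeps. Each sweep renders levels 10..40 in steps of 2, estimates
#'   the eSRT and compares it with the forward-model oracle: the lowest
#'   tested level whose true twitch amplitude exceeds `threshold_k`
#'   times the run's measured noise floor.
#' @param n_sweeps number of seeded sweeps.
#' @export
validation_esrt_recovery <- function(n_sweeps = 50, seed = 1) {
  levels <- seq(10, 40, by = 2)
  hits <- 0L; est <- oracle <- numeric(n_sweeps)
  for (k in seq_len(n_sweeps)) {
    s <- seed * 1000L + k
    r <- run_synthetic_batch(s, levels = levels)
    det <- r$analysis$detections
    es <- estimate_esrt(det)
    # brute-force forward-model crossing at this run's own noise floor
    tw <- twitch_model()
    thr <- det$threshold_px[1]
    amp <- amplitude_at_level(tw, levels)
    cross <- levels[which(amp > thr)[1]]
    est[k] <- if (es$reflex_present) es$esrt_level else NA
    oracle[k] <- cross
    if (!is.na(est[k]) && abs(est[k] - cross) <= 2) hits <- hits + 1L
  }
  list(success_rate = hits / n_sweeps, n_sweeps = n_sweeps,
       estimated = est, oracle = oracle)
}

#' @describeIn validation Heartbeat rejection: stimulus trains on scenes
#'   whose only perturbation is a pure heartbeat-rate sinusoidal
#'   oscillation (no twitch, no other noise). Returns the fraction of
#'   runs with zero detections.
#' @param n_runs number of seeded runs.
#' @param n_stimuli_per_run stimuli per run.
#' @export
validation_heartbeat_rejection <- function(n_runs = 10, seed = 1,
                                           n_stimuli_per_run = 20) {
  clean <- 0L
  nuis <- nuisance_model(respiration_amp_px = 0, jitter_sd_px = 0,
                         sensor_noise_sd = 0)
  for (k in seq_len(n_runs)) {
    r <- run_synthetic_batch(seed * 1000L + k,
                             levels = rep(0, n_stimuli_per_run),
                             nuisance = nuis)
    if (!any(r$analysis$detections$detected)) clean <- clean + 1L
  }
  list(clean_fraction = clean / n_runs, n_runs = n_runs)
}

#' @describeIn validation Sub-pixel tracking accuracy on noise-free
#'   pure-translation sequences: the whole scene translates along a
#'   smooth trajectory, stabilization is bypassed, and tracked marker
#'   displacements are compared with the applied shift. Returns the RMS
#'   error in px.
#' @param n_frames frames per sequence.
#' @export
validation_tracking_accuracy <- function(seed = 1, n_frames = 60) {
  scene <- scene_spec(texture_seed = seed)
  nuis <- nuisance_model(heartbeat_amp_px = 1.2, heartbeat_freq_hz = 0.9,
                         respiration_amp_px = 0, jitter_sd_px = 0,
                         sensor_noise_sd = 0)
  sim <- synthesize_sequence(scene, stimulus_schedule(numeric(0), numeric(0)),
                             nuis, twitch_model(),
                             duration_s = n_frames / 50, seed = seed)
  markers <- select_markers(detect_regions(sim$sequence$frames[[1]],
                                           tendon_roi(scene)))
  traj <- track_markers(sim$sequence, markers)
  tr <- sim$truth$frames
  errs <- c(sweep(traj$x, 2, traj$baseline$x) -
              matrix(tr$nuisance_dx - tr$nuisance_dx[1], nrow(traj$x),
                     ncol(traj$x)),
            sweep(traj$y, 2, traj$baseline$y) -
              matrix(tr$nuisance_dy - tr$nuisance_dy[1], nrow(traj$y),
                     ncol(traj$y)))
  errs <- errs[c(traj$valid, traj$valid)]
  list(rms_error_px = sqrt(mean(errs^2)), n_markers = nrow(markers),
       n_frames = n_frames)
}

#' @describeIn validation Stabilization quality on heartbeat-only
#'   sequences: residual motion of the reference patch after
#'   stabilization, as the RMS difference between recovered and true
#'   nuisance shifts.
#' @export
validation_stabilization <- function(seed = 1, n_frames = 100) {
  scene <- scene_spec(texture_seed = seed)
  nuis <- nuisance_model(respiration_amp_px = 0, jitter_sd_px = 0,
                         sensor_noise_sd = 0)
  sim <- synthesize_sequence(scene, stimulus_schedule(numeric(0), numeric(0)),
                             nuis, twitch_model(),
                             duration_s = n_frames / 50, seed = seed)
  stab <- stabilize_sequence(sim$sequence, reference_roi(scene),
                             search_radius_px = 8)
  tr <- sim$truth$frames
  ex <- stab$shifts$dx - (tr$nuisance_dx - tr$nuisance_dx[1])
  ey <- stab$shifts$dy - (tr$nuisance_dy - tr$nuisance_dy[1])
  list(residual_rms_px = sqrt(mean(ex^2 + ey^2)), n_frames = n_frames)
}
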