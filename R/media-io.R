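#' Frame sequences
#'
#' A `frame_sequence` is the pipeline's raw input: an ordered stack of
#' equally sized grayscale frames with a frame rate and per-frame
#' timestamps. Frames are numeric matrices indexed `[y, x]` with
#' intensities in `[0, 1]`; all pixel coordinates in this package are
#' 0-based, so the centre of the top-left pixel is at `(0, 0)`.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param fps frame rate in Hz.
#' @param timestamps optional per-frame times in seconds; defaults to
#'   `(0:(n-1))/fps`. Must be strictly increasing and consistent with
#'   `fps` within 1 ms.
#' @return An object of class `frame_sequence` with elements `frames`,
#'   `fps`, `timestamps`.
#' @export
frame_sequence <- function(frames, fps, timestamps = NULL) {
  if (!is.list(frames) || length(frames) < 2L)
    stopf("a frame sequence needs at least 2 frames", class = "format_error")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must have identical dimensions", class = "format_error")
  if (!is.numeric(fps) || fps <= 0) stopf("fps must be > 0")
  n <- length(frames)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / fps
  if (length(timestamps) != n || any(diff(timestamps) <= 0))
    stopf("timestamps must be strictly increasing, one per frame")
  if (max(abs(timestamps - (timestamps[1] + (seq_len(n) - 1) / fps))) > 1e-3)
    stopf("timestamps inconsistent with fps (> 1 ms)")
  structure(list(frames = frames, fps = fps, timestamps = timestamps),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> %d frames, %d x %d px, %.4g fps, %.3f s\n",
              length(x$frames), d[2], d[1], x$fps,
              x$timestamps[length(x$timestamps)] - x$timestamps[1]))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

frame_dim <- function(seq) dim(seq$frames[[1]])

#' Rectangular region of interest
#'
#' Rectangle in 0-based, half-open pixel coordinates: columns
#' `x .. x+width-1` and rows `y .. y+height-1` are inside.
#'
#' @param x,y top-left corner (0-based pixels).
#' @param width,height extent in pixels, both at least 8.
#' @param label either `"tendon"` (signal region on the stapedius tendon)
#'   or `"reference"` (stabilization patch on the cochlear promontory).
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, width, height, label = c("tendon", "reference")) {
  label <- match.arg(label)
  if (width < 8 || height < 8) stopf("ROI must be at least 8 x 8 px")
  if (x < 0 || y < 0) stopf("ROI origin must be non-negative")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 label = label), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi:%s> x=%g y=%g w=%g h=%g\n", x$label, x$x, x$y,
              x$width, x$height))
  invisible(x)
}

check_roi_in_frame <- function(r, dims) {
  if (r$x + r$width > dims[2] || r$y + r$height > dims[1])
    stopf("ROI (%g,%g,%gx%g) does not fit in a %d x %d frame",
          r$x, r$y, r$width, r$height, dims[2], dims[1])
  invisible(r)
}

crop_roi <- function(frame, r) {
  frame[(r$y + 1):(r$y + r$height), (r$x + 1):(r$x + r$width), drop = FALSE]
}

#' Read and write ROI definitions as JSON
#'
#' @param path file path.
#' @param rois a list of [roi()] objects (named or not).
#' @return `read_rois()` returns a list of `roi` objects.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "roi")) rois <- list(rois)
  out <- lapply(rois, function(r) r[c("x", "y", "width", "height", "label")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) roi(r$x, r$y, r$width, r$height, r$label))
}

# ---------------------------------------------------------------------------
# frame stack I/O: numbered 16-bit TIFF (or PNG) directory + meta.json
# ---------------------------------------------------------------------------

to_gray <- function(img) {
  # ITU-R BT.601 luma for RGB(A) input; already-gray input passes through
  if (length(dim(img)) == 3L)
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  img
}

#' Write a frame sequence to a numbered image directory
#'
#' Frames are stored as 16-bit grayscale TIFF files plus a `meta.json`
#' carrying the frame rate, so that [read_frames()] round-trips exactly.
#'
#' @param seq a [frame_sequence()].
#' @param dir output directory (created if missing).
#' @param format `"tiff"` or `"png"` (PNG is 8-bit).
#' @export
write_frames <- function(seq, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  for (i in seq_along(seq$frames)) {
    f <- file.path(dir, sprintf("frame_%06d.%s", i, ext))
    img <- pmin(pmax(seq$frames[[i]], 0), 1)
    if (format == "tiff") tiff::writeTIFF(img, f, bits.per.sample = 16L)
    else png::writePNG(img, f)
  }
  jsonlite::write_json(
    list(fps = seq$fps, n_frames = length(seq$frames),
         width = ncol(seq$frames[[1]]), height = nrow(seq$frames[[1]])),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame sequence from an image directory
#'
#' Reads a directory of numbered TIFF/PNG frames (as written by
#' [write_frames()], or any lexicographically ordered stack). Color input
#' is converted to grayscale with BT.601 luma weights.
#'
#' @param path directory containing the frames.
#' @param downsample_factor integer spatial downsampling factor; blocks of
#'   `k x k` pixels are averaged (1 = native resolution).
#' @param fps frame rate override; defaults to the value in `meta.json`.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, downsample_factor = 1L, fps = NULL) {
  if (!dir.exists(path)) stopf("no such directory: %s", path, class = "io_error")
  files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$", full.names = TRUE))
  if (length(files) < 2L)
    stopf("directory %s holds fewer than 2 frames", path, class = "io_error")
  meta_path <- file.path(path, "meta.json")
  if (is.null(fps)) {
    if (!file.exists(meta_path))
      stopf("no meta.json in %s and no fps given", path, class = "io_error")
    fps <- jsonlite::read_json(meta_path)$fps
  }
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    to_gray(img)
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("mixed frame sizes in %s", path, class = "format_error")
  k <- as.integer(downsample_factor)
  if (k > 1L) frames <- lapply(frames, downsample_block, k = k)
  frame_sequence(frames, fps = fps)
}

downsample_block <- function(img, k) {
  h <- (nrow(img) %/% k) * k
  w <- (ncol(img) %/% k) * k
  img <- img[seq_len(h), seq_len(w), drop = FALSE]
  # mean over k x k blocks
  m <- matrix(colMeans(matrix(img, nrow = k)), nrow = h %/% k)
  t(matrix(colMeans(matrix(t(m), nrow = k)), nrow = w %/% k))
}

# ---------------------------------------------------------------------------
# WAV sync track I/O (minimal mono PCM16 RIFF)
# ---------------------------------------------------------------------------

#' Audio sync tracks
#'
#' The stimulation system emits a tone burst simultaneous with each
#' electrical stimulus; the recorded mono audio track is used to place
#' stimuli on the video timeline.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @return An object of class `sync_track`.
#' @export
sync_track <- function(samples, sample_rate) {
  if (sample_rate <= 0) stopf("sample_rate must be > 0")
  if (any(!is.finite(samples))) stopf("sync track samples must be finite")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "sync_track")
}

#' Read and write mono 16-bit PCM WAV files
#'
#' @param track a [sync_track()].
#' @param path file path.
#' @return `read_wav()` returns a [sync_track()].
#' @export
write_wav <- function(track, path) {
  s <- as.integer(round(pmin(pmax(track$samples, -1), 1) * 32767))
  n <- length(s)
  sr <- as.integer(round(track$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + 2 * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(1); w16(1)            # PCM, mono
  w32(sr); w32(sr * 2)      # sample rate, byte rate
  w16(2); w16(16)           # block align, bits per sample
  writeChar("data", con, eos = NULL); w32(2 * n)
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  hdr <- readChar(con, 4); r32()
  if (!identical(hdr, "RIFF") || !identical(readChar(con, 4), "WAVE"))
    stopf("%s is not a RIFF/WAVE file", path, class = "io_error")
  sr <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stopf("no data chunk in %s", path)
    size <- r32()
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stopf("only mono PCM WAV is supported", class = "io_error")
      sr <- r32(); r32()
      ba <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba[2] != 16) stopf("only 16-bit WAV is supported", class = "io_error")
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (identical(id, "data")) {
      s <- readBin(con, "integer", n = size / 2, size = 2, endian = "little")
      return(sync_track(s / 32767, sr))
    } else {
      readBin(con, "raw", n = size)
    }
  }
}

#' Detect sync-tone onsets in an audio track
#'
#' Rectifies the track, smooths it with a short moving-average envelope,
#' and returns the rising-edge times where the envelope crosses a
#' threshold expressed as a fraction of the envelope maximum (so the
#' result is invariant to global gain). Edges closer than `min_gap_s` to
#' the previous onset are suppressed.
#'
#' @param track a [sync_track()].
#' @param envelope_threshold fraction of the envelope maximum in (0, 1).
#' @param min_gap_s minimal spacing between reported onsets, seconds.
#' @param envelope_window_s moving-average window for the envelope.
#' @return Sorted numeric vector of onset times in seconds (empty for a
#'   silent track).
#' @export
detect_sync_onsets <- function(track, envelope_threshold = 0.5,
                               min_gap_s = 0.1, envelope_window_s = 0.005) {
  if (envelope_threshold <= 0 || envelope_threshold >= 1)
    stopf("envelope_threshold must be in (0, 1)")
  x <- abs(track$samples)
  k <- max(1L, as.integer(round(envelope_window_s * track$sample_rate)))
  env <- as.numeric(stats::filter(c(x, numeric(k)), rep(1 / k, k), sides = 1))
  env <- env[k:(k + length(x) - 1)]  # shift so the window is causal-centred
  peak <- max(env)
  if (peak <= 0) return(numeric(0))
  above <- env >= envelope_threshold * peak
  edges <- which(above & !c(FALSE, above[-length(above)]))
  if (length(edges) == 0) return(numeric(0))
  t <- (edges - 1) / track$sample_rate
  keep <- c(TRUE, diff(t) >= min_gap_s)
  # refractory: enforce the gap against the last *kept* onset
  out <- t[1]
  for (ti in t[-1]) if (ti - out[length(out)] >= min_gap_s) out <- c(out, ti)
  out
}

# ---------------------------------------------------------------------------
# stimulus logs and alignment
# ---------------------------------------------------------------------------

ELECTRODES <- c("basal", "middle", "apical")

#' Read a stimulus log CSV
#'
#' Expected columns: `stimulus_id, patient_id, electrode, level`, with
#' `electrode` one of basal/middle/apical; an optional `onset_s` column
#' places stimuli on the video timeline when no audio sync track exists.
#'
#' @param path CSV path.
#' @return A data frame of stimulus records.
#' @export
read_stimulus_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus_id", "patient_id", "electrode", "level")
  miss <- setdiff(need, names(log))
  if (length(miss))
    stopf("stimulus log %s lacks columns: %s", path,
          paste(miss, collapse = ", "), class = "format_error")
  bad <- setdiff(unique(log$electrode), ELECTRODES)
  if (length(bad))
    stopf("unknown electrode position(s): %s", paste(bad, collapse = ", "),
          class = "format_error")
  log
}

#' @rdname read_stimulus_log
#' @param log stimulus-record data frame.
#' @export
write_stimulus_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Align stimulus records with sync-tone onsets
#'
#' Pairs the k-th log record with the k-th detected onset (plus a fixed
#' audio-video offset), preserving order.
#'
#' @param onsets numeric vector of onset times in seconds.
#' @param log stimulus-record data frame (see [read_stimulus_log()]).
#' @param offset_s constant audio-to-video offset added to every onset.
#' @return The log data frame with an `onset_s` column.
#' @export
align_stimuli <- function(onsets, log, offset_s = 0) {
  if (length(onsets) != nrow(log))
    stopf("cannot align %d sync onsets with %d log records",
          length(onsets), nrow(log), class = "alignment_error")
  log$onset_s <- onsets + offset_s
  log
}

#' Read/write per-stimulus detection reports
#'
#' CSV schema: `stimulus_id, electrode, level, detected,
#' motion_vector_length_px, latency_s, noise_floor_px, threshold_px`.
#'
#' @param detections detection data frame from [detect_reflexes()].
#' @param path CSV path.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$detected <- as.logical(d$detected)
  d
}
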