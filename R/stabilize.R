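#' Estimate the global shift of a frame against a reference template
#'
#' Normalized cross-correlation of the reference template over a square
#' search window; the integer peak is refined to sub-pixel precision by
#' 1-D quadratic interpolation along each axis and then polished by a
#' few Lucas-Kanade iterations of the template against the frame (the
#' parabola fit alone carries a periodic sub-pixel bias that would leak
#' slow nuisance motion into the displacement signal). `quality` is the
#' peak NCC in `[-1, 1]`.
#'
#' @param frame numeric matrix.
#' @param template reference-patch pixels (matrix), cut from the
#'   reference frame at position `(tx, ty)`.
#' @param tx,ty template top-left position in the reference frame
#'   (0-based).
#' @param search_radius_px maximal shift searched, per axis.
#' @return List with `dx`, `dy` (content shift of `frame` relative to
#'   the reference, px) and `quality`.
#' @export
estimate_shift <- function(frame, template, tx, ty, search_radius_px = 20) {
  if (search_radius_px < 1) stopf("search radius must be >= 1")
  if (nrow(template) >= nrow(frame) || ncol(template) >= ncol(frame))
    stopf("template must be smaller than the frame")
  r <- cpp_ncc_match(frame, template, as.integer(tx), as.integer(ty),
                     as.integer(search_radius_px))
  rf <- cpp_refine_shift(frame, template, as.integer(tx), as.integer(ty),
                         r[1], r[2], 20L, 0.005)
  if (rf[3] > 0 && abs(rf[1] - r[1]) <= 1 && abs(rf[2] - r[2]) <= 1) {
    r[1] <- rf[1]; r[2] <- rf[2]
  }
  list(dx = r[1], dy = r[2], quality = r[3])
}

#' Stabilize a frame sequence against a reference patch
#'
#' Registers every frame to the reference ROI (typically a patch on the
#' cochlear promontory) cut from the reference frame, then translates
#' each frame by the negated shift with bilinear interpolation. This
#' removes global scene motion (heartbeat, respiration, microscope
#' vibration) while local tendon motion inside the tendon ROI survives.
#' Frames whose peak correlation falls below `quality_floor` get their
#' shift linearly interpolated from neighbouring confident frames.
#'
#' @param seq a [frame_sequence()].
#' @param ref_roi a [roi()] with label `"reference"` (any `roi` accepted).
#' @param search_radius_px search radius per axis, px.
#' @param quality_floor NCC below which a frame is flagged low-confidence.
#' @param reference_frame index of the frame the template is cut from.
#' @return List of class `stabilized` with `sequence` (the stabilized
#'   [frame_sequence()]), `shifts` (data frame `frame, dx, dy, quality,
#'   interpolated`) and `border_px` (maximal absolute shift; a border of
#'   this width is edge-padded and should be excluded from ROIs).
#' @export
stabilize_sequence <- function(seq, ref_roi, search_radius_px = 20,
                               quality_floor = 0.5, reference_frame = 1L) {
  dims <- frame_dim(seq)
  check_roi_in_frame(ref_roi, dims)
  template <- crop_roi(seq$frames[[reference_frame]], ref_roi)
  n <- length(seq$frames)
  dx <- dy <- q <- numeric(n)
  for (i in seq_len(n)) {
    if (i == reference_frame) { dx[i] <- 0; dy[i] <- 0; q[i] <- 1; next }
    e <- estimate_shift(seq$frames[[i]], template, ref_roi$x, ref_roi$y,
                        search_radius_px)
    dx[i] <- e$dx; dy[i] <- e$dy; q[i] <- e$quality
  }
  low <- q < quality_floor
  if (any(low)) {
    good <- which(!low)
    if (length(good) == 0) stopf("no frame reached the quality floor")
    dx[low] <- approx(good, dx[good], xout = which(low), rule = 2)$y
    dy[low] <- approx(good, dy[good], xout = which(low), rule = 2)$y
  }
  frames <- vector("list", n)
  for (i in seq_len(n))
    frames[[i]] <- if (dx[i] == 0 && dy[i] == 0) seq$frames[[i]]
                   else cpp_translate(seq$frames[[i]], -dx[i], -dy[i])
  structure(list(
    sequence = frame_sequence(frames, fps = seq$fps, timestamps = seq$timestamps),
    shifts = data.frame(frame = seq_len(n), dx = dx, dy = dy, quality = q,
                        interpolated = low),
    border_px = ceiling(max(abs(c(dx, dy, 0))))),
    class = "stabilized")
}

#' @export
print.stabilized <- function(x, ...) {
  cat(sprintf("<stabilized> %d frames, shift RMS %.3f px, min quality %.3f\n",
              nrow(x$shifts), sqrt(mean(x$shifts$dx^2 + x$shifts$dy^2)),
              min(x$shifts$quality)))
  invisible(x)
}

#' Export a shift trace as CSV
#'
#' @param stab result of [stabilize_sequence()].
#' @param path CSV path.
#' @export
write_shift_trace <- function(stab, path) {
  utils::write.csv(stab$shifts[, c("frame", "dx", "dy", "quality")], path,
                   row.names = FALSE)
  invisible(path)
}
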