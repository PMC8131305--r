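#' MSER detector parameters
#'
#' @param delta intensity step (on the 0..255 scale) across which region
#'   stability is evaluated.
#' @param min_area_px,max_area_px area bounds for accepted regions;
#'   `max_area_px = NULL` defaults at detection time to 1% of the ROI
#'   area, floored at `4 * min_area_px` so small ROIs remain usable.
#' @param max_variation maximal relative area change across `delta`
#'   intensity steps for a region to count as stable.
#' @return An object of class `mser_params`.
#' @export
mser_params <- function(delta = 5, min_area_px = 30, max_area_px = NULL,
                        max_variation = 0.25) {
  if (delta < 1) stopf("delta must be >= 1")
  if (min_area_px <= 0) stopf("min_area_px must be > 0")
  if (!is.null(max_area_px) && max_area_px <= min_area_px)
    stopf("max_area_px must exceed min_area_px")
  if (max_variation <= 0) stopf("max_variation must be > 0")
  structure(list(delta = as.integer(delta),
                 min_area_px = as.integer(min_area_px),
                 max_area_px = max_area_px,
                 max_variation = max_variation), class = "mser_params")
}

#' Detect maximally stable extremal regions in a ROI
#'
#' Runs MSER in both polarities (bright-on-dark and dark-on-bright, the
#' latter by inverting the ROI), summarizes every stable region by the
#' ellipse matching its zeroth/second pixel moments, and deduplicates
#' near-identical regions across stability plateaus and polarities.
#' Deterministic for fixed input.
#'
#' @param image numeric matrix, intensities in `[0, 1]`.
#' @param roi a [roi()] inside the image.
#' @param params an [mser_params()].
#' @return Data frame of class `ellipse_regions`: `center_x, center_y`
#'   (full-image 0-based sub-pixel coords), `major_axis_px,
#'   minor_axis_px, orientation_rad, pixel_count, level, variation,
#'   polarity`. Empty when the ROI holds no stable region (for example a
#'   uniform ROI) or is smaller than `min_area_px`.
#' @export
detect_regions <- function(image, roi, params = mser_params()) {
  check_roi_in_frame(roi, dim(image))
  empty <- data.frame(center_x = numeric(0), center_y = numeric(0),
                      major_axis_px = numeric(0), minor_axis_px = numeric(0),
                      orientation_rad = numeric(0), pixel_count = numeric(0),
                      level = numeric(0), variation = numeric(0),
                      polarity = character(0))
  class(empty) <- c("ellipse_regions", "data.frame")
  roi_area <- roi$width * roi$height
  if (roi_area < params$min_area_px) return(empty)
  max_area <- params$max_area_px %||%
    max(ceiling(0.01 * roi_area), 4 * params$min_area_px)
  img8 <- matrix(as.integer(round(pmin(pmax(crop_roi(image, roi), 0), 1) * 255)),
                 roi$height, roi$width)
  m1 <- cpp_mser(img8, params$delta, params$min_area_px, max_area,
                 params$max_variation)
  m2 <- cpp_mser(255L - img8, params$delta, params$min_area_px, max_area,
                 params$max_variation)
  cand <- rbind(if (nrow(m1)) cbind(m1, 1), if (nrow(m2)) cbind(m2, 2))
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  colnames(cand) <- c("cx", "cy", "mxx", "myy", "mxy", "area", "level",
                      "variation", "polarity")
  cand <- as.data.frame(cand)
  # deduplicate: most stable first, drop near-coincident duplicates
  cand <- cand[order(cand$variation, -cand$area, cand$cy, cand$cx), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    dup <- FALSE
    for (j in which(keep)) {
      d <- sqrt((cand$cx[i] - cand$cx[j])^2 + (cand$cy[i] - cand$cy[j])^2)
      ratio <- cand$area[i] / cand$area[j]
      if (d <= 2 && ratio >= 0.7 && ratio <= 1.43) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  cand <- cand[keep, , drop = FALSE]
  # ellipse from central second moments: semi-axes 2*sqrt(eigenvalues)
  ell <- t(apply(cand, 1, function(r) {
    m <- matrix(c(r["mxx"], r["mxy"], r["mxy"], r["myy"]), 2)
    e <- eigen(m, symmetric = TRUE)
    v <- e$vectors[, 1]
    c(major = 4 * sqrt(max(e$values[1], 0)),
      minor = 4 * sqrt(max(e$values[2], 0)),
      orient = atan2(v[2], v[1]))
  }))
  out <- data.frame(center_x = cand$cx + roi$x, center_y = cand$cy + roi$y,
                    major_axis_px = ell[, "major"],
                    minor_axis_px = ell[, "minor"],
                    orientation_rad = ell[, "orient"],
                    pixel_count = cand$area, level = cand$level,
                    variation = cand$variation,
                    polarity = c("bright", "dark")[cand$polarity])
  # stable output order: by position
  out <- out[order(out$center_y, out$center_x), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ellipse_regions", "data.frame")
  out
}

#' Select well-separated marker points from detected regions
#'
#' Region centers are accepted greedily in descending `pixel_count`
#' order (ties broken by `(y, x)` lexicographic order), subject to a
#' minimal pairwise separation, up to `max_markers`.
#'
#' @param regions an `ellipse_regions` data frame from [detect_regions()].
#' @param max_markers maximal number of markers.
#' @param min_separation_px minimal pairwise distance between markers.
#' @return Data frame of class `marker_set`: `marker_id, x, y,
#'   source_region` with attribute `min_separation_px`. Empty (with a
#'   warning) when no regions were supplied.
#' @export
select_markers <- function(regions, max_markers = 8, min_separation_px = 6) {
  if (max_markers < 1) stopf("max_markers must be >= 1")
  if (nrow(regions) == 0) {
    warning("no regions to select markers from; marker set is empty")
    out <- data.frame(marker_id = integer(0), x = numeric(0), y = numeric(0),
                      source_region = integer(0))
    attr(out, "min_separation_px") <- min_separation_px
    class(out) <- c("marker_set", "data.frame")
    return(out)
  }
  ord <- order(-regions$pixel_count, regions$center_y, regions$center_x)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) >= max_markers) break
    ok <- TRUE
    for (j in sel) {
      d <- sqrt((regions$center_x[i] - regions$center_x[j])^2 +
                (regions$center_y[i] - regions$center_y[j])^2)
      if (d < min_separation_px) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
  }
  out <- data.frame(marker_id = seq_along(sel), x = regions$center_x[sel],
                    y = regions$center_y[sel], source_region = sel)
  attr(out, "min_separation_px") <- min_separation_px
  class(out) <- c("marker_set", "data.frame")
  out
}
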