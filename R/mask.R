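#' Cell analysis mask
#'
#' A boolean map selecting the analyzed cell interior. The analysis disk
#' deliberately excludes the cell edges, where membrane vibrations are
#' elevated and would dominate the fluctuation statistics.
#'
#' @param pixels logical matrix (`TRUE` = analyzed).
#' @param center disk centre (row, col), pixels; `NA` when not disk-shaped.
#' @param radius_px disk radius in pixels; `NA` when not disk-shaped.
#' @return a `cell_mask` object.
#' @export
cell_mask <- function(pixels, center = c(NA_real_, NA_real_), radius_px = NA_real_) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (sum(pixels) < 100) abort("a cell mask needs at least 100 selected pixels")
  border <- c(pixels[1, ], pixels[nrow(pixels), ], pixels[, 1], pixels[, ncol(pixels)])
  if (any(border)) abort("mask must lie strictly inside the frame border")
  structure(list(pixels = pixels, center = center, radius_px = radius_px),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d x %d px, %d selected", nrow(x$pixels),
              ncol(x$pixels), sum(x$pixels)))
  if (is.finite(x$radius_px)) {
    cat(sprintf(" (disk r = %.1f px at %.1f, %.1f)", x$radius_px,
                x$center[1], x$center[2]))
  }
  cat("\n")
  invisible(x)
}

disk_pixels <- function(dim, center, radius) {
  outer((seq_len(dim[1]) - center[1])^2, (seq_len(dim[2]) - center[2])^2, "+") <=
    radius^2
}

#' Build the cell analysis mask from the first frame of a video
#'
#' Thresholds the frame at `threshold_frac` of its maximum to detect the cell
#' support, then places a disk at the support centroid with radius
#' `erode_frac` times the equivalent cell radius (`sqrt(area/pi)`), excluding
#' the cell edge region. The disk is shrunk, if needed, to stay strictly
#' inside the frame.
#'
#' @param first_frame an [opd_map()] or numeric matrix (nm).
#' @param threshold_frac support threshold as a fraction of the frame maximum
#'   (default 0.2).
#' @param erode_frac disk radius as a fraction of the equivalent cell radius
#'   (default 0.7).
#' @return a [cell_mask()] with `center` and `radius_px` set.
#' @export
build_mask <- function(first_frame, threshold_frac = 0.2, erode_frac = 0.7) {
  if (inherits(first_frame, "opd_map")) first_frame <- unclass(first_frame)
  stopifnot(is.matrix(first_frame))
  assert_finite(first_frame)
  stopifnot(threshold_frac > 0, threshold_frac < 1, erode_frac > 0, erode_frac < 1)
  top <- max(first_frame)
  if (top <= 0) abort("no cell detected: frame maximum is not above zero")
  support <- first_frame > threshold_frac * top
  if (!any(support)) abort("no cell detected: no pixels above threshold")
  idx <- which(support, arr.ind = TRUE)
  center <- colMeans(idx)
  radius <- erode_frac * sqrt(nrow(idx) / pi)
  # keep the disk strictly inside the frame border
  margin <- min(center[1] - 1, center[2] - 1,
                nrow(first_frame) - center[1], ncol(first_frame) - center[2]) - 1
  radius <- min(radius, margin)
  pix <- disk_pixels(dim(first_frame), center, radius)
  if (sum(pix) < 100) {
    abort(sprintf("analysis disk too small: %d px (< 100); cell support %d px",
                  sum(pix), nrow(idx)))
  }
  cell_mask(pix, center = unname(center), radius_px = radius)
}

#' Apply a mask to an OPD video
#'
#' Zeroes every pixel outside the mask in every frame.
#'
#' @param video an [opd_video()].
#' @param mask a [cell_mask()] with matching frame dimensions.
#' @return an [opd_video()].
#' @export
apply_mask <- function(video, mask) {
  stopifnot(inherits(video, "opd_video"), inherits(mask, "cell_mask"))
  d <- dim(video$frames)
  if (!identical(d[1:2], dim(mask$pixels))) {
    abort("mask and video frame dimensions differ")
  }
  out <- video$frames * as.numeric(mask$pixels)  # recycles over frames
  opd_video(out, video$frame_rate_hz, video$pixel_size_um, video$wavelength_nm)
}
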