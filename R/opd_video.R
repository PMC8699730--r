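#' Optical path delay (OPD) map
#'
#' A single quantitative-phase image: per-pixel optical path delay in
#' nanometres (refractive-index difference integrated along the optical axis).
#'
#' @param values numeric matrix of OPD values (nm).
#' @param pixel_size_um effective object-plane pixel size in micrometres,
#'   or `NA` when unknown.
#' @return an `opd_map` object (a matrix with metadata attributes).
#' @export
opd_map <- function(values, pixel_size_um = NA_real_) {
  stopifnot(is.matrix(values))
  assert_finite(values)
  structure(values, pixel_size_um = pixel_size_um, class = c("opd_map", "matrix", "array"))
}

#' @export
print.opd_map <- function(x, ...) {
  cat(sprintf("<opd_map> %d x %d px, range [%.2f, %.2f] nm\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Optical path delay video
#'
#' A stack of OPD maps over time, stored as an `H x W x T` array (nm) with the
#' acquisition frame rate attached. The central object of the pipeline: a
#' 4 s recording at 500 frames/s gives `T = 2000` frames.
#'
#' @param frames numeric array of dimension `H x W x T` (nm), or a list of
#'   equally-sized matrices.
#' @param frame_rate_hz acquisition rate in Hz (> 0).
#' @param pixel_size_um object-plane pixel size (um), optional.
#' @param wavelength_nm central illumination wavelength (nm), optional.
#' @return an `opd_video` object.
#' @export
opd_video <- function(frames, frame_rate_hz, pixel_size_um = NA_real_,
                      wavelength_nm = NA_real_) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) abort("all frames must share the same dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3] < 2L) abort("an OPD video needs at least 2 frames")
  if (!is_scalar_number(frame_rate_hz) || frame_rate_hz <= 0) {
    abort("`frame_rate_hz` must be a positive number")
  }
  assert_finite(frames)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, wavelength_nm = wavelength_nm),
            class = "opd_video")
}

#' @export
print.opd_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<opd_video> %d x %d px, %d frames @ %g Hz (%.3g s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, n_frames(x) / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.opd_video <- function(x) dim(x$frames)

n_frames <- function(video) dim(video$frames)[3]

#' Duration of an OPD video in seconds
#' @param video an [opd_video()].
#' @return scalar, `T / frame_rate_hz`.
#' @export
video_duration_s <- function(video) n_frames(video) / video$frame_rate_hz

#' Time-averaged OPD frame
#'
#' The per-pixel temporal mean of an OPD video; used as the stationary
#' morphology map of the cell.
#'
#' @param video an [opd_video()].
#' @return an [opd_map()].
#' @export
mean_frame <- function(video) {
  d <- dim(video$frames)
  m <- matrix(rowMeans(matrix(video$frames, ncol = d[3])), d[1], d[2])
  opd_map(m, pixel_size_um = video$pixel_size_um)
}

#' Standardize an OPD video to the pipeline working resolution
#'
#' Resizes every frame to `size x size` pixels (antialiased bilinear, see
#' [resize_map()]); the working resolution mirrors the published pipeline's
#' 512 to 250 pixel standardization. OPD units (nm) and the frame count are
#' unchanged; the pixel size metadata is rescaled accordingly.
#'
#' @param video an [opd_video()].
#' @param size output side length in pixels (default 250).
#' @return an [opd_video()] with `size x size` frames.
#' @export
standardize_video <- function(video, size = 250L) {
  stopifnot(inherits(video, "opd_video"))
  if (!is_scalar_number(size) || size < 2) abort("`size` must be an integer >= 2")
  size <- as.integer(size)
  d <- dim(video$frames)
  ry <- resize_operator(d[1], size)
  rx <- t(resize_operator(d[2], size))
  out <- array(0, c(size, size, d[3]))
  for (t in seq_len(d[3])) out[, , t] <- ry %*% video$frames[, , t] %*% rx
  px <- video$pixel_size_um
  if (is.finite(px)) px <- px * d[1] / size
  opd_video(out, video$frame_rate_hz, pixel_size_um = px,
            wavelength_nm = video$wavelength_nm)
}

# ---- disk I/O: multi-page 32-bit float TIFF + YAML sidecar -------------------
# TIFF float pages hold only [0,1]; values are affine-mapped and the map is
# recorded in the sidecar, so the round trip is exact to float32 precision.

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write an OPD video as multi-page float TIFF with a YAML sidecar
#'
#' @param video an [opd_video()].
#' @param path output TIFF path; metadata goes to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_opd_video <- function(video, path) {
  stopifnot(inherits(video, "opd_video"))
  v <- video$frames
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]), function(t) (v[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(format = "phasefluct-opd-video", value_offset = lo,
               value_scale = scale, frame_rate_hz = video$frame_rate_hz,
               pixel_size_um = video$pixel_size_um,
               wavelength_nm = video$wavelength_nm)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read an OPD video written by [write_opd_video()]
#'
#' @param path TIFF path with a `<path>.yaml` sidecar.
#' @return an [opd_video()].
#' @export
read_opd_video <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (!file.exists(sidecar_path(path))) {
    abort(sprintf("missing metadata sidecar: %s", sidecar_path(path)))
  }
  meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages, use.names = FALSE),
               dim = c(dim(pages[[1]])[1:2], length(pages)))
  arr <- arr * meta$value_scale + meta$value_offset
  opd_video(arr, frame_rate_hz = meta$frame_rate_hz,
            pixel_size_um = meta$pixel_size_um %||% NA_real_,
            wavelength_nm = meta$wavelength_nm %||% NA_real_)
}
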