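# Turning OPD videos into the classifier's two input maps, and assembling
# dataset tibbles (one row per cell) used by the training protocol.

#' Prepare the classifier inputs for one OPD video
#'
#' Computes the stationary morphology map (time-averaged OPD) and the
#' spatio-temporal fluctuation map, each min-max normalized to `[0, 1]`
#' (the fluctuation map on a log10 scale, see
#' [normalize_fluctuation_map()]) and resized to the network input size.
#' Also returns the per-cell summary statistics.
#'
#' @param video an [opd_video()].
#' @param mask a [cell_mask()]; derived from the first frame when omitted.
#' @param input_size network input side length (default 32).
#' @return list with `morph` and `fluct` (`input_size` x `input_size`
#'   matrices in `[0, 1]`), `mean_opd_nm` and `mean_abs_fluct`.
#' @export
prepare_classifier_input <- function(video, mask = NULL, input_size = 32L) {
  stopifnot(inherits(video, "opd_video"))
  if (is.null(mask)) mask <- build_mask(video$frames[, , 1])
  mf <- mean_frame(video)
  fmap <- fluctuation_map(video, mask)
  list(morph = resize_map(minmax(unclass(mf)), input_size, input_size),
       fluct = normalize_fluctuation_map(fmap, input_size),
       mean_opd_nm = mean_opd(mf, mask),
       mean_abs_fluct = mean_abs_fluct(fmap))
}

#' Add classifier input maps to a dataset of videos
#'
#' @param data tibble with a `video` list-column (e.g.
#'   [simulate_cell_dataset()]).
#' @param input_size network input side length.
#' @param drop_video drop the raw videos after processing (default `TRUE`).
#' @return the tibble with list-columns `morph`, `fluct` and columns
#'   `mean_opd_nm`, `mean_abs_fluct` added.
#' @export
add_classifier_inputs <- function(data, input_size = 32L, drop_video = TRUE) {
  stopifnot(is.data.frame(data), "video" %in% names(data))
  prep <- purrr::map(data$video, prepare_classifier_input,
                     input_size = input_size)
  data$morph <- purrr::map(prep, "morph")
  data$fluct <- purrr::map(prep, "fluct")
  data$mean_opd_nm <- purrr::map_dbl(prep, "mean_opd_nm")
  data$mean_abs_fluct <- purrr::map_dbl(prep, "mean_abs_fluct")
  if (drop_video) data$video <- NULL
  data
}

#' Simulate a classifier-ready two-class dataset
#'
#' Streams over the cells of a synthetic dataset: simulates each OPD video,
#' derives the normalized morphology and fluctuation input maps plus the
#' per-cell summary statistics, and discards the raw video, keeping memory
#' flat. Deterministic given `seed`.
#'
#' @inheritParams simulate_cell_dataset
#' @param input_size network input side length (default 32).
#' @return a tibble with columns `cell_id`, `label`, list-columns `morph`,
#'   `fluct`, and `mean_opd_nm`, `mean_abs_fluct`.
#' @export
simulate_classification_data <- function(n_per_class = 50L, seed = 1L,
                                         size = 64L, frames = 256L,
                                         frame_rate_hz = 500,
                                         input_size = 32L) {
  draws <- draw_cell_params(n_per_class, seed, size, frames, frame_rate_hz)
  purrr::imap_dfr(draws, function(params, i) {
    video <- simulate_cell_video(params)$video
    prep <- prepare_classifier_input(video, input_size = input_size)
    tibble::tibble(cell_id = sprintf("cell_%03d", i),
                   label = params$class_label,
                   morph = list(prep$morph), fluct = list(prep$fluct),
                   mean_opd_nm = prep$mean_opd_nm,
                   mean_abs_fluct = prep$mean_abs_fluct)
  })
}

# stack the morph/fluct list-columns of a dataset tibble into the H x W x 1 x N
# input tensors the model consumes
dataset_tensors <- function(data, input_size) {
  stopifnot(all(c("morph", "fluct") %in% names(data)))
  n <- nrow(data)
  stopifnot(n >= 1)
  d <- dim(data$morph[[1]])
  if (d[1] != input_size) {
    abort(sprintf("dataset maps are %d px but the model expects %d px",
                  d[1], input_size))
  }
  morph <- array(unlist(data$morph, use.names = FALSE), c(d[1], d[2], 1L, n))
  fluct <- array(unlist(data$fluct, use.names = FALSE), c(d[1], d[2], 1L, n))
  list(morphology = morph, fluctuations = fluct)
}

# one-hot (2 x N) label matrix, classes = c("primary", "metastatic")
label_onehot <- function(labels, classes = c("primary", "metastatic")) {
  idx <- match(labels, classes)
  if (anyNA(idx)) abort("labels must be 'primary' or 'metastatic'")
  y <- matrix(0, 2, length(labels))
  y[cbind(idx, seq_along(labels))] <- 1
  y
}
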