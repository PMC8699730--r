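# Manifest and fluctuation-map file handling. Manifests are CSV with one row
# per cell (cell_id, label, opd_path, optionally fluct_path); fluctuation
# maps are stored as plain CSV matrices with a YAML sidecar carrying the
# frequency axes.

#' Read and validate a cell manifest
#'
#' @param path CSV file with header columns `cell_id`, `label`, `opd_path`
#'   and optionally `fluct_path`; relative paths are resolved against the
#'   manifest's directory.
#' @param check_files verify that referenced files exist (default `TRUE`).
#' @return a tibble.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "label", "opd_path")
  if (!all(need %in% names(man))) {
    abort(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(man$cell_id)) abort("manifest cell_id values must be unique")
  bad <- setdiff(unique(man$label), c("primary", "metastatic"))
  if (length(bad)) {
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  }
  root <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  man$opd_path <- resolve(man$opd_path)
  if ("fluct_path" %in% names(man)) man$fluct_path <- resolve(man$fluct_path)
  if (check_files) {
    missing <- man$opd_path[!file.exists(man$opd_path)]
    if (length(missing)) {
      abort(sprintf("missing video file(s): %s",
                    paste(utils::head(missing, 3), collapse = ", ")))
    }
  }
  man
}

#' Write a fluctuation map to CSV with a YAML axes sidecar
#'
#' @param fmap a [fluctuation_map()].
#' @param path output CSV path (power matrix, omega rows x q columns);
#'   axes and acquisition metadata go to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_fluctuation_map <- function(fmap, path) {
  stopifnot(inherits(fmap, "fluctuation_map"))
  utils::write.table(fmap$power, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(format = "phasefluct-fluctuation-map",
                        omega_axis_hz = as.numeric(fmap$omega_axis_hz),
                        q_axis = as.numeric(fmap$q_axis),
                        frame_rate_hz = fmap$frame_rate_hz,
                        n_frames = fmap$n_frames),
                   sidecar_path(path))
  invisible(path)
}

#' Read a fluctuation map written by [write_fluctuation_map()]
#'
#' @param path CSV path with `<path>.yaml` sidecar.
#' @return a [fluctuation_map()].
#' @export
read_fluctuation_map <- function(path) {
  if (!file.exists(sidecar_path(path))) {
    abort(sprintf("missing metadata sidecar: %s", sidecar_path(path)))
  }
  meta <- yaml::read_yaml(sidecar_path(path))
  power <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(power) <- NULL
  structure(list(power = power,
                 omega_axis_hz = as.numeric(meta$omega_axis_hz),
                 q_axis = as.numeric(meta$q_axis),
                 frame_rate_hz = meta$frame_rate_hz,
                 n_frames = meta$n_frames),
            class = "fluctuation_map")
}

#' Build a classifier dataset from a manifest on disk
#'
#' Reads each cell's OPD video, derives the normalized morphology input, and
#' takes the fluctuation map from `fluct_path` when the manifest provides one
#' (recomputing it otherwise).
#'
#' @param manifest tibble from [read_manifest()] or a manifest CSV path.
#' @param input_size network input side length.
#' @return dataset tibble (`cell_id`, `label`, `morph`, `fluct`,
#'   `mean_opd_nm`, `mean_abs_fluct`).
#' @export
dataset_from_manifest <- function(manifest, input_size = 32L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  purrr::pmap_dfr(manifest, function(cell_id, label, opd_path, ...) {
    extra <- list(...)
    video <- read_opd_video(opd_path)
    mask <- build_mask(video$frames[, , 1])
    fmap <- if (!is.null(extra$fluct_path) && !is.na(extra$fluct_path) &&
                file.exists(extra$fluct_path)) {
      read_fluctuation_map(extra$fluct_path)
    } else {
      fluctuation_map(video, mask)
    }
    tibble::tibble(
      cell_id = cell_id, label = label,
      morph = list(resize_map(minmax(unclass(mean_frame(video))),
                              input_size, input_size)),
      fluct = list(normalize_fluctuation_map(fmap, input_size)),
      mean_opd_nm = mean_opd(mean_frame(video), mask),
      mean_abs_fluct = mean_abs_fluct(fmap))
  })
}
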