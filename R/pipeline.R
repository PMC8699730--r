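# Config-driven pipeline front end: executes the named stages in order
# (simulate | reconstruct | fluctmap | stats | train | evaluate), writing
# every artifact with a provenance sidecar (package version, master seed,
# config digest, stage parameters). All randomness flows from the config
# seed, so identical configs reproduce identical artifacts.

pkg_version <- function() as.character(utils::packageVersion("phasefluct"))

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(artifact, config, stage_params) {
  yaml::write_yaml(list(package = "phasefluct", version = pkg_version(),
                        seed = config$seed, config_md5 = config_digest(config),
                        stage = stage_params),
                   paste0(artifact, ".prov.yaml"))
}

stage_field <- function(stage, name, default = NULL, required = FALSE) {
  val <- stage[[name]] %||% default
  if (required && is.null(val)) {
    abort(sprintf("stage '%s': missing required field '%s'",
                  stage$stage %||% "?", name))
  }
  val
}

#' Run a configured analysis pipeline
#'
#' Executes pipeline stages in the order given by the config (a YAML file or
#' an equivalent list). Supported stages and their parameters:
#'
#' * `simulate`: `n_per_class`, `size`, `frames`, `frame_rate_hz` — writes
#'   per-cell OPD videos (TIFF + sidecar) and `manifest.csv`.
#' * `reconstruct`: `input`, `meta`, `out` — reconstructs an OPD video from a
#'   hologram TIFF stack with a YAML sidecar giving `carrier_freq`,
#'   `wavelength_nm`, `frame_rate_hz`.
#' * `fluctmap`: `mask_threshold`, `mask_erode` — computes and stores each
#'   cell's fluctuation map, adding `fluct_path` to the manifest.
#' * `stats`: writes `summary.csv` (per-cell summaries) and
#'   `group_stats.csv` (between-group Welch p-values).
#' * `train`: `model` (variant/backbone/inputs), `n_shuffles`, `epochs`,
#'   `learning_rate`, `batch_size`, `input_size` — runs the repeated-shuffle
#'   protocol, writing `per_shuffle.csv` and `curves.csv`.
#' * `evaluate`: aggregates `per_shuffle.csv` into `report.csv` (mean and sd
#'   per metric).
#'
#' Top-level config fields: `out_dir` (required), `seed` (default 1).
#'
#' @param config path to a YAML config or a named list.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stages)) {
    abort("config must provide a `stages` list")
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) abort("config must name an `out_dir`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- config$seed %||% 1L
  artifacts <- list()
  manifest_path <- file.path(out_dir, "manifest.csv")

  for (stage in config$stages) {
    name <- stage$stage %||% stage$name
    if (is.null(name)) abort("each stage must name its `stage`")
    artifacts <- switch(name,
      simulate = stage_simulate(stage, config, out_dir, manifest_path, artifacts),
      reconstruct = stage_reconstruct(stage, config, artifacts),
      fluctmap = stage_fluctmap(stage, config, out_dir, manifest_path, artifacts),
      stats = stage_stats(stage, config, out_dir, manifest_path, artifacts),
      train = stage_train(stage, config, out_dir, manifest_path, artifacts),
      evaluate = stage_evaluate(stage, config, out_dir, artifacts),
      abort(sprintf("unknown stage '%s'", name))
    )
  }
  invisible(artifacts)
}

stage_simulate <- function(stage, config, out_dir, manifest_path, artifacts) {
  n_per_class <- stage_field(stage, "n_per_class", required = TRUE)
  size <- stage_field(stage, "size", 64L)
  frames <- stage_field(stage, "frames", 256L)
  fps <- stage_field(stage, "frame_rate_hz", 500)
  vid_dir <- file.path(out_dir, "videos")
  dir.create(vid_dir, showWarnings = FALSE)
  draws <- draw_cell_params(n_per_class, config$seed, size, frames, fps)
  rows <- purrr::imap_dfr(draws, function(params, i) {
    cell_id <- sprintf("cell_%03d", i)
    path <- file.path(vid_dir, paste0(cell_id, ".tiff"))
    write_opd_video(simulate_cell_video(params)$video, path)
    tibble::tibble(cell_id = cell_id, label = params$class_label,
                   opd_path = path)
  })
  readr::write_csv(rows, manifest_path)
  write_provenance(manifest_path, config,
                   list(stage = "simulate", n_per_class = n_per_class,
                        size = size, frames = frames, frame_rate_hz = fps))
  c(artifacts, list(manifest = manifest_path))
}

stage_reconstruct <- function(stage, config, artifacts) {
  input <- stage_field(stage, "input", required = TRUE)
  meta_path <- stage_field(stage, "meta", required = TRUE)
  out <- stage_field(stage, "out", required = TRUE)
  meta <- yaml::read_yaml(meta_path)
  for (f in c("carrier_freq", "wavelength_nm", "frame_rate_hz")) {
    if (is.null(meta[[f]])) {
      abort(sprintf("hologram metadata %s: missing required field '%s'",
                    meta_path, f))
    }
  }
  pages <- tiff::readTIFF(input, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$intensity_scale %||% 1
  opd <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    holo <- hologram(pg * scale, as.numeric(meta$carrier_freq),
                     meta$wavelength_nm)
    unclass(reconstruct_opd(holo))
  })
  video <- opd_video(opd, frame_rate_hz = meta$frame_rate_hz,
                     wavelength_nm = meta$wavelength_nm)
  size <- stage_field(stage, "size")
  if (!is.null(size)) video <- standardize_video(video, size)
  write_opd_video(video, out)
  write_provenance(out, config, list(stage = "reconstruct", input = input))
  c(artifacts, list(reconstructed = out))
}

stage_fluctmap <- function(stage, config, out_dir, manifest_path, artifacts) {
  man <- read_manifest(manifest_path)
  fm_dir <- file.path(out_dir, "fluctmaps")
  dir.create(fm_dir, showWarnings = FALSE)
  thr <- stage_field(stage, "mask_threshold", 0.2)
  erode <- stage_field(stage, "mask_erode", 0.7)
  man$fluct_path <- purrr::map2_chr(man$opd_path, man$cell_id, function(vp, id) {
    video <- read_opd_video(vp)
    mask <- build_mask(video$frames[, , 1], threshold_frac = thr,
                       erode_frac = erode)
    path <- file.path(fm_dir, paste0(id, ".csv"))
    write_fluctuation_map(fluctuation_map(video, mask), path)
    path
  })
  readr::write_csv(man, manifest_path)
  write_provenance(manifest_path, config,
                   list(stage = "fluctmap", mask_threshold = thr,
                        mask_erode = erode))
  c(artifacts, list(manifest = manifest_path))
}

stage_stats <- function(stage, config, out_dir, manifest_path, artifacts) {
  data <- dataset_from_manifest(manifest_path)
  summary_path <- file.path(out_dir, "summary.csv")
  readr::write_csv(
    data[, c("cell_id", "label", "mean_opd_nm", "mean_abs_fluct")],
    summary_path)
  groups <- summarize_groups(cell_summaries(data),
                             method = stage_field(stage, "method", "welch"))
  group_path <- file.path(out_dir, "group_stats.csv")
  readr::write_csv(groups, group_path)
  write_provenance(summary_path, config, list(stage = "stats"))
  c(artifacts, list(summary = summary_path, group_stats = group_path))
}

stage_train <- function(stage, config, out_dir, manifest_path, artifacts) {
  input_size <- stage_field(stage, "input_size", 32L)
  data <- dataset_from_manifest(manifest_path, input_size = input_size)
  model_cfg <- stage_field(stage, "model", list())
  spec <- fusion_model_spec(
    variant = model_cfg$variant %||% "single",
    inputs = model_cfg$inputs,
    backbone = model_cfg$backbone %||% "small-cnn",
    pretrained = isTRUE(model_cfg$pretrained),
    input_size = input_size)
  plan <- make_shuffles(data$cell_id,
                        n_shuffles = stage_field(stage, "n_shuffles", 20L),
                        seed = config$seed,
                        stratify = isTRUE(stage_field(stage, "stratify", FALSE)),
                        labels = data$label)
  cfg <- train_config(batch_size = stage_field(stage, "batch_size", 8L),
                      learning_rate = stage_field(stage, "learning_rate", 2e-6),
                      epochs = stage_field(stage, "epochs", 100L),
                      schedule = stage_field(stage, "schedule", "constant"),
                      seed = config$seed)
  report <- run_protocol(data, spec, plan, cfg)
  ps_path <- file.path(out_dir, "per_shuffle.csv")
  readr::write_csv(report$per_shuffle, ps_path)
  curves_path <- file.path(out_dir, "curves.csv")
  readr::write_csv(report$curves, curves_path)
  write_provenance(ps_path, config,
                   list(stage = "train", variant = spec$variant,
                        backbone = spec$backbone, epochs = cfg$epochs,
                        learning_rate = cfg$learning_rate,
                        n_shuffles = plan$n_shuffles))
  c(artifacts, list(per_shuffle = ps_path, curves = curves_path))
}

stage_evaluate <- function(stage, config, out_dir, artifacts) {
  ps_path <- file.path(out_dir, "per_shuffle.csv")
  if (!file.exists(ps_path)) {
    abort("evaluate stage requires a previous train stage (per_shuffle.csv)")
  }
  per_shuffle <- readr::read_csv(ps_path, show_col_types = FALSE, progress = FALSE)
  report_path <- file.path(out_dir, "report.csv")
  readr::write_csv(aggregate_reports(per_shuffle), report_path)
  write_provenance(report_path, config, list(stage = "evaluate"))
  c(artifacts, list(report = report_path))
}
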