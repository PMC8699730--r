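# Memoized heavy computations shared between test files: the default-scale
# synthetic datasets and the scaled repeated-shuffle protocol runs. Each
# repetition r uses dataset seed r, shuffle-plan seed 100 + r and training
# seed 200 + r, so results are deterministic and computed once per session.

.phasefluct_cache <- new.env(parent = emptyenv())

cached_dataset <- function(n_per_class, seed) {
  key <- sprintf("data_%d_%d", n_per_class, seed)
  if (is.null(.phasefluct_cache[[key]])) {
    .phasefluct_cache[[key]] <-
      simulate_classification_data(n_per_class = n_per_class, seed = seed)
  }
  .phasefluct_cache[[key]]
}

# one repetition of the scaled protocol analogue: n = 120 cells, small-cnn,
# 30 epochs, 5 shuffles; single-morphology vs triple on identical splits
cached_protocol_rep <- function(r) {
  key <- sprintf("rep_%d", r)
  if (is.null(.phasefluct_cache[[key]])) {
    data <- cached_dataset(60L, r)
    plan <- make_shuffles(data$cell_id, n_shuffles = 5L, seed = 100L + r)
    cfg <- scaled_protocol_config(seed = 200L + r)
    single <- run_protocol(data, fusion_model_spec("single", backbone = "small-cnn"),
                           plan, cfg, keep_curves = FALSE)
    triple <- run_protocol(data, fusion_model_spec("triple", backbone = "small-cnn"),
                           plan, cfg, keep_curves = FALSE)
    .phasefluct_cache[[key]] <- list(
      single = single, triple = triple,
      single_mean = single$aggregate$mean[single$aggregate$metric == "accuracy"],
      triple_mean = triple$aggregate$mean[triple$aggregate$metric == "accuracy"])
  }
  .phasefluct_cache[[key]]
}

# small in-memory dataset for fast classifier tests (48 px frames keep the
# analysis disk above the 100-pixel mask minimum)
cached_small_dataset <- function() {
  if (is.null(.phasefluct_cache$small)) {
    .phasefluct_cache$small <- simulate_classification_data(
      n_per_class = 10L, seed = 42L, size = 48L, frames = 64L)
  }
  .phasefluct_cache$small
}
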