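# Fusion classifier architectures: single-path (one modality), double-path
# (late fusion: per-modality backbones, concatenated feature vectors),
# early fusion (two-channel input, one backbone) and the triple-path model
# (morphology path + fluctuation path + two-channel path whose feature vector
# is added to each of the other two before concatenation).

backbone_specs <- function(backbone) {
  switch(backbone,
    "small-cnn" = list(
      specs = list(nn_conv(8), nn_relu(), nn_avgpool(2),
                   nn_conv(16), nn_relu(), nn_avgpool(2),
                   nn_conv(128, stride = 2L), nn_relu(), nn_gap()),
      feature_len = 128L),
    "resnet50-style" = {
      bottleneck <- function(mid, stride = 1L, project = FALSE) {
        main <- list(nn_conv(mid, kernel = 1L, pad = 0L, bias = FALSE),
                     nn_batchnorm(), nn_relu(),
                     nn_conv(mid, kernel = 3L, stride = stride, pad = 1L, bias = FALSE),
                     nn_batchnorm(), nn_relu(),
                     nn_conv(4L * mid, kernel = 1L, pad = 0L, bias = FALSE),
                     nn_batchnorm())
        shortcut <- if (project) {
          list(nn_conv(4L * mid, kernel = 1L, stride = stride, pad = 0L,
                       bias = FALSE), nn_batchnorm())
        }
        nn_residual(main, shortcut)
      }
      stage <- function(mid, blocks, stride) {
        c(list(bottleneck(mid, stride, project = TRUE)),
          lapply(seq_len(blocks - 1), function(i) bottleneck(mid)))
      }
      list(specs = c(list(nn_conv(64L, kernel = 7L, stride = 2L, pad = 3L,
                                  bias = FALSE),
                          nn_batchnorm(), nn_relu(), nn_maxpool()),
                     stage(64L, 3L, 1L), stage(128L, 4L, 2L),
                     stage(256L, 6L, 2L), stage(512L, 3L, 2L),
                     list(nn_gap())),
           feature_len = 2048L)
    },
    abort(sprintf("unknown backbone '%s' (use 'resnet50-style' or 'small-cnn')",
                  backbone))
  )
}

canonical_inputs <- c("morphology", "fluctuations", "two_channel")

#' Specify a fusion classifier architecture
#'
#' @param variant `"single"` (one path), `"double"` (two paths, late fusion)
#'   or `"triple"` (morphology, fluctuation and two-channel paths; the
#'   two-channel feature vector is added to each of the other two before
#'   concatenation).
#' @param inputs subset of `c("morphology", "fluctuations", "two_channel")`;
#'   defaults to the canonical set for the variant (single: morphology;
#'   double: morphology + fluctuations; triple: all three).
#' @param backbone `"resnet50-style"` (50-layer bottleneck-residual backbone,
#'   feature length 2048) or `"small-cnn"` (3 conv blocks, feature length 128,
#'   sized for CPU work).
#' @param head_dims strictly decreasing fully-connected output lengths ending
#'   at 2 (the two-class softmax); default `[256, 2]` after a long fused
#'   vector, scaled down proportionally for short ones.
#' @param pretrained logical; reserved flag for initializing the backbone from
#'   pretrained weights. No weights ship with the package, so initialization
#'   is always the seeded random scheme.
#' @param input_size network input side length in pixels (default 32).
#' @return a `fusion_model_spec` object.
#' @export
fusion_model_spec <- function(variant = c("single", "double", "triple"),
                              inputs = NULL, backbone = "resnet50-style",
                              head_dims = NULL, pretrained = FALSE,
                              input_size = 32L) {
  variant <- match.arg(variant)
  if (is.null(inputs)) {
    inputs <- switch(variant,
                     single = "morphology",
                     double = c("morphology", "fluctuations"),
                     triple = canonical_inputs)
  }
  inputs <- canonical_inputs[canonical_inputs %in% inputs]
  if (length(inputs) == 0 || !all(inputs %in% canonical_inputs)) {
    abort("`inputs` must be drawn from morphology, fluctuations, two_channel")
  }
  need <- switch(variant, single = 1L, double = 2L, triple = 3L)
  if (length(inputs) != need) {
    abort(sprintf("variant '%s' requires exactly %d input(s), got %d",
                  variant, need, length(inputs)))
  }
  if (variant == "triple" && !setequal(inputs, canonical_inputs)) {
    abort("the triple variant uses all three inputs")
  }
  bk <- backbone_specs(backbone)
  fused_len <- if (variant == "single") bk$feature_len else 2L * bk$feature_len
  if (is.null(head_dims)) {
    head_dims <- c(if (fused_len > 256L) 256L else max(4L, fused_len %/% 4L), 2L)
  }
  head_dims <- as.integer(head_dims)
  if (utils::tail(head_dims, 1) != 2L ||
      any(diff(c(fused_len, head_dims)) >= 0)) {
    abort("`head_dims` must be strictly decreasing and end at 2")
  }
  structure(list(variant = variant, inputs = inputs, backbone = backbone,
                 feature_len = bk$feature_len, fused_len = fused_len,
                 head_dims = head_dims, pretrained = isTRUE(pretrained),
                 input_size = as.integer(input_size)),
            class = "fusion_model_spec")
}

#' @export
print.fusion_model_spec <- function(x, ...) {
  cat(sprintf("<fusion_model_spec> %s-path [%s], backbone %s (L=%d), head %s\n",
              x$variant, paste(x$inputs, collapse = "+"), x$backbone,
              x$feature_len, paste(x$head_dims, collapse = "->")))
  invisible(x)
}

#' Build a fusion classifier from its specification
#'
#' Instantiates one backbone per path (independent weights), truncated after
#' global average pooling so each path emits a feature vector, plus the
#' fully-connected head acting on the fused vector. Weights follow seeded
#' He-normal initialization, so the same seed rebuilds the same model.
#'
#' @param spec a [fusion_model_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `fusion_model` object (a callable handle used by
#'   [train_one_shuffle()], [evaluate_model()] and [predict.fusion_model()]).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_model_spec"))
  if (spec$pretrained) {
    rlang::inform(paste("no pretrained weights are bundled;",
                        "using seeded random initialization"))
  }
  bk <- backbone_specs(spec$backbone)
  in_shape <- c(spec$input_size, spec$input_size, 3L)
  with_seed(seed, {
    paths <- lapply(stats::setNames(spec$inputs, spec$inputs), function(p) {
      ini <- seq_init(bk$specs, in_shape)
      stopifnot(identical(as.integer(ini$out_shape), spec$feature_len))
      ini$layers
    })
    head_specs <- list()
    for (hd in spec$head_dims) {
      head_specs <- c(head_specs, list(nn_linear(hd)))
      if (hd != 2L) head_specs <- c(head_specs, list(nn_relu()))
    }
    head <- seq_init(head_specs, spec$fused_len)$layers
  })
  structure(list(spec = spec, paths = paths, head = head,
                 classes = c("primary", "metastatic")),
            class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s-path, backbone %s, %s parameters\n",
              x$spec$variant, x$spec$backbone,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a fusion model
#' @param model a `fusion_model`.
#' @return integer-valued scalar.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "fusion_model"))
  tree_count(list(lapply(model$paths, seq_params), seq_params(model$head)))
}

#' Glance at a fusion model
#'
#' @param x a `fusion_model`.
#' @param ... unused.
#' @return a one-row tibble with the architecture summary.
#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(variant = x$spec$variant,
                 inputs = paste(x$spec$inputs, collapse = "+"),
                 backbone = x$spec$backbone,
                 feature_len = x$spec$feature_len,
                 fused_len = x$spec$fused_len,
                 n_parameters = n_parameters(x),
                 input_size = x$spec$input_size)
}

#' Stack morphology and fluctuation maps into a two-channel image
#'
#' Channel 1 holds the morphology map, channel 2 the fluctuation map
#' (early-fusion input).
#'
#' @param morph,fluct numeric matrices of identical size (or `H x W x 1 x N`
#'   arrays for batches).
#' @return `H x W x 2` array (or `H x W x 2 x N`).
#' @export
make_two_channel <- function(morph, fluct) {
  if (is.matrix(morph) && is.matrix(fluct)) {
    if (!identical(dim(morph), dim(fluct))) abort("map dimensions differ")
    return(array(c(morph, fluct), c(dim(morph), 2L)))
  }
  stopifnot(length(dim(morph)) == 4, length(dim(fluct)) == 4)
  if (!identical(dim(morph), dim(fluct)) || dim(morph)[3] != 1L) {
    abort("batch inputs must be H x W x 1 x N arrays of identical dimensions")
  }
  d <- dim(morph)
  out <- array(0, c(d[1], d[2], 2L, d[4]))
  out[, , 1L, ] <- morph
  out[, , 2L, ] <- fluct
  out
}

#' Late fusion of two feature vectors
#'
#' Concatenation in (morphology, fluctuations) order.
#'
#' @param v_morph,v_fluct numeric vectors (or `L x N` matrices) of equal
#'   length.
#' @return vector (or matrix) of length `2L`.
#' @export
fuse_double <- function(v_morph, v_fluct) {
  if (is.matrix(v_morph) || is.matrix(v_fluct)) {
    if (!identical(dim(v_morph), dim(v_fluct))) abort("feature lengths differ")
    return(rbind(v_morph, v_fluct))
  }
  if (length(v_morph) != length(v_fluct)) abort("feature lengths differ")
  c(v_morph, v_fluct)
}

#' Triple-path fusion of three feature vectors
#'
#' The two-channel feature vector is added element-wise to the morphology and
#' to the fluctuation feature vectors, and the two sums are concatenated:
#' `concat(v_morph + v_2ch, v_fluct + v_2ch)`. With `v_2ch = 0` this reduces
#' exactly to [fuse_double()].
#'
#' @param v_morph,v_fluct,v_2ch numeric vectors (or `L x N` matrices) of equal
#'   length.
#' @return vector (or matrix) of length `2L`.
#' @export
fuse_triple <- function(v_morph, v_fluct, v_2ch) {
  if (is.matrix(v_morph)) {
    if (!identical(dim(v_morph), dim(v_fluct)) ||
        !identical(dim(v_morph), dim(v_2ch))) abort("feature lengths differ")
    return(rbind(v_morph + v_2ch, v_fluct + v_2ch))
  }
  if (length(v_morph) != length(v_fluct) || length(v_morph) != length(v_2ch)) {
    abort("feature lengths differ")
  }
  c(v_morph + v_2ch, v_fluct + v_2ch)
}

#' Adapt an image to the backbone's expected channel count
#'
#' Single-channel inputs are replicated to 3 channels; two-channel inputs get
#' a third channel equal to the mean of the two; three-channel inputs pass
#' through unchanged.
#'
#' @param image `H x W x C` or `H x W x C x N` array with `C` in 1..3.
#' @param k target channel count (only 3 supported).
#' @return array with `k` channels.
#' @export
adapt_input_channels <- function(image, k = 3L) {
  stopifnot(k == 3L)
  d <- dim(image)
  if (length(d) == 3) {
    image <- array(image, c(d, 1L))
    d <- dim(image)
    drop_batch <- TRUE
  } else {
    drop_batch <- FALSE
  }
  stopifnot(length(d) == 4)
  c_in <- d[3]
  out <- switch(as.character(c_in),
    "1" = {
      o <- array(0, c(d[1], d[2], 3L, d[4]))
      for (ch in 1:3) o[, , ch, ] <- image[, , 1L, ]
      o
    },
    "2" = {
      o <- array(0, c(d[1], d[2], 3L, d[4]))
      o[, , 1L, ] <- image[, , 1L, ]
      o[, , 2L, ] <- image[, , 2L, ]
      o[, , 3L, ] <- (image[, , 1L, ] + image[, , 2L, ]) / 2
      o
    },
    "3" = image,
    abort(sprintf("cannot adapt %d channels to %d", c_in, k))
  )
  if (drop_batch) array(out, dim(out)[1:3]) else out
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# forward pass through all paths + head; inputs: list(morphology=, fluctuations=)
# of H x W x 1 x N arrays. Returns probabilities plus caches for backprop.
model_forward <- function(model, inputs, training = FALSE) {
  spec <- model$spec
  path_in <- list()
  for (p in spec$inputs) {
    raw <- switch(p,
                  morphology = inputs$morphology,
                  fluctuations = inputs$fluctuations,
                  two_channel = make_two_channel(inputs$morphology,
                                                 inputs$fluctuations))
    path_in[[p]] <- adapt_input_channels(raw, 3L)
  }
  feats <- list(); caches <- list()
  for (p in spec$inputs) {
    f <- seq_forward(model$paths[[p]], path_in[[p]], training)
    feats[[p]] <- f$out
    caches[[p]] <- f$caches
  }
  fused <- switch(spec$variant,
    single = feats[[spec$inputs]],
    double = fuse_double(feats[[spec$inputs[1]]], feats[[spec$inputs[2]]]),
    triple = fuse_triple(feats$morphology, feats$fluctuations, feats$two_channel))
  hf <- seq_forward(model$head, fused, training)
  list(logits = hf$out, probs = softmax_cols(hf$out),
       caches = list(paths = caches, head = hf$caches))
}

# backward pass from dlogits; returns the parameter-gradient tree
model_backward <- function(model, caches, dlogits) {
  spec <- model$spec
  hb <- seq_backward(model$head, caches$head, dlogits)
  dfused <- hb$dx
  l <- spec$feature_len
  dfeat <- switch(spec$variant,
    single = stats::setNames(list(dfused), spec$inputs),
    double = stats::setNames(list(dfused[seq_len(l), , drop = FALSE],
                                  dfused[l + seq_len(l), , drop = FALSE]),
                             spec$inputs),
    triple = {
      d1 <- dfused[seq_len(l), , drop = FALSE]
      d2 <- dfused[l + seq_len(l), , drop = FALSE]
      list(morphology = d1, fluctuations = d2, two_channel = d1 + d2)
    })
  path_grads <- list()
  for (p in spec$inputs) {
    path_grads[[p]] <- seq_backward(model$paths[[p]], caches$paths[[p]],
                                    dfeat[[p]])$grads
  }
  list(paths = path_grads, head = hb$grads)
}

model_params <- function(model) {
  list(paths = lapply(model$paths, seq_params), head = seq_params(model$head))
}

model_set_params <- function(model, params) {
  for (p in names(model$paths)) {
    model$paths[[p]] <- seq_set_params(model$paths[[p]], params$paths[[p]])
  }
  model$head <- seq_set_params(model$head, params$head)
  model
}

#' Predict class probabilities with a fusion model
#'
#' @param object a `fusion_model`.
#' @param data a dataset tibble with list-columns `morph` and `fluct`
#'   (normalized network inputs, as produced by
#'   [simulate_classification_data()] or [prepare_classifier_input()]).
#' @param ... unused.
#' @return a tibble with `prob_primary`, `prob_metastatic` (softmax, summing
#'   to 1) and the argmax `pred` label.
#' @export
predict.fusion_model <- function(object, data, ...) {
  inputs <- dataset_tensors(data, object$spec$input_size)
  probs <- model_forward(object, inputs, training = FALSE)$probs
  tibble::tibble(prob_primary = probs[1, ], prob_metastatic = probs[2, ],
                 pred = object$classes[apply(probs, 2, which.max)])
}
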