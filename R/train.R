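# Repeated-shuffle training protocol: random 60/20/20 train/validation/test
# splits, per-shuffle training with best-validation-epoch checkpointing, the
# five-metric evaluation (metastatic = positive class) and cross-shuffle
# aggregation.

#' Create a repeated-shuffle split plan
#'
#' Randomly partitions the cell ids into train/validation/test sets
#' (`fractions`, default 60/20/20), independently for each shuffle. Train and
#' validation sizes are rounded half-up; the remainder goes to test. Splits
#' are plain random (unstratified) by default; `stratify` balances class
#' proportions per partition.
#'
#' @param cell_ids character or integer vector of unique ids (N >= 10).
#' @param n_shuffles number of shuffles (default 20).
#' @param fractions length-3 numeric summing to 1: train, validation, test.
#' @param seed master seed; the plan is deterministic given it.
#' @param stratify logical; balance classes across partitions.
#' @param labels class labels, required when `stratify = TRUE`.
#' @return a `shuffle_plan`: list with `assignments` (tibble of `shuffle`,
#'   `cell_id`, `partition`) and the plan parameters.
#' @export
make_shuffles <- function(cell_ids, n_shuffles = 20L,
                          fractions = c(0.6, 0.2, 0.2), seed = 1L,
                          stratify = FALSE, labels = NULL) {
  if (anyDuplicated(cell_ids)) abort("`cell_ids` must be unique")
  n <- length(cell_ids)
  if (n < 10) abort("at least 10 cells are required")
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8,
            n_shuffles >= 1)
  n_train <- round_half_up(fractions[1] * n)
  n_val <- round_half_up(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (min(n_train, n_val, n_test) < 1) abort("dataset too small for nonempty partitions")
  if (stratify && is.null(labels)) abort("`labels` required when stratifying")

  assignments <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_shuffles), function(s) {
      part <- character(n)
      if (stratify) {
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          k_tr <- round_half_up(fractions[1] * length(idx))
          k_va <- round_half_up(fractions[2] * length(idx))
          part[idx] <- rep(c("train", "validation", "test"),
                           c(k_tr, k_va, length(idx) - k_tr - k_va))
        }
      } else {
        idx <- sample.int(n)
        part[idx] <- rep(c("train", "validation", "test"),
                         c(n_train, n_val, n_test))
      }
      tibble::tibble(shuffle = s, cell_id = cell_ids, partition = part)
    })
  })
  structure(list(assignments = assignments, n_shuffles = as.integer(n_shuffles),
                 fractions = fractions, seed = seed,
                 sizes = c(train = n_train, validation = n_val, test = n_test)),
            class = "shuffle_plan")
}

#' @export
print.shuffle_plan <- function(x, ...) {
  cat(sprintf("<shuffle_plan> %d shuffles, %d/%d/%d train/val/test\n",
              x$n_shuffles, x$sizes[1], x$sizes[2], x$sizes[3]))
  invisible(x)
}

#' Tidy a shuffle plan
#' @param x a `shuffle_plan`.
#' @param ... unused.
#' @return the assignments tibble (`shuffle`, `cell_id`, `partition`).
#' @export
tidy.shuffle_plan <- function(x, ...) x$assignments

#' Training configuration
#'
#' Defaults mirror the published protocol: cross-entropy loss, batch size 8,
#' learning rate 2e-6, Adam, 100 epochs, best-validation-epoch checkpoint
#' selection. The default learning rate suits fine-tuning a pretrained
#' backbone; training the small CNN from scratch uses
#' [scaled_protocol_config()].
#'
#' @param batch_size minibatch size (default 8).
#' @param learning_rate Adam step size (default 2e-6).
#' @param epochs training epochs (default 100).
#' @param schedule `"constant"` (the published fine-tuning protocol) or
#'   `"cosine"` (half-cosine decay of the learning rate to zero over the
#'   epoch budget; the customary choice when training from random
#'   initialization under a fixed small epoch budget).
#' @param seed seed governing weight initialization and batch shuffling.
#' @return a `train_config` object.
#' @export
train_config <- function(batch_size = 8L, learning_rate = 2e-6,
                         epochs = 100L, schedule = c("constant", "cosine"),
                         seed = 1L) {
  schedule <- match.arg(schedule)
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1)
  structure(list(loss = "cross-entropy", optimizer = "adam",
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 schedule = schedule,
                 selection = "best-validation-epoch", seed = as.integer(seed)),
            class = "train_config")
}

#' Scaled-down protocol configuration
#'
#' The from-scratch counterpart of [train_config()] used for the CPU-scale
#' synthetic study: 30 epochs with a half-cosine learning-rate decay from
#' 2e-3 — the customary Adam regime for training from random initialization
#' under a fixed small epoch budget (fast early progress, stable finish for
#' every architecture size). The published 2e-6 is a fine-tuning rate and
#' barely moves freshly initialized weights in 30 epochs.
#'
#' @inheritParams train_config
#' @return a `train_config` object.
#' @export
scaled_protocol_config <- function(batch_size = 8L, learning_rate = 2e-3,
                                   epochs = 30L, seed = 1L) {
  train_config(batch_size = batch_size, learning_rate = learning_rate,
               epochs = epochs, schedule = "cosine", seed = seed)
}

cross_entropy <- function(probs, y) {
  -mean(colSums(y * log(pmax(probs, 1e-12))))
}

eval_loss_acc <- function(model, data) {
  inputs <- dataset_tensors(data, model$spec$input_size)
  probs <- model_forward(model, inputs, training = FALSE)$probs
  y <- label_onehot(data$label, model$classes)
  pred <- apply(probs, 2, which.max)
  list(loss = cross_entropy(probs, y),
       acc = mean(pred == max.col(t(y))),
       probs = probs)
}

#' Train a fusion model on one shuffle
#'
#' Minibatch training with cross-entropy loss and Adam. After every epoch the
#' validation loss and accuracy are recorded; the returned model carries the
#' weights of the epoch with the highest validation accuracy (ties broken by
#' lower validation loss, then by the earlier epoch). Fully deterministic
#' given the spec and config seeds.
#'
#' @param spec a [fusion_model_spec()].
#' @param train_data,val_data dataset tibbles (`label`, `morph`, `fluct`).
#' @param config a [train_config()].
#' @return a `trained_model`: list with `model` (best checkpoint), `curves`
#'   (tibble of per-epoch train/validation loss and accuracy) and
#'   `best_epoch`.
#' @export
train_one_shuffle <- function(spec, train_data, val_data, config = train_config()) {
  stopifnot(inherits(spec, "fusion_model_spec"), inherits(config, "train_config"))
  if (nrow(train_data) < 1 || nrow(val_data) < 1) abort("empty partition")
  model <- build_model(spec, seed = config$seed)
  params <- model_params(model)
  opt <- adam_init(params, lr = config$learning_rate)
  tensors <- dataset_tensors(train_data, spec$input_size)
  y_all <- label_onehot(train_data$label, model$classes)
  n <- nrow(train_data)

  curves <- vector("list", config$epochs)
  best <- list(acc = -Inf, loss = Inf, epoch = NA_integer_, params = NULL)

  schedule <- config$schedule %||% "constant"
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      if (schedule == "cosine") {
        opt$lr <- config$learning_rate *
          (1 + cos(pi * (epoch - 1) / config$epochs)) / 2
      }
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, n)]
        nb <- length(take)
        batch <- list(
          morphology = tensors$morphology[, , , take, drop = FALSE],
          fluctuations = tensors$fluctuations[, , , take, drop = FALSE])
        y <- y_all[, take, drop = FALSE]
        fw <- model_forward(model, batch, training = TRUE)
        loss <- cross_entropy(fw$probs, y)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss * nb
        ep_correct <- ep_correct + sum(apply(fw$probs, 2, which.max) == max.col(t(y)))
        grads <- model_backward(model, fw$caches, (fw$probs - y) / nb)
        upd <- adam_step(opt, params, grads)
        opt <- upd$state
        params <- upd$params
        model <- model_set_params(model, params)
      }
      val <- eval_loss_acc(model, val_data)
      curves[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val$loss, val_acc = val$acc)
      if (val$acc > best$acc ||
          (val$acc == best$acc && val$loss < best$loss - 1e-12)) {
        best <- list(acc = val$acc, loss = val$loss, epoch = epoch,
                     params = params)
      }
    }
  })
  structure(list(model = model_set_params(model, best$params),
                 curves = dplyr::bind_rows(curves), best_epoch = best$epoch,
                 config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> best epoch %d (val acc %.3f)\n", x$best_epoch,
              x$curves$val_acc[x$best_epoch]))
  invisible(x)
}

#' Tidy training curves
#' @param x a `trained_model`.
#' @param ... unused.
#' @return tibble of per-epoch train/validation loss and accuracy.
#' @export
tidy.trained_model <- function(x, ...) x$curves

#' Plot training curves
#'
#' Per-epoch train/validation accuracy and loss of a trained model.
#'
#' @param object a `trained_model` (or the curves tibble).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curves, -"epoch",
                            names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL, title = "Training curves")
}

#' Rank-based AUC of positive-class scores
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic on the
#' positive-class scores (ties contribute 1/2).
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param positive logical vector, `TRUE` for positive-class items.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) abort("AUC undefined: test set has one class")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Five-metric suite from predictions
#'
#' Computes, with the metastatic class as positive: accuracy `(TP+TN)/N`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)` and the rank-based AUC of the positive-class score.
#' Precision is `NA` (flagged undefined) when no positive predictions are
#' made.
#'
#' @param truth,pred character vectors of true and predicted labels
#'   (`"primary"` / `"metastatic"`).
#' @param scores numeric positive-class scores for the AUC.
#' @param positive the positive class (default `"metastatic"`).
#' @return a one-row tibble of metrics plus the confusion counts.
#' @export
classification_metrics <- function(truth, pred, scores,
                                   positive = "metastatic") {
  stopifnot(length(truth) == length(pred), length(truth) == length(scores))
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  tp <- sum(pred_pos & truth_pos); fp <- sum(pred_pos & !truth_pos)
  tn <- sum(!pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  tibble::tibble(
    accuracy = (tp + tn) / length(truth_pos),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    auc = rank_auc(scores, truth_pos),
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate a trained model on a test set
#'
#' Runs the model on the test items and scores the argmax predictions with
#' [classification_metrics()] (metastatic = positive).
#'
#' @param model a `fusion_model` or `trained_model`.
#' @param test_data dataset tibble containing both classes.
#' @return a one-row tibble of metrics (plus the confusion counts).
#' @export
evaluate_model <- function(model, test_data) {
  if (inherits(model, "trained_model")) model <- model$model
  stopifnot(inherits(model, "fusion_model"))
  if (length(unique(test_data$label)) < 2) {
    abort("AUC undefined: test set contains a single class")
  }
  pr <- predict(model, test_data)
  classification_metrics(test_data$label, pr$pred, pr$prob_metastatic)
}

#' Aggregate per-shuffle metric rows
#'
#' Mean and sample standard deviation (n - 1 denominator) of each metric
#' across shuffles.
#'
#' @param reports tibble of per-shuffle metric rows (>= 2 rows).
#' @param metrics metric columns to aggregate.
#' @return tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_reports <- function(reports,
                              metrics = c("accuracy", "sensitivity",
                                          "specificity", "precision", "auc")) {
  stopifnot(nrow(reports) >= 2)
  purrr::map_dfr(metrics, function(m) {
    v <- reports[[m]]
    tibble::tibble(metric = m, mean = mean(v, na.rm = TRUE),
                   sd = stats::sd(v, na.rm = TRUE), n = sum(!is.na(v)))
  })
}

#' Run the full repeated-shuffle protocol for one architecture
#'
#' For each shuffle of the plan: trains on the train partition, checkpoints
#' the best-validation epoch, evaluates on the test partition; then
#' aggregates the five metrics across shuffles. Per-shuffle training seeds
#' are derived deterministically from the config seed.
#'
#' @param data dataset tibble (`cell_id`, `label`, `morph`, `fluct`).
#' @param spec a [fusion_model_spec()].
#' @param plan a [make_shuffles()] plan over `data$cell_id`.
#' @param config a [train_config()].
#' @param keep_curves retain per-shuffle training curves (default `TRUE`).
#' @return an `eval_report`: list with `per_shuffle` (tibble of per-shuffle
#'   metrics), `aggregate` (tibble from [aggregate_reports()]), `curves`,
#'   `spec`, `config`.
#' @export
run_protocol <- function(data, spec, plan, config = train_config(),
                         keep_curves = TRUE) {
  stopifnot(inherits(plan, "shuffle_plan"))
  if (!setequal(plan$assignments$cell_id, data$cell_id)) {
    abort("plan and dataset cell ids differ")
  }
  rows <- vector("list", plan$n_shuffles)
  curves <- vector("list", plan$n_shuffles)
  for (s in seq_len(plan$n_shuffles)) {
    asg <- plan$assignments[plan$assignments$shuffle == s, ]
    pick <- function(p) data[data$cell_id %in% asg$cell_id[asg$partition == p], ]
    cfg <- config
    cfg$seed <- config$seed + 1000L * s
    fit <- train_one_shuffle(spec, pick("train"), pick("validation"), cfg)
    rows[[s]] <- dplyr::mutate(evaluate_model(fit, pick("test")),
                               shuffle = s, best_epoch = fit$best_epoch,
                               .before = 1)
    if (keep_curves) curves[[s]] <- dplyr::mutate(fit$curves, shuffle = s)
  }
  per_shuffle <- dplyr::bind_rows(rows)
  structure(list(per_shuffle = per_shuffle,
                 aggregate = aggregate_reports(per_shuffle),
                 curves = if (keep_curves) dplyr::bind_rows(curves),
                 spec = spec, config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s-path [%s], %d shuffles\n", x$spec$variant,
              paste(x$spec$inputs, collapse = "+"), nrow(x$per_shuffle)))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %.4f +/- %.4f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}

#' Tidy an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return the per-shuffle metrics tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_shuffle

#' Glance at an evaluation report
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return a one-row tibble: model descriptor plus `<metric>_mean` and
#'   `<metric>_sd` columns (the layout of the published performance table).
#' @export
glance.eval_report <- function(x, ...) {
  agg <- x$aggregate
  wide <- tibble::as_tibble(
    stats::setNames(as.list(c(agg$mean, agg$sd)),
                    c(paste0(agg$metric, "_mean"), paste0(agg$metric, "_sd"))))
  dplyr::bind_cols(tibble::tibble(model = x$spec$variant,
                                  input = paste(x$spec$inputs, collapse = "+")),
                   wide)
}

#' Plot per-shuffle metric distributions
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$per_shuffle[, c("shuffle", "accuracy", "sensitivity", "specificity",
                           "precision", "auc")],
    -"shuffle", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-shuffle test metrics")
}
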