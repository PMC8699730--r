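test_that("shuffle plans have the documented sizes and determinism", {
  ids <- sprintf("c%03d", 1:216)
  plan <- make_shuffles(ids, n_shuffles = 3, seed = 7)
  tab <- table(plan$assignments$partition[plan$assignments$shuffle == 1])
  expect_equal(unname(tab[c("train", "validation", "test")]), c(130L, 43L, 43L),
               ignore_attr = TRUE)
  # partitions disjoint, union = everything, per shuffle
  for (s in 1:3) {
    a <- plan$assignments[plan$assignments$shuffle == s, ]
    expect_setequal(a$cell_id, ids)
    expect_equal(nrow(a), 216L)
  }
  plan2 <- make_shuffles(ids, n_shuffles = 3, seed = 7)
  expect_identical(plan$assignments, plan2$assignments)
  expect_false(identical(plan$assignments,
                         make_shuffles(ids, n_shuffles = 3, seed = 8)$assignments))

  small <- make_shuffles(letters[1:10], n_shuffles = 1, seed = 1)
  expect_equal(unname(small$sizes), c(6L, 2L, 2L), ignore_attr = TRUE)
  expect_error(make_shuffles(letters[1:5]), "at least 10")
  expect_error(make_shuffles(c("a", "a", letters[1:10])), "unique")

  # stratified plans keep class proportions per partition
  labs <- rep(c("primary", "metastatic"), each = 108)
  sp <- make_shuffles(ids, n_shuffles = 1, seed = 2, stratify = TRUE,
                      labels = labs)
  a <- sp$assignments
  tr <- a$cell_id[a$partition == "train"]
  expect_equal(sum(labs[match(tr, ids)] == "primary"), 65L)
})

test_that("classification metrics reproduce hand-computed values", {
  truth <- c(rep("metastatic", 5), rep("primary", 5))
  pred <- c(rep("metastatic", 5), "metastatic", rep("primary", 4))
  scores <- c(0.9, 0.8, 0.85, 0.95, 0.7, 0.6, 0.2, 0.1, 0.3, 0.25)
  m <- classification_metrics(truth, pred, scores)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 5 / 6)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(5, 1, 4, 0))

  # perfect separation: AUC 1
  expect_equal(m$auc, 1)

  # worked 4-score example: 3 of 4 concordant pairs
  expect_equal(rank_auc(c(0.8, 0.6, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)

  # no positive predictions: precision flagged undefined
  m0 <- classification_metrics(truth, rep("primary", 10), scores)
  expect_true(is.na(m0$precision))
  expect_error(rank_auc(1:3, c(TRUE, TRUE, TRUE)), "one class")
})

test_that("rank AUC equals the Mann-Whitney statistic on random scores", {
  set.seed(12)
  for (i in 1:50) {
    n_pos <- sample(3:10, 1); n_neg <- sample(3:10, 1)
    scores <- round(c(rnorm(n_pos, 0.5), rnorm(n_neg)), 1)  # force some ties
    positive <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    expect_equal(rank_auc(scores, positive), oracle_auc(scores, positive),
                 tolerance = 1e-12)
    w <- suppressWarnings(stats::wilcox.test(scores[positive],
                                             scores[!positive]))
    expect_equal(rank_auc(scores, positive),
                 unname(w$statistic) / (n_pos * n_neg), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(30); pos <- rep(c(TRUE, FALSE), 15)
  expect_equal(rank_auc(sc, pos),
               as.numeric(suppressMessages(pROC::auc(pos, sc))),
               tolerance = 1e-9)
})

test_that("training learns separable toys and selects the best epoch", {
  set.seed(31)
  n <- 32
  mk <- function(cls) {
    base <- matrix(0.1, 16, 16)
    if (cls == "metastatic") base[4:12, 4:12] <- 0.9 else base[4:6, 4:6] <- 0.9
    base + matrix(runif(256, 0, 0.05), 16, 16)
  }
  labels <- rep(c("primary", "metastatic"), each = n / 2)
  data <- tibble::tibble(cell_id = sprintf("t%02d", 1:n), label = labels,
                         morph = lapply(labels, mk),
                         fluct = lapply(labels, function(...) matrix(runif(256), 16)))
  spec <- fusion_model_spec("single", backbone = "small-cnn", input_size = 16)
  cfg <- scaled_protocol_config(epochs = 10, seed = 3)
  fit <- train_one_shuffle(spec, data[c(1:12, 17:28), ], data[c(13:14, 29:30), ],
                           cfg)
  expect_equal(max(fit$curves$val_acc), 1)
  expect_equal(nrow(fit$curves), 10)

  # epochs = 1 selects epoch 1
  one <- train_one_shuffle(spec, data[c(1:12, 17:28), ], data[c(13:14, 29:30), ],
                           scaled_protocol_config(epochs = 1, seed = 3))
  expect_equal(one$best_epoch, 1L)

  # fixed seeds give identical metric trajectories
  fit2 <- train_one_shuffle(spec, data[c(1:12, 17:28), ], data[c(13:14, 29:30), ],
                            cfg)
  expect_identical(fit$curves, fit2$curves)

  ev <- evaluate_model(fit, data[c(15:16, 31:32), ])
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))
  expect_error(evaluate_model(fit, data[15:16, ]), "single class")
})

test_that("aggregation reports cross-shuffle mean and sample sd", {
  rows <- tibble::tibble(accuracy = c(0.8, 0.9), sensitivity = c(1, 1),
                         specificity = c(0.5, 0.7), precision = c(0.6, 0.8),
                         auc = c(0.9, 1))
  agg <- aggregate_reports(rows)
  expect_equal(agg$mean[agg$metric == "accuracy"], 0.85)
  expect_equal(agg$sd[agg$metric == "accuracy"], sd(c(0.8, 0.9)))
  expect_equal(agg$sd[agg$metric == "sensitivity"], 0)

  set.seed(14)
  r20 <- tibble::tibble(accuracy = runif(20), sensitivity = runif(20),
                        specificity = runif(20), precision = runif(20),
                        auc = runif(20))
  agg <- aggregate_reports(r20)
  for (m in agg$metric) {
    v <- r20[[m]]
    expect_equal(agg$mean[agg$metric == m], sum(v) / 20, tolerance = 1e-12)
    expect_equal(agg$sd[agg$metric == m],
                 sqrt(sum((v - mean(v))^2) / 19), tolerance = 1e-12)
  }
})

test_that("tidiers expose per-shuffle rows and table-style aggregates", {
  rep1 <- cached_protocol_rep(1)$single
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_equal(nrow(tidy(rep1)), 5L)
  g <- glance(rep1)
  expect_equal(g$model, "single")
  expect_true(all(c("accuracy_mean", "accuracy_sd", "auc_mean") %in% names(g)))
  expect_true(all(tidy(rep1)$accuracy >= 0 & tidy(rep1)$accuracy <= 1))
})
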