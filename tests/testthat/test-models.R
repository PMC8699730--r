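test_that("fusion specs enforce the variant/input rules", {
  expect_equal(fusion_model_spec("single")$inputs, "morphology")
  expect_equal(fusion_model_spec("double")$inputs, c("morphology", "fluctuations"))
  expect_equal(fusion_model_spec("triple")$inputs,
               c("morphology", "fluctuations", "two_channel"))
  expect_error(fusion_model_spec("single", inputs = c("morphology", "fluctuations")),
               "exactly 1")
  expect_error(fusion_model_spec("double", inputs = "morphology"), "exactly 2")
  expect_error(fusion_model_spec("triple", inputs = c("morphology", "fluctuations")),
               "exactly 3|three")
  expect_error(fusion_model_spec("single", inputs = "nonsense"), "inputs")
  expect_error(fusion_model_spec("single", head_dims = c(64, 3)), "end at 2")
  expect_error(fusion_model_spec("single", backbone = "small-cnn",
                                 head_dims = c(256, 2)), "decreasing")
  # early fusion = single path on the two-channel input
  s2 <- fusion_model_spec("single", inputs = "two_channel", backbone = "small-cnn")
  expect_equal(s2$fused_len, 128L)
})

test_that("softmax outputs are proper probabilities for any variant", {
  set.seed(1)
  inputs <- list(morphology = array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3)),
                 fluctuations = array(runif(16 * 16 * 1 * 3), c(16, 16, 1, 3)))
  for (variant in c("single", "double", "triple")) {
    model <- build_model(fusion_model_spec(variant, backbone = "small-cnn",
                                           input_size = 16), seed = 2)
    probs <- phasefluct:::model_forward(model, inputs)$probs
    expect_equal(dim(probs), c(2L, 3L))
    expect_true(all(probs >= 0 & probs <= 1))
    expect_equal(colSums(probs), rep(1, 3), tolerance = 1e-6)
  }
  # smoke: triple path on 64 px inputs
  big <- list(morphology = array(runif(64 * 64), c(64, 64, 1, 1)),
              fluctuations = array(runif(64 * 64), c(64, 64, 1, 1)))
  m64 <- build_model(fusion_model_spec("triple", backbone = "small-cnn",
                                       input_size = 64), seed = 1)
  expect_equal(sum(phasefluct:::model_forward(m64, big)$probs), 1,
               tolerance = 1e-6)
})

test_that("the default triple model has three independent backbones", {
  single <- build_model(fusion_model_spec("single"), seed = 1)
  triple <- build_model(fusion_model_spec("triple"), seed = 1)
  backbone_params <- phasefluct:::tree_count(
    phasefluct:::seq_params(single$paths$morphology))
  expect_gt(backbone_params, 2e7)      # ResNet-50-scale backbone
  expect_gt(n_parameters(triple), 3 * backbone_params)
  expect_equal(single$spec$feature_len, 2048L)
})

test_that("fusion algebra matches its definitions", {
  expect_equal(fuse_double(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  expect_equal(fuse_double(rep(0, 5), rep(0, 5)), rep(0, 10))
  expect_equal(fuse_triple(c(1, 0), c(0, 1), c(1, 1)), c(2, 1, 1, 2))
  expect_error(fuse_double(1:3, 1:4), "lengths differ")
  expect_error(fuse_triple(1:3, 1:3, 1:4), "lengths differ")

  set.seed(9)
  for (i in 1:20) {
    l <- sample(1:64, 1)
    v1 <- rnorm(l); v2 <- rnorm(l); v3 <- rnorm(l)
    want <- numeric(2 * l)
    for (j in seq_len(l)) {
      want[j] <- v1[j] + v3[j]
      want[l + j] <- v2[j] + v3[j]
    }
    expect_equal(fuse_triple(v1, v2, v3), want)
    expect_equal(fuse_triple(v1, v2, numeric(l)), fuse_double(v1, v2))
  }
})

test_that("two-channel stacking and channel adaptation are faithful", {
  a <- matrix(1:12 / 12, 3, 4); b <- matrix(12:1 / 12, 3, 4)
  tc <- make_two_channel(a, b)
  expect_equal(tc[, , 1], a)
  expect_equal(tc[, , 2], b)
  sw <- make_two_channel(b, a)
  expect_equal(sw[, , 1], b)
  expect_equal(mean(tc[, , 1]), mean(a))
  expect_error(make_two_channel(a, matrix(0, 4, 3)), "dimensions differ")

  one <- array(0.5, c(4, 4, 1))
  expect_equal(adapt_input_channels(one), array(0.5, c(4, 4, 3)))
  three <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(adapt_input_channels(three), three)
  two <- array(runif(4 * 4 * 2), c(4, 4, 2))
  ad <- adapt_input_channels(two)
  expect_equal(ad[, , 3], (two[, , 1] + two[, , 2]) / 2)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(21)
  spec <- fusion_model_spec("triple", backbone = "small-cnn", input_size = 8)
  model <- build_model(spec, seed = 3)
  inputs <- list(morphology = array(runif(8 * 8 * 1 * 4), c(8, 8, 1, 4)),
                 fluctuations = array(runif(8 * 8 * 1 * 4), c(8, 8, 1, 4)))
  y <- phasefluct:::label_onehot(c("primary", "metastatic", "primary",
                                   "metastatic"))
  fw <- phasefluct:::model_forward(model, inputs, training = TRUE)
  grads <- phasefluct:::model_backward(model, fw$caches, (fw$probs - y) / 4)
  params <- phasefluct:::model_params(model)
  loss_of <- function(p) {
    m <- phasefluct:::model_set_params(model, p)
    phasefluct:::cross_entropy(
      phasefluct:::model_forward(m, inputs, training = TRUE)$probs, y)
  }
  eps <- 1e-5
  for (path in c("morphology", "two_channel")) {
    for (li in c(1L, 4L, 7L)) {
      pv <- params$paths[[path]][[li]]$W
      gv <- grads$paths[[path]][[li]]$W
      for (i in sample(length(pv), 2)) {
        p2 <- params
        p2$paths[[path]][[li]]$W[i] <- pv[i] + eps
        up <- loss_of(p2)
        p2$paths[[path]][[li]]$W[i] <- pv[i] - eps
        dn <- loss_of(p2)
        expect_equal(gv[i], (up - dn) / (2 * eps), tolerance = 1e-4)
      }
    }
  }
  # head and a residual/batchnorm backbone, too
  pv <- params$head[[1]]$W; gv <- grads$head[[1]]$W
  i <- which.max(abs(gv))
  p2 <- params; p2$head[[1]]$W[i] <- pv[i] + eps; up <- loss_of(p2)
  p2$head[[1]]$W[i] <- pv[i] - eps; dn <- loss_of(p2)
  expect_equal(gv[i], (up - dn) / (2 * eps), tolerance = 1e-4)
})

test_that("residual batchnorm backbones backpropagate correctly", {
  set.seed(30)
  specs <- list(phasefluct:::nn_conv(4, bias = FALSE),
                phasefluct:::nn_batchnorm(), phasefluct:::nn_relu(),
                phasefluct:::nn_residual(
                  list(phasefluct:::nn_conv(4, kernel = 1L, pad = 0L, bias = FALSE),
                       phasefluct:::nn_batchnorm(), phasefluct:::nn_relu(),
                       phasefluct:::nn_conv(8, kernel = 3L, stride = 2L, bias = FALSE),
                       phasefluct:::nn_batchnorm()),
                  list(phasefluct:::nn_conv(8, kernel = 1L, stride = 2L,
                                            pad = 0L, bias = FALSE),
                       phasefluct:::nn_batchnorm())),
                phasefluct:::nn_gap(), phasefluct:::nn_linear(2))
  ini <- phasefluct:::seq_init(specs, c(8L, 8L, 2L))
  x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  y <- phasefluct:::label_onehot(c("primary", "metastatic", "primary"))
  loss_of <- function(layers) {
    out <- phasefluct:::seq_forward(layers, x, training = TRUE)$out
    phasefluct:::cross_entropy(phasefluct:::softmax_cols(out), y)
  }
  fw <- phasefluct:::seq_forward(ini$layers, x, training = TRUE)
  probs <- phasefluct:::softmax_cols(fw$out)
  bk <- phasefluct:::seq_backward(ini$layers, fw$caches, (probs - y) / 3)
  params <- phasefluct:::seq_params(ini$layers)
  eps <- 1e-5
  # conv inside the residual main branch and a batchnorm gamma
  pick <- list(
    list(get = function(p) p[[4]]$main[[4]]$W,
         set = function(p, i, d) { p[[4]]$main[[4]]$W[i] <- p[[4]]$main[[4]]$W[i] + d; p },
         grad = bk$grads[[4]]$main[[4]]$W),
    list(get = function(p) p[[4]]$shortcut[[2]]$gamma,
         set = function(p, i, d) { p[[4]]$shortcut[[2]]$gamma[i] <- p[[4]]$shortcut[[2]]$gamma[i] + d; p },
         grad = bk$grads[[4]]$shortcut[[2]]$gamma),
    list(get = function(p) p[[2]]$beta,
         set = function(p, i, d) { p[[2]]$beta[i] <- p[[2]]$beta[i] + d; p },
         grad = bk$grads[[2]]$beta))
  for (pk in pick) {
    pv <- pk$get(params)
    i <- which.max(abs(pk$grad))
    up <- loss_of(phasefluct:::seq_set_params(ini$layers, pk$set(params, i, eps)))
    dn <- loss_of(phasefluct:::seq_set_params(ini$layers, pk$set(params, i, -eps)))
    expect_equal(pk$grad[i], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("model predictions are reproducible from the spec seed", {
  d <- cached_small_dataset()
  spec <- fusion_model_spec("double", backbone = "small-cnn")
  m1 <- build_model(spec, seed = 5)
  m2 <- build_model(spec, seed = 5)
  expect_identical(predict(m1, d[1:4, ]), predict(m2, d[1:4, ]))
  g <- glance(m1)
  expect_equal(g$variant, "double")
  expect_equal(g$fused_len, 256L)
})
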