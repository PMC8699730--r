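test_that("mean_opd and mean_abs_fluct match direct computation", {
  mask <- make_disk_mask(16, 6)
  uni <- matrix(7.5, 16, 16)
  expect_equal(mean_opd(uni, mask), 7.5)

  half <- matrix(2, 16, 16); half[1:8, ] <- 4
  m <- mask$pixels
  expect_equal(mean_opd(half, mask), mean(half[m]))

  set.seed(2)
  rnd <- matrix(rnorm(16 * 16), 16, 16)
  acc <- 0; cnt <- 0
  for (i in 1:16) for (j in 1:16) if (m[i, j]) { acc <- acc + rnd[i, j]; cnt <- cnt + 1 }
  expect_equal(mean_opd(rnd, mask), acc / cnt, tolerance = 1e-12)

  expect_equal(mean_abs_fluct(matrix(0, 4, 5)), 0)
  expect_equal(mean_abs_fluct(matrix(2.5, 4, 5)), 2.5)
  p <- matrix(rexp(12), 3, 4)
  expect_equal(mean_abs_fluct(p), sum(abs(p)) / 12, tolerance = 1e-12)
})

test_that("compare_groups behaves like a proper two-sample test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(compare_groups(x, x), 1, tolerance = 1e-9)

  set.seed(4)
  a <- rnorm(50); b <- rnorm(50) + 10
  expect_lt(compare_groups(a, b), 1e-10)

  # symmetry and affine invariance (Welch t)
  expect_equal(compare_groups(a, b), compare_groups(b, a))
  expect_equal(compare_groups(a, b), compare_groups(3 * a - 7, 3 * b - 7),
               tolerance = 1e-9)

  # degenerate equal-constant groups
  expect_equal(compare_groups(rep(2, 5), rep(2, 4)), 1)

  expect_lt(compare_groups(a, b, method = "wilcoxon"), 1e-10)
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("two-class summaries separate without full separation", {
  data <- cached_small_dataset()
  s <- cell_summaries(data)
  expect_named(s, c("cell_id", "label", "mean_opd_nm", "mean_abs_fluct"))
  g <- summarize_groups(s)
  expect_equal(nrow(g), 2)
  expect_true(all(g$p_value >= 0 & g$p_value <= 1))
  # metastatic cells fluctuate more on average
  fl <- g[g$statistic == "mean_abs_fluct", ]
  meta <- if (fl$group1 == "metastatic") fl$mean_group1 else fl$mean_group2
  prim <- if (fl$group1 == "metastatic") fl$mean_group2 else fl$mean_group1
  expect_gt(meta, prim)
  # overlapping class distributions: no threshold separates them fully
  am <- s$mean_abs_fluct[s$label == "metastatic"]
  ap <- s$mean_abs_fluct[s$label == "primary"]
  expect_true(max(ap) > min(am))
})
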