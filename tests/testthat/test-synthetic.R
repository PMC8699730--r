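test_that("simulated videos are deterministic and respect their parameters", {
  p <- synthetic_cell_params(size = 48, frames = 32, seed = 77)
  v1 <- simulate_cell_video(p)
  v2 <- simulate_cell_video(p)
  expect_identical(v1$video$frames, v2$video$frames)
  expect_false(identical(
    v1$video$frames,
    simulate_cell_video(synthetic_cell_params(size = 48, frames = 32,
                                              seed = 78))$video$frames))

  # no fluctuations, no noise: the video is static inside the cell
  p0 <- synthetic_cell_params(size = 48, frames = 16, fluct_amp_nm = 0,
                              noise_floor_nm = 0, seed = 1)
  s0 <- simulate_cell_video(p0)
  expect_equal(max(temporal_std_map(s0$video, s0$mask)), 0, tolerance = 1e-9)

  expect_error(synthetic_cell_params(size = 32, dome_radius_px = 30), "inside")
})

test_that("the interior fluctuation RMS matches the requested amplitude", {
  p <- synthetic_cell_params(fluct_amp_nm = 5, noise_floor_nm = 0,
                             frames = 512, seed = 9)
  sim <- simulate_cell_video(p)
  r <- sqrt(outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+"))
  interior <- r < 0.8 * p$dome_radius_px
  x <- matrix(sim$video$frames, ncol = 512)
  x <- x - rowMeans(x)
  rms <- sqrt(mean(x[as.vector(interior), ]^2))
  expect_lt(abs(rms - 5) / 5, 0.10)
})

test_that("hologram simulation produces the stated fringe pattern", {
  h <- simulate_hologram(matrix(0, 64, 64), carrier_freq = c(0, 0.25),
                         visibility = 0.8)
  expect_true(all(h$intensity >= 0))
  # pure fringes: spectrum concentrated at DC and +/- carrier
  spec <- Mod(fft(h$intensity))^2
  top <- order(spec, decreasing = TRUE)[1:3]
  bins <- arrayInd(top, c(64, 64))
  expect_setequal(bins[, 2], c(1L, 17L, 49L))   # 0, +16, -16 cycles/frame
  expect_true(all(bins[, 1] == 1L))
  # period 4 px along columns
  expect_equal(h$intensity[1, 1], h$intensity[1, 5], tolerance = 1e-9)
})

test_that("class-conditional datasets differ in the designed directions", {
  d <- cached_small_dataset()
  expect_equal(nrow(d), 20L)
  expect_equal(sum(d$label == "primary"), 10L)
  # metastatic cells are smaller and fluctuate more, on average
  expect_gt(mean(d$mean_opd_nm[d$label == "primary"]),
            mean(d$mean_opd_nm[d$label == "metastatic"]))
  expect_gt(mean(d$mean_abs_fluct[d$label == "metastatic"]),
            mean(d$mean_abs_fluct[d$label == "primary"]))
  # maps are network-ready
  expect_true(all(vapply(d$morph, function(m) all(dim(m) == 32L), logical(1))))
  expect_true(all(vapply(d$fluct, function(m) min(m) >= 0 && max(m) <= 1,
                         logical(1))))
  # determinism of the full generator
  d2 <- simulate_classification_data(n_per_class = 10L, seed = 42L,
                                     size = 48L, frames = 64L)
  expect_identical(d$morph[[3]], d2$morph[[3]])
  expect_identical(d$mean_abs_fluct, d2$mean_abs_fluct)
})
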