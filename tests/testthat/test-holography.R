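test_that("resize preserves constants exactly and means closely", {
  x <- matrix(5.5, 512, 512)
  y <- resize_map(x, 250, 250)
  expect_equal(dim(y), c(250L, 250L))
  expect_equal(max(abs(y - 5.5)), 0)

  checker <- outer(1:512, 1:512, function(i, j) (i + j) %% 2)
  z <- resize_map(checker, 250, 250)
  expect_lt(abs(mean(z) - mean(checker)) / mean(checker), 0.01)

  expect_equal(resize_map(checker, 512, 512), checker)
})

test_that("standardize_video resizes frames and keeps metadata", {
  v <- opd_video(array(rnorm(24 * 20 * 3), c(24, 20, 3)), frame_rate_hz = 500)
  s <- standardize_video(v, 10)
  expect_equal(dim(s), c(10L, 10L, 3L))
  expect_equal(s$frame_rate_hz, 500)
  const <- opd_video(array(7, c(16, 16, 2)), frame_rate_hz = 100)
  expect_equal(max(abs(standardize_video(const, 9)$frames - 7)), 0)
  expect_error(standardize_video(v, 1), "size")
})

test_that("unwrap_phase recovers smooth phases and stays congruent mod 2*pi", {
  # constant map is unchanged up to 2*pi*k
  cst <- matrix(1.2, 16, 16)
  u <- unwrap_phase(cst)
  d <- (u - cst) / (2 * pi)
  expect_lt(max(abs(d - round(d))), 1e-9)

  # planar ramp spanning 6*pi: exact recovery up to a global 2*pi*k
  m <- 64
  ramp <- outer(seq(0, 6 * pi, length.out = m), rep(1, m)) +
    outer(rep(1, m), seq(0, 2 * pi, length.out = m))
  w <- (ramp + pi) %% (2 * pi) - pi
  u <- unwrap_phase(w)
  err <- u - ramp
  expect_lt(max(abs(err - 2 * pi * round(err[1, 1] / (2 * pi)))), 1e-6)

  # already-smooth map with range < 2*pi comes back unchanged (up to 2*pi*k)
  sm <- random_smooth_opd(32, amplitude_nm = 5, seed = 2)   # range 0..5 rad
  sm <- sm - mean(sm)
  u <- unwrap_phase(sm)
  expect_lt(max(abs(u - sm - 2 * pi * round((u - sm)[1, 1] / (2 * pi)))), 1e-9)

  # congruence holds even for rough inputs
  set.seed(3)
  rough <- matrix(runif(15 * 17, -pi, pi), 15, 17)
  u <- unwrap_phase(rough)
  resid <- (u - rough) / (2 * pi)
  expect_lt(max(abs(resid - round(resid))), 1e-9)
})

test_that("reconstruct_opd inverts simulate_hologram", {
  # flat phase: reconstruction is zero after piston removal
  flat <- reconstruct_opd(simulate_hologram(matrix(0, 64, 64), c(0, 0.25)))
  expect_lt(max(abs(flat)), 0.1)

  # Gaussian bump of 300 nm at 633 nm illumination: peak within 2%
  g <- 300 * exp(-(outer((1:128) - 64, rep(1, 128))^2 +
                   outer(rep(1, 128), (1:128) - 64)^2) / (2 * 15^2))
  rec <- reconstruct_opd(simulate_hologram(g, c(0, 0.25), 633, 0.9))
  expect_lt(abs(max(rec) - 300) / 300, 0.02)
  expect_lt(sqrt(mean((rec - g)^2)) / diff(range(g)), 0.01)

  # small-phase linearity: doubling the OPD doubles the reconstruction
  s <- g / 30
  r1 <- reconstruct_opd(simulate_hologram(s, c(0, 0.25)))
  r2 <- reconstruct_opd(simulate_hologram(2 * s, c(0, 0.25)))
  expect_lt(abs(max(r2) / max(r1) - 2), 0.02)
})

test_that("reconstruction rejects degenerate carriers and inputs", {
  holo <- hologram(matrix(1, 64, 64), c(0.01, 0), 633)
  expect_error(reconstruct_opd(holo, crop_radius = 0.05), "overlaps the DC")
  expect_error(hologram(matrix(c(NA, 1:63), 8, 8), c(0, 0.25), 633), "finite")
  expect_error(hologram(matrix(1, 8, 8), c(0, 0.6), 633), "Nyquist")
  expect_error(simulate_hologram(matrix(0, 8, 8), visibility = 1.5), "visibility")
})

test_that("OPD video TIFF round trip preserves values and metadata", {
  v <- opd_video(array(rnorm(16 * 16 * 4, sd = 120), c(16, 16, 4)),
                 frame_rate_hz = 500, wavelength_nm = 633)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_opd_video(v, path)
  r <- read_opd_video(path)
  expect_lt(max(abs(r$frames - v$frames)), 1e-4)  # float32 storage
  expect_equal(r$frame_rate_hz, 500)
  expect_equal(r$wavelength_nm, 633)
  expect_error(read_opd_video(file.path(tempdir(), "nope.tiff")), "no such file")
})
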