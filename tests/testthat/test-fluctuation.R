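test_that("build_mask places an eroded disk at the cell centroid", {
  # dome whose 20%-threshold support has radius ~80 px
  n <- 220
  r <- sqrt(outer((seq_len(n) - 105)^2, (seq_len(n) - 118)^2, "+"))
  dome <- 300 * pmax(1 - (r / (80 / sqrt(0.8)))^2, 0)
  mask <- build_mask(dome, threshold_frac = 0.2, erode_frac = 0.7)
  expect_equal(mask$center, c(105, 118), tolerance = 0.01)
  expect_equal(mask$radius_px, 56, tolerance = 0.02)

  # every selected pixel is above threshold (disk is interior to the support)
  expect_true(all(dome[mask$pixels] > 0.2 * max(dome)))

  expect_error(build_mask(matrix(0, 64, 64)), "no cell")
  expect_error(build_mask(matrix(-1, 64, 64) + diag(64)), "no cell|too small")
})

test_that("temporal_std_map matches closed forms and a per-pixel oracle", {
  mask <- make_disk_mask(16, 6)
  static <- opd_video(array(3, c(16, 16, 8)), frame_rate_hz = 10)
  expect_equal(max(abs(temporal_std_map(static, mask))), 0)

  # one pixel alternating +/- a: sd = |a| * sqrt(T/(T-1))
  fr <- array(0, c(16, 16, 8))
  fr[8, 8, ] <- 2.5 * c(1, -1, 1, -1, 1, -1, 1, -1)
  s <- temporal_std_map(opd_video(fr, 10), mask)
  expect_equal(s[8, 8], 2.5 * sqrt(8 / 7), tolerance = 1e-12)

  set.seed(5)
  v <- opd_video(array(rnorm(16 * 16 * 16), c(16, 16, 16)), 10)
  m16 <- make_disk_mask(16, 6.2)
  got <- temporal_std_map(v, m16)
  want <- oracle_std_map(v$frames) * m16$pixels
  expect_equal(unclass(got), want, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(temporal_std_map(v, make_disk_mask(32, 12)), "dimensions differ")
})

test_that("radial_average matches the brute-force binning loop", {
  set.seed(7)
  for (i in 1:50) {
    m <- sample(4:16, 1); n <- sample(4:16, 1)
    nb <- sample(2:6, 1)
    p <- matrix(rexp(m * n), m, n)
    got <- radial_average(p, nb)
    want <- oracle_radial_average(p, nb)
    expect_equal(as.numeric(got), want, tolerance = 1e-12)
  }

  # constant plane: every nonempty bin equals the constant
  ra <- radial_average(matrix(3, 9, 9), 4)
  expect_true(all(ra[!is.na(ra)] == 3))

  # single nonzero pixel: only its radial bin is nonzero
  p <- matrix(0, 9, 9); p[5, 8] <- 10   # offset (0, 3)/9 -> r = 1/3
  ra <- radial_average(p, 4)
  hot <- findInterval(1 / 3, seq(0, 0.5, length.out = 5), rightmost.closed = TRUE)
  expect_true(ra[hot] > 0)
  expect_true(all(ra[-hot] == 0, na.rm = TRUE))

  # count-weighted means conserve total mass
  p <- matrix(rexp(15 * 15), 15)
  ra <- radial_average(p, 7)
  counts <- attr(ra, "counts")
  fr <- (1:15 - 8) / 15
  inside <- sqrt(outer(fr^2, fr^2, "+")) <= 0.5
  expect_equal(sum(ra * counts, na.rm = TRUE), sum(p[inside]), tolerance = 1e-9)

  expect_error(radial_average(p, 0), "n_bins")
})

test_that("fluctuation_map localizes a traveling wave and kills statics", {
  mask <- make_disk_mask(32, 14)
  static <- opd_video(array(rep(rnorm(32 * 32), 32), c(32, 32, 32)), 500)
  fm <- fluctuation_map(static, mask)
  expect_equal(max(fm$power), 0)

  # traveling wave at an on-bin (q0, omega0)
  kx <- 6L; kt <- 5L
  x <- outer(rep(1, 32), 0:31); tt <- 0:31
  fr <- array(0, c(32, 32, 32))
  for (s in seq_len(32)) {
    fr[, , s] <- 4 * cos(2 * pi * kx * x / 32 - 2 * pi * kt * tt[s] / 32)
  }
  wave <- opd_video(fr, frame_rate_hz = 500)
  fm <- fluctuation_map(wave, mask)
  peak <- which(fm$power == max(fm$power), arr.ind = TRUE)
  expect_equal(fm$omega_axis_hz[peak[1]], kt * 500 / 32)
  qbin <- findInterval(kx / 32, seq(0, 0.5, length.out = 17),
                       rightmost.closed = TRUE)
  expect_equal(fm$q_axis[peak[2]], (qbin - 0.5) * 0.5 / 16)
  others <- fm$power
  others[peak[1], peak[2]] <- NA
  expect_gt(max(fm$power), 10 * max(others, na.rm = TRUE))
})

test_that("fluctuation_map is offset-invariant and scales quadratically", {
  set.seed(11)
  mask <- make_disk_mask(16, 6.5)
  fr <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  v <- opd_video(fr, 500)
  fm <- fluctuation_map(v, mask)

  offset <- matrix(rnorm(16 * 16), 16, 16)
  v2 <- opd_video(fr + as.vector(offset), 500)
  fm2 <- fluctuation_map(v2, mask)
  expect_equal(fm2$power, fm$power, tolerance = 1e-9)

  v3 <- opd_video(3 * fr, 500)
  fm3 <- fluctuation_map(v3, mask)
  expect_equal(fm3$power, 9 * fm$power, tolerance = 1e-9)

  expect_error(fluctuation_map(opd_video(fr[, , 1:2], 500), mask), "at least 4")
})

test_that("white-noise videos give a flat bin-averaged spectrum", {
  mask <- make_disk_mask(16, 6.5)
  set.seed(13)
  acc <- 0
  n_rep <- 200
  for (i in seq_len(n_rep)) {
    v <- opd_video(array(rnorm(16 * 16 * 16), c(16, 16, 16)), 100)
    acc <- acc + fluctuation_map(v, mask)$power
  }
  avg <- acc / n_rep
  counts <- attr(radial_average(matrix(1, 16, 16), 8), "counts")
  counts <- counts[counts > 0]
  mu <- mean(avg)
  # spectral power per cell is exponential-like (relative sd 1); averaging
  # over pixels-in-bin, omega rows and repetitions gives the standard error
  flat_q <- colMeans(avg) / mu - 1
  se_q <- 1 / sqrt(counts * nrow(avg) * n_rep)
  expect_true(all(abs(flat_q) < 3 * se_q + 1e-3))
  flat_w <- rowMeans(avg) / mu - 1
  # unweighted mean over q bins: small-count bins dominate the variance
  se_w <- sqrt(sum(1 / counts) / n_rep) / length(counts)
  expect_true(all(abs(flat_w) < 3 * se_w + 1e-3))
})

test_that("normalized fluctuation maps are unit-range and resized", {
  d <- cached_small_dataset()
  f <- d$fluct[[1]]
  expect_equal(dim(f), c(32L, 32L))
  expect_gte(min(f), 0); expect_lte(max(f), 1)
})

test_that("fluctuation map CSV round trip preserves content", {
  mask <- make_disk_mask(16, 6.5)
  set.seed(3)
  v <- opd_video(array(rnorm(16 * 16 * 8), c(16, 16, 8)), 250)
  fm <- fluctuation_map(v, mask)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluctuation_map(fm, path)
  r <- read_fluctuation_map(path)
  expect_equal(r$power, fm$power, tolerance = 1e-6)
  expect_equal(r$omega_axis_hz, fm$omega_axis_hz)
  expect_equal(r$q_axis, fm$q_axis, tolerance = 1e-9)
})
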