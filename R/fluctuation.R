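#' Temporal standard-deviation map
#'
#' Per-pixel sample standard deviation of the OPD over time inside the mask
#' (zero outside): a map of local membrane-fluctuation strength.
#'
#' @param video an [opd_video()] with at least 2 frames.
#' @param mask a [cell_mask()] matching the frame dimensions.
#' @return a `temporal_std_map`: a numeric matrix (nm) with the mask attached.
#' @export
temporal_std_map <- function(video, mask) {
  stopifnot(inherits(video, "opd_video"), inherits(mask, "cell_mask"))
  d <- dim(video$frames)
  if (!identical(d[1:2], dim(mask$pixels))) {
    abort("mask and video frame dimensions differ")
  }
  x <- matrix(video$frames, ncol = d[3])           # pixels x time
  mu <- rowMeans(x)
  s <- sqrt(pmax(0, rowSums((x - mu)^2) / (d[3] - 1)))
  out <- matrix(s, d[1], d[2]) * mask$pixels
  structure(out, mask = mask, class = c("temporal_std_map", "matrix", "array"))
}

#' Radially averaged power spectrum
#'
#' Averages a centred 2D power plane over annular spatial-frequency bins of
#' equal width spanning 0 to the Nyquist frequency (0.5 cycles/pixel).
#' Corner pixels beyond Nyquist are excluded; bins containing no pixels are
#' returned as `NA`.
#'
#' @param power2d non-negative numeric matrix with the zero-frequency bin at
#'   the centre (apply an fftshift first).
#' @param n_bins number of annular bins (default `floor(min(dim)/2)`).
#' @return numeric vector of per-bin means with attributes `centers`
#'   (bin-centre frequency, cycles/pixel) and `counts` (pixels per bin).
#' @export
radial_average <- function(power2d, n_bins = floor(min(dim(power2d)) / 2)) {
  stopifnot(is.matrix(power2d))
  if (!is_scalar_number(n_bins) || n_bins < 1) abort("`n_bins` must be >= 1")
  n_bins <- as.integer(n_bins)
  assert_finite(power2d)
  m <- nrow(power2d); n <- ncol(power2d)
  fr <- (seq_len(m) - (floor(m / 2) + 1)) / m      # cycles/pixel after fftshift
  fc <- (seq_len(n) - (floor(n / 2) + 1)) / n
  r <- sqrt(outer(fr^2, fc^2, "+"))
  edges <- seq(0, 0.5, length.out = n_bins + 1)
  keep <- r <= 0.5
  bin <- findInterval(r[keep], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  sums <- rep(0, n_bins)
  agg <- rowsum(power2d[keep], group = bin)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  out <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  attr(out, "centers") <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  attr(out, "counts") <- counts
  out
}

#' Spatio-temporal fluctuation map of an OPD video
#'
#' The single image summarizing a cell's membrane dynamics: the video is
#' masked, the temporal mean frame is subtracted, a 3D DFT over (t, y, x) is
#' taken, and for each positive temporal frequency omega up to Nyquist the
#' squared-magnitude spatial plane is radially averaged over spatial-frequency
#' annuli q ([radial_average()]). Rows are ordered by increasing omega; the
#' omega = 0 plane (identically zero after mean subtraction) is excluded and
#' negative temporal frequencies are folded onto positive ones by the
#' conjugate symmetry of the real-valued input.
#'
#' An internal Parseval check asserts that the total 3D spectral power equals
#' `N * sum(signal^2)` before any averaging.
#'
#' @param video an [opd_video()] with at least 4 frames.
#' @param mask a [cell_mask()]; built from the first frame via [build_mask()]
#'   when omitted.
#' @param n_bins number of spatial-frequency bins
#'   (default `floor(min(H, W)/2)`).
#' @return a `fluctuation_map`: list with `power` (omega x q matrix, nm^2
#'   units per DFT bin), `omega_axis_hz`, `q_axis` (cycles/pixel),
#'   `frame_rate_hz`, `n_frames`.
#' @export
fluctuation_map <- function(video, mask = NULL,
                            n_bins = floor(min(dim(video)[1:2]) / 2)) {
  stopifnot(inherits(video, "opd_video"))
  d <- dim(video$frames)
  if (d[3] < 4) abort("fluctuation analysis needs at least 4 frames")
  if (is.null(mask)) mask <- build_mask(video$frames[, , 1])
  masked <- apply_mask(video, mask)
  x <- matrix(masked$frames, ncol = d[3])
  x <- x - rowMeans(x)                              # subtract the mean frame
  arr <- array(x, d)
  spec <- fft(arr)
  pow <- Re(spec * Conj(spec))

  # Parseval bookkeeping: total spectral power == N * sum(signal^2)
  total_signal <- sum(x^2)
  n_tot <- prod(d)
  if (total_signal > 0) {
    rel <- abs(sum(pow) - n_tot * total_signal) / (n_tot * total_signal)
    if (rel > 1e-6) {
      abort(sprintf("internal Parseval check failed (relative error %.2e)", rel))
    }
  }

  n_omega <- floor(d[3] / 2)
  rows <- vector("list", n_omega)
  for (k in seq_len(n_omega)) {
    plane <- fft_shift2(pow[, , k + 1])
    mirror <- d[3] - k + 1                          # conjugate plane at -omega
    if (mirror != k + 1) plane <- (plane + fft_shift2(pow[, , mirror])) / 2
    rows[[k]] <- radial_average(plane, n_bins)
  }
  power <- do.call(rbind, rows)
  centers <- attr(rows[[1]], "centers")
  nonempty <- colSums(!is.na(power)) > 0
  structure(list(power = power[, nonempty, drop = FALSE],
                 omega_axis_hz = seq_len(n_omega) * video$frame_rate_hz / d[3],
                 q_axis = centers[nonempty],
                 frame_rate_hz = video$frame_rate_hz, n_frames = d[3]),
            class = "fluctuation_map")
}

#' @export
print.fluctuation_map <- function(x, ...) {
  cat(sprintf("<fluctuation_map> %d omega bins (%.2f-%.1f Hz) x %d q bins (cycles/px)\n",
              nrow(x$power), x$omega_axis_hz[1], max(x$omega_axis_hz),
              ncol(x$power)))
  invisible(x)
}

#' Classifier-ready rendering of a fluctuation map
#'
#' Power spectral densities span several decades, so the map fed to the
#' network is `log10(power + eps)` with `eps = 1e-12 * max(power)`, min-max
#' normalized to `[0, 1]` per map, and resized to the common network input
#' size.
#'
#' @param fmap a [fluctuation_map()].
#' @param size output side length in pixels (default 32).
#' @return numeric `size x size` matrix in `[0, 1]`.
#' @export
normalize_fluctuation_map <- function(fmap, size = 32L) {
  stopifnot(inherits(fmap, "fluctuation_map"))
  p <- fmap$power
  eps <- 1e-12 * max(p)
  if (eps <= 0) eps <- 1e-300
  resize_map(minmax(log10(p + eps)), size, size)
}

#' Estimate the spatial power-law exponent of a fluctuation map
#'
#' Fits `log(power) ~ log(q)` by least squares over a band of spatial
#' frequencies, after averaging the map over a band of temporal frequencies.
#' The default q band is the central decade of the available axis (5% to 50%
#' of Nyquist), which avoids both the low-q smearing from the finite analysis
#' disk and the high-q bins where detection noise dominates; the default
#' omega band is the lower quarter of the axis, where the colored signal is
#' strongest.
#'
#' @param fmap a [fluctuation_map()].
#' @param q_range length-2 numeric, q band (cycles/pixel).
#' @param omega_range length-2 numeric, omega band (Hz); default the lower
#'   quarter of the axis.
#' @return the estimated exponent `a` of `power ~ q^(-a)` (positive for
#'   decaying spectra).
#' @export
estimate_spatial_exponent <- function(fmap, q_range = c(0.025, 0.25),
                                      omega_range = NULL) {
  stopifnot(inherits(fmap, "fluctuation_map"))
  if (is.null(omega_range)) {
    omega_range <- c(min(fmap$omega_axis_hz), stats::quantile(fmap$omega_axis_hz, 0.25))
  }
  rows <- fmap$omega_axis_hz >= omega_range[1] & fmap$omega_axis_hz <= omega_range[2]
  cols <- fmap$q_axis >= q_range[1] & fmap$q_axis <= q_range[2]
  if (sum(rows) < 1 || sum(cols) < 3) abort("not enough bins in the requested band")
  p <- colMeans(fmap$power[rows, cols, drop = FALSE])
  q <- fmap$q_axis[cols]
  ok <- is.finite(p) & p > 0
  fit <- stats::lm.fit(cbind(1, log(q[ok])), log(p[ok]))
  -unname(fit$coefficients[2])
}

#' Tidy a fluctuation map into a long tibble
#'
#' @param x a [fluctuation_map()].
#' @param ... unused.
#' @return a tibble with columns `omega_hz`, `q_cyc_px`, `power`.
#' @export
tidy.fluctuation_map <- function(x, ...) {
  tibble::tibble(
    omega_hz = rep(x$omega_axis_hz, times = ncol(x$power)),
    q_cyc_px = rep(x$q_axis, each = nrow(x$power)),
    power = as.vector(x$power)
  )
}

#' Plot a fluctuation map
#'
#' Renders the radially averaged power spectral density as a raster with
#' spatial frequency q on the horizontal axis, temporal frequency omega on
#' the vertical axis, and log10 power as fill.
#'
#' @param object a [fluctuation_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fluctuation_map <- function(object, ...) {
  df <- tidy.fluctuation_map(object)
  eps <- 1e-12 * max(df$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q_cyc_px, y = .data$omega_hz,
                                   fill = log10(.data$power + eps))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(log[10] ~ PSD)) +
    ggplot2::labs(x = "spatial frequency q (cycles/pixel)",
                  y = expression(omega ~ "(Hz)"),
                  title = "Spatio-temporal fluctuation map")
}
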