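#' Off-axis hologram
#'
#' A camera intensity image carrying the sample field on a tilted-reference
#' carrier: the spatial spectrum has a DC (self-interference) term plus two
#' cross-correlation lobes at +/- the carrier frequency; cropping one lobe
#' retrieves the complex field in a single shot.
#'
#' @param intensity non-negative numeric matrix (camera counts).
#' @param carrier_freq length-2 numeric, carrier spatial frequency in
#'   cycles/pixel along (rows, columns); each component must satisfy
#'   `0 < |f| < 0.5` in magnitude overall and stay below Nyquist per axis.
#' @param wavelength_nm central illumination wavelength (nm).
#' @return a `hologram` object.
#' @export
hologram <- function(intensity, carrier_freq, wavelength_nm) {
  stopifnot(is.matrix(intensity))
  assert_finite(intensity)
  if (any(intensity < 0)) abort("hologram intensity must be non-negative")
  carrier_freq <- as.numeric(carrier_freq)
  if (length(carrier_freq) != 2L || !all(is.finite(carrier_freq))) {
    abort("`carrier_freq` must be two finite numbers (cycles/pixel)")
  }
  if (sqrt(sum(carrier_freq^2)) <= 0 || any(abs(carrier_freq) >= 0.5)) {
    abort("carrier frequency must be > 0 and below Nyquist (|f| < 0.5 cycles/pixel)")
  }
  if (!is_scalar_number(wavelength_nm) || wavelength_nm <= 0) {
    abort("`wavelength_nm` must be a positive number")
  }
  structure(list(intensity = intensity, carrier_freq = carrier_freq,
                 wavelength_nm = wavelength_nm), class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, carrier (%.3f, %.3f) cyc/px, lambda %.1f nm\n",
              nrow(x$intensity), ncol(x$intensity),
              x$carrier_freq[1], x$carrier_freq[2], x$wavelength_nm))
  invisible(x)
}

wrap_angle <- function(x) (x + pi) %% (2 * pi) - pi

#' Two-dimensional phase unwrapping
#'
#' Least-squares unwrapping: the wrapped phase gradients are integrated by
#' solving the discrete Poisson equation under Neumann boundary conditions
#' (DCT-equivalent, via a mirror-extended FFT), then the solution is snapped
#' back so that every pixel is congruent to the input modulo 2*pi. For phase
#' maps whose true gradient magnitude stays below pi per pixel the result is
#' the true phase up to a global additive multiple of 2*pi.
#'
#' @param wrapped numeric matrix of wrapped phase values in `(-pi, pi]`.
#' @return numeric matrix, unwrapped phase (radians).
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped))
  assert_finite(wrapped)
  m <- nrow(wrapped); n <- ncol(wrapped)
  if (m < 2 || n < 2) return(wrapped)

  dy <- wrap_angle(wrapped[-1, , drop = FALSE] - wrapped[-m, , drop = FALSE])
  dx <- wrap_angle(wrapped[, -1, drop = FALSE] - wrapped[, -n, drop = FALSE])
  rho <- matrix(0, m, n)
  rho[-m, ] <- rho[-m, ] + dy
  rho[-1, ] <- rho[-1, ] - dy
  rho[, -n] <- rho[, -n] + dx
  rho[, -1] <- rho[, -1] - dx

  # Neumann Poisson solve via even (half-sample) mirror extension + FFT
  re <- rbind(cbind(rho, rho[, n:1]), cbind(rho[m:1, ], rho[m:1, n:1]))
  denom <- outer(2 * cos(pi * (0:(2 * m - 1)) / m),
                 2 * cos(pi * (0:(2 * n - 1)) / n), "+") - 4
  denom[1, 1] <- 1
  ph <- fft(re) / denom
  ph[1, 1] <- 0
  phi <- Re(fft(ph, inverse = TRUE)) / (4 * m * n)
  phi <- phi[seq_len(m), seq_len(n)]

  # restore congruence mod 2*pi; pin the free constant at a reference pixel
  # (so clean inputs round exactly), then centre the wrapped residuals
  ref <- c(floor(m / 2) + 1, floor(n / 2) + 1)
  phi <- phi - (phi[ref[1], ref[2]] - wrapped[ref[1], ref[2]])
  d <- phi - wrapped
  resid <- d - 2 * pi * round(d / (2 * pi))
  phi <- phi - mean(resid)
  wrapped + 2 * pi * round((phi - wrapped) / (2 * pi))
}

# circular shift so that FFT bin `at` (0-based, per axis) moves to bin 0
fft_recenter <- function(x, at) {
  m <- nrow(x); n <- ncol(x)
  x[((seq_len(m) - 1 + at[1]) %% m) + 1, ((seq_len(n) - 1 + at[2]) %% n) + 1]
}

# centre the zero-frequency bin of a 2D spectrum (fftshift)
fft_shift2 <- function(x) {
  m <- nrow(x); n <- ncol(x)
  x[c((floor(m / 2) + 1):m, 1:floor(m / 2)), c((floor(n / 2) + 1):n, 1:floor(n / 2))]
}

#' Reconstruct an OPD map from an off-axis hologram
#'
#' Fourier transforms the hologram, crops a disk around the cross-correlation
#' lobe at the carrier frequency, recentres the lobe to DC, inverse transforms,
#' unwraps the phase argument ([unwrap_phase()]) and divides by `2*pi/lambda`
#' to obtain optical path delay in nm. The piston term is removed by
#' subtracting the mean OPD over the background (pixels outside the detected
#' cell support); the map is therefore background-referenced to 0 nm.
#'
#' @param holo a [hologram()].
#' @param crop_radius crop radius in cycles/pixel; default half the distance
#'   from the carrier peak to DC, capped at the margin to the Nyquist edge.
#' @param support_frac threshold (fraction of the max deviation from the
#'   median) used to detect the cell support for background referencing.
#' @return an [opd_map()] in nm.
#' @export
reconstruct_opd <- function(holo, crop_radius = NULL, support_frac = 0.2) {
  stopifnot(inherits(holo, "hologram"))
  m <- nrow(holo$intensity); n <- ncol(holo$intensity)
  fc <- holo$carrier_freq
  dist_dc <- sqrt(sum(fc^2))
  nyq_margin <- 0.5 - max(abs(fc))
  if (is.null(crop_radius)) crop_radius <- min(dist_dc / 2, nyq_margin)
  if (!is_scalar_number(crop_radius) || crop_radius <= 0) {
    abort("`crop_radius` must be a positive number (cycles/pixel)")
  }
  if (crop_radius >= dist_dc) {
    abort(sprintf(paste0("cross-correlation lobe overlaps the DC term: crop radius ",
                         "%.3f cyc/px >= carrier offset %.3f cyc/px; increase the ",
                         "carrier frequency or reduce the crop radius"),
                  crop_radius, dist_dc))
  }
  if (crop_radius * min(m, n) < 2) {
    abort("crop radius below 2 frequency bins: carrier too small for this image size")
  }

  spec <- fft(holo$intensity)
  # wrapped frequency coordinates of each bin, cycles/pixel
  fr <- ((seq_len(m) - 1) / m + 0.5) %% 1 - 0.5
  fcl <- ((seq_len(n) - 1) / n + 0.5) %% 1 - 0.5
  d2 <- outer((fr - fc[1])^2, rep(1, n)) + outer(rep(1, m), (fcl - fc[2])^2)
  # distances must wrap around Nyquist as well
  d2 <- pmin(d2,
             outer((fr - fc[1] + 1)^2, rep(1, n)) + outer(rep(1, m), (fcl - fc[2])^2),
             outer((fr - fc[1] - 1)^2, rep(1, n)) + outer(rep(1, m), (fcl - fc[2])^2),
             outer((fr - fc[1])^2, rep(1, n)) + outer(rep(1, m), (fcl - fc[2] + 1)^2),
             outer((fr - fc[1])^2, rep(1, n)) + outer(rep(1, m), (fcl - fc[2] - 1)^2))
  spec[d2 > crop_radius^2] <- 0

  peak <- c(round(fc[1] * m) %% m, round(fc[2] * n) %% n)
  field <- fft(fft_recenter(spec, peak), inverse = TRUE) / (m * n)
  phase <- unwrap_phase(wrap_angle(Arg(field)))
  opd <- phase * holo$wavelength_nm / (2 * pi)

  # piston removal referenced to the background outside the cell support;
  # the background level is its median, which ignores skirt pixels of the
  # cell that leak into the low-deviation set
  dev <- abs(opd - stats::median(opd))
  bg <- dev <= support_frac * max(dev)
  if (sum(bg) < 16) bg <- rep(TRUE, length(opd))
  opd_map(matrix(opd - stats::median(opd[bg]), m, n))
}

#' Simulate an off-axis hologram from an OPD map
#'
#' Synthesizes the interferogram `1 + visibility * cos(2*pi*carrier.r + phi)`
#' with `phi = 2*pi*opd/lambda`; the round trip through [reconstruct_opd()]
#' recovers the OPD map and serves as the reconstruction oracle.
#'
#' @param opd an [opd_map()] or numeric matrix (nm).
#' @param carrier_freq length-2 carrier frequency, cycles/pixel (rows, cols).
#' @param wavelength_nm illumination wavelength (nm), default 633.
#' @param visibility fringe visibility in `(0, 1]`.
#' @return a [hologram()].
#' @export
simulate_hologram <- function(opd, carrier_freq = c(0, 0.25),
                              wavelength_nm = 633, visibility = 0.9) {
  if (inherits(opd, "opd_map")) opd <- unclass(opd)
  stopifnot(is.matrix(opd))
  assert_finite(opd)
  if (!is_scalar_number(visibility) || visibility <= 0 || visibility > 1) {
    abort("`visibility` must be in (0, 1]")
  }
  m <- nrow(opd); n <- ncol(opd)
  phi <- 2 * pi * opd / wavelength_nm
  carrier_phase <- 2 * pi * (outer((seq_len(m) - 1) * carrier_freq[1],
                                   (seq_len(n) - 1) * carrier_freq[2], "+"))
  intensity <- 1 + visibility * cos(carrier_phase + phi)
  hologram(intensity, carrier_freq, wavelength_nm)
}
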