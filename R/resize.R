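# Separable linear-kernel resampling.
#
# One 1-D operator per axis: each output pixel is a normalized triangle-kernel
# average of input pixels, with the kernel widened by the downscale factor so
# that shrinking acts as an area-weighted average (antialiased bilinear).
# Rows sum to 1, so constants are preserved exactly and the image mean is
# preserved to well under 1% for typical downscales.

resize_operator <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  if (n_in == n_out) return(diag(n_out))
  scale <- n_out / n_in
  kw <- min(1, scale)            # kernel width scale (widen when downscaling)
  support <- 1 / kw
  op <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    centre <- (i - 0.5) / scale + 0.5   # input coordinate of output pixel i
    j0 <- max(1L, floor(centre - support))
    j1 <- min(n_in, ceiling(centre + support))
    j <- j0:j1
    w <- pmax(0, 1 - abs((j - centre) * kw))
    if (sum(w) == 0) {                  # degenerate: nearest neighbour
      j <- max(1L, min(n_in, round(centre)))
      w <- 1
    }
    op[i, j] <- w / sum(w)
  }
  op
}

#' Resize a 2D map with antialiased bilinear interpolation
#'
#' Separable triangle-kernel resampling; when downscaling, the kernel is
#' widened by the scale factor so values are area-weighted averages.
#' Constant images are preserved exactly.
#'
#' @param x numeric matrix.
#' @param out_h,out_w output dimensions (rows, columns).
#' @return numeric matrix of dimension `out_h` x `out_w`.
#' @export
resize_map <- function(x, out_h, out_w = out_h) {
  stopifnot(is.matrix(x), out_h >= 1, out_w >= 1)
  assert_finite(x)
  ry <- resize_operator(nrow(x), out_h)
  rx <- resize_operator(ncol(x), out_w)
  ry %*% x %*% t(rx)
}
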