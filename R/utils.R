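#' @importFrom rlang abort warn %||%
#' @importFrom stats fft rnorm runif sd t.test wilcox.test var
#' @importFrom Rcpp evalCpp
#' @import tibble
#' @useDynLib phasefluct, .registration = TRUE
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic entry points route through this so
# identical seeds give bitwise-identical results without disturbing the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` must contain only finite values", name))
  }
  invisible(x)
}

# min-max normalization to [0, 1]; constant input maps to all zeros
minmax <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) {
    array(0, dim = dim(x) %||% length(x))
  } else {
    (x - r[1]) / (r[2] - r[1])
  }
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
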