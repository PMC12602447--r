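#' @importFrom rlang abort warn %||% .data
#' @importFrom stats fft sd median mad quantile lm residuals shapiro.test
#'   t.test wilcox.test p.adjust rnorm runif rpois
NULL

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation helpers do not disturb the global stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Hanning (raised-cosine) taper of length n, periodic convention.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

# Half-open interval membership: x in [lo, hi)
in_window <- function(x, lo, hi) x >= lo & x < hi

# id of the 1-based epoch covering time t for unit epochs starting at 0
stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
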