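#' @keywords internal
"_PACKAGE"

#' @useDynLib reverbdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm runif rbinom fft qt sd var cor lm coef convolve
#' @importFrom utils head tail
NULL

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7907 * as.numeric(k)) %% 2147483647L)
}

rms <- function(x) sqrt(mean(x^2))

db <- function(x, floor_db = -300) {
  out <- 20 * log10(pmax(abs(x), 10^(floor_db / 20)))
  out
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar", name))
  }
}
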