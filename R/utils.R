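#' @keywords internal
"_PACKAGE"

#' @importFrom methods as is
#' @importFrom stats runif rbinom predict coef residuals simulate setNames
#' @importFrom utils head read.csv write.csv
NULL

relu <- function(x) x * (x > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Derive a child RNG seed from a master seed; keeps results inside 32-bit
# integer range so seeds survive as.integer().
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 9973) %% 2147483647L)
}

# Evaluate expr with a local RNG state seeded by `seed`, restoring the caller's
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
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
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ccg <- function(...) stop(..., call. = FALSE)
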