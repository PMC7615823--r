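#' @importFrom stats fft median rnorm runif rpois sd var pchisq pt qt
#' @importFrom utils head tail
NULL

# Run code with a temporarily seeded RNG, restoring global RNG state after.
# All stochastic functions in the package route through this so that a given
# seed yields bitwise-identical output regardless of the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

# Derive a stream-specific child seed from a user seed. Kept below 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 1299721) %% 2147483647
}

stop_validation <- function(...) {
  stop(structure(class = c("hpdlfp_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_range <- function(...) {
  stop(structure(class = c("hpdlfp_range_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("hpdlfp_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
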