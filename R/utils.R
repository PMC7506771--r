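# Internal helpers: classed error conditions and seeded RNG scoping.

abort_rehabsig <- function(message, class) {
  stop(structure(
    class = c(paste0("rehabsig_", class), "rehabsig_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_invalid_parameter <- function(msg) abort_rehabsig(msg, "invalid_parameter")
stop_invalid_input     <- function(msg) abort_rehabsig(msg, "invalid_input")
stop_insufficient_data <- function(msg) abort_rehabsig(msg, "insufficient_data")
stop_format_error      <- function(msg) abort_rehabsig(msg, "format_error")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. All generator randomness goes through this; no
# package function leaves .Random.seed altered when given an explicit seed.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid_parameter("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
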