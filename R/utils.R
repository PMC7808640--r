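# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  All user-facing determinism contracts go through
# this so that library code never perturbs the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a classed condition so tests can assert on error type rather
# than message wording
abort_taafgex <- function(message, class) {
  stop(structure(
    class = c(class, "taafgex_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_dimension <- function(msg) abort_taafgex(msg, "taafgex_dimension_error")
stop_argument  <- function(msg) abort_taafgex(msg, "taafgex_argument_error")
stop_schema    <- function(msg) abort_taafgex(msg, "taafgex_schema_error")
stop_format    <- function(msg) abort_taafgex(msg, "taafgex_format_error")
stop_infeasible <- function(msg) abort_taafgex(msg, "taafgex_infeasibility_error")
stop_degenerate <- function(msg) abort_taafgex(msg, "taafgex_degenerate_scale_error")
stop_divergence <- function(msg) abort_taafgex(msg, "taafgex_divergence_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
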