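# Small shared utilities.

# Set the RNG to a known state, returning the previous state so callers can
# restore it (keeps seeded package functions from disturbing the caller's RNG
# stream when a seed is supplied).
local_seed <- function(seed) {
  force(seed)  # the argument may itself consume the caller's RNG stream
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
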