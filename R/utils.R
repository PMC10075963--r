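# internal helpers

# Set the RNG seed, returning the previous .Random.seed so callers can
# restore it; keeps exported functions deterministic-by-seed without
# clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
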