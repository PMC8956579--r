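# RNG scoping: functions that take an explicit `seed` argument must not
# disturb the caller's random stream.  local_rng() saves the current
# .Random.seed and seeds the stream; restore_rng() puts it back.
local_rng <- function(seed) {
  saved <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  set.seed(seed)
  saved
}

restore_rng <- function(saved) {
  if (is.null(saved)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", saved, envir = globalenv())
  }
  invisible(NULL)
}

# Dimension of a vector-field closure, probed by trial evaluation.
probe_dim <- function(f) {
  for (d in 2:3) {
    ok <- tryCatch(length(f(rep(0.1, d))) == d, error = function(e) FALSE)
    if (isTRUE(ok)) return(d)
  }
  stop_input("could not determine system dimension; pass a dim x 2 'box' matrix")
}
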