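# Seed plumbing: every stochastic stage runs inside local_seed() so global
# RNG state is never consumed, and sub-seeds are derived deterministically
# and kept inside the 32-bit integer range.

local_seed <- function(seed, expr) {
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
  expr
}

derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 10007 + 7919 * as.numeric(index)) %% 2147483629L)
}
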