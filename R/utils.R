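#' @importFrom rlang %||% .data
NULL

# run code under a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# derive a stream-specific child seed, kept within 32-bit integer range
.child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset) %% 2147483647
}
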