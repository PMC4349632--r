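# Small internal helpers.

# Save/restore the global RNG state so seeded subroutines do not disturb
# the caller's random stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Derive a stream seed from a master seed and an index, kept inside the
# 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + as.numeric(index) * 7919) %%
               .Machine$integer.max)
}
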