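# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a master seed, kept inside 32-bit range.
child_seed <- function(master, i) {
  (as.numeric(master) + 7919 * as.numeric(i)) %% 2147483647
}

is_missing_cell <- function(x) is.na(x) | (is.character(x) & trimws(x) == "")
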