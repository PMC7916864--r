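# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so package functions never clobber it.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Deterministic child seeds (< 2^31) so one user seed drives several stages.
derive_seed <- function(seed, k) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647
}
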