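# Run expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs expr with the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific 31-bit sub-seed so that independent pieces of a
# simulation (design, pRFs, noise per run, ...) do not share streams.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset * 97) %% 2147483647L)
}
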