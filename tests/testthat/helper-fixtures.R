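# Small, fast generator configurations shared across tests.

# A lean subject: fewer columns, fewer runs, no retinotopy runs.
fastConfig <- function(...) {
  args <- utils::modifyList(list(nColumns = 10, nRuns = 4,
                                 retinotopy = FALSE), list(...))
  do.call(subjectConfig, args)
}

# Strong-signal, near-noiseless settings for exactness checks.
cleanConfig <- function(...) {
  fastConfig(noiseSd = 1e-8, ...)
}

# Build a BetaMatrix directly from patterns: `means` is a named list
# condition -> voxel vector; red trials get +v, green trials -v, plus
# N(0, noise) jitter. Each run holds 3 red and 3 green trials per
# condition.
patternBetas <- function(means, nRuns = 4, noise = 0.05, seed = 1) {
  nv <- length(means[[1]])
  set.seed(seed)
  vals <- NULL
  labs <- NULL
  for (r in seq_len(nRuns)) {
    for (cond in names(means)) {
      for (col in c("red", "green")) {
        sgn <- if (col == "red") 1 else -1
        block <- matrix(sgn * means[[cond]], nrow = 3, ncol = nv,
                        byrow = TRUE) + matrix(rnorm(3 * nv, 0, noise), 3)
        vals <- rbind(vals, block)
        labs <- rbind(labs, data.frame(run = r, condition = cond,
                                       colour = col, onset = 0)[rep(1, 3), ])
      }
    }
  }
  rownames(labs) <- NULL
  new("BetaMatrix", values = vals, labels = labs)
}
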