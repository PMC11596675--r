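# Brute-force isotopologue oracle: enumerates every isotope placement over
# the individual atoms (feasible for formulas of a few atoms) and sums the
# exact placement probabilities by total nominal mass shift. Shares only the
# abundance constants with the implementation, not the convolution code.
brute_force_isotopes <- function(counts, max_shift = 6L) {
  iso <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = c(1)
  )
  atoms <- rep(names(counts), counts)
  opts <- lapply(atoms, function(el) seq_along(iso[[el]]) - 1L)
  grid <- do.call(expand.grid, c(opts, KEEP.OUT.ATTRS = FALSE))
  probs <- rep(1, nrow(grid))
  for (j in seq_along(atoms)) {
    probs <- probs * iso[[atoms[j]]][grid[[j]] + 1L]
  }
  shift <- if (ncol(grid)) rowSums(grid) else rep(0, nrow(grid))
  out <- numeric(max_shift + 1L)
  for (k in 0:max_shift) out[k + 1L] <- sum(probs[shift == k])
  out
}

# noiseless simulator configuration used by several suites
noiseless_config <- function(...) {
  sim_config(cv_technical = 0, cv_biological = 0, cv_injection = 0, ...)
}
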