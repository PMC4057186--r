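# shared fixtures: small random models and exhaustive state tables

random_pim <- function(L, pairs = NULL, seed = 1, h_sd = 1, j_sd = 0.7) {
  withr::with_seed(seed, {
    if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
    pairs <- matrix(as.integer(pairs), ncol = 2)
    J <- lapply(seq_len(nrow(pairs)), function(k) matrix(rnorm(16, 0, j_sd), 4, 4))
    pim(L, matrix(rnorm(L * 4, 0, h_sd), L, 4), pairs, J)
  })
}

all_states <- function(L) pimotif:::.code_to_mat(seq_len(4^L), L)

# brute-force probabilities over all 4^L states, independent of the
# component-factorized path (plain R sum over the enumerated energies)
brute_probs <- function(params) {
  mat <- all_states(params$L)
  e <- pim_energy(params, mat)
  p <- exp(-e)
  p / sum(p)
}
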