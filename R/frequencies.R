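#' Pseudo-counted single and pairwise nucleotide frequencies
#'
#' Computes `f_i(a) = (n_i(a) + beta1) / (N + 4 beta1)` for every position and
#' `f_ij(a,b) = (n_ij(a,b) + beta2) / (N + 16 beta2)` for every ordered pair
#' i < j. With the default `beta2 = beta1 / 4` the pairwise tables marginalize
#' exactly onto the single-nucleotide table, so the two sets of constraints
#' handed to the maximum-entropy fit are mutually consistent.
#'
#' @param sites A [site_set()].
#' @param beta1 Pseudo-count per single-nucleotide cell (default 1).
#' @param beta2 Pseudo-count per dinucleotide cell (default `beta1 / 4`).
#' @return An object of class `pair_freqs`: list with `L`, `f1` (L x 4),
#'   `f2` (named list of 4 x 4 joints keyed `"i_j"`), `N`, and the
#'   pseudo-counts used.
#' @export
empirical_frequencies <- function(sites, beta1 = 1, beta2 = beta1 / 4) {
  stopifnot(inherits(sites, "site_set"), beta1 >= 0, beta2 >= 0)
  L <- sites$L
  counts <- .letter_counts(sites)
  f1 <- (counts + beta1) / (sites$N + 4 * beta1)
  f2 <- list()
  for (i in seq_len(L - 1)) {
    for (j in seq((i + 1), L)) {
      tab <- pair_counts(sites, i, j)
      f2[[.pair_key(i, j)]] <- (tab + beta2) / (sites$N + 16 * beta2)
    }
  }
  structure(list(L = L, f1 = f1, f2 = f2, N = sites$N,
                 beta1 = beta1, beta2 = beta2),
            class = "pair_freqs")
}

.pair_key <- function(i, j) paste0(i, "_", j)

#' Raw dinucleotide counts for one pair of positions
#'
#' @param sites A [site_set()].
#' @param i,j Positions (1-based, i < j).
#' @return 4 x 4 matrix of multiplicity-weighted counts.
#' @export
pair_counts <- function(sites, i, j) {
  stopifnot(i < j, j <= sites$L)
  tab <- matrix(0, 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  agg <- rowsum(sites$counts, (sites$mat[, i] - 1L) * 4L + sites$mat[, j])
  cell <- as.integer(rownames(agg))
  tab[cbind((cell - 1L) %/% 4L + 1L, (cell - 1L) %% 4L + 1L)] <- agg[, 1]
  tab
}

#' @export
print.pair_freqs <- function(x, ...) {
  cat(sprintf("pair_freqs: L = %d, N = %g (beta1 = %g, beta2 = %g)\n",
              x$L, x$N, x$beta1, x$beta2))
  invisible(x)
}
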