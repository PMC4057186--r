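#' Fix the gauge of a PIM
#'
#' The split of the binding energy between fields and couplings is not
#' unique: probabilities are invariant under constant shifts of the fields
#' and under moving row/column profiles of a coupling block into the fields.
#' `fix_gauge` resolves this by the minimum-square-norm convention: every
#' coupling block is made doubly centered (all row sums and column sums
#' zero), absorbing its row and column means into the fields, and every
#' field row is then centered to sum to zero. All site probabilities are
#' unchanged.
#'
#' @param params A [pim()].
#' @return The gauge-fixed model (`gauge_fixed = TRUE`, `logZ` refreshed if
#'   it was cached).
#' @export
fix_gauge <- function(params) {
  h <- params$h
  J <- params$J
  for (k in seq_len(nrow(params$pairs))) {
    b <- J[[k]]
    rmean <- rowMeans(b)
    cmean <- colMeans(b)
    tot <- mean(b)
    J[[k]] <- b - outer(rmean, rep(1, 4)) - outer(rep(1, 4), cmean) + tot
    i <- params$pairs[k, 1]; j <- params$pairs[k, 2]
    h[i, ] <- h[i, ] + rmean - tot / 2
    h[j, ] <- h[j, ] + cmean - tot / 2
  }
  h <- h - rowMeans(h)
  out <- pim(params$L, h, params$pairs, J, gauge_fixed = TRUE)
  if (!is.null(params$logZ)) out <- cache_logz(out)
  out
}

#' Check the zero-sum gauge conditions
#'
#' @param params A [pim()].
#' @param tol Tolerance on the zero sums.
#' @return `TRUE` if every field row sums to zero and every coupling block
#'   has zero row and column sums, within `tol`.
#' @export
is_gauge_fixed <- function(params, tol = 1e-10) {
  if (any(abs(rowSums(params$h)) > tol)) return(FALSE)
  for (b in params$J) {
    if (any(abs(rowSums(b)) > tol) || any(abs(colSums(b)) > tol)) return(FALSE)
  }
  TRUE
}

## Random gauge transformation (tests): shifts fields by per-position
## constants and exchanges row/column profiles between couplings and fields.
## Leaves all probabilities invariant.
.random_gauge_transform <- function(params, seed = NULL) {
  run <- function() {
    h <- params$h
    J <- params$J
    h <- h + runif(params$L, -1, 1)  # per-position constant shift
    for (k in seq_len(nrow(params$pairs))) {
      A <- runif(4, -1, 1)
      B <- runif(4, -1, 1)
      J[[k]] <- J[[k]] + outer(A, rep(1, 4)) + outer(rep(1, 4), B)
      i <- params$pairs[k, 1]; j <- params$pairs[k, 2]
      h[i, ] <- h[i, ] - A
      h[j, ] <- h[j, ] - B
    }
    pim(params$L, h, params$pairs, J)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
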