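#' Position weight matrix
#'
#' An L x 4 matrix of per-position nucleotide probabilities (columns in
#' A,C,G,T order), the independent-positions model of a binding site.
#'
#' @param mat Numeric L x 4 matrix; rows are normalized to sum to one.
#' @param pseudocount Pseudo-count recorded as provenance (attribute
#'   `pseudocount`); does not alter `mat`.
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, pseudocount = NA_real_) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L) stop("a PWM must have 4 columns (A,C,G,T)")
  if (any(mat < 0)) stop("negative probabilities")
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("a PWM row sums to zero")
  mat <- mat / rs
  colnames(mat) <- DNA_ALPHABET
  rownames(mat) <- NULL
  structure(mat, class = c("pwm", "matrix"), pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm: L = %d\n", nrow(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Estimate a PWM from a site sample with pseudo-counts
#'
#' Laplace-style smoothing: `p_i(a) = (n_i(a) + beta) / (N + 4 beta)`, with
#' `n_i(a)` the multiplicity-weighted count of letter `a` at position `i`.
#'
#' @param sites A [site_set()].
#' @param beta Pseudo-count per nucleotide cell (default 1).
#' @return A [pwm()].
#' @export
estimate_pwm <- function(sites, beta = 1) {
  stopifnot(inherits(sites, "site_set"), beta >= 0)
  counts <- .letter_counts(sites)
  pwm((counts + beta) / (sites$N + 4 * beta), pseudocount = beta)
}

## multiplicity-weighted letter counts, L x 4
.letter_counts <- function(sites) {
  L <- sites$L
  counts <- matrix(0, L, 4, dimnames = list(NULL, DNA_ALPHABET))
  for (i in seq_len(L)) {
    tab <- rowsum(sites$counts, sites$mat[, i])
    counts[i, as.integer(rownames(tab))] <- tab[, 1]
  }
  counts
}

#' Probability of sites under a PWM
#'
#' The independent-positions likelihood `prod_i p_i(s_i)`.
#'
#' @param x A [pwm()].
#' @param sites A [site_set()], encoded matrix, or character vector of L-mers.
#' @return Numeric vector of probabilities (one per site / distinct site of a
#'   `site_set`).
#' @export
pwm_probability <- function(x, sites) {
  exp(site_logprob(x, .as_site_mat(sites, nrow(x))))
}

.as_site_mat <- function(sites, L) {
  mat <- if (inherits(sites, "site_set")) sites$mat
         else if (is.matrix(sites)) sites
         else if (is.character(sites)) encode_seq(sites)
         else matrix(as.integer(sites), nrow = 1L)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)
  if (ncol(mat) != L) {
    stop(sprintf("site length %d does not match model length %d", ncol(mat), L))
  }
  mat
}

#' Log-probability of encoded sites under a model
#'
#' Generic over the model classes (`pwm`, `pim`, `pwm_mix`). Natural log.
#'
#' @param model A fitted model object.
#' @param mat Integer matrix of encoded sites (rows).
#' @return Numeric vector of natural-log probabilities.
#' @export
site_logprob <- function(model, mat) UseMethod("site_logprob")

#' @export
site_logprob.pwm <- function(model, mat) {
  mat <- .as_site_mat(mat, nrow(model))
  lp <- log(unclass(model))
  out <- numeric(nrow(mat))
  for (i in seq_len(ncol(mat))) out <- out + lp[i, ][mat[, i]]
  unname(out)
}

#' Per-position entropy of a PWM in bits
#'
#' @param x A [pwm()] (or any L x 4 row-stochastic matrix).
#' @return Numeric vector of length L.
#' @export
pwm_entropy <- function(x) {
  p <- unclass(x)
  apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
}

#' Position information content relative to a background
#'
#' `IC_i = sum_a p_i(a) log2(p_i(a) / q(a))`, the per-position relative
#' entropy against background letter frequencies `q`.
#'
#' @param x A [pwm()].
#' @param background Background nucleotide frequencies (length 4, A,C,G,T);
#'   default uniform.
#' @return Numeric vector of length L, in bits.
#' @export
pwm_information <- function(x, background = rep(0.25, 4)) {
  p <- unclass(x)
  background <- background / sum(background)
  apply(p, 1, function(r) {
    keep <- r > 0
    sum(r[keep] * log2(r[keep] / background[keep]))
  })
}

#' Kullback-Leibler divergence between two PWMs (bits)
#'
#' Sum over positions of the row-wise divergence; for independent-positions
#' models this equals the divergence between the full sequence distributions.
#'
#' @param p,q [pwm()] objects of equal length.
#' @return Divergence in bits.
#' @export
pwm_dkl <- function(p, q) {
  stopifnot(nrow(p) == nrow(q))
  sum(vapply(seq_len(nrow(p)), function(i) {
    dkl(unclass(p)[i, ], unclass(q)[i, ])
  }, numeric(1)))
}
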