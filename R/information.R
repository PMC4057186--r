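#' Kullback-Leibler divergence in bits
#'
#' `sum_x P(x) log2(P(x) / Q(x))` with the convention `0 log 0 = 0`. If P
#' puts mass where Q has none the divergence is `Inf`.
#'
#' @param P,Q Nonnegative vectors (or matrices) on the same support; each is
#'   normalized to sum to one.
#' @return Divergence in bits (possibly `Inf`).
#' @export
dkl <- function(P, Q) {
  P <- as.vector(P); Q <- as.vector(Q)
  stopifnot(length(P) == length(Q), all(P >= 0), all(Q >= 0))
  P <- P / sum(P); Q <- Q / sum(Q)
  on <- P > 0
  if (any(Q[on] == 0)) return(Inf)
  sum(P[on] * log2(P[on] / Q[on]))
}

#' DKL between a site sample and a model (bits)
#'
#' Divergence of the empirical site frequencies from the model distribution,
#' `sum_s fhat(s) log2(fhat(s) / P_model(s))`, over the observed sites.
#'
#' @param sites A [site_set()].
#' @param model A `pwm`, `pim` or `pwm_mix`.
#' @return Divergence in bits.
#' @export
dkl_data_model <- function(sites, model) {
  f <- sites$counts / sites$N
  lp <- site_logprob(model, sites$mat)
  sum(f * (log2(f) - lp / log(2)))
}

#' Finite-sampling control: the self-DKL of a model
#'
#' Draws `reps` independent samples of size N exactly from the model and
#' computes the DKL between each sample's empirical frequencies and the model
#' itself. The mean and standard deviation calibrate how large a data-model
#' DKL is expected from finite sampling alone; an observed DKL above
#' `mean + 2 sd` signals a real model mismatch.
#'
#' @param model A [pim()] (a PWM can be wrapped via `pim(L, h = -log(p))`).
#' @param N Sample size per replicate.
#' @param reps Number of replicates (default 100).
#' @param seed Master seed (replicate seeds derived from it).
#' @return A list with `mean`, `sd` (bits) and `values` (per-replicate DKLs).
#' @export
self_dkl <- function(model, N, reps = 100, seed = NULL) {
  run <- function() {
    vapply(seq_len(reps), function(r) {
      s <- sample_sites(model, N)
      dkl_data_model(s, model)
    }, numeric(1))
  }
  v <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(mean = mean(v), sd = stats::sd(v), values = v)
}

#' Positional entropies in bits
#'
#' @param f1 L x 4 matrix of single-site frequencies.
#' @return Numeric vector of per-position entropies.
#' @export
positional_entropy <- function(f1) {
  apply(f1, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
}

#' Solve the two-site direct model for one coupling block
#'
#' Builds the direct dinucleotide distribution
#' `P_dir(a,b) = exp(-J(a,b) - ht_i(a) - ht_j(b)) / z`, where the effective
#' single-nucleotide energies `ht` are determined by requiring the marginals
#' of `P_dir` to equal the supplied single-site frequencies. The energies are
#' anchored to vanish at T (the last alphabet letter) and the 6 remaining
#' unknowns are solved by Levenberg-Marquardt.
#'
#' @param J_block 4 x 4 coupling block (letter at i in rows, j in columns).
#' @param f_i,f_j Strictly positive single-site frequencies (length 4).
#' @param tol Tolerance on the largest marginal residual (default 1e-10).
#' @param max_iter Solver iteration cap (default 500).
#' @return A list with `P_dir` (4 x 4), `h_i`, `h_j` (anchored energies),
#'   `residual` and `converged`.
#' @export
solve_direct_fields <- function(J_block, f_i, f_j, tol = 1e-10,
                                max_iter = 500) {
  stopifnot(all(f_i > 0), all(f_j > 0))
  f_i <- f_i / sum(f_i); f_j <- f_j / sum(f_j)
  pdir <- function(x) {
    hi <- c(x[1:3], 0)
    hj <- c(x[4:6], 0)
    P <- exp(-J_block - outer(hi, rep(0, 4), "+") -
               outer(rep(0, 4), hj, "+"))
    P / sum(P)
  }
  resid <- function(x) {
    P <- pdir(x)
    c(rowSums(P) - f_i, colSums(P) - f_j)
  }
  sol <- minpack.lm::nls.lm(par = rep(0, 6), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-16, ptol = 1e-16, gtol = 0,
                              maxiter = max_iter))
  P <- pdir(sol$par)
  r <- max(abs(resid(sol$par)))
  if (r > tol) {
    warning(sprintf("direct-field solver residual %.3g above tol %.3g", r,
                    tol))
  }
  list(P_dir = P, h_i = c(sol$par[1:3], 0), h_j = c(sol$par[4:6], 0),
       residual = r, converged = r <= tol)
}

#' Direct information of a solved pair (bits)
#'
#' `DI = sum_ab P_dir(a,b) log2(P_dir(a,b) / (f_i(a) f_j(b)))`: the mutual
#' information of the direct two-site distribution, i.e. the dependence
#' attributable to the direct coupling alone.
#'
#' @param solution Output of [solve_direct_fields()].
#' @param f_i,f_j The single-site frequencies used in the solve.
#' @return DI in bits (>= 0 up to solver tolerance).
#' @export
direct_information <- function(solution, f_i, f_j) {
  f_i <- f_i / sum(f_i); f_j <- f_j / sum(f_j)
  mutual_information(solution$P_dir, f_i, f_j)
}

#' Mutual information of a dinucleotide table (bits)
#'
#' `MI = sum_ab f_ij(a,b) log2(f_ij(a,b) / (f_i(a) f_j(b)))`.
#'
#' @param f_ij 4 x 4 joint frequencies.
#' @param f_i,f_j Marginal frequencies; taken from `f_ij` when omitted.
#' @return MI in bits.
#' @export
mutual_information <- function(f_ij, f_i = rowSums(f_ij),
                               f_j = colSums(f_ij)) {
  f_ij <- f_ij / sum(f_ij)
  prod <- outer(f_i / sum(f_i), f_j / sum(f_j))
  on <- f_ij > 0
  sum(f_ij[on] * log2(f_ij[on] / prod[on]))
}

#' Entropy-normalized information
#'
#' Divides an information value by `min(H_i, H_j)` so that a deterministic
#' copy of a position scores 1 and independence scores 0. When both
#' entropies vanish there is no variability to correlate and the value is 0.
#'
#' @param I Information in bits (DI or MI).
#' @param H_i,H_j Positional entropies in bits.
#' @return Normalized value in `[0, 1]` (up to solver tolerance).
#' @export
normalized_information <- function(I, H_i, H_j) {
  d <- min(H_i, H_j)
  if (d <= 0) return(0)
  I / d
}

#' Direct/mutual information matrices of a PIM
#'
#' For every pair of positions computes the Direct Information implied by the
#' model's coupling block (zero block => DI = 0) with the supplied
#' single-site frequencies, the Mutual Information of the pairwise frequency
#' tables, and their entropy-normalized versions.
#'
#' @param params A fitted [pim()].
#' @param freqs A `pair_freqs` object (typically [empirical_frequencies()] of
#'   the training sites; [model_marginals()] also works).
#' @param tol Solver tolerance for the direct model.
#' @return A list of symmetric L x L matrices `DI`, `NDI`, `MI`, `NMI` with
#'   zero diagonals, plus `H` (positional entropies, bits).
#' @export
info_matrices <- function(params, freqs, tol = 1e-10) {
  L <- params$L
  stopifnot(freqs$L == L)
  H <- positional_entropy(freqs$f1)
  DI <- MI <- NDI <- NMI <- matrix(0, L, L)
  key_active <- character(0)
  if (nrow(params$pairs) > 0) {
    key_active <- .pair_key(params$pairs[, 1], params$pairs[, 2])
  }
  for (i in seq_len(L - 1)) {
    for (j in seq((i + 1), L)) {
      key <- .pair_key(i, j)
      k <- match(key, key_active)
      if (!is.na(k)) {
        sol <- solve_direct_fields(params$J[[k]], freqs$f1[i, ],
                                   freqs$f1[j, ], tol = tol)
        DI[i, j] <- max(0, direct_information(sol, freqs$f1[i, ],
                                              freqs$f1[j, ]))
      }
      MI[i, j] <- max(0, mutual_information(freqs$f2[[key]], freqs$f1[i, ],
                                            freqs$f1[j, ]))
      NDI[i, j] <- normalized_information(DI[i, j], H[i], H[j])
      NMI[i, j] <- normalized_information(MI[i, j], H[i], H[j])
      DI[j, i] <- DI[i, j]; MI[j, i] <- MI[i, j]
      NDI[j, i] <- NDI[i, j]; NMI[j, i] <- NMI[i, j]
    }
  }
  list(DI = DI, NDI = NDI, MI = MI, NMI = NMI, H = H)
}

#' Participation ratio of a pairwise weight matrix
#'
#' `R = (sum w)^2 / (N_pairs * sum w^2)` over the off-diagonal entries, with
#' `N_pairs = L(L-1)` counting both orientations. Uniform weights give 1
#' (every interaction represented); a single interacting pair gives
#' `2 / N_pairs`.
#'
#' @param w Symmetric nonnegative L x L matrix with zero diagonal (e.g. the
#'   squared NDI matrix).
#' @return The participation ratio.
#' @export
participation_ratio <- function(w) {
  L <- nrow(w)
  off <- w[row(w) != col(w)]
  if (all(off == 0)) {
    warning("all weights are zero; participation ratio undefined")
    return(NA_real_)
  }
  sum(off)^2 / (length(off) * sum(off^2))
}

#' Interaction weight per distance
#'
#' Sums the weights over all pairs at separation `d = |i - j|` and divides by
#' the number `L - d` of such pairs (the finite-size correction: random
#' uniform interactions would otherwise over-represent short distances), then
#' normalizes the profile to sum to one.
#'
#' @param w Symmetric L x L weight matrix, zero diagonal.
#' @param L Site length (defaults to `nrow(w)`).
#' @return Named numeric vector over d = 1..L-1, summing to 1.
#' @export
distance_profile <- function(w, L = nrow(w)) {
  d <- abs(row(w) - col(w))
  prof <- vapply(seq_len(L - 1), function(dd) {
    sum(w[d == dd]) / (L - dd)
  }, numeric(1))
  if (sum(prof) > 0) prof <- prof / sum(prof)
  setNames(prof, seq_len(L - 1))
}

#' Per-position interaction totals
#'
#' Row sums of an NDI (or NMI) matrix: the total interaction weight carried
#' by each position. Optionally averaged over the two site orientations
#' (position i with L + 1 - i).
#'
#' @param m Symmetric L x L matrix.
#' @param orientation_average Average position i with its mirror (default
#'   `FALSE`).
#' @return Numeric vector of length L.
#' @export
positional_interaction_sum <- function(m, orientation_average = FALSE) {
  s <- rowSums(m)
  if (orientation_average) s <- (s + rev(s)) / 2
  s
}

#' Write an L x L matrix as a tab-separated table with 1-based headers
#'
#' @param m Matrix to export.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_matrix_tsv <- function(m, path) {
  dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
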