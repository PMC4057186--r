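#' Fit a PIM by marginal-matching gradient descent
#'
#' Finds the maximum-entropy model whose single-nucleotide marginals match
#' the pseudo-counted data frequencies at every position and whose pairwise
#' marginals match the data for the active pairs. Fields are updated by
#' `h <- h - eta * (f_data - f_model)` and active coupling blocks likewise;
#' the exact model marginals are recomputed each sweep by component-wise
#' enumeration. The problem is convex, so the fitted distribution does not
#' depend on the initialization.
#'
#' @param sites A [site_set()].
#' @param active_pairs Integer matrix (or vector of length 2) of coupling
#'   pairs (i, j), i < j; `NULL` for a coupling-free (PWM-equivalent) fit.
#' @param init Optional [pim()] used as a warm start.
#' @param eta Base step size (default 0.1).
#' @param tol Convergence tolerance on the largest absolute difference
#'   between model and data marginals (default 1e-4).
#' @param max_iter Maximum gradient sweeps per component (default 20000).
#' @param adapt Use per-parameter adaptive gain on `eta` (default `TRUE`);
#'   `FALSE` gives the plain fixed-step schedule.
#' @param beta1,beta2 Pseudo-counts passed to [empirical_frequencies()]
#'   (ignored when `freqs` is given).
#' @param freqs Optional precomputed [empirical_frequencies()] object.
#' @return A list with `params` (the gauge-fixed fitted [pim()] with cached
#'   `logZ`), `iterations` (largest sweep count over components),
#'   `residual` (final max marginal residual) and `converged`.
#' @export
fit_pim <- function(sites, active_pairs = NULL, init = NULL, eta = 0.1,
                    tol = 1e-4, max_iter = 20000, adapt = TRUE,
                    beta1 = 1, beta2 = beta1 / 4, freqs = NULL) {
  stopifnot(inherits(sites, "site_set"))
  L <- sites$L
  if (is.null(freqs)) freqs <- empirical_frequencies(sites, beta1, beta2)
  if (is.null(active_pairs) || NROW(active_pairs) == 0L) {
    pairs <- matrix(integer(0), 0, 2)
  } else {
    pairs <- matrix(as.integer(active_pairs), ncol = 2)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    if (any(pairs[, 1] >= pairs[, 2])) stop("active pairs must have i < j")
  }
  h0 <- if (!is.null(init)) init$h else matrix(0, L, 4)
  J0 <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    J0[[k]] <- matrix(0, 4, 4)
    if (!is.null(init) && nrow(init$pairs) > 0) {
      hit <- which(init$pairs[, 1] == pairs[k, 1] &
                   init$pairs[, 2] == pairs[k, 2])
      if (length(hit) == 1) J0[[k]] <- init$J[[hit]]
    }
  }

  comps <- .components(L, pairs)
  h <- matrix(0, L, 4)
  J <- vector("list", nrow(pairs))
  iters <- 0L
  residual <- 0
  converged <- TRUE
  for (pos in comps) {
    idx <- setNames(seq_along(pos), pos)
    ks <- which(pairs[, 1] %in% pos & pairs[, 2] %in% pos)
    sub_pairs <- matrix(0L, length(ks), 2)
    Jm <- matrix(0, 16, length(ks))
    f2d <- matrix(0, 16, length(ks))
    for (t in seq_along(ks)) {
      k <- ks[t]
      sub_pairs[t, ] <- c(idx[[as.character(pairs[k, 1])]],
                          idx[[as.character(pairs[k, 2])]]) - 1L
      Jm[, t] <- as.vector(J0[[k]])
      f2d[, t] <- as.vector(freqs$f2[[.pair_key(pairs[k, 1], pairs[k, 2])]])
    }
    fit <- cpp_fit_component(h0[pos, , drop = FALSE], sub_pairs, Jm,
                             freqs$f1[pos, , drop = FALSE], f2d,
                             eta, tol, max_iter, adapt)
    h[pos, ] <- fit$h
    for (t in seq_along(ks)) {
      J[[ks[t]]] <- matrix(fit$J[, t], 4, 4,
                           dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
    }
    iters <- max(iters, fit$iterations)
    residual <- max(residual, fit$residual)
    converged <- converged && fit$converged
  }
  if (!converged) {
    warning(sprintf("fit did not reach tol = %g (residual %.3g)", tol,
                    residual))
  }
  params <- cache_logz(fix_gauge(pim(L, h, pairs, J)))
  list(params = params, iterations = iters, residual = residual,
       converged = converged)
}

#' Negative log-likelihood of a site sample under a model
#'
#' `-sum_s n_s log P(s)` with raw multiplicities (natural log).
#'
#' @param model A `pwm`, `pim` or `pwm_mix` model.
#' @param sites A [site_set()].
#' @return The negative log-likelihood.
#' @export
model_nll <- function(model, sites) {
  -sum(sites$counts * site_logprob(model, sites$mat))
}

#' Bayesian information criterion
#'
#' `BIC = -log Lhat + (k/2) log N` (natural log), the Laplace-approximation
#' penalty on the number of free parameters.
#'
#' @param nll Negative log-likelihood at the fitted parameters.
#' @param k Number of free parameters.
#' @param N Sample size.
#' @return The BIC value.
#' @export
bic_score <- function(nll, k, N) {
  stopifnot(N >= 1, k >= 0)
  nll + (k / 2) * log(N)
}

#' Free-parameter count of a PIM
#'
#' Gauge-independent counting: 3 per position for the fields (zero-sum gauge
#' removes one of four) and 9 per active coupling (doubly centered 4 x 4
#' block).
#'
#' @param L Site length.
#' @param n_pairs Number of active couplings.
#' @return Integer parameter count `3 L + 9 n_pairs`.
#' @export
pim_param_count <- function(L, n_pairs) 3L * L + 9L * n_pairs

## exact two-sided binomial tail ("minimum-likelihood" convention): the sum
## of the probabilities of all outcomes no more likely than the observed one
.binom_two_sided <- function(x, n, p) {
  if (p <= 0) return(as.numeric(x == 0))
  if (p >= 1) return(as.numeric(x == n))
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

#' Choose the next coupling to add
#'
#' Scores every inactive pair by how much its dinucleotide distribution under
#' the current model differs from the data: for each of the 16 cells the
#' exact two-sided binomial tail probability of the observed count out of N
#' under the model cell probability is computed, the pair score is the
#' minimum over cells, and the pair with the smallest score wins (ties go to
#' the lexicographically first pair).
#'
#' @param params The current fitted [pim()].
#' @param sites A [site_set()].
#' @param excluded Optional matrix of pairs (i, j) to skip (in addition to
#'   the already-active ones).
#' @param universe Optional matrix of candidate pairs; defaults to all i < j.
#' @return A list with `pair` (integer c(i, j), or `NULL` if no inactive
#'   candidate remains) and `score` (its minimum binomial tail).
#' @export
select_next_pair <- function(params, sites, excluded = NULL, universe = NULL) {
  L <- params$L
  if (is.null(universe)) {
    universe <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  }
  universe <- matrix(as.integer(universe), ncol = 2)
  universe <- universe[order(universe[, 1], universe[, 2]), , drop = FALSE]
  skip <- character(0)
  if (nrow(params$pairs) > 0) {
    skip <- c(skip, .pair_key(params$pairs[, 1], params$pairs[, 2]))
  }
  if (!is.null(excluded) && NROW(excluded) > 0) {
    excluded <- matrix(as.integer(excluded), ncol = 2)
    skip <- c(skip, .pair_key(excluded[, 1], excluded[, 2]))
  }
  keep <- !(.pair_key(universe[, 1], universe[, 2]) %in% skip)
  universe <- universe[keep, , drop = FALSE]
  if (nrow(universe) == 0) return(list(pair = NULL, score = NA_real_))
  marg <- model_marginals(params)
  N <- round(sites$N)
  best <- NULL
  best_score <- Inf
  for (t in seq_len(nrow(universe))) {
    i <- universe[t, 1]; j <- universe[t, 2]
    obs <- round(pair_counts(sites, i, j))
    pmod <- marg$f2[[.pair_key(i, j)]]
    score <- min(vapply(1:16, function(c) {
      .binom_two_sided(obs[c], N, pmod[c])
    }, numeric(1)))
    if (score < best_score) {  # strict: lexicographic tie-break
      best_score <- score
      best <- c(i, j)
    }
  }
  list(pair = best, score = best_score)
}

#' Learn a PIM with greedy, BIC-controlled coupling addition
#'
#' Starting from the coupling-free fit, repeatedly adds the coupling whose
#' dinucleotide statistics deviate most from the current model (see
#' [select_next_pair()]), refits, and scores the BIC. The loop stops when
#' the BIC has failed to improve for `patience` consecutive additions or the
#' pair universe is exhausted, and returns the BIC-minimal model together
#' with the full trace.
#'
#' @param sites A [site_set()].
#' @param pair_universe `"all"` for any i < j, or `"nearest_neighbor"` to
#'   restrict candidates to adjacent positions (the NNM, equivalent to a
#'   first-order Markov model).
#' @param patience Consecutive non-improving additions tolerated (default 3).
#' @param max_pairs Optional hard cap on the number of couplings considered.
#' @inheritParams fit_pim
#' @return A list with `params` (BIC-optimal gauge-fixed [pim()]), `trace`
#'   (data.frame: step, pair_i, pair_j, nll, bic, residual, iterations) and
#'   `bic` (the optimal value).
#' @export
build_pim <- function(sites, pair_universe = c("all", "nearest_neighbor"),
                      beta1 = 1, beta2 = beta1 / 4, eta = 0.1, tol = 1e-4,
                      max_iter = 20000, adapt = TRUE, patience = 3,
                      max_pairs = NULL) {
  pair_universe <- match.arg(pair_universe)
  stopifnot(sites$N >= 2)
  L <- sites$L
  universe <- if (pair_universe == "nearest_neighbor") {
    cbind(seq_len(L - 1), seq_len(L - 1) + 1L)
  } else {
    pu <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    pu[order(pu[, 1], pu[, 2]), , drop = FALSE]
  }
  if (is.null(max_pairs)) max_pairs <- nrow(universe)
  freqs <- empirical_frequencies(sites, beta1, beta2)

  fit <- fit_pim(sites, NULL, eta = eta, tol = tol, max_iter = max_iter,
                 adapt = adapt, freqs = freqs)
  nll <- model_nll(fit$params, sites)
  bic <- bic_score(nll, pim_param_count(L, 0), sites$N)
  trace <- data.frame(step = 0L, pair_i = NA_integer_, pair_j = NA_integer_,
                      nll = nll, bic = bic, residual = fit$residual,
                      iterations = fit$iterations)
  best <- list(params = fit$params, bic = bic, step = 0L)
  active <- matrix(integer(0), 0, 2)
  step <- 0L
  while (nrow(active) < max_pairs) {
    sel <- select_next_pair(fit$params, sites, universe = universe)
    if (is.null(sel$pair)) break
    active <- rbind(active, sel$pair)
    step <- step + 1L
    fit <- fit_pim(sites, active, init = fit$params, eta = eta, tol = tol,
                   max_iter = max_iter, adapt = adapt, freqs = freqs)
    nll <- model_nll(fit$params, sites)
    bic <- bic_score(nll, pim_param_count(L, nrow(active)), sites$N)
    trace <- rbind(trace, data.frame(step = step, pair_i = sel$pair[1],
                                     pair_j = sel$pair[2], nll = nll,
                                     bic = bic, residual = fit$residual,
                                     iterations = fit$iterations))
    if (bic < best$bic) {
      best <- list(params = fit$params, bic = bic, step = step)
    } else if (step - best$step >= patience) {
      break
    }
  }
  list(params = best$params, trace = trace, bic = best$bic)
}

#' Write a greedy-fit trace as a tab-separated table
#'
#' @param trace The `trace` element returned by [build_pim()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_fit_trace <- function(trace, path) {
  write.table(trace[, c("step", "pair_i", "pair_j", "nll", "bic", "residual")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
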