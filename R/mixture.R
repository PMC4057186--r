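#' Hamming-distance K-means on binding sites
#'
#' Clusters the distinct sites of a sample (weighted by multiplicity) around
#' consensus-string centroids under the Hamming metric. The centroid of a
#' cluster is the per-position modal nucleotide (ties broken by alphabet
#' order); assignment ties go to the lowest cluster index; empty clusters are
#' re-seeded from the point farthest from its centroid. The best of
#' `n_restarts` runs by total (multiplicity-weighted) Hamming cost is kept.
#'
#' @param sites A [site_set()].
#' @param K Number of clusters (1 <= K <= number of distinct sites).
#' @param seed Master seed; restart seeds are derived from it.
#' @param n_restarts Independent restarts (default 10).
#' @param max_iter Iteration cap per run (default 100).
#' @return A list with `assignment` (cluster index per distinct site of
#'   `sites`), `centroids` (K x L encoded matrix), `objective` (total
#'   weighted Hamming distance) and `K`.
#' @export
kmeans_hamming <- function(sites, K, seed = NULL, n_restarts = 10,
                           max_iter = 100) {
  stopifnot(inherits(sites, "site_set"), K >= 1)
  mat <- sites$mat
  w <- sites$counts
  n <- nrow(mat)
  if (K > n) stop("K exceeds the number of distinct sites")
  run_once <- function() {
    centroids <- mat[sample.int(n, K), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      D <- .hamming_to_centroids(mat, centroids)
      assignment <- max.col(-D, ties.method = "first")
      ## re-seed empty clusters from the farthest points
      for (k in seq_len(K)) {
        if (!any(assignment == k)) {
          far <- which.max(D[cbind(seq_len(n), assignment)])
          centroids[k, ] <- mat[far, ]
          assignment[far] <- k
        }
      }
      if (identical(assignment, assign_old)) break
      assign_old <- assignment
      for (k in seq_len(K)) {
        centroids[k, ] <- .consensus(mat[assignment == k, , drop = FALSE],
                                     w[assignment == k])
      }
    }
    D <- .hamming_to_centroids(mat, centroids)
    assignment <- max.col(-D, ties.method = "first")
    list(assignment = assignment, centroids = centroids,
         objective = sum(w * D[cbind(seq_len(n), assignment)]), K = K)
  }
  runs <- function() {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once()
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    best
  }
  if (is.null(seed)) runs() else withr::with_seed(seed, runs())
}

.hamming_to_centroids <- function(mat, centroids) {
  D <- matrix(0L, nrow(mat), nrow(centroids))
  for (k in seq_len(nrow(centroids))) {
    D[, k] <- rowSums(mat != matrix(centroids[k, ], nrow(mat), ncol(mat),
                                    byrow = TRUE))
  }
  D
}

## per-position modal letter, weighted; ties to the alphabetically first
.consensus <- function(mat, w) {
  vapply(seq_len(ncol(mat)), function(i) {
    cnt <- numeric(4)
    tab <- rowsum(w, mat[, i])
    cnt[as.integer(rownames(tab))] <- tab[, 1]
    which.max(cnt)  # first maximum = alphabet order
  }, integer(1))
}

#' Mixture of PWMs
#'
#' `P(s) = sum_k pi_k prod_i p_i^(k)(s_i)`: K component PWMs with weights.
#'
#' @param components List of [pwm()] objects sharing one length.
#' @param weights Positive weights summing to one.
#' @return An object of class `pwm_mix`.
#' @export
pwm_mix <- function(components, weights) {
  stopifnot(length(components) == length(weights), all(weights > 0))
  L <- unique(vapply(components, nrow, integer(1)))
  if (length(L) != 1) stop("components must share one length")
  weights <- weights / sum(weights)
  structure(list(K = length(components), L = L, weights = weights,
                 components = components),
            class = "pwm_mix")
}

#' @export
print.pwm_mix <- function(x, ...) {
  cat(sprintf("pwm_mix: K = %d components, L = %d\n", x$K, x$L))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
site_logprob.pwm_mix <- function(model, mat) {
  mat <- .as_site_mat(mat, model$L)
  lp <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) + site_logprob(model$components[[k]], mat)
  }, numeric(nrow(mat)))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1)
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' Probability of sites under a PWM mixture
#' @param mix A [pwm_mix()].
#' @param sites Sites in any form accepted by [pwm_probability()].
#' @return Numeric vector of probabilities.
#' @export
mixture_probability <- function(mix, sites) {
  exp(site_logprob(mix, .as_site_mat(sites, mix$L)))
}

#' Fit a K-component PWM mixture by Hamming K-means
#'
#' Clusters the sites with [kmeans_hamming()], estimates one pseudo-counted
#' PWM per cluster, and weights each component by its cluster's share of N.
#'
#' @inheritParams kmeans_hamming
#' @param beta Pseudo-count per nucleotide cell for the component PWMs.
#' @return A [pwm_mix()] with a `clustering` attribute holding the K-means
#'   result.
#' @export
fit_mixture <- function(sites, K, beta = 1, seed = NULL, n_restarts = 10) {
  cl <- kmeans_hamming(sites, K, seed = seed, n_restarts = n_restarts)
  comps <- vector("list", K)
  wts <- numeric(K)
  for (k in seq_len(K)) {
    sel <- cl$assignment == k
    sub <- site_set(sites$mat[sel, , drop = FALSE], sites$counts[sel])
    comps[[k]] <- estimate_pwm(sub, beta = beta)
    wts[k] <- sub$N / sites$N
  }
  out <- pwm_mix(comps, wts)
  attr(out, "clustering") <- cl
  out
}

#' Parameter count of a PWM mixture
#'
#' Each PWM carries 3L free entries (rows are normalized) and the weights
#' add K - 1 more, giving `K * 3L + (K - 1)`.
#'
#' @param K Number of components (>= 1).
#' @param L Site length (>= 1).
#' @return Integer parameter count.
#' @examples
#' mixture_param_count(5, 12)  # 184
#' @export
mixture_param_count <- function(K, L) {
  stopifnot(K >= 1, L >= 1)
  as.integer(K * 3 * L + (K - 1))
}

#' Select the mixture order by BIC
#'
#' Fits mixtures of order K = 1..K_max and returns the BIC-minimal one. The
#' likelihood is the mixture probability of the site sample (hard clustering
#' is only the estimation device).
#'
#' @inheritParams fit_mixture
#' @param K_max Largest order tried.
#' @return A list with `model` (the BIC-optimal [pwm_mix()]), `trace`
#'   (data.frame: K, nll, k_params, bic) and `bic`.
#' @export
select_mixture <- function(sites, K_max, beta = 1, seed = NULL,
                           n_restarts = 10) {
  stopifnot(K_max >= 1)
  K_max <- min(K_max, nrow(sites$mat))
  fits <- vector("list", K_max)
  trace <- data.frame(K = seq_len(K_max), nll = NA_real_,
                      k_params = NA_integer_, bic = NA_real_)
  for (K in seq_len(K_max)) {
    sub_seed <- if (is.null(seed)) NULL else seed + K
    fits[[K]] <- fit_mixture(sites, K, beta = beta, seed = sub_seed,
                             n_restarts = n_restarts)
    nll <- model_nll(fits[[K]], sites)
    k <- mixture_param_count(K, sites$L)
    trace$nll[K] <- nll
    trace$k_params[K] <- k
    trace$bic[K] <- bic_score(nll, k, sites$N)
  }
  best <- which.min(trace$bic)
  list(model = fits[[best]], trace = trace, bic = trace$bic[best], K = best)
}
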