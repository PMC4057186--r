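#' Pairwise interaction model
#'
#' A maximum-entropy model of L-mers with per-position fields `h_i(a)` and
#' sparse pairwise couplings `J_ij(a,b)` between positions. The binding
#' energy of a site `s` is
#' `E(s) = sum_i h_i(s_i) + sum_(i<j active) J_ij(s_i, s_j)`
#' and its probability `P(s) = exp(-E(s)) / Z`; lower energy means more
#' probable. A PWM is the special case with no couplings.
#'
#' @param L Site length.
#' @param h L x 4 field matrix (energy units, natural log scale); defaults
#'   to zeros.
#' @param pairs Integer matrix with two columns (i, j), i < j, one row per
#'   active coupling; may have zero rows.
#' @param J List of 4 x 4 coupling blocks aligned with the rows of `pairs`
#'   (row = letter at i, column = letter at j).
#' @param gauge_fixed Logical flag; set by [fix_gauge()].
#' @return An object of class `pim`.
#' @export
pim <- function(L, h = NULL, pairs = NULL, J = NULL, gauge_fixed = FALSE) {
  if (is.null(h)) h <- matrix(0, L, 4)
  h <- as.matrix(h)
  stopifnot(nrow(h) == L, ncol(h) == 4)
  colnames(h) <- DNA_ALPHABET
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), 0, 2)
    J <- list()
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (any(pairs[, 1] >= pairs[, 2]) || any(pairs < 1) || any(pairs > L)) {
      stop("pairs must satisfy 1 <= i < j <= L")
    }
    key <- paste(pairs[, 1], pairs[, 2])
    if (anyDuplicated(key)) stop("duplicate coupling pairs")
    if (length(J) != nrow(pairs)) stop("J must align with pairs")
    J <- lapply(J, function(b) {
      b <- as.matrix(b)
      stopifnot(all(dim(b) == c(4, 4)))
      dimnames(b) <- list(DNA_ALPHABET, DNA_ALPHABET)
      b
    })
  }
  colnames(pairs) <- c("i", "j")
  structure(list(L = L, h = h, pairs = pairs, J = J,
                 gauge_fixed = isTRUE(gauge_fixed), logZ = NULL),
            class = "pim")
}

#' @export
print.pim <- function(x, ...) {
  cat(sprintf("pim: L = %d, %d coupling(s)%s\n", x$L, nrow(x$pairs),
              if (x$gauge_fixed) ", gauge-fixed" else ""))
  if (nrow(x$pairs) > 0) {
    cat("  pairs:", paste(sprintf("(%d,%d)", x$pairs[, 1], x$pairs[, 2]),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of active couplings
#' @param params A [pim()].
#' @return Integer count of coupling pairs.
#' @export
n_couplings <- function(params) nrow(params$pairs)

#' Binding energy of sites under a PIM
#'
#' `E(s) = sum_i h_i(s_i) + sum_(i<j) J_ij(s_i, s_j)` over active couplings.
#'
#' @param params A [pim()].
#' @param sites A [site_set()], encoded matrix, integer vector (one site) or
#'   character vector of L-mers.
#' @return Numeric vector of energies.
#' @export
pim_energy <- function(params, sites) {
  mat <- .as_site_mat(sites, params$L)
  e <- numeric(nrow(mat))
  for (i in seq_len(params$L)) e <- e + params$h[i, ][mat[, i]]
  for (k in seq_len(nrow(params$pairs))) {
    e <- e + params$J[[k]][cbind(mat[, params$pairs[k, 1]],
                                 mat[, params$pairs[k, 2]])]
  }
  unname(e)
}

## ---- connected components of the coupling graph -------------------------
## Exact factorization: Z, marginals and sampling decompose over connected
## components of the active-pair graph; enumeration only ever covers one
## component's 4^m states.
.components <- function(L, pairs) {
  parent <- seq_len(L)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(L), find, integer(1))
  split(seq_len(L), roots)
}

## Enumerate one component: logZ, singles, and joints for `want` pairs
## (global position indices, both within the component).
.component_stats <- function(params, positions, want = NULL) {
  m <- length(positions)
  idx <- setNames(seq_len(m), positions)
  in_comp <- params$pairs[, 1] %in% positions & params$pairs[, 2] %in% positions
  ks <- which(in_comp)
  sub_pairs <- matrix(0L, length(ks), 2)
  Jm <- matrix(0, 16, length(ks))
  for (t in seq_along(ks)) {
    k <- ks[t]
    sub_pairs[t, ] <- c(idx[[as.character(params$pairs[k, 1])]],
                        idx[[as.character(params$pairs[k, 2])]]) - 1L
    Jm[, t] <- as.vector(params$J[[k]])
  }
  if (is.null(want)) want <- matrix(integer(0), 0, 2)
  want_sub <- matrix(0L, nrow(want), 2)
  if (nrow(want) > 0) {
    for (t in seq_len(nrow(want))) {
      want_sub[t, ] <- c(idx[[as.character(want[t, 1])]],
                         idx[[as.character(want[t, 2])]]) - 1L
    }
  }
  res <- cpp_enum_stats(params$h[positions, , drop = FALSE], sub_pairs, Jm,
                        want_sub)
  res$positions <- positions
  res
}

#' Log partition function of a PIM
#'
#' `log Z = log sum_s exp(-E(s))` over all 4^L sites, computed exactly with
#' overflow-safe accumulation. The sum factorizes over connected components
#' of the coupling graph; each component is enumerated (at most 14 coupled
#' positions per component).
#'
#' @param params A [pim()].
#' @return `log Z` (natural log).
#' @export
log_partition <- function(params) {
  if (params$L > 14 && nrow(params$pairs) == 0) {
    ## coupling-free models factorize position by position at any length
    return(sum(log(rowSums(exp(-params$h)))))
  }
  if (params$L > 14) stop("L above the exact enumeration bound (14)")
  comps <- .components(params$L, params$pairs)
  sum(vapply(comps, function(pos) .component_stats(params, pos)$logZ,
             numeric(1)))
}

#' Site probabilities under a PIM
#'
#' `P(s) = exp(-E(s)) / Z` with the exact partition function.
#'
#' @inheritParams pim_energy
#' @return Numeric vector of probabilities.
#' @export
pim_probability <- function(params, sites) {
  exp(site_logprob(params, .as_site_mat(sites, params$L)))
}

#' @export
site_logprob.pim <- function(model, mat) {
  lz <- if (!is.null(model$logZ)) model$logZ else log_partition(model)
  -pim_energy(model, mat) - lz
}

#' Cache the log partition function inside a PIM
#' @param params A [pim()].
#' @return The model with `logZ` filled in.
#' @export
cache_logz <- function(params) {
  params$logZ <- log_partition(params)
  params
}

#' Exact single and pairwise marginals of a PIM
#'
#' Computes `f_i(a)` for every position and `f_ij(a,b)` for every pair
#' i < j of the model distribution, by exact summation (component-wise
#' enumeration; pairs spanning two components factorize).
#'
#' @param params A [pim()].
#' @return A `pair_freqs` object (with `beta1 = beta2 = 0`).
#' @export
model_marginals <- function(params) {
  L <- params$L
  if (L > 14) stop("L above the exact enumeration bound (14)")
  comps <- .components(L, params$pairs)
  comp_of <- integer(L)
  for (ci in seq_along(comps)) comp_of[comps[[ci]]] <- ci
  all_pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  all_pairs <- all_pairs[order(all_pairs[, 1], all_pairs[, 2]), , drop = FALSE]
  f1 <- matrix(NA_real_, L, 4, dimnames = list(NULL, DNA_ALPHABET))
  f2 <- list()
  for (ci in seq_along(comps)) {
    pos <- comps[[ci]]
    w <- all_pairs[comp_of[all_pairs[, 1]] == ci &
                   comp_of[all_pairs[, 2]] == ci, , drop = FALSE]
    st <- .component_stats(params, pos, want = w)
    f1[pos, ] <- st$f1
    for (t in seq_len(nrow(w))) {
      f2[[.pair_key(w[t, 1], w[t, 2])]] <-
        matrix(st$f2[, t], 4, 4, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
    }
  }
  for (t in seq_len(nrow(all_pairs))) {
    i <- all_pairs[t, 1]; j <- all_pairs[t, 2]
    key <- .pair_key(i, j)
    if (is.null(f2[[key]])) f2[[key]] <- outer(f1[i, ], f1[j, ])
  }
  structure(list(L = L, f1 = f1, f2 = f2, N = Inf, beta1 = 0, beta2 = 0),
            class = "pair_freqs")
}

#' Energies of all 4^L sites of a PIM
#'
#' States are ordered by the mixed-radix code
#' `1 + sum_i (s_i - 1) 4^(i-1)` (position 1 varies fastest). Materializes
#' the full vector, so L is capped at 12.
#'
#' @param params A [pim()].
#' @return Numeric vector of length 4^L.
#' @export
all_energies <- function(params) {
  if (nrow(params$pairs) == 0) {
    pr <- matrix(0L, 0, 2)
    Jm <- matrix(0, 16, 0)
  } else {
    pr <- params$pairs - 1L
    Jm <- vapply(params$J, as.vector, numeric(16))
    if (!is.matrix(Jm)) Jm <- matrix(Jm, 16, 1)
  }
  cpp_all_energies(params$h, pr, Jm)
}

## encoded matrix -> state code 1..4^L, and back
.state_code <- function(mat) {
  L <- ncol(mat)
  code <- numeric(nrow(mat))
  for (i in seq_len(L)) code <- code + (mat[, i] - 1) * 4^(i - 1)
  code + 1
}

.code_to_mat <- function(code, L) {
  code <- code - 1
  mat <- matrix(0L, length(code), L)
  for (i in seq_len(L)) {
    mat[, i] <- as.integer(code %% 4) + 1L
    code <- code %/% 4
  }
  mat
}
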