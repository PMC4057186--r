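#' Full symmetric coupling matrix of a PIM
#'
#' Extends the sparse i < j coupling blocks to the full symmetric 4L x 4L
#' matrix indexed by (position, letter): block (i, j) holds `J_ij`, block
#' (j, i) its transpose, and the within-position diagonal blocks are zero.
#' With the 4L one-hot indicator `x(s)` of a sequence, the coupling energy is
#' `(1/2) x(s)' Jhat x(s)`, so `E(s) = sum_i h_i(s_i) + (1/2) x' Jhat x`.
#'
#' @param params A [pim()].
#' @return A 4L x 4L symmetric matrix.
#' @export
build_full_matrix <- function(params) {
  L <- params$L
  M <- matrix(0, 4 * L, 4 * L)
  for (k in seq_len(nrow(params$pairs))) {
    i <- params$pairs[k, 1]; j <- params$pairs[k, 2]
    ri <- (i - 1) * 4 + 1:4
    rj <- (j - 1) * 4 + 1:4
    M[ri, rj] <- params$J[[k]]
    M[rj, ri] <- t(params$J[[k]])
  }
  M
}

#' One-hot indicator vectors of encoded sites
#'
#' @param mat Encoded site matrix (rows) or vector.
#' @param L Site length.
#' @return Matrix with 4L columns, one row per site.
#' @export
site_indicator <- function(mat, L) {
  mat <- .as_site_mat(mat, L)
  X <- matrix(0, nrow(mat), 4 * L)
  for (i in seq_len(L)) {
    X[cbind(seq_len(nrow(mat)), (i - 1) * 4 + mat[, i])] <- 1
  }
  X
}

#' Hopfield-pattern decomposition of the coupling matrix
#'
#' Eigendecomposes the full symmetric coupling matrix into orthonormal
#' patterns `xi_k` with real eigenvalues `lambda_k`, ranked by decreasing
#' |lambda| (ties: larger lambda first, then original index). The coupling
#' energy decomposes over patterns as
#' `(1/2) sum_k lambda_k (xi_k . x(s))^2`. The diagonal blocks are zero, so
#' the trace and hence the eigenvalue sum vanish. Each pattern's sign is
#' fixed so its largest-magnitude coordinate is positive.
#'
#' @param params A [pim()] or a precomputed 4L x 4L symmetric matrix.
#' @return An object of class `coupling_spectrum`: list with `L`, `J_full`,
#'   `values` (ranked eigenvalues) and `patterns` (4L x 4L, columns ranked).
#' @export
hopfield_decompose <- function(params) {
  if (inherits(params, "pim")) {
    M <- build_full_matrix(params)
    L <- params$L
  } else {
    M <- as.matrix(params)
    stopifnot(nrow(M) == ncol(M), nrow(M) %% 4 == 0,
              max(abs(M - t(M))) < 1e-12)
    L <- nrow(M) / 4
  }
  eig <- eigen(M, symmetric = TRUE)
  ord <- order(-abs(eig$values), -eig$values, seq_along(eig$values))
  values <- eig$values[ord]
  patterns <- eig$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(patterns))) {
    top <- which.max(abs(patterns[, k]))
    if (patterns[top, k] < 0) patterns[, k] <- -patterns[, k]
  }
  structure(list(L = L, J_full = M, values = values, patterns = patterns),
            class = "coupling_spectrum")
}

#' @export
print.coupling_spectrum <- function(x, ...) {
  cat(sprintf("coupling_spectrum: L = %d (4L = %d), top |eigenvalues|: %s\n",
              x$L, 4 * x$L,
              paste(sprintf("%.3f", head(x$values, 5)), collapse = " ")))
  invisible(x)
}

#' Truncated reconstruction from the top Hopfield patterns
#'
#' Rebuilds the coupling matrix from the `p` patterns of largest |lambda|,
#' `J^(p) = sum_(k<=p) lambda_k xi_k xi_k'`, and re-zeroes the within-position
#' diagonal blocks (truncation leaks small values there that have no meaning
#' as couplings). `p = 4L` reproduces the full matrix exactly; `p = 0` gives
#' the zero matrix.
#'
#' @param spectrum A [hopfield_decompose()] result.
#' @param p Number of patterns kept, 0..4L.
#' @return A list with `J_p` (the truncated 4L x 4L matrix, diagonal blocks
#'   zeroed), `pairs` and `J` (the i < j blocks, every pair), and `p`.
#' @export
truncate_spectrum <- function(spectrum, p) {
  L <- spectrum$L
  if (p < 0 || p > 4 * L) stop("p must lie in 0..4L")
  Jp <- matrix(0, 4 * L, 4 * L)
  if (p > 0) {
    V <- spectrum$patterns[, seq_len(p), drop = FALSE]
    Jp <- V %*% (spectrum$values[seq_len(p)] * t(V))
    Jp <- (Jp + t(Jp)) / 2
  }
  for (i in seq_len(L)) {
    ri <- (i - 1) * 4 + 1:4
    Jp[ri, ri] <- 0
  }
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  J <- lapply(seq_len(nrow(pairs)), function(t) {
    i <- pairs[t, 1]; j <- pairs[t, 2]
    Jp[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4]
  })
  list(J_p = Jp, pairs = pairs, J = J, p = p)
}

#' NDI matrix of a truncated coupling matrix
#'
#' Feeds the truncated i < j blocks through the direct-information machinery
#' with the supplied single-site frequencies; blocks that are numerically
#' zero contribute zero.
#'
#' @param truncation Output of [truncate_spectrum()].
#' @param f1 L x 4 single-site frequencies.
#' @param tol Solver tolerance.
#' @param zero_tol Blocks with all |entries| below this are treated as
#'   uncoupled.
#' @return Symmetric L x L NDI matrix.
#' @export
truncated_ndi <- function(truncation, f1, tol = 1e-10, zero_tol = 1e-12) {
  L <- nrow(f1)
  H <- positional_entropy(f1)
  NDI <- matrix(0, L, L)
  for (t in seq_len(nrow(truncation$pairs))) {
    i <- truncation$pairs[t, 1]; j <- truncation$pairs[t, 2]
    B <- truncation$J[[t]]
    if (max(abs(B)) <= zero_tol) next
    sol <- solve_direct_fields(B, f1[i, ], f1[j, ], tol = tol)
    di <- max(0, direct_information(sol, f1[i, ], f1[j, ]))
    NDI[i, j] <- NDI[j, i] <- normalized_information(di, H[i], H[j])
  }
  NDI
}

#' Export a spectrum as plain text tables
#'
#' Writes the ranked eigenvalues as a one-column table and the first `p`
#' patterns as a 4L x p matrix table.
#'
#' @param spectrum A [hopfield_decompose()] result.
#' @param values_path,patterns_path Output files.
#' @param p Number of patterns to export (default all).
#' @return Invisibly, the two paths.
#' @export
write_spectrum <- function(spectrum, values_path, patterns_path,
                           p = 4 * spectrum$L) {
  write.table(data.frame(eigenvalue = spectrum$values), values_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(spectrum$patterns[, seq_len(p), drop = FALSE], patterns_path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = paste0("pattern", seq_len(p)))
  invisible(c(values_path, patterns_path))
}
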