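#' Binding-site sample
#'
#' A `site_set` holds a multiset of fixed-length nucleotide words (the TFBS
#' sample): the distinct encoded words, their multiplicities, and the total
#' count N. All model estimation functions take a `site_set`.
#'
#' @param sequences Character vector of L-mers (repeats allowed), or an
#'   integer matrix of codes in 1..4 with one row per site occurrence.
#' @param counts Optional multiplicities aligned with `sequences`; defaults
#'   to 1 each.
#' @return An object of class `site_set` with elements `L`, `mat` (distinct
#'   encoded sites, one row each), `counts` (multiplicities) and `N`.
#' @examples
#' s <- site_set(c("ACGT", "ACGT", "ACGA"))
#' s$N
#' @export
site_set <- function(sequences, counts = NULL) {
  mat <- if (is.matrix(sequences)) sequences else encode_seq(sequences)
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)
  storage.mode(mat) <- "integer"
  if (nrow(mat) < 1L) stop("empty site set")
  if (any(mat < 1L | mat > 4L)) stop("codes must lie in 1..4")
  if (is.null(counts)) counts <- rep(1, nrow(mat))
  if (length(counts) != nrow(mat)) stop("counts must align with sequences")
  if (any(counts < 1)) stop("multiplicities must be >= 1")
  key <- apply(mat, 1, paste, collapse = "")
  agg <- rowsum(as.numeric(counts), key)
  ord <- match(rownames(agg), key)
  structure(
    list(L = ncol(mat), mat = mat[ord, , drop = FALSE],
         counts = as.numeric(agg[, 1]), N = sum(counts)),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set: N = %g sites (%d distinct), L = %d\n",
              x$N, nrow(x$mat), x$L))
  invisible(x)
}

#' @export
format.site_set <- function(x, ...) {
  sprintf("site_set(N = %g, distinct = %d, L = %d)", x$N, nrow(x$mat), x$L)
}

#' Site sequences as character strings
#'
#' @param x A `site_set`.
#' @param expand If `TRUE`, repeat each distinct site by its multiplicity.
#' @return Character vector of L-mers.
#' @export
site_strings <- function(x, expand = FALSE) {
  s <- decode_seq(x$mat)
  if (expand) s <- rep(s, times = x$counts)
  s
}
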