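#' Encode nucleotide sequences as integer vectors
#'
#' Maps sequences over the DNA alphabet to integer codes in the fixed order
#' A = 1, C = 2, G = 3, T = 4 (case-insensitive). The mapping is bijective
#' with [decode_seq()].
#'
#' @param x Character vector of sequences (all of equal length for matrix
#'   output) or a single string.
#' @return For a single string, an integer vector of codes; for a character
#'   vector, an integer matrix with one row per sequence.
#' @examples
#' encode_seq("ACGT")
#' decode_seq(encode_seq("ACGT"))
#' @export
encode_seq <- function(x) {
  if (length(x) == 1L) {
    return(.encode_one(x))
  }
  mats <- lapply(x, .encode_one)
  lens <- lengths(mats)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths")
  }
  do.call(rbind, mats)
}

.encode_one <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  code <- match(ch, DNA_ALPHABET)
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop(sprintf("non-ACGT character '%s' at position %d", ch[bad], bad))
  }
  code
}

#' @rdname encode_seq
#' @param code Integer vector or matrix of codes in 1..4.
#' @export
decode_seq <- function(code) {
  if (is.matrix(code)) {
    return(apply(code, 1, function(r) paste(DNA_ALPHABET[r], collapse = "")))
  }
  paste(DNA_ALPHABET[code], collapse = "")
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive;
#'   N maps to N).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

## Reverse complement of an encoded matrix: A<->T, C<->G is code 5 - code.
.revcomp_mat <- function(mat) {
  5L - mat[, rev(seq_len(ncol(mat))), drop = FALSE]
}
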