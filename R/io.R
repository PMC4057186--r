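#' Read fragments from a FASTA file
#'
#' Gzip-transparent. Lowercase is accepted as sequence; N is kept as a mask;
#' any other character is rejected with the offending record named.
#'
#' @param path FASTA file (optionally .gz).
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  for (i in seq_along(out)) {
    bad <- regmatches(out[i], regexpr("[^ACGTN]", out[i]))
    if (length(bad) > 0 && nchar(bad) > 0) {
      stop(sprintf("record '%s' contains invalid character '%s'",
                   names(out)[i], bad))
    }
  }
  out
}

#' Write fragments as FASTA
#'
#' @param fragments Named character vector.
#' @param path Output file (gz compression if the name ends in .gz).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(fragments, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(fragments), path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a count or probability matrix as a PWM
#'
#' Supported dialects: `"jaspar_pfm"` (optional `>` header, then four rows
#' `A [ 1 2 3 ]` in A,C,G,T order, brackets and letter optional),
#' `"transfac"` (rows `01 n_A n_C n_G n_T consensus` between PO/P0 and XX),
#' and `"plain"` (whitespace-separated numeric L x 4 or 4 x L block, A,C,G,T
#' order). Counts are converted to probabilities with pseudo-count `beta`;
#' matrices whose rows already sum to one pass through when `beta = 0`.
#'
#' @param path Matrix file.
#' @param dialect One of `"jaspar_pfm"`, `"transfac"`, `"plain"`.
#' @param beta Pseudo-count per cell used in the count-to-probability
#'   conversion (default 1).
#' @return A [pwm()].
#' @export
read_matrix <- function(path, dialect = c("jaspar_pfm", "transfac", "plain"),
                        beta = 1) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  mat <- switch(dialect,
    jaspar_pfm = {
      rows <- grep("^>", lines, invert = TRUE, value = TRUE)
      if (length(rows) != 4) stop("expected 4 nucleotide rows")
      vals <- lapply(rows, function(r) {
        r <- gsub("^[ACGTacgt]", "", trimws(r))
        as.numeric(strsplit(trimws(gsub("[][]", " ", r)), "\\s+")[[1]])
      })
      len <- unique(lengths(vals))
      if (length(len) != 1) stop("inconsistent row lengths")
      t(do.call(rbind, vals))  # rows are A,C,G,T -> transpose to L x 4
    },
    transfac = {
      body <- grep("^[0-9]+\\s", trimws(lines), value = TRUE)
      if (length(body) == 0) stop("no numbered TRANSFAC rows found")
      vals <- lapply(body, function(r) {
        f <- strsplit(trimws(r), "\\s+")[[1]]
        as.numeric(f[2:5])
      })
      if (any(vapply(vals, anyNA, logical(1)))) {
        stop("malformed TRANSFAC row")
      }
      do.call(rbind, vals)
    },
    plain = {
      vals <- lapply(lines, function(r) {
        as.numeric(strsplit(trimws(r), "[[:space:],]+")[[1]])
      })
      len <- unique(lengths(vals))
      if (length(len) != 1) stop("inconsistent row lengths")
      m <- do.call(rbind, vals)
      if (ncol(m) == 4) m else if (nrow(m) == 4) t(m) else
        stop("plain matrix must be L x 4 or 4 x L")
    })
  if (any(is.na(mat))) stop("non-numeric matrix entries")
  if (any(mat < 0)) stop("negative matrix entries")
  pwm((mat + beta) / (rowSums(mat) + 4 * beta), pseudocount = beta)
}

#' Serialize a PIM to JSON
#'
#' One JSON document with keys, in order: `L`, `h` (L x 4, A,C,G,T columns),
#' `couplings` (array of objects `i`, `j`, `block`, 1-based positions),
#' `gauge_fixed`, `meta`.
#'
#' @param params A [pim()].
#' @param path Output file.
#' @param meta Optional named list stored verbatim.
#' @return Invisibly, the path.
#' @export
write_pim <- function(params, path, meta = list()) {
  doc <- list(
    L = params$L,
    h = unname(params$h),
    couplings = lapply(seq_len(nrow(params$pairs)), function(k) {
      list(i = params$pairs[k, 1], j = params$pairs[k, 2],
           block = unname(params$J[[k]]))
    }),
    gauge_fixed = params$gauge_fixed,
    meta = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pim
#' @export
read_pim <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- if (is.null(doc$couplings) || length(doc$couplings) == 0) 0 else
    nrow(as.data.frame(doc$couplings[c("i", "j")]))
  if (n == 0) {
    return(pim(doc$L, matrix(unlist(doc$h), doc$L, 4, byrow = FALSE),
               gauge_fixed = isTRUE(doc$gauge_fixed)))
  }
  pairs <- cbind(doc$couplings$i, doc$couplings$j)
  J <- lapply(doc$couplings$block, function(b) matrix(unlist(b), 4, 4))
  pim(doc$L, doc$h, pairs, J, gauge_fixed = isTRUE(doc$gauge_fixed))
}

#' Serialize a PWM mixture to JSON
#'
#' Document `{K, weights, components}` with each component an L x 4
#' probability matrix.
#'
#' @param mix A [pwm_mix()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_mixture <- function(mix, path) {
  doc <- list(K = mix$K, weights = mix$weights,
              components = lapply(mix$components, function(p)
                unname(unclass(p))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  doc <- jsonlite::read_json(path)
  comps <- lapply(doc$components, function(m) {
    pwm(do.call(rbind, lapply(m, function(r) as.numeric(unlist(r)))))
  })
  pwm_mix(comps, as.numeric(unlist(doc$weights)))
}

#' Write predicted sites as BED6
#'
#' 0-based half-open coordinates on the fragment; the score column is the
#' log-odds in bits times 100, rounded; the name column holds the site
#' L-mer as matched on its strand.
#'
#' @param sites Data.frame with fragment, offset (1-based), strand, site,
#'   score (bits).
#' @param path Output file.
#' @param L Site length (inferred from the first site when omitted).
#' @return Invisibly, the path.
#' @export
write_sites_bed <- function(sites, path, L = NULL) {
  if (is.null(L)) L <- if (nrow(sites) > 0) nchar(sites$site[1]) else 0L
  bed <- data.frame(chrom = sites$fragment,
                    start = sites$offset - 1L,
                    end = sites$offset - 1L + L,
                    name = sites$site,
                    score = round(sites$score * 100),
                    strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a flat key=value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), "=", vapply(config, as.character,
                                               character(1))), path)
  invisible(path)
}
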