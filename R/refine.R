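## fast row-wise decode of an encoded matrix
.decode_rows <- function(mat) {
  cols <- lapply(seq_len(ncol(mat)), function(i) DNA_ALPHABET[mat[, i]])
  do.call(paste0, cols)
}

## encode a fragment allowing N (-> NA); rejects other characters
.encode_frag <- function(s, id = "?") {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  code <- match(ch, c(DNA_ALPHABET, "N"))
  if (anyNA(code)) {
    bad <- which(is.na(code))[1]
    stop(sprintf("fragment '%s': invalid character '%s' at position %d",
                 id, ch[bad], bad))
  }
  code[code == 5L] <- NA_integer_
  code
}

#' Learn a background model from fragment windows
#'
#' Pools every valid L-mer window from both strands of the fragments.
#' `order = "pwm"` returns the position-independent background PWM (each row
#' the pooled nucleotide frequency, strand-symmetric by construction);
#' `order = "pim"` learns a background PIM on the window multiset with
#' [build_pim()] (slower; captures dinucleotide structure such as CpG
#' depletion).
#'
#' @param fragments Named character vector of fragment sequences.
#' @param L Window length.
#' @param order `"pwm"` (default) or `"pim"`.
#' @param beta Pseudo-count for the background frequencies.
#' @param ... Passed on to [build_pim()] when `order = "pim"`.
#' @return A [pwm()] or [pim()] background model.
#' @export
learn_background <- function(fragments, L, order = c("pwm", "pim"),
                             beta = 1, ...) {
  order <- match.arg(order)
  stopifnot(length(fragments) > 0)
  counts <- numeric(4)
  win_list <- if (order == "pim") vector("list", length(fragments)) else NULL
  n_windows <- 0
  for (f in seq_along(fragments)) {
    code <- .encode_frag(fragments[f], names(fragments)[f])
    if (length(code) < L) next
    offs <- seq_len(length(code) - L + 1L)
    idx <- outer(offs, 0:(L - 1L), "+")
    mat <- matrix(code[idx], nrow = length(offs))
    ok <- !apply(is.na(mat), 1, any)
    mat <- mat[ok, , drop = FALSE]
    if (nrow(mat) == 0) next
    both <- rbind(mat, .revcomp_mat(mat))
    n_windows <- n_windows + nrow(both)
    counts <- counts + tabulate(both, nbins = 4)
    if (order == "pim") win_list[[f]] <- both
  }
  if (n_windows == 0) stop("no valid windows of length L in the fragments")
  q <- (counts + beta) / sum(counts + beta)
  if (order == "pwm") {
    return(pwm(matrix(q, L, 4, byrow = TRUE), pseudocount = beta))
  }
  wins <- site_set(do.call(rbind, win_list))
  build_pim(wins, ...)$params
}

#' Log-odds score of sites against a background (bits)
#'
#' `score = log2(P_model(site) / P_background(site))`.
#'
#' @param model,background Models accepted by [site_logprob()].
#' @param sites Sites in any accepted form.
#' @return Numeric vector of scores in bits.
#' @export
score_site <- function(model, background, sites) {
  L <- if (inherits(model, "pwm")) nrow(model) else model$L
  mat <- .as_site_mat(sites, L)
  (site_logprob(model, mat) - site_logprob(background, mat)) / log(2)
}

#' Scan fragments with a model/background score
#'
#' Scores every L-window of every fragment on both strands; windows
#' containing N are skipped. The reported L-mer is the site as it reads on
#' its strand (minus-strand sites are the reverse complement of the
#' plus-strand slice); offsets are 1-based plus-strand window starts.
#'
#' @param model Site model (`pwm`, `pim`, or `pwm_mix`).
#' @param background Background model.
#' @param fragments Named character vector.
#' @return A data.frame with columns fragment, offset, strand, site, score
#'   (bits).
#' @export
scan_fragments <- function(model, background, fragments) {
  L <- if (inherits(model, "pwm")) nrow(model) else model$L
  out <- vector("list", length(fragments))
  for (f in seq_along(fragments)) {
    id <- names(fragments)[f]
    code <- .encode_frag(fragments[f], id)
    if (length(code) < L) next
    offs <- seq_len(length(code) - L + 1L)
    idx <- outer(offs, 0:(L - 1L), "+")
    mat <- matrix(code[idx], nrow = length(offs))
    ok <- !apply(is.na(mat), 1, any)
    if (!any(ok)) next
    mat <- mat[ok, , drop = FALSE]
    offs <- offs[ok]
    minus <- .revcomp_mat(mat)
    out[[f]] <- data.frame(
      fragment = id,
      offset = c(offs, offs),
      strand = rep(c("+", "-"), each = length(offs)),
      site = c(.decode_rows(mat), .decode_rows(minus)),
      score = c(score_site(model, background, mat),
                score_site(model, background, minus)))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(fragment = character(0), offset = integer(0),
                      strand = character(0), site = character(0),
                      score = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Score cutoff at a target true-positive rate
#'
#' The largest threshold such that at least `ceiling(tpr * M)` of the M
#' fragments have their best window score at or above it — i.e. the
#' `ceiling(tpr * M)`-th largest per-fragment best score. Ties can push the
#' passing fraction above `tpr`.
#'
#' @param best_scores Numeric vector of per-fragment best scores.
#' @param tpr Target fraction of fragments retained (default 0.5).
#' @return The cutoff score.
#' @export
choose_cutoff <- function(best_scores, tpr = 0.5) {
  stopifnot(length(best_scores) >= 1, tpr > 0, tpr <= 1)
  k <- ceiling(tpr * length(best_scores))
  sort(best_scores, decreasing = TRUE)[k]
}

#' Re-center a PWM on its information-content center of mass
#'
#' Computes per-column information content relative to the background
#' nucleotide frequencies, places the (half-up rounded) center of mass at
#' the central column `floor(L/2) + 1` of a length-L output, keeps the input
#' columns that fall inside the window, and pads with background-frequency
#' columns elsewhere. A PWM with no information anywhere is centered on its
#' midpoint.
#'
#' @param x Input [pwm()] of any length.
#' @param background Background nucleotide frequencies (length 4).
#' @param L Output length (default 12).
#' @return A [pwm()] of length L.
#' @export
recenter_pwm <- function(x, background = rep(0.25, 4), L = 12) {
  background <- background / sum(background)
  ic <- pwm_information(x, background)
  len_in <- nrow(x)
  com <- if (sum(ic) <= 1e-12) (len_in + 1) / 2 else
    sum(seq_len(len_in) * ic) / sum(ic)
  com <- floor(com + 0.5)  # half-up
  cc <- floor(L / 2) + 1L
  out <- matrix(background, L, 4, byrow = TRUE)
  for (c in seq_len(L)) {
    src <- com - cc + c
    if (src >= 1 && src <= len_in) out[c, ] <- unclass(x)[src, ]
  }
  pwm(out, pseudocount = attr(x, "pseudocount"))
}

## Above-cutoff windows -> training sites: per fragment, greedy
## non-overlapping selection by descending score (ties: offset, then +).
.select_training_sites <- function(scanned, cutoff, L) {
  hits <- scanned[scanned$score >= cutoff, , drop = FALSE]
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$fragment, -hits$score, hits$offset,
                     hits$strand), , drop = FALSE]
  keep <- logical(nrow(hits))
  taken <- split(seq_len(nrow(hits)), hits$fragment)
  for (rows in taken) {
    occupied <- integer(0)
    for (r in rows) {
      o <- hits$offset[r]
      if (all(abs(o - occupied) >= L)) {
        keep[r] <- TRUE
        occupied <- c(occupied, o)
      }
    }
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Self-consistent refinement of a model and its binding-site set
#'
#' Alternates (i) scanning the fragments with the current model against the
#' background and selecting sites at the `tpr` cutoff with (ii) relearning
#' the model on the selected sites, until the selected site multiset is
#' unchanged between rounds or `max_rounds` is reached. The PWM stage
#' re-centers the learned matrix on its information center of mass each
#' round; PIM/NNM stages use BIC-controlled greedy coupling addition;
#' the mixture stage selects its order by BIC.
#'
#' @param initial_pwm Starting [pwm()] (any length; re-centered to L).
#' @param fragments Named character vector of fragment sequences.
#' @param model_builder `"pwm"`, `"pim"`, `"nnm"` or `"mixture"`.
#' @param L Site length (default 12).
#' @param tpr Fragment true-positive rate for the cutoff (default 0.5).
#' @param max_rounds Round cap (default 20).
#' @param background_order Background model class, see [learn_background()].
#' @param beta1,beta2 Pseudo-counts for model estimation.
#' @param K_max Largest mixture order tried (mixture builder only).
#' @param seed Seed for the stochastic stages (mixture restarts).
#' @param ... Further arguments to [build_pim()] (PIM/NNM builders).
#' @return A list: `model` (final model), `sites` ([site_set()] of training
#'   sites), `selected` (their table: fragment, offset, strand, site,
#'   score), `background`, `cutoff`, `rounds`, `converged`, and `history`
#'   (per-round data.frame with site counts and Jaccard overlap with the
#'   previous round's selection).
#' @export
iterate_refinement <- function(initial_pwm, fragments,
                               model_builder = c("pwm", "pim", "nnm",
                                                 "mixture"),
                               L = 12, tpr = 0.5, max_rounds = 20,
                               background_order = "pwm", beta1 = 1,
                               beta2 = beta1 / 4, K_max = 5, seed = 1, ...) {
  model_builder <- match.arg(model_builder)
  stopifnot(length(fragments) > 0)
  background <- learn_background(fragments, L, order = background_order)
  bg_freq <- if (inherits(background, "pwm")) unclass(background)[1, ]
             else rep(0.25, 4)
  model <- recenter_pwm(initial_pwm, bg_freq, L)
  prev_key <- NULL
  history <- data.frame(round = integer(0), n_sites = integer(0),
                        cutoff = numeric(0), jaccard = numeric(0))
  converged <- FALSE
  selected <- NULL
  cutoff <- NA_real_
  for (round in seq_len(max_rounds)) {
    scanned <- scan_fragments(model, background, fragments)
    if (nrow(scanned) == 0) stop("no scannable windows in the fragments")
    best <- tapply(scanned$score, scanned$fragment, max)
    cutoff <- choose_cutoff(as.numeric(best), tpr)
    selected <- .select_training_sites(scanned, cutoff, L)
    key <- sort(paste(selected$fragment, selected$offset, selected$strand))
    jac <- if (is.null(prev_key)) NA_real_ else
      length(intersect(key, prev_key)) / length(union(key, prev_key))
    history <- rbind(history, data.frame(round = round,
                                         n_sites = nrow(selected),
                                         cutoff = cutoff, jaccard = jac))
    if (!is.null(prev_key) && identical(key, prev_key)) {
      converged <- TRUE
      break
    }
    prev_key <- key
    sites <- site_set(selected$site)
    model <- switch(model_builder,
      pwm = recenter_pwm(estimate_pwm(sites, beta = beta1), bg_freq, L),
      pim = build_pim(sites, "all", beta1 = beta1, beta2 = beta2, ...)$params,
      nnm = build_pim(sites, "nearest_neighbor", beta1 = beta1,
                      beta2 = beta2, ...)$params,
      mixture = select_mixture(sites, K_max = K_max, beta = beta1,
                               seed = seed)$model)
  }
  if (!converged) {
    warning("site set did not stabilize within max_rounds; returning last state")
  }
  list(model = model, sites = site_set(selected$site), selected = selected,
       background = background, cutoff = cutoff, rounds = nrow(history),
       converged = converged, history = history)
}

#' Overlap between two predicted site lists
#'
#' Compares the `top_k` best-scoring sites per fragment between two scan
#' results by exact (fragment, offset, strand) identity. The shared
#' proportion is the number of matched sites divided by the attainable
#' matches `sum_f min(|A_f|, |B_f|)` over fragments present in both lists;
#' `difference = 1 - shared` (the quantity plotted per factor in site-set
#' comparisons).
#'
#' @param sites_a,sites_b Data.frames with fragment, offset, strand, score.
#' @param top_k Sites kept per fragment (1 or 2).
#' @return A list with `shared` and `difference`.
#' @export
overlap_report <- function(sites_a, sites_b, top_k = 1) {
  pick <- function(df) {
    df <- df[order(df$fragment, -df$score, df$offset, df$strand), ,
             drop = FALSE]
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$fragment), head,
                         n = top_k), use.names = FALSE)
    df[idx, , drop = FALSE]
  }
  a <- pick(sites_a)
  b <- pick(sites_b)
  frags <- intersect(unique(a$fragment), unique(b$fragment))
  shared_n <- 0L
  possible <- 0L
  for (f in frags) {
    ka <- with(a[a$fragment == f, ], paste(offset, strand))
    kb <- with(b[b$fragment == f, ], paste(offset, strand))
    shared_n <- shared_n + length(intersect(ka, kb))
    possible <- possible + min(length(ka), length(kb))
  }
  shared <- if (possible == 0) 0 else shared_n / possible
  list(shared = shared, difference = 1 - shared)
}
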