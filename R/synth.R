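#' Draw sites exactly from a model distribution
#'
#' Exact i.i.d. sampling: coupled components are enumerated and sampled as
#' joint categorical variables; uncoupled positions are sampled independently
#' from their field softmax. For a [pwm()] each position is categorical with
#' its row probabilities. No Markov chain is involved, so the sample is exact
#' at any size.
#'
#' @param model A [pim()] (coupled components capped at 12 positions) or a
#'   [pwm()].
#' @param n Number of sites to draw.
#' @param seed Optional seed.
#' @return A [site_set()] of n sites.
#' @export
sample_sites <- function(model, n, seed = NULL) {
  run <- function() {
    if (inherits(model, "pwm")) {
      L <- nrow(model)
      mat <- matrix(0L, n, L)
      for (i in seq_len(L)) {
        mat[, i] <- sample.int(4, n, replace = TRUE, prob = unclass(model)[i, ])
      }
      return(site_set(mat))
    }
    stopifnot(inherits(model, "pim"))
    L <- model$L
    mat <- matrix(0L, n, L)
    for (pos in .components(L, model$pairs)) {
      m <- length(pos)
      if (m == 1) {
        p <- exp(-model$h[pos, ])
        mat[, pos] <- sample.int(4, n, replace = TRUE, prob = p / sum(p))
      } else {
        idx <- setNames(seq_len(m), pos)
        ks <- which(model$pairs[, 1] %in% pos & model$pairs[, 2] %in% pos)
        sub_pairs <- matrix(0L, length(ks), 2)
        Jm <- matrix(0, 16, length(ks))
        for (t in seq_along(ks)) {
          k <- ks[t]
          sub_pairs[t, ] <- c(idx[[as.character(model$pairs[k, 1])]],
                              idx[[as.character(model$pairs[k, 2])]]) - 1L
          Jm[, t] <- as.vector(model$J[[k]])
        }
        E <- cpp_all_energies(model$h[pos, , drop = FALSE], sub_pairs, Jm)
        p <- exp(-(E - min(E)))
        draw <- sample.int(length(p), n, replace = TRUE, prob = p / sum(p))
        mat[, pos] <- .code_to_mat(draw, m)
      }
    }
    site_set(mat)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate background fragments with optional CpG-like dinucleotide bias
#'
#' Fragments are drawn from a first-order Markov chain whose stationary
#' single-nucleotide distribution equals `base_freqs` exactly while the C->G
#' transition is suppressed by `1 - dinucleotide_bias`. The chain is built by
#' scaling the CG cell of the product dinucleotide table and restoring both
#' marginals by iterative proportional fitting, so `bias = 0` gives an
#' i.i.d. background and `bias > 0` depletes CG below the product of its
#' marginals (the CpG depletion typical of mammalian genomes).
#'
#' @param length Fragment length in bp.
#' @param n_fragments Number of fragments.
#' @param base_freqs Stationary nucleotide frequencies (A,C,G,T), summing
#'   to 1; default uniform.
#' @param dinucleotide_bias CG suppression in `[0, 1)` (default 0).
#' @param seed Optional seed.
#' @return Named character vector of fragment sequences (`frag_1`, ...),
#'   with the transition matrix as attribute `transition`.
#' @export
sample_background <- function(length, n_fragments,
                              base_freqs = rep(0.25, 4),
                              dinucleotide_bias = 0, seed = NULL) {
  stopifnot(length >= 1, n_fragments >= 1,
            all(base_freqs > 0), abs(sum(base_freqs) - 1) < 1e-8,
            dinucleotide_bias >= 0, dinucleotide_bias < 1)
  W <- outer(base_freqs, base_freqs)
  W[2, 3] <- W[2, 3] * (1 - dinucleotide_bias)  # C->G cell
  for (it in seq_len(200)) {  # IPF back to the target marginals
    W <- W * (base_freqs / rowSums(W))
    W <- t(t(W) * (base_freqs / colSums(W)))
    if (max(abs(rowSums(W) - base_freqs)) < 1e-14) break
  }
  trans <- W / rowSums(W)
  run <- function() {
    mat <- matrix(0L, n_fragments, length)
    mat[, 1] <- sample.int(4, n_fragments, replace = TRUE, prob = base_freqs)
    for (t in seq(2, length.out = length - 1)) {
      u <- runif(n_fragments)
      cum <- t(apply(trans, 1, cumsum))
      prev <- mat[, t - 1]
      mat[, t] <- 1L + (u > cum[prev, 1]) + (u > cum[prev, 2]) +
        (u > cum[prev, 3])
    }
    frags <- decode_seq(mat)
    names(frags) <- paste0("frag_", seq_len(n_fragments))
    attr(frags, "transition") <- trans
    frags
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plant model-drawn sites into background fragments
#'
#' Samples sites from the model and writes each at a uniformly chosen
#' non-overlapping offset on a uniformly chosen strand (the reverse
#' complement is written when the minus strand is drawn). The truth table
#' records, per planted site, the fragment, the 1-based offset of the
#' occupied window on the plus-strand coordinates, the strand, and the site
#' as it reads on its strand.
#'
#' @param fragments Named character vector of fragments.
#' @param model A [pim()] or [pwm()] to draw sites from.
#' @param sites_per_fragment Sites planted per fragment (default 1).
#' @param seed Optional seed.
#' @param max_tries Rejection cap for non-overlapping placement.
#' @return A list with `fragments` (sites written in) and `truth`
#'   (data.frame: fragment, offset, strand, site).
#' @export
plant_sites <- function(fragments, model, sites_per_fragment = 1,
                        seed = NULL, max_tries = 100) {
  L <- if (inherits(model, "pwm")) nrow(model) else model$L
  if (sites_per_fragment == 0) {
    return(list(fragments = fragments,
                truth = data.frame(fragment = character(0),
                                   offset = integer(0),
                                   strand = character(0),
                                   site = character(0))))
  }
  if (min(nchar(fragments)) < L * sites_per_fragment) {
    stop("fragments too short for the requested number of sites")
  }
  run <- function() {
    total <- length(fragments) * sites_per_fragment
    drawn <- site_strings(sample_sites(model, total), expand = TRUE)
    ## sample_sites collapses duplicates; re-expand preserving randomness
    drawn <- sample(drawn, total)
    truth <- vector("list", length(fragments))
    out <- fragments
    t0 <- 0L
    for (f in seq_along(fragments)) {
      len <- nchar(out[f])
      offs <- integer(0)
      for (s in seq_len(sites_per_fragment)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          o <- sample.int(len - L + 1L, 1)
          if (all(abs(o - offs) >= L)) {
            offs <- c(offs, o)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place sites without overlap")
      }
      offs <- sort(offs)
      strands <- sample(c("+", "-"), sites_per_fragment, replace = TRUE)
      words <- drawn[t0 + seq_len(sites_per_fragment)]
      t0 <- t0 + sites_per_fragment
      seq_f <- out[f]
      for (s in seq_len(sites_per_fragment)) {
        w <- if (strands[s] == "+") words[s] else revcomp(words[s])
        substr(seq_f, offs[s], offs[s] + L - 1L) <- w
      }
      out[f] <- seq_f
      truth[[f]] <- data.frame(fragment = names(fragments)[f],
                               offset = offs, strand = strands,
                               site = words)
    }
    list(fragments = out, truth = do.call(rbind, truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Reference planted models for simulation studies
#'
#' Two ready-made PIMs used throughout the package's synthetic studies:
#' `"sharp"` concentrates nearly all probability on one consensus word
#' (strong fields, one mild adjacent coupling) and is the planted model for
#' site-recovery studies; `"two_basin"` superposes a field-favored word with
#' a second word stabilized by three mutual couplings among the positions
#' where the words differ, giving an energy landscape with two basins of
#' attraction.
#'
#' @param kind `"sharp"` or `"two_basin"`.
#' @param L Site length (default 12; must be >= 9).
#' @return A gauge-fixed [pim()].
#' @export
planted_pim <- function(kind = c("sharp", "two_basin"), L = 12) {
  kind <- match.arg(kind)
  stopifnot(L >= 9)
  if (kind == "sharp") {
    ## A/T-rich 5' half, G/C-rich 3' half: against an AT-rich background the
    ## information center of mass then sits decisively at one column, so the
    ## re-centering convention is not left on a rounding knife edge (an
    ## exactly symmetric profile centers between two columns and sampling
    ## noise would make the recovered window convention-dependent)
    w1 <- encode_seq(paste(rep(c("A", "T", "T", "A", "A", "T",
                                 "G", "C", "C", "G", "G", "C"),
                               length.out = L), collapse = ""))
    h <- matrix(0, L, 4)
    h[cbind(seq_len(L), w1)] <- -7
    J <- matrix(0, 4, 4)
    J[w1[5], w1[6]] <- -0.5
    return(fix_gauge(pim(L, h, cbind(5L, 6L), list(J))))
  }
  w1 <- encode_seq(paste(rep(c("T", "G", "A", "C"), length.out = L),
                         collapse = ""))
  h <- matrix(0, L, 4)
  ## two-basin: second word differs at positions 3, 6, 9 and is held
  ## together by pairwise couplings among those positions
  h[cbind(seq_len(L), w1)] <- -1.5
  d <- c(3L, 6L, 9L)
  w2 <- w1
  w2[d] <- (w1[d] %% 4L) + 1L  # a different letter at each flipped position
  mk <- function(a, b) {
    J <- matrix(0, 4, 4)
    J[a, b] <- -1.9
    J
  }
  pairs <- rbind(c(3L, 6L), c(3L, 9L), c(6L, 9L))
  J <- list(mk(w2[3], w2[6]), mk(w2[3], w2[9]), mk(w2[6], w2[9]))
  fix_gauge(pim(L, h, pairs, J))
}
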