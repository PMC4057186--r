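#' Energy descent to a local minimum
#'
#' From a starting L-mer, repeatedly applies single-nucleotide substitutions
#' that strictly lower the PIM energy until none exists. `"deterministic"`
#' takes the steepest decrease (ties broken by position, then alphabet
#' order); `"random"` picks uniformly among the strictly improving moves.
#' The energy strictly decreases at every step, so descent always terminates
#' at a local minimum.
#'
#' @param params A [pim()].
#' @param site An encoded integer vector, L-mer string, or single-row matrix.
#' @param mode `"deterministic"` (default) or `"random"`.
#' @param seed Optional seed for random mode.
#' @return The local-minimum site as an encoded integer vector, with
#'   attributes `energy` and `steps`.
#' @export
descend <- function(params, site, mode = c("deterministic", "random"),
                    seed = NULL) {
  mode <- match.arg(mode)
  s <- as.integer(.as_site_mat(site, params$L)[1, ])
  run <- function() .descend_one(params, s, mode)
  if (mode == "random" && !is.null(seed)) withr::with_seed(seed, run())
  else run()
}

.descend_one <- function(params, s, mode) {
  L <- params$L
  ## couplings touching each position, for O(degree) energy deltas
  touch <- vector("list", L)
  for (k in seq_len(nrow(params$pairs))) {
    i <- params$pairs[k, 1]; j <- params$pairs[k, 2]
    touch[[i]] <- c(touch[[i]], k)
    touch[[j]] <- c(touch[[j]], k)
  }
  e <- pim_energy(params, matrix(s, 1))
  steps <- 0L
  repeat {
    ## ΔE for substituting letter b at position i
    delta <- matrix(0, L, 4)
    for (i in seq_len(L)) {
      d <- params$h[i, ] - params$h[i, s[i]]
      for (k in touch[[i]]) {
        pi <- params$pairs[k, 1]; pj <- params$pairs[k, 2]
        if (pi == i) {
          d <- d + params$J[[k]][, s[pj]] - params$J[[k]][s[pi], s[pj]]
        } else {
          d <- d + params$J[[k]][s[pi], ] - params$J[[k]][s[pi], s[pj]]
        }
      }
      delta[i, ] <- d
    }
    improving <- which(delta < 0, arr.ind = TRUE)
    if (nrow(improving) == 0) break
    if (mode == "deterministic") {
      ## steepest; ties by position then alphabet order
      best <- which(delta == min(delta), arr.ind = TRUE)
      best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
      mv <- best[1, ]
    } else {
      mv <- improving[sample.int(nrow(improving), 1), ]
    }
    s[mv[1]] <- mv[2]
    e <- e + delta[mv[1], mv[2]]
    steps <- steps + 1L
  }
  structure(s, energy = as.numeric(e), steps = steps)
}

#' Basins of attraction of a site sample
#'
#' Descends every distinct site of the sample to its local energy minimum
#' and groups sites by terminal minimum. Basin weights are the member
#' fractions of N.
#'
#' @param params A [pim()].
#' @param sites A [site_set()].
#' @param mode Descent mode, see [descend()].
#' @param seed Seed for random mode.
#' @return A data.frame with one row per basin: `minimum` (L-mer string),
#'   `energy`, `n_members` (multiplicity-weighted), `weight`, ordered by
#'   decreasing weight; the per-site minima are attached as attribute
#'   `assignment` (character vector aligned with the distinct sites).
#' @export
find_basins <- function(params, sites, mode = c("deterministic", "random"),
                        seed = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    memo <- new.env(parent = emptyenv())
    mins <- character(nrow(sites$mat))
    ener <- numeric(nrow(sites$mat))
    for (r in seq_len(nrow(sites$mat))) {
      key <- paste(sites$mat[r, ], collapse = "")
      if (mode == "deterministic" && !is.null(memo[[key]])) {
        hit <- memo[[key]]
      } else {
        m <- .descend_one(params, as.integer(sites$mat[r, ]), mode)
        hit <- list(min = decode_seq(as.integer(m)),
                    energy = attr(m, "energy"))
        if (mode == "deterministic") memo[[key]] <- hit
      }
      mins[r] <- hit$min
      ener[r] <- hit$energy
    }
    agg <- rowsum(sites$counts, mins)
    basins <- data.frame(minimum = rownames(agg),
                         energy = ener[match(rownames(agg), mins)],
                         n_members = agg[, 1],
                         weight = agg[, 1] / sites$N)
    basins <- basins[order(-basins$weight, basins$minimum), ]
    rownames(basins) <- NULL
    attr(basins, "assignment") <- mins
    basins
  }
  if (mode == "random" && !is.null(seed)) withr::with_seed(seed, run())
  else run()
}

#' All local minima of a PIM by exhaustive enumeration
#'
#' Checks every one of the 4^L sites for single-substitution stability:
#' a site is a local minimum when none of its 3L neighbors has strictly
#' lower energy. Intended for small L (capped at 8).
#'
#' @param params A [pim()].
#' @return Character vector of local-minimum L-mers, sorted.
#' @export
enumerate_minima <- function(params) {
  L <- params$L
  if (L > 8) stop("exhaustive minima enumeration capped at L = 8")
  E <- all_energies(params)
  S <- length(E)
  code <- seq_len(S) - 1
  stable <- rep(TRUE, S)
  for (i in seq_len(L)) {
    digit <- (code %/% 4^(i - 1)) %% 4
    for (b in 0:3) {
      nbr <- code + (b - digit) * 4^(i - 1)
      stable <- stable & (E[nbr + 1] >= E)
    }
  }
  sort(decode_seq(.code_to_mat(which(stable), L)))
}

#' PWMs of the basins of attraction
#'
#' Learns one pseudo-counted PWM per basin from its member sites; weights
#' carry over from the basin weights.
#'
#' @param params A [pim()].
#' @param sites A [site_set()].
#' @param basins Output of [find_basins()] on the same sites (recomputed if
#'   omitted).
#' @param beta Pseudo-count for the per-basin PWMs.
#' @param mode,seed Passed to [find_basins()] when recomputing.
#' @return A list with `pwms` (list of [pwm()]), `weights`, `minima`
#'   (character), and `basins` (the basin table).
#' @export
basin_pwms <- function(params, sites, basins = NULL, beta = 1,
                       mode = "deterministic", seed = NULL) {
  if (is.null(basins)) basins <- find_basins(params, sites, mode, seed)
  assign <- attr(basins, "assignment")
  pwms <- vector("list", nrow(basins))
  for (b in seq_len(nrow(basins))) {
    sel <- assign == basins$minimum[b]
    sub <- site_set(sites$mat[sel, , drop = FALSE], sites$counts[sel])
    pwms[[b]] <- estimate_pwm(sub, beta = beta)
  }
  list(pwms = pwms, weights = basins$weight, minima = basins$minimum,
       basins = basins)
}

#' Match basin PWMs to mixture components by DKL
#'
#' Computes the position-summed DKL (bits) from every basin PWM to every
#' mixture component and assigns each basin to its nearest component.
#'
#' @param basin_set Output of [basin_pwms()].
#' @param mixture A [pwm_mix()] of the same site length.
#' @return A list with `dkl` (basins x components matrix, bits) and
#'   `assignment` (component index per basin).
#' @export
match_basins_to_mixture <- function(basin_set, mixture) {
  nb <- length(basin_set$pwms)
  D <- matrix(NA_real_, nb, mixture$K)
  for (b in seq_len(nb)) {
    for (k in seq_len(mixture$K)) {
      D[b, k] <- pwm_dkl(basin_set$pwms[[b]], mixture$components[[k]])
    }
  }
  list(dkl = D, assignment = apply(D, 1, which.min))
}

#' Write a basin report as a tab-separated table
#'
#' @param basin_set Output of [basin_pwms()].
#' @param match Optional output of [match_basins_to_mixture()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_basin_report <- function(basin_set, path, match = NULL) {
  tab <- basin_set$basins[, c("minimum", "energy", "weight")]
  if (!is.null(match)) {
    tab$component <- match$assignment
    tab$dkl <- match$dkl[cbind(seq_len(nrow(tab)), match$assignment)]
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
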