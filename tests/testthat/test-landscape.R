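test_that("descent terminates at the consensus for coupling-free models", {
  withr::with_seed(60, {
    m <- pim(5, matrix(rnorm(20), 5, 4))
  })
  consensus <- apply(m$h, 1, which.min)
  for (start in c(1, 17, 300, 1000)) {
    d <- descend(m, all_states(5)[start, ])
    expect_identical(as.integer(d), as.integer(consensus))
  }
  # starting at a minimum returns it unchanged with zero steps
  d0 <- descend(m, consensus)
  expect_identical(as.integer(d0), as.integer(consensus))
  expect_identical(attr(d0, "steps"), 0L)
})

test_that("deterministic descent matches exhaustive steepest descent at L=4", {
  m <- random_pim(4, rbind(c(1L, 2L), c(3L, 4L), c(2L, 3L)), seed = 61)
  E <- all_energies(m)
  states <- all_states(4)
  # independent exhaustive oracle: follow the steepest strictly-improving
  # single substitution by full neighbor enumeration
  oracle <- function(s) {
    repeat {
      e0 <- pim_energy(m, matrix(s, 1))
      best <- NULL; best_e <- e0
      for (i in 1:4) for (b in 1:4) {
        t <- s; t[i] <- b
        et <- pim_energy(m, matrix(t, 1))
        if (et < best_e - 1e-15) { best <- t; best_e <- et }
      }
      if (is.null(best)) return(s)
      s <- best
    }
  }
  withr::with_seed(62, idx <- sample.int(256, 40))
  for (r in idx) {
    expect_identical(as.integer(descend(m, states[r, ])),
                     as.integer(oracle(states[r, ])))
  }
  # energy strictly decreases and path length is bounded
  d <- descend(m, states[137, ])
  expect_lte(attr(d, "steps"), 3 * 4 * 4)
  expect_lte(attr(d, "energy"), pim_energy(m, states[137, , drop = FALSE]))
})

test_that("enumerated minima equal the single-substitution-stable set", {
  for (seed in 63:65) {
    m <- random_pim(4, rbind(c(1L, 3L), c(2L, 4L)), seed = seed, j_sd = 1.5)
    E <- all_energies(m)
    states <- all_states(4)
    stable <- vapply(seq_len(256), function(r) {
      s <- states[r, ]
      for (i in 1:4) for (b in 1:4) {
        t <- s; t[i] <- b
        if (pim_energy(m, matrix(t, 1)) < E[r] - 1e-15) return(FALSE)
      }
      TRUE
    }, logical(1))
    expect_identical(enumerate_minima(m), sort(decode_seq(states[stable, ])))
    # every deterministic descent ends in that set
    mins <- enumerate_minima(m)
    withr::with_seed(seed + 100, idx <- sample.int(256, 25))
    for (r in idx) {
      expect_true(decode_seq(as.integer(descend(m, states[r, ]))) %in% mins)
    }
  }
})

test_that("basins: single basin for coupling-free, two wells for the planted model", {
  withr::with_seed(66, m0 <- pim(4, matrix(rnorm(16), 4, 4)))
  s0 <- sample_sites(m0, 400, seed = 67)
  b0 <- find_basins(m0, s0)
  expect_identical(nrow(b0), 1L)
  expect_equal(b0$weight, 1)
  expect_identical(b0$minimum, decode_seq(apply(m0$h, 1, which.min)))

  tw <- planted_pim("two_basin", 12)
  s <- sample_sites(tw, 1500, seed = 68)
  b <- find_basins(tw, s)
  expect_gte(nrow(b), 2)
  expect_equal(sum(b$weight), 1)
  expect_gt(b$weight[2], 0.1)  # both wells carry substantial mass
  # both planted minima really are single-substitution stable
  for (w in b$minimum[1:2]) {
    e0 <- pim_energy(tw, w)
    v <- encode_seq(w)
    for (i in 1:12) for (a in 1:4) {
      t <- v; t[i] <- a
      expect_gte(pim_energy(tw, matrix(t, 1)), e0 - 1e-12)
    }
  }
})

test_that("random and deterministic descent agree on basin weights", {
  # deep two-well model: the mode-consistency property presumes clearly
  # separated basins (shallow ridges make boundary paths genuinely ambiguous)
  w1 <- encode_seq("TGACTGACTGAC")
  h <- matrix(0, 12, 4)
  h[cbind(1:12, w1)] <- -3
  d <- c(3L, 6L, 9L)
  w2 <- w1; w2[d] <- (w1[d] %% 4L) + 1L
  mk <- function(a, b) { J <- matrix(0, 4, 4); J[a, b] <- -4.5; J }
  deep <- fix_gauge(pim(12, h, rbind(c(3L, 6L), c(3L, 9L), c(6L, 9L)),
                        list(mk(w2[3], w2[6]), mk(w2[3], w2[9]),
                             mk(w2[6], w2[9]))))
  s <- sample_sites(deep, 1200, seed = 69)
  det <- find_basins(deep, s, mode = "deterministic")
  expect_gte(nrow(det), 2)
  for (seed in 1:3) {
    rnd <- find_basins(deep, s, mode = "random", seed = seed)
    shared <- intersect(det$minimum, rnd$minimum)
    expect_gte(length(shared), 2)
    dw <- det$weight[match(shared, det$minimum)]
    rw <- rnd$weight[match(shared, rnd$minimum)]
    expect_lt(max(abs(dw - rw)), 0.02)
  }
})

test_that("basin PWMs reflect their wells and match mixture components by DKL", {
  tw <- planted_pim("two_basin", 12)
  s <- sample_sites(tw, 2000, seed = 70)
  bp <- basin_pwms(tw, s)
  expect_equal(sum(bp$weights), 1)
  # the top-weight basin PWMs peak on their minima
  for (b in 1:2) {
    cons <- decode_seq(apply(unclass(bp$pwms[[b]]), 1, which.max))
    expect_identical(cons, bp$minima[b])
  }
  # identity matching when the mixture is the basin PWMs themselves
  mix <- pwm_mix(bp$pwms[1:2], bp$weights[1:2] / sum(bp$weights[1:2]))
  m2 <- match_basins_to_mixture(list(pwms = bp$pwms[1:2]), mix)
  expect_identical(m2$assignment, 1:2)
  expect_equal(diag(m2$dkl), c(0, 0), tolerance = 1e-12)
  expect_true(all(m2$dkl >= 0))
  # permuting the mixture components permutes the assignment
  mixp <- pwm_mix(bp$pwms[2:1], rep(0.5, 2))
  mp <- match_basins_to_mixture(list(pwms = bp$pwms[1:2]), mixp)
  expect_identical(mp$assignment, 2:1)
})
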