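test_that("dkl closed forms and support handling", {
  expect_equal(dkl(c(.3, .7), c(.3, .7)), 0)
  expect_equal(dkl(c(1, 0), c(.5, .5)), 1)
  expect_identical(dkl(c(.5, .5), c(1, 0)), Inf)
  withr::with_seed(80, {
    p <- runif(16); q <- runif(16)
    expect_gte(dkl(p, q), 0)
  })
})

test_that("self-DKL matches the chi-square asymptotic and is reproducible", {
  u <- pim(1)  # uniform 4-state model
  res <- self_dkl(u, 100, reps = 400, seed = 81)
  expect_equal(res$mean, 3 / (2 * 100 * log(2)), tolerance = 0.15)
  res2 <- self_dkl(u, 100, reps = 400, seed = 81)
  expect_identical(res$values, res2$values)
  # consistency: mean shrinks ~ 1/N
  big <- self_dkl(u, 4000, reps = 60, seed = 82)
  expect_lt(big$mean, res$mean / 10)
})

test_that("direct fields: independence at J = 0 and tight marginal matching", {
  f1 <- c(.4, .3, .2, .1); f2 <- c(.1, .2, .3, .4)
  sol <- solve_direct_fields(matrix(0, 4, 4), f1, f2)
  expect_equal(sol$P_dir, outer(f1, f2), tolerance = 1e-9)
  expect_equal(direct_information(sol, f1, f2), 0, tolerance = 1e-9)
  withr::with_seed(83, {
    for (r in 1:5) {
      J <- matrix(rnorm(16), 4, 4)
      s <- solve_direct_fields(J, f1, f2)
      expect_lt(s$residual, 1e-10)
      expect_equal(rowSums(s$P_dir), f1, tolerance = 1e-9)
      expect_equal(colSums(s$P_dir), f2, tolerance = 1e-9)
      expect_equal(s$h_i[4], 0)  # anchored at T
      # DI is symmetric under relabeling the two positions
      st <- solve_direct_fields(t(J), f2, f1)
      expect_equal(direct_information(s, f1, f2),
                   direct_information(st, f2, f1), tolerance = 1e-8)
    }
  })
})

test_that("strong same-letter coupling saturates DI at 2 bits", {
  sol <- solve_direct_fields(-20 * diag(4), rep(.25, 4), rep(.25, 4))
  expect_equal(direct_information(sol, rep(.25, 4), rep(.25, 4)), 2,
               tolerance = 1e-4)
})

test_that("for an L=2 single-coupling model DI equals the model MI", {
  for (seed in 84:86) {
    m <- random_pim(2, cbind(1L, 2L), seed = seed)
    mm <- model_marginals(m)
    sol <- solve_direct_fields(m$J[[1]], mm$f1[1, ], mm$f1[2, ])
    di <- direct_information(sol, mm$f1[1, ], mm$f1[2, ])
    mi <- mutual_information(mm$f2[["1_2"]], mm$f1[1, ], mm$f1[2, ])
    expect_equal(di, mi, tolerance = 1e-6)
  }
})

test_that("mutual information closed forms", {
  expect_equal(mutual_information(outer(c(.4, .3, .2, .1), c(.1, .2, .3, .4))),
               0, tolerance = 1e-12)
  expect_equal(mutual_information(diag(4) / 4), 2)
  withr::with_seed(87, {
    f <- matrix(runif(16), 4, 4); f <- f / sum(f)
    expect_gte(mutual_information(f), 0)
  })
})

test_that("normalization maps independence to 0 and deterministic copy to 1", {
  expect_equal(normalized_information(0, 1.3, 0.8), 0)
  expect_equal(normalized_information(2, 2, 2), 1)  # copied uniform position
  expect_equal(normalized_information(0, 0, 0), 0)  # no variability
  # NDI <= 1 across random models (DI bounded by the min marginal entropy)
  withr::with_seed(88, {
    for (r in 1:5) {
      f1 <- runif(4, .05, 1); f1 <- f1 / sum(f1)
      f2 <- runif(4, .05, 1); f2 <- f2 / sum(f2)
      J <- matrix(rnorm(16, 0, 1.5), 4, 4)
      s <- solve_direct_fields(J, f1, f2)
      di <- direct_information(s, f1, f2)
      H <- c(-sum(f1 * log2(f1)), -sum(f2 * log2(f2)))
      expect_lte(normalized_information(di, H[1], H[2]), 1 + 1e-9)
    }
  })
})

test_that("info_matrices: zero DI off the coupling support, symmetry, bounds", {
  m <- fix_gauge(random_pim(4, rbind(c(1L, 3L)), seed = 89, j_sd = 1))
  s <- sample_sites(m, 4000, seed = 90)
  fr <- empirical_frequencies(s)
  im <- info_matrices(m, fr)
  expect_equal(im$DI, t(im$DI))
  expect_equal(diag(im$NDI), rep(0, 4))
  expect_gt(im$NDI[1, 3], 0)
  expect_equal(im$DI[1, 2], 0)  # no coupling there
  expect_true(all(im$NDI >= 0 & im$NDI <= 1 + 1e-9))
  expect_true(all(im$NMI >= 0 & im$NMI <= 1 + 1e-9))
})

test_that("interactions are more localized than correlations on a chain", {
  chain <- random_pim(6, cbind(1:5, 2:6), seed = 91, h_sd = 0.3, j_sd = 1.2)
  s <- sample_sites(chain, 6000, seed = 92)
  ft <- fit_pim(s, chain$pairs)
  im <- info_matrices(ft$params, empirical_frequencies(s))
  expect_lte(participation_ratio(im$NDI^2),
             participation_ratio(im$NMI^2))
})

test_that("participation ratio limits and scale invariance", {
  w <- matrix(1, 6, 6); diag(w) <- 0
  expect_equal(participation_ratio(w), 1)
  w1 <- matrix(0, 6, 6); w1[2, 5] <- w1[5, 2] <- 4
  expect_equal(participation_ratio(w1), 2 / (6 * 5))
  withr::with_seed(93, {
    r <- matrix(runif(36), 6, 6); r <- r + t(r); diag(r) <- 0
    expect_equal(participation_ratio(r), participation_ratio(3.7 * r),
                 tolerance = 1e-12)
  })
  expect_warning(participation_ratio(matrix(0, 3, 3)), "undefined")
})

test_that("distance profile is flat for uniform weights and sums to one", {
  w <- matrix(1, 5, 5); diag(w) <- 0
  prof <- distance_profile(w)
  expect_equal(unname(prof), rep(0.25, 4))
  wn <- matrix(0, 5, 5)
  for (i in 1:4) wn[i, i + 1] <- wn[i + 1, i] <- 1
  pn <- distance_profile(wn)
  expect_equal(unname(pn[1]), 1)
  expect_equal(sum(pn), 1)
})

test_that("positional sums: zeros, single pair, orientation averaging", {
  expect_equal(positional_interaction_sum(matrix(0, 4, 4)), rep(0, 4))
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 0.6
  s <- positional_interaction_sum(w)
  expect_equal(s, c(0.6, 0.6, 0, 0))
  sym <- matrix(0.2, 4, 4); diag(sym) <- 0
  expect_equal(positional_interaction_sum(sym, orientation_average = TRUE),
               positional_interaction_sum(sym))
})
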