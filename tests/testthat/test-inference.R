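test_that("estimate_pwm implements the pseudo-count rule", {
  s <- site_set(c("AA", "AC", "AG"))  # position 1: (3,0,0,0); position 2: (1,1,1,0)
  p <- estimate_pwm(s, beta = 1)
  expect_equal(unclass(p)[1, ], c(A = 4, C = 1, G = 1, T = 1) / 7)
  expect_equal(unclass(p)[2, ], c(A = 2, C = 2, G = 2, T = 1) / 7)
  p0 <- estimate_pwm(s, beta = 0)
  expect_equal(unname(unclass(p0)[1, ]), c(1, 0, 0, 0))

  s2 <- site_set(c("AC", "AC", "GT"), counts = c(3, 1, 4))
  expect_equal(unname(unclass(estimate_pwm(s2, 0))[1, ]), c(0.5, 0, 0.5, 0))
})

test_that("empirical frequencies are consistent and scale-invariant", {
  s <- site_set("AA")
  f <- empirical_frequencies(s, beta1 = 0, beta2 = 0)
  expect_equal(unname(f$f2[["1_2"]][1, 1]), 1)
  expect_equal(sum(f$f2[["1_2"]]), 1)

  s2 <- site_set(c("ACG", "TTG", "ACG", "CGA"))
  f2 <- empirical_frequencies(s2, beta1 = 0, beta2 = 0)
  expect_equal(rowSums(f2$f2[["1_3"]]), f2$f1[1, ], tolerance = 1e-12)
  # duplication leaves frequencies unchanged
  s2dup <- site_set(rep(c("ACG", "TTG", "ACG", "CGA"), 2))
  f2dup <- empirical_frequencies(s2dup, beta1 = 0, beta2 = 0)
  expect_equal(f2dup$f2, f2$f2, tolerance = 1e-12)
  # default beta2 = beta1/4 keeps pair tables marginally consistent with f1
  fp <- empirical_frequencies(s2, beta1 = 1)
  expect_equal(rowSums(fp$f2[["2_3"]]), fp$f1[2, ], tolerance = 1e-12)
})

test_that("fix_gauge enforces the zero-sum conditions without moving probabilities", {
  m <- random_pim(3, rbind(c(1L, 2L), c(2L, 3L)), seed = 20)
  g <- fix_gauge(m)
  expect_true(is_gauge_fixed(g, 1e-10))
  expect_equal(pim_probability(g, all_states(3)),
               pim_probability(m, all_states(3)), tolerance = 1e-10)
  # idempotence
  g2 <- fix_gauge(g)
  expect_equal(g2$h, g$h, tolerance = 1e-12)
  expect_equal(g2$J, g$J, tolerance = 1e-12)
  # constant field rows vanish
  mc <- pim(2, matrix(c(3, 3, 3, 3, -1, -1, -1, -1), 2, 4, byrow = TRUE))
  expect_equal(unname(fix_gauge(mc)$h), matrix(0, 2, 4))
  # a block with constant rows is absorbed entirely into the fields
  J <- outer(c(1, 2, -1, 0.5), rep(1, 4))  # J(a, b) = r(a)
  mj <- pim(2, matrix(0, 2, 4), cbind(1L, 2L), list(J))
  gj <- fix_gauge(mj)
  expect_equal(max(abs(gj$J[[1]])), 0, tolerance = 1e-12)
  # by-hand application of the centering identities
  expect_equal(unname(gj$h[1, ]),
               c(1, 2, -1, 0.5) - mean(c(1, 2, -1, 0.5)), tolerance = 1e-12)
})

test_that("coupling-free fit reproduces the PWM product distribution", {
  withr::with_seed(21, {
    s <- sample_sites(pwm(matrix(runif(16, 0.05, 1), 4, 4)), 400)
  })
  ft <- fit_pim(s, NULL, tol = 1e-6)
  fr <- empirical_frequencies(s)
  expect_lt(max(abs(model_marginals(ft$params)$f1 - fr$f1)), 1e-6)
  # full distribution equals the product of the pseudo-counted marginals
  pw <- pwm(fr$f1)
  expect_equal(pim_probability(ft$params, all_states(4)),
               pwm_probability(pw, all_states(4)), tolerance = 1e-4)
})

test_that("full-pair fit at L=2 reproduces the pseudo-counted joint", {
  withr::with_seed(22, {
    s <- site_set(decode_seq(matrix(sample.int(4, 600, TRUE,
                                               prob = c(.5, .2, .2, .1)),
                                    300, 2)))
  })
  ft <- fit_pim(s, cbind(1L, 2L), tol = 1e-6)
  fr <- empirical_frequencies(s)
  mm <- model_marginals(ft$params)
  expect_lt(max(abs(mm$f2[["1_2"]] - fr$f2[["1_2"]])), 1e-6)
})

test_that("fit is initialization-independent (convexity)", {
  withr::with_seed(23, {
    s <- sample_sites(random_pim(3, rbind(c(1L, 2L)), seed = 30), 500)
  })
  f1 <- fit_pim(s, rbind(c(1L, 2L), c(2L, 3L)), tol = 1e-6)
  init <- random_pim(3, rbind(c(1L, 2L), c(2L, 3L)), seed = 31)
  f2 <- fit_pim(s, rbind(c(1L, 2L), c(2L, 3L)), init = init, tol = 1e-6)
  expect_equal(pim_probability(f1$params, all_states(3)),
               pim_probability(f2$params, all_states(3)), tolerance = 1e-4)
})

test_that("the plain fixed-step schedule reaches the same fixed point", {
  withr::with_seed(24, {
    s <- sample_sites(random_pim(2, rbind(c(1L, 2L)), seed = 32, h_sd = 0.5,
                                 j_sd = 0.4), 400)
  })
  fa <- fit_pim(s, cbind(1L, 2L), tol = 1e-6, adapt = TRUE)
  fp <- fit_pim(s, cbind(1L, 2L), tol = 1e-6, adapt = FALSE, max_iter = 2e5)
  expect_equal(pim_probability(fa$params, all_states(2)),
               pim_probability(fp$params, all_states(2)), tolerance = 1e-4)
  expect_gt(fp$iterations, fa$iterations)  # adaptive gain converges faster
})

test_that("select_next_pair finds planted correlation by exact binomial tails", {
  withr::with_seed(25, {
    a <- sample.int(4, 400, TRUE)
    c3 <- sample.int(4, 400, TRUE)
    s <- site_set(decode_seq(cbind(a, a, c3)))  # positions 1-2 perfectly correlated
  })
  base <- fit_pim(s, NULL)
  sel <- select_next_pair(base$params, s)
  expect_identical(sel$pair, c(1L, 2L))
  # the score is the smallest of the by-hand per-cell binomial tails
  marg <- model_marginals(base$params)
  byhand <- min(vapply(1:16, function(c) {
    pimotif:::.binom_two_sided(round(pair_counts(s, 1, 2))[c], s$N,
                               marg$f2[["1_2"]][c])
  }, numeric(1)))
  expect_equal(sel$score, byhand)
  # exhausted universe
  done <- select_next_pair(base$params, s,
                           excluded = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_null(done$pair)
})

test_that("a pair is always proposed while candidates remain, with i < j", {
  s3 <- site_set(rep(c("AAA", "CCC", "GGG", "TTT",
                       "ACG", "CAT", "GTA", "TGC"), 2))
  base <- fit_pim(s3, NULL)
  sel <- select_next_pair(base$params, s3)
  expect_false(is.null(sel$pair))
  expect_true(sel$pair[1] < sel$pair[2])
})

test_that("bic arithmetic follows -logL + (k/2) log N", {
  expect_equal(bic_score(12.5, 0, 100), 12.5)
  expect_equal(bic_score(0, 9, exp(2)) - bic_score(0, 0, exp(2)), 9)
  b <- vapply(0:5, function(k) bic_score(3, k, 50), numeric(1))
  expect_true(all(diff(b) > 0))
  expect_equal(pim_param_count(12, 0), 36)
  expect_equal(pim_param_count(12, 4), 72)
})

test_that("greedy BIC selection is parsimonious on PWM data and finds planted pairs", {
  withr::with_seed(26, {
    s <- sample_sites(pwm(matrix(runif(24, 0.05, 1), 6, 4)), 2000)
  })
  res <- build_pim(s)
  expect_lte(nrow(res$params$pairs), 2)
  # likelihood never decreases along the greedy trace
  expect_true(all(diff(res$trace$nll) < 1e-6))

  planted <- random_pim(5, rbind(c(2L, 3L)), seed = 33, h_sd = 0.3, j_sd = 1.2)
  sp <- sample_sites(planted, 3000, seed = 34)
  full <- build_pim(sp)
  nnm <- build_pim(sp, "nearest_neighbor")
  expect_identical(c(full$trace$pair_i[2], full$trace$pair_j[2]), c(2L, 3L))
  expect_identical(c(nnm$trace$pair_i[2], nnm$trace$pair_j[2]), c(2L, 3L))
})

test_that("NNM never beats the full PIM on planted non-adjacent couplings", {
  planted <- random_pim(5, rbind(c(1L, 4L), c(2L, 5L)), seed = 35,
                        h_sd = 0.3, j_sd = 1.2)
  s <- sample_sites(planted, 3000, seed = 36)
  full <- build_pim(s)
  nnm <- build_pim(s, "nearest_neighbor")
  expect_gte(nnm$bic, full$bic)
  expect_lte(nrow(nnm$params$pairs), 4)  # universe size L-1
})

test_that("parameter recovery at scale from exactly sampled sites", {
  pairs <- rbind(c(1L, 4L), c(2L, 3L), c(4L, 5L), c(5L, 8L), c(6L, 7L))
  blk <- function(c) c * (diag(4) - 0.25)
  truth <- fix_gauge(pim(8, matrix(0, 8, 4), pairs,
                         list(-blk(1), blk(0.8), -blk(0.9), blk(1),
                              -blk(0.7))))
  s <- sample_sites(truth, 50000, seed = 1)
  ft <- fit_pim(s, truth$pairs, tol = 1e-5)
  expect_true(ft$converged)
  expect_lt(max(abs(ft$params$h - truth$h)), 0.05)
  expect_lt(max(abs(unlist(ft$params$J) - unlist(truth$J))), 0.05)
})
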