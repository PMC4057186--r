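test_that("background learning is strand-symmetric", {
  polyA <- setNames(rep(strrep("A", 50), 3), paste0("f", 1:3))
  bg <- learn_background(polyA, 12)
  q <- unclass(bg)[1, ]
  expect_equal(q[["A"]], q[["T"]])
  expect_gt(q[["A"]], q[["C"]])
  expect_equal(q[["C"]], q[["G"]])

  rand <- sample_background(300, 40, seed = 120)
  bgr <- learn_background(rand, 12)
  expect_equal(unname(unclass(bgr)[1, ]), rep(0.25, 4), tolerance = 0.02)
  expect_error(learn_background(setNames("ACGT", "x"), 12), "no valid windows")
})

test_that("log-odds scores: zero at model==background, antisymmetric, positive at consensus", {
  bg <- pwm(matrix(0.25, 6, 4))
  expect_equal(score_site(bg, bg, "ACGTAC"), 0)
  sharp <- pwm(matrix(c(.91, .03, .03, .03), 6, 4, byrow = TRUE))
  expect_gt(score_site(sharp, bg, "AAAAAA"), 0)
  expect_equal(score_site(sharp, bg, "AAAAAA"),
               -score_site(bg, sharp, "AAAAAA"))
})

test_that("scanning produces (len - L + 1) windows per strand and skips N", {
  bg <- pwm(matrix(0.25, 4, 4))
  m <- pwm(matrix(c(.7, .1, .1, .1), 4, 4, byrow = TRUE))
  hits <- scan_fragments(m, bg, c(f1 = "ACGT"))
  expect_identical(nrow(hits), 2L)
  hits2 <- scan_fragments(m, bg, c(f1 = "ACGTA"))
  expect_identical(nrow(hits2), 4L)
  withN <- scan_fragments(m, bg, c(f1 = "ACGTNACGT"))  # windows crossing N drop
  expect_identical(nrow(withN), 4L)
  # palindromic window scores equally on both strands (site reads the same)
  hitsp <- scan_fragments(m, bg, c(f1 = "AGCT"))
  expect_identical(hitsp$site[1], hitsp$site[2])
  expect_equal(hitsp$score[1], hitsp$score[2])
  # minus-strand site is the reverse complement of the slice
  nonpal <- scan_fragments(m, bg, c(f1 = "AACG"))
  expect_identical(nonpal$site[nonpal$strand == "-"], revcomp("AACG"))
})

test_that("cutoff is the order statistic with tie handling", {
  expect_equal(choose_cutoff(c(3, 2, 1, 0), 0.5), 2)
  expect_equal(sum(c(3, 2, 1, 0) >= choose_cutoff(c(3, 2, 1, 0), 0.5)), 2)
  expect_equal(choose_cutoff(rep(1.5, 6), 0.5), 1.5)  # all pass on ties
  expect_equal(choose_cutoff(c(5, 4, 1), 1.0), 1)     # tpr = 1: the minimum
})

test_that("re-centering pads with background and centers the information mass", {
  bgq <- c(.3, .2, .2, .3)
  sharp4 <- pwm(matrix(c(.91, .03, .03, .03), 4, 4, byrow = TRUE))
  out <- recenter_pwm(sharp4, bgq, 12)
  expect_identical(nrow(out), 12L)
  ic <- pwm_information(out, bgq)
  inside <- which(ic > 0.5)
  expect_identical(length(inside), 4L)
  expect_true(all(diff(inside) == 1))  # contiguous original columns
  # flanks are exactly the background
  expect_equal(unname(unclass(out)[1, ]), bgq)
  # uniform input against a uniform background -> all-background output
  # (no information anywhere; the center defaults to the input midpoint)
  unif <- recenter_pwm(pwm(matrix(0.25, 5, 4)), rep(0.25, 4), 12)
  expect_equal(unname(unclass(unif)), matrix(0.25, 12, 4),
               ignore_attr = TRUE)
  # length-L input with symmetric information stays put
  sym <- pwm(matrix(rep(c(.7, .1, .1, .1), 12), 12, 4, byrow = TRUE))
  expect_equal(unclass(recenter_pwm(sym, rep(.25, 4), 12)), unclass(sym),
               tolerance = 1e-12)
})

test_that("training-site selection keeps non-overlapping windows above cutoff", {
  scanned <- data.frame(
    fragment = "f1",
    offset = c(1L, 3L, 20L, 40L),
    strand = c("+", "+", "-", "+"),
    site = c("AAAA", "AAAC", "CCCC", "GGGG"),
    score = c(5, 7, 6, 1))
  sel <- pimotif:::.select_training_sites(scanned, 2, 4)
  # offset 3 (score 7) wins over overlapping offset 1; offset 40 is below cutoff
  expect_identical(sort(sel$offset), c(3L, 20L))
})

test_that("refinement converges on planted consensus fragments and recovers the PWM", {
  sharp <- planted_pim("sharp", 12)
  frags <- sample_background(150, 120, base_freqs = c(.3, .2, .2, .3),
                             seed = 121)
  pl <- plant_sites(frags, sharp, 1, seed = 122)
  init <- estimate_pwm(sample_sites(sharp, 40, seed = 123))
  ref <- iterate_refinement(init, pl$fragments, "pwm", L = 12, seed = 124)
  expect_true(ref$converged)
  expect_lte(ref$rounds, 4)
  key_t <- paste(pl$truth$fragment, pl$truth$offset, pl$truth$strand)
  key_s <- paste(ref$selected$fragment, ref$selected$offset,
                 ref$selected$strand)
  expect_gt(mean(key_s %in% key_t), 0.9)  # selected sites are planted sites
  # determinism: identical seeds give identical site sets
  ref2 <- iterate_refinement(init, pl$fragments, "pwm", L = 12, seed = 124)
  expect_identical(ref$selected, ref2$selected)

  # learned PWM matches the generating single-site distribution
  mm <- model_marginals(sharp)
  withr::with_seed(125, {
    s5k <- sample_sites(sharp, 5000)
  })
  learned <- estimate_pwm(s5k, beta = 0)
  expect_lt(max(abs(unclass(learned) - mm$f1)), 0.03)
})

test_that("refinement site sets are fixed points of re-scoring", {
  sharp <- planted_pim("sharp", 12)
  frags <- sample_background(120, 80, base_freqs = c(.3, .2, .2, .3),
                             seed = 126)
  pl <- plant_sites(frags, sharp, 1, seed = 127)
  init <- estimate_pwm(sample_sites(sharp, 40, seed = 128))
  ref <- iterate_refinement(init, pl$fragments, "pwm", L = 12, seed = 129)
  scanned <- scan_fragments(ref$model, ref$background, pl$fragments)
  best <- tapply(scanned$score, scanned$fragment, max)
  cut <- choose_cutoff(as.numeric(best), 0.5)
  resel <- pimotif:::.select_training_sites(scanned, cut, 12)
  expect_identical(sort(paste(resel$fragment, resel$offset, resel$strand)),
                   sort(paste(ref$selected$fragment, ref$selected$offset,
                              ref$selected$strand)))
  # at least half the fragments contribute sites
  expect_gte(length(unique(ref$selected$fragment)), ceiling(80 / 2))
})

test_that("overlap report counts shared per-fragment best sites", {
  a <- data.frame(fragment = c("f1", "f2"), offset = c(5L, 9L),
                  strand = "+", score = c(2, 3))
  expect_equal(overlap_report(a, a)$difference, 0)
  b <- a; b$offset <- c(50L, 90L)
  expect_equal(overlap_report(a, b)$difference, 1)
  half <- a; half$offset <- c(5L, 77L)  # half shared
  expect_equal(overlap_report(a, half)$difference, 0.5)
})
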