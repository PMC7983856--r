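# Mixed-mating likelihood kernels, EM estimator, maternal inference,
# bootstrap.

test_that("selfing kernel matches Mendelian gamete enumeration", {
  # homozygous mother transmits her allele with certainty
  expect_equal(self_offspring_prob(c(1L, 1L), c(1L, 1L)), 1.0)
  # heterozygous mother: 4 ordered gamete pairs
  expect_equal(self_offspring_prob(c(1L, 1L), c(1L, 2L)), 0.25)
  expect_equal(self_offspring_prob(c(1L, 2L), c(1L, 2L)), 0.5)
  expect_equal(self_offspring_prob(c(2L, 2L), c(1L, 2L)), 0.25)
  # allele absent from the mother is impossible under selfing
  expect_equal(self_offspring_prob(c(1L, 3L), c(1L, 2L)), 0)
  # random spot checks against the enumeration oracle
  set.seed(11)
  for (i in 1:50) {
    mom <- sort(sample.int(4L, 2L, replace = TRUE))
    off <- sort(sample.int(4L, 2L, replace = TRUE))
    expect_equal(self_offspring_prob(off, mom), oracle_self_prob(off, mom))
  }
})

test_that("outcross kernel combines maternal gamete and pollen pool", {
  p <- c("1" = 0.7, "2" = 0.3)
  expect_equal(outcross_offspring_prob(c(1L, 2L), c(1L, 1L), p), 0.3)
  p2 <- c("1" = 0.5, "2" = 0.5)
  expect_equal(outcross_offspring_prob(c(1L, 1L), c(1L, 2L), p2), 0.25)
  # no shared maternal allele -> impossible
  expect_equal(outcross_offspring_prob(c(2L, 2L), c(1L, 1L), p), 0)
  set.seed(12)
  for (i in 1:50) {
    mom <- sort(sample.int(3L, 2L, replace = TRUE))
    off <- sort(sample.int(3L, 2L, replace = TRUE))
    pr <- runif(3) + 0.05
    pr <- pr / sum(pr)
    names(pr) <- as.character(1:3)
    expect_equal(outcross_offspring_prob(off, mom, pr),
                 oracle_outcross_prob(off, mom, pr))
  }
})

make_pool <- function(freq_list) structure(freq_list, class = "pollen_pool")

test_that("EM matches exhaustive grid maximization on small families", {
  set.seed(21)
  for (rep in 1:10) {
    fam <- random_small_family(n_off = sample(4:10, 1),
                               n_loci = sample(1:3, 1))
    est <- em_estimate(fam$array, fam$mom, fam$pollen, tol = 1e-12,
                       max_iter = 10000L)
    s_grid <- oracle_grid_shat(fam$array, fam$mom, fam$pollen)
    expect_lt(abs(est$s - s_grid), 1e-4)
    # the EM optimum dominates the oracle likelihood at the grid argmax
    expect_gte(oracle_loglik(min(max(est$s, 1e-12), 1 - 1e-12),
                             fam$array, fam$mom, fam$pollen),
               oracle_loglik(min(max(s_grid, 1e-12), 1 - 1e-12),
                             fam$array, fam$mom, fam$pollen) - 1e-6)
  }
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  set.seed(22)
  for (rep in 1:10) {
    fam <- random_small_family(n_off = 10, n_loci = 2)
    est <- em_estimate(fam$array, fam$mom, fam$pollen, s_init = runif(1))
    trace <- attr(est, "ll_trace")
    expect_true(all(diff(trace) >= -1e-10))
  }
})

test_that("offspring incompatible with selfing drive tm to exactly 1", {
  # mother 1/1; every offspring 1/2: L_self = 0, L_out > 0
  off <- matrix(rep(c(1L, 2L), 10), ncol = 2, byrow = TRUE)
  arr <- progeny_array("f", "p", off, "L1")
  pool <- make_pool(list(L1 = c("1" = 0.5, "2" = 0.5)))
  est <- em_estimate(arr, c(1L, 1L), pool)
  expect_identical(est$s, 0)
  expect_identical(est$tm, 1)
})

test_that("flat likelihood (het mother, even pollen, 1 locus) keeps s at s_init", {
  # with p = (1/2, 1/2) the selfing and outcrossing kernels coincide for
  # every offspring genotype (1/4, 1/2, 1/4), so the likelihood is flat
  off <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 2L), ncol = 2, byrow = TRUE)
  arr <- progeny_array("f", "p", off, "L1")
  pool <- make_pool(list(L1 = c("1" = 0.5, "2" = 0.5)))
  est <- em_estimate(arr, c(1L, 2L), pool, s_init = 0.37)
  expect_equal(est$s, 0.37, tolerance = 1e-9)
  expect_true(est$converged)
})

test_that("mother-offspring mismatch loci are demoted to missing and counted", {
  # locus 1 informative; locus 2: offspring 3/3 shares no allele with a 1/1
  # mother -> mismatch
  off <- matrix(c(1L, 1L, 3L, 3L,
                  1L, 2L, 1L, 1L), ncol = 4, byrow = TRUE)
  arr <- progeny_array("f", "p", off, c("L1", "L2"))
  pool <- make_pool(list(L1 = c("1" = 0.5, "2" = 0.5),
                         L2 = c("1" = 0.5, "3" = 0.5)))
  est <- em_estimate(arr, c(1L, 1L, 1L, 1L), pool)
  expect_identical(est$n_mismatch_loci, 1L)
  expect_identical(est$n_offspring_used, 2L)
})

test_that("family with no informative offspring errors", {
  off <- matrix(NA_integer_, 3, 2)
  arr <- progeny_array("f", "p", off, "L1")
  pool <- make_pool(list(L1 = c("1" = 1)))
  expect_error(em_estimate(arr, c(1L, 1L), pool), "no informative offspring")
})

test_that("maternal genotype inference recovers the mother", {
  pool <- make_pool(list(L1 = c("1" = 0.5, "2" = 0.5)))
  # 20/20 homozygous 1/1 offspring -> mother 1/1
  off <- matrix(1L, 20, 2)
  arr <- progeny_array("f", "p", off, "L1")
  inf <- infer_maternal_genotype(arr, pool)
  expect_identical(inf$genotype, c(1L, 1L))
  # both homozygote classes present among offspring -> mother must be 1/2
  # (a homozygous mother gives zero selfing mass to the other homozygote)
  off2 <- matrix(c(rep(c(1L, 1L), 5), rep(c(2L, 2L), 5), rep(c(1L, 2L), 10)),
                 ncol = 2, byrow = TRUE)
  arr2 <- progeny_array("f", "p", off2, "L1")
  inf2 <- infer_maternal_genotype(arr2, pool)
  expect_identical(inf2$genotype, c(1L, 2L))
  # provided maternal genotype short-circuits inference
  arr3 <- progeny_array("f", "p", off2, "L1", mother = c(2L, 2L))
  inf3 <- infer_maternal_genotype(arr3, pool)
  expect_identical(inf3$genotype, c(2L, 2L))
  # all-missing locus stays missing
  off4 <- matrix(NA_integer_, 5, 2)
  arr4 <- progeny_array("f", "p", off4, "L1")
  inf4 <- infer_maternal_genotype(arr4, pool)
  expect_true(all(is.na(inf4$genotype)))
})

test_that("pollen pool smoothing covers offspring-only alleles", {
  off <- matrix(c(1L, 2L), 1, 2)
  arr <- list(progeny_array("f", "p", off, "L1", mother = c(1L, 1L)))
  mothers <- matrix(c(1L, 1L), 1, 2)
  pool <- build_pollen_pool(arr, mothers)
  expect_gt(pool[["L1"]][["2"]], 0)
  expect_equal(sum(pool[["L1"]]), 1)
  # two homozygous mothers, no smoothing -> equal frequencies
  arr2 <- list(
    progeny_array("f1", "p", matrix(c(1L, 1L), 1, 2), "L1", mother = c(1L, 1L)),
    progeny_array("f2", "p", matrix(c(2L, 2L), 1, 2), "L1", mother = c(2L, 2L))
  )
  pool2 <- build_pollen_pool(arr2, matrix(c(1L, 1L, 2L, 2L), 2, 2, byrow = TRUE),
                             smoothing = 0)
  expect_equal(unname(pool2[["L1"]]), c(0.5, 0.5))
})

test_that("bootstrap SE/CI behave at the edges", {
  pool <- make_pool(list(L1 = c("1" = 0.6, "2" = 0.4)))
  off <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 2L), ncol = 2,
                byrow = TRUE)
  arr <- progeny_array("f", "p", off, "L1")
  # B = 1: SE undefined, reported absent
  b1 <- bootstrap_family(arr, c(1L, 2L), pool, B = 1L, seed = 5)
  expect_true(is.na(b1$bootstrap_se))
  # degenerate family (identical offspring): SE exactly 0
  offd <- matrix(rep(c(1L, 1L), 8), ncol = 2, byrow = TRUE)
  arrd <- progeny_array("fd", "p", offd, "L1")
  bd <- bootstrap_family(arrd, c(1L, 1L), pool, B = 30L, seed = 6)
  expect_equal(bd$bootstrap_se, 0)
  expect_true(bd$ci_low <= bd$tm && bd$tm <= bd$ci_high)
})

test_that("estimate_mating handles per-population locus subsets", {
  set.seed(31)
  cfg5 <- sim_config(n_families = 4, n_loci = 5, missing_rate = 0)
  sim5 <- simulate_population(cfg5, 1)
  cfg6 <- sim_config(n_families = 4, n_loci = 6, missing_rate = 0)
  sim6 <- simulate_population(cfg6, 2)
  e5 <- estimate_mating(sim5$arrays)
  e6 <- estimate_mating(sim6$arrays)
  expect_identical(nrow(e5), 4L)
  expect_identical(nrow(e6), 4L)
  expect_true(all(e5$s >= 0 & e5$s <= 1))
  expect_true(all(e6$tm + e6$s == 1))
})
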