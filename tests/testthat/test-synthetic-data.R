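# Forward simulator: allele frequencies, maternal genotypes, herkogamy,
# progeny arrays with culling, fitness experiment, reproducibility.

test_that("allele frequency draws are valid Dirichlet samples", {
  cfg <- sim_config(n_loci = 4, alleles_per_locus = c(2, 3, 5, 8))
  set.seed(61)
  fr <- draw_allele_frequencies(cfg)
  expect_identical(lengths(fr), c(2L, 3L, 5L, 8L))
  for (p in fr) {
    expect_true(all(p > 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # huge concentration -> near-uniform frequencies
  cfgU <- sim_config(n_loci = 1, alleles_per_locus = 4,
                     allele_freq_concentration = 1e6)
  set.seed(62)
  pu <- draw_allele_frequencies(cfgU)[[1]]
  expect_equal(unname(pu), rep(0.25, 4), tolerance = 0.01)
  # Dirichlet(1) moments: per-entry mean 1/k over many draws
  cfg5 <- sim_config(n_loci = 1, alleles_per_locus = 5,
                     allele_freq_concentration = 1)
  set.seed(63)
  draws <- replicate(10000, draw_allele_frequencies(cfg5)[[1]])
  expect_equal(unname(rowMeans(draws)), rep(0.2, 5), tolerance = 0.01)
  expect_error(sim_config(allele_freq_concentration = 0), "positive")
})

test_that("maternal genotypes follow the inbreeding-adjusted HWE law", {
  fr <- list(L1 = c("1" = 0.5, "2" = 0.5))
  set.seed(64)
  # F = 1: no heterozygotes
  g1 <- draw_maternal_genotypes(fr, 500, adult_F = 1)
  expect_true(all(g1[, 1] == g1[, 2]))
  # F = 0: heterozygosity ~ 2pq = 0.5
  g0 <- draw_maternal_genotypes(fr, 4000, adult_F = 0)
  expect_equal(mean(g0[, 1] != g0[, 2]), 0.5, tolerance = 0.03)
  # F = -1 at p = 0.5: all heterozygotes
  gm <- draw_maternal_genotypes(fr, 500, adult_F = -1)
  expect_true(all(gm[, 1] != gm[, 2]))
  # infeasible F errors, naming the locus
  fr2 <- list(L1 = c("1" = 0.9, "2" = 0.1))
  expect_error(draw_maternal_genotypes(fr2, 10, adult_F = -0.5),
               "infeasible at locus 1")
})

test_that("maternal draws at adult_F = 0 pass HWE chi-square at nominal rate", {
  set.seed(65)
  fr <- list(L1 = c("1" = 0.6, "2" = 0.4))
  n_rep <- 200L
  rej <- 0L
  for (i in seq_len(n_rep)) {
    g <- draw_maternal_genotypes(fr, 300, adult_F = 0)
    counts <- c(sum(g[, 1] == 1 & g[, 2] == 1),
                sum(g[, 1] != g[, 2]),
                sum(g[, 1] == 2 & g[, 2] == 2))
    p <- (2 * counts[1] + counts[2]) / 600
    expected <- 300 * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((counts - expected)^2 / expected)
    if (stats::pchisq(x2, df = 1, lower.tail = FALSE) < 0.05) rej <- rej + 1L
  }
  # nominal 5% rejection, binomial tolerance
  expect_lt(abs(rej / n_rep - 0.05), 0.045)
})

test_that("herkogamy simulation honors its variance structure", {
  cfg0 <- sim_config(n_families = 5, herkogamy_sd_among = 2,
                     herkogamy_sd_within = 0)
  set.seed(66)
  h0 <- simulate_herkogamy(cfg0)
  within_sd <- tapply(h0$herkogamy, h0$plant, sd)
  expect_true(all(within_sd < 1e-12))
  cfg00 <- sim_config(n_families = 5, herkogamy_sd_among = 0,
                      herkogamy_sd_within = 0, herkogamy_mean = 2.57)
  h00 <- simulate_herkogamy(cfg00)
  expect_true(all(h00$herkogamy == 2.57))
  # variance-components recovery: sd_among 2, sd_within 1 -> share 0.8
  cfgv <- sim_config(n_families = 500, herkogamy_sd_among = 2,
                     herkogamy_sd_within = 1, flowers_per_plant = c(5, 5))
  set.seed(67)
  hv <- simulate_herkogamy(cfgv)
  vc <- variance_components(hv)
  expect_equal(vc$proportion_among, 0.8, tolerance = 0.05)
})

test_that("progeny arrays obey Mendelian and mixed-mating structure", {
  loci <- "L1"
  freqs <- list(L1 = c("1" = 0, "2" = 1))  # pollen fixed for allele 2
  mothers <- genotype_matrix(matrix(c(1L, 1L), 1), loci)
  cfg <- sim_config(n_families = 1, n_progeny = 30, n_loci = 1,
                    missing_rate = 0)
  set.seed(68)
  sim <- simulate_progeny_arrays(cfg, mothers, s_true = 0, freqs = freqs)
  off <- sim$arrays[[1]]$offspring
  expect_true(all(off[, 1] == 1 & off[, 2] == 2))
  # full selfing of a heterozygous mother: 1:2:1
  freqs2 <- list(L1 = c("1" = 0.5, "2" = 0.5))
  mothers2 <- genotype_matrix(matrix(c(1L, 2L), 1), loci)
  cfg2 <- sim_config(n_families = 1, n_progeny = 4000, n_loci = 1,
                     missing_rate = 0, delta_true = 0)
  set.seed(69)
  sim2 <- simulate_progeny_arrays(cfg2, mothers2, s_true = 1, freqs = freqs2)
  off2 <- sim2$arrays[[1]]$offspring
  het <- mean(off2[, 1] != off2[, 2])
  hom1 <- mean(off2[, 1] == 1 & off2[, 2] == 1)
  expect_equal(het, 0.5, tolerance = 0.04)
  expect_equal(hom1, 0.25, tolerance = 0.03)
})

test_that("culling shifts the genotyped selfed fraction below s_true", {
  # s_true = 0.5, delta = 0.5 -> genotyped selfed fraction 1/3
  freqs <- list(L1 = c("1" = 0.5, "2" = 0.5))
  mothers <- genotype_matrix(matrix(c(1L, 2L), 1), "L1")
  cfg <- sim_config(n_families = 1, n_progeny = 6000, n_loci = 1,
                    missing_rate = 0, delta_true = 0.5)
  set.seed(70)
  sim <- simulate_progeny_arrays(cfg, mothers, s_true = 0.5, freqs = freqs)
  expect_equal(sim$truth$realized_selfed, 1 / 3, tolerance = 0.03)
})

test_that("simulation is reproducible bytewise and configs validate", {
  cfg <- sim_config(n_families = 4, n_progeny = 5)
  a <- simulate_population(cfg, 99)
  b <- simulate_population(cfg, 99)
  ta <- withr::local_tempfile(); tb <- withr::local_tempfile()
  write_progeny_table(a$arrays, ta)
  write_progeny_table(b$arrays, tb)
  expect_identical(readLines(ta), readLines(tb))
  expect_identical(a$herkogamy, b$herkogamy)
  expect_identical(a$fitness, b$fitness)
  rec1 <- simulate_fitness_experiment(cfg, seed = 5)
  rec2 <- simulate_fitness_experiment(cfg, seed = 5)
  expect_identical(rec1, rec2)
  expect_error(sim_config(delta_true = 1.3), "\\[0,1\\]")
  expect_error(sim_config(n_progeny = 0), ">= 1")
  expect_error(sim_config(alleles_per_locus = 1), ">= 2")
})

test_that("optional null-allele corruption produces mother-offspring mismatches", {
  cfg <- sim_config(n_families = 8, n_progeny = 20, null_allele_rate = 1,
                    missing_rate = 0, allele_freq_concentration = 5)
  set.seed(71)
  sim <- simulate_population(cfg, 12)
  est <- estimate_mating(sim$arrays)
  # with every locus carrying a silent allele, some offspring should look
  # incompatible with their (true) mothers and be demoted, not crash
  expect_true(sum(est$n_mismatch_loci) > 0)
  expect_true(all(est$s >= 0 & est$s <= 1))
})
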