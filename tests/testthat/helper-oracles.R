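# Independent brute-force oracles for the mixed-mating likelihood.
# These enumerate gametes directly and never call the package's kernels,
# so agreement with the EM path is a genuine cross-check.

oracle_self_prob <- function(off, mom) {
  # enumerate the 4 ordered maternal gamete pairs
  p <- 0
  for (g1 in mom) for (g2 in mom) {
    if (setequal2(c(g1, g2), off)) p <- p + 0.25
  }
  p
}

oracle_outcross_prob <- function(off, mom, pollen) {
  p <- 0
  for (g1 in mom) {
    for (a in names(pollen)) {
      if (setequal2(c(g1, as.integer(a)), off)) {
        p <- p + 0.5 * unname(pollen[[a]])
      }
    }
  }
  p
}

setequal2 <- function(x, y) {
  identical(sort(as.integer(unname(x))), sort(as.integer(unname(y))))
}

# Per-offspring multilocus likelihood components computed by enumeration
# (mismatch loci dropped, matching the model's stated missing-data
# treatment); shared by the loglik and grid oracles below.
oracle_components <- function(array, mom, pollen) {
  n <- nrow(array$offspring)
  Ls <- numeric(0); Lo <- numeric(0)
  for (i in seq_len(n)) {
    ls <- 1; lo_prod <- 1; inf <- 0L
    for (l in seq_along(array$loci)) {
      cc <- c(2L * l - 1L, 2L * l)
      off <- array$offspring[i, cc]
      m <- mom[cc]
      if (anyNA(off) || anyNA(m)) next
      lo <- oracle_outcross_prob(off, m, pollen[[l]])
      if (lo == 0) next  # mismatch: demoted to missing
      ls <- ls * oracle_self_prob(off, m)
      lo_prod <- lo_prod * lo
      inf <- inf + 1L
    }
    if (inf == 0L) next
    Ls <- c(Ls, ls); Lo <- c(Lo, lo_prod)
  }
  list(Ls = Ls, Lo = Lo)
}

# Multilocus mixture log-likelihood at selfing rate s for one family.
oracle_loglik <- function(s, array, mom, pollen) {
  cmp <- oracle_components(array, mom, pollen)
  sum(log(s * cmp$Ls + (1 - s) * cmp$Lo))
}

# Exhaustive grid maximization of the same likelihood.
oracle_grid_shat <- function(array, mom, pollen, step = 1e-4) {
  cmp <- oracle_components(array, mom, pollen)
  grid <- seq(0, 1, by = step)
  # avoid log(0) at the exact boundary when a component is zero
  sg <- pmin(pmax(grid, 1e-12), 1 - 1e-12)
  lls <- vapply(sg, function(s) sum(log(s * cmp$Ls + (1 - s) * cmp$Lo)),
                numeric(1))
  grid[which.max(lls)]
}

# Small random family generator for oracle comparisons (independent of the
# package simulator: plain R draws).
random_small_family <- function(n_off, n_loci, k = 3L) {
  pollen <- lapply(seq_len(n_loci), function(l) {
    p <- runif(k) + 0.1
    p <- p / sum(p)
    names(p) <- as.character(seq_len(k))
    p
  })
  mom <- unlist(lapply(seq_len(n_loci), function(l) sort(sample.int(k, 2L, TRUE))))
  s_true <- runif(1)
  off <- matrix(NA_integer_, n_off, 2L * n_loci)
  for (i in seq_len(n_off)) {
    for (l in seq_len(n_loci)) {
      cc <- c(2L * l - 1L, 2L * l)
      a <- mom[cc][sample.int(2L, 1L)]
      b <- if (runif(1) < s_true) {
        mom[cc][sample.int(2L, 1L)]
      } else {
        as.integer(sample(names(pollen[[l]]), 1L, prob = pollen[[l]]))
      }
      off[i, cc] <- c(a, b)
    }
  }
  list(
    array = progeny_array("fam", "pop", off, paste0("L", seq_len(n_loci))),
    mom = mom, pollen = structure(pollen, class = "pollen_pool"),
    s_true = s_true
  )
}

# Balanced one-way expected-mean-squares variance-component estimates
# (closed form, independent of REML).
ems_variance_components <- function(values, plant) {
  plant <- factor(plant)
  k <- unique(table(plant))
  stopifnot(length(k) == 1L)  # balanced only
  n <- nlevels(plant)
  means <- tapply(values, plant, mean)
  grand <- mean(values)
  msb <- k * sum((means - grand)^2) / (n - 1)
  msw <- sum((values - means[plant])^2) / (n * (k - 1))
  list(sigma2_within = msw, sigma2_among = max((msb - msw) / k, 0))
}

# Beta-regression negative log-likelihood for the grid oracle,
# written directly from the density (no package code).
oracle_beta_ll <- function(b0, b1, phi, y, x, linkinv) {
  mu <- pmin(pmax(linkinv(b0 + b1 * x), 1e-10), 1 - 1e-10)
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}
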