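#' Simulation configuration for a study population
#'
#' Defines the generative model used for parameter-recovery validation:
#' maternal plants with plant-level herkogamy (among- and within-plant
#' normal components), family selfing rates tied to plant mean herkogamy
#' through a logistic link, Mendelian progeny arrays drawn under the
#' mixed-mating model with early culling of selfed zygotes (emulating
#' early-acting inbreeding depression, which makes the genotyped selfing
#' rate s sit below the primary rate r), and a paired self/outcross
#' hand-pollination fitness experiment.
#'
#' Defaults describe the Mapimi-like condition: 29 maternal families of 20
#' genotyped progeny at 6 microsatellite loci with 5 alleles each, positive
#' mean herkogamy (2.57 mm) with 77% of its variance among plants, and
#' delta_true = 0.25. [sim_config_cm()] gives the contrasting
#' Canada-Moreno-like condition (27 families, 5 loci, mean herkogamy
#' -4.72 mm with ~51% of variance among plants, delta_true = 0.09).
#'
#' @param population population label.
#' @param n_families number of maternal families.
#' @param n_progeny genotyped offspring per family.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus allele count per locus (scalar or per-locus).
#' @param allele_freq_concentration symmetric Dirichlet concentration for
#'   allele frequencies; larger values give more even frequencies.
#' @param adult_F inbreeding coefficient of the adult (maternal) cohort used
#'   when drawing maternal genotypes; must satisfy
#'   `adult_F >= -p/(1-p)` for every allele frequency p.
#' @param herkogamy_mean population mean herkogamy, mm (pistil minus stamen).
#' @param herkogamy_sd_among among-plant standard deviation, mm.
#' @param herkogamy_sd_within within-plant (flower-to-flower) sd, mm.
#' @param flowers_per_plant integer range `c(min, max)` of measured flowers.
#' @param selfing_intercept,selfing_slope logit-scale intercept/slope mapping
#'   plant mean herkogamy to the family's primary selfing rate; the default
#'   slope is negative (more herkogamous plants self less).
#' @param delta_true probability that a selfed zygote is culled before
#'   genotyping (early inbreeding depression), in `[0, 1)`.
#' @param missing_rate per-locus probability of a missing genotype call.
#' @param null_allele_rate optional stress-test: probability that a locus
#'   carries a silent (non-amplifying) allele; off by default.
#' @param n_mothers,fruits_per_treatment,fruit_set_prob crossing-experiment
#'   design: candidate mothers, flowers pollinated per treatment, and the
#'   probability each flower sets a fruit (mothers lacking a fruit in either
#'   treatment are dropped, as in greenhouse practice).
#' @param seedset_out_mean mean seed-set (seeds/ovules) of outcrossed fruits.
#' @param seedset_phi beta precision of seed-set around its mean.
#' @param seed_mass_mean,seed_mass_sd per-seed mass distribution, mg.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(population = "Map",
                       n_families = 29L,
                       n_progeny = 20L,
                       n_loci = 6L,
                       alleles_per_locus = 5L,
                       allele_freq_concentration = 1,
                       adult_F = 0,
                       herkogamy_mean = 2.57,
                       herkogamy_sd_among = 9.80,
                       herkogamy_sd_within = 5.31,
                       flowers_per_plant = c(4L, 6L),
                       selfing_intercept = -0.38,
                       selfing_slope = -0.15,
                       delta_true = 0.25,
                       missing_rate = 0.02,
                       null_allele_rate = 0,
                       n_mothers = 100L,
                       fruits_per_treatment = 2L,
                       fruit_set_prob = 0.8,
                       seedset_out_mean = 0.8,
                       seedset_phi = 30,
                       seed_mass_mean = 9,
                       seed_mass_sd = 1.5) {
  cfg <- list(
    population = as.character(population),
    n_families = as.integer(n_families),
    n_progeny = as.integer(n_progeny),
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(rep_len(alleles_per_locus, n_loci)),
    allele_freq_concentration = allele_freq_concentration,
    adult_F = adult_F,
    herkogamy_mean = herkogamy_mean,
    herkogamy_sd_among = herkogamy_sd_among,
    herkogamy_sd_within = herkogamy_sd_within,
    flowers_per_plant = as.integer(flowers_per_plant),
    selfing_intercept = selfing_intercept,
    selfing_slope = selfing_slope,
    delta_true = delta_true,
    missing_rate = missing_rate,
    null_allele_rate = null_allele_rate,
    n_mothers = as.integer(n_mothers),
    fruits_per_treatment = as.integer(fruits_per_treatment),
    fruit_set_prob = fruit_set_prob,
    seedset_out_mean = seedset_out_mean,
    seedset_phi = seedset_phi,
    seed_mass_mean = seed_mass_mean,
    seed_mass_sd = seed_mass_sd
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @export
sim_config_cm <- function(...) {
  base <- list(
    population = "CM", n_families = 27L, n_loci = 5L,
    herkogamy_mean = -4.72,
    herkogamy_sd_among = 5.5 * sqrt(0.5062),
    herkogamy_sd_within = 5.5 * sqrt(0.4938),
    selfing_intercept = 0.17, delta_true = 0.09
  )
  over <- list(...)
  do.call(sim_config, utils::modifyList(base, over))
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c(delta_true = cfg$delta_true, missing_rate = cfg$missing_rate,
             null_allele_rate = cfg$null_allele_rate,
             fruit_set_prob = cfg$fruit_set_prob,
             seedset_out_mean = cfg$seedset_out_mean)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop("probabilities must lie in [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$delta_true >= 1) stop("delta_true must be < 1", call. = FALSE)
  if (cfg$n_families < 1L || cfg$n_progeny < 1L || cfg$n_loci < 1L ||
      cfg$n_mothers < 1L || cfg$fruits_per_treatment < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (any(cfg$alleles_per_locus < 2L)) {
    stop("alleles_per_locus must be >= 2", call. = FALSE)
  }
  if (cfg$allele_freq_concentration <= 0) {
    stop("allele_freq_concentration must be positive", call. = FALSE)
  }
  if (cfg$herkogamy_sd_among < 0 || cfg$herkogamy_sd_within < 0) {
    stop("herkogamy sd parameters must be >= 0", call. = FALSE)
  }
  if (cfg$adult_F < -1 || cfg$adult_F > 1) {
    stop("adult_F must lie in [-1, 1]", call. = FALSE)
  }
  if (length(cfg$flowers_per_plant) != 2L ||
      any(cfg$flowers_per_plant < 1L) ||
      cfg$flowers_per_plant[1L] > cfg$flowers_per_plant[2L]) {
    stop("flowers_per_plant must be an increasing pair of counts",
         call. = FALSE)
  }
  cfg
}

#' Draw per-locus allele frequency vectors
#'
#' Symmetric Dirichlet draw per locus; the concentration controls evenness.
#'
#' @param config a [sim_config()].
#' @return list of named numeric vectors (names are allele codes "1"..."k"),
#'   each strictly positive and summing to 1.
#' @export
draw_allele_frequencies <- function(config) {
  validate_sim_config(config)
  conc <- config$allele_freq_concentration
  lapply(seq_len(config$n_loci), function(l) {
    k <- config$alleles_per_locus[l]
    x <- stats::rgamma(k, shape = conc, rate = 1)
    # guard against an all-zero draw at tiny concentrations
    while (sum(x) == 0) x <- stats::rgamma(k, shape = conc, rate = 1)
    p <- x / sum(x)
    p[p == 0] <- .Machine$double.xmin
    p <- p / sum(p)
    names(p) <- as.character(seq_len(k))
    p
  })
}

# Unordered genotype distribution at one locus under inbreeding F:
# P(ii) = p_i^2 + F p_i (1-p_i); P(ij) = 2 p_i p_j (1-F).
genotype_distribution <- function(p, F) {
  k <- length(p)
  pairs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  prob <- ifelse(pairs[, 1L] == pairs[, 2L],
                 p[pairs[, 1L]]^2 + F * p[pairs[, 1L]] * (1 - p[pairs[, 1L]]),
                 2 * p[pairs[, 1L]] * p[pairs[, 2L]] * (1 - F))
  list(a = pairs[, 1L], b = pairs[, 2L], prob = prob)
}

#' Draw maternal multilocus genotypes for the adult cohort
#'
#' Genotype frequencies follow the inbreeding-adjusted Hardy-Weinberg law
#' `P(ii) = p_i^2 + F p_i (1 - p_i)`, `P(ij) = 2 p_i p_j (1 - F)`.
#'
#' @param freqs list of per-locus allele frequency vectors
#'   (see [draw_allele_frequencies()]).
#' @param n_families number of mothers to draw.
#' @param adult_F adult-cohort inbreeding coefficient.
#' @return integer matrix `n_families x 2*n_loci` (a genotype matrix).
#' @export
draw_maternal_genotypes <- function(freqs, n_families, adult_F = 0) {
  n_loci <- length(freqs)
  g <- matrix(NA_integer_, n_families, 2L * n_loci)
  for (l in seq_len(n_loci)) {
    p <- freqs[[l]]
    dist <- genotype_distribution(p, adult_F)
    if (any(dist$prob < -1e-12)) {
      i <- dist$a[which.min(dist$prob)]
      stop(sprintf(
        "adult_F = %.3f infeasible at locus %d: requires F >= %.4f (allele %s)",
        adult_F, l, -p[i] / (1 - p[i]), names(p)[i]), call. = FALSE)
    }
    prob <- pmax(dist$prob, 0)
    idx <- sample.int(length(prob), n_families, replace = TRUE, prob = prob)
    g[, locus_cols(l)] <- cbind(dist$a[idx], dist$b[idx])
  }
  genotype_matrix(g, names(freqs) %||% paste0("L", seq_len(n_loci)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-flower herkogamy measurements
#'
#' Flower value = population mean + plant effect (Normal, sd_among) +
#' flower effect (Normal, sd_within).
#'
#' @param config a [sim_config()].
#' @param plant_means optional vector of pre-drawn plant mean herkogamies
#'   (mm), used to keep herkogamy consistent with family selfing rates.
#' @return data.frame with columns population, plant, flower, herkogamy,
#'   plus a `plant_means` attribute carrying the true plant effects.
#' @export
simulate_herkogamy <- function(config, plant_means = NULL) {
  validate_sim_config(config)
  n <- config$n_families
  if (is.null(plant_means)) {
    plant_means <- config$herkogamy_mean +
      stats::rnorm(n, 0, config$herkogamy_sd_among)
  }
  stopifnot(length(plant_means) == n)
  nf <- sample(seq(config$flowers_per_plant[1L], config$flowers_per_plant[2L]),
               n, replace = TRUE)
  # the measured plants are the maternal plants, so plant ids double as
  # family ids downstream
  plant_ids <- sprintf("%s_F%02d", config$population, seq_len(n))
  out <- data.frame(
    population = config$population,
    plant = rep(plant_ids, nf),
    flower = unlist(lapply(nf, seq_len)),
    herkogamy = rep(plant_means, nf) +
      stats::rnorm(sum(nf), 0, config$herkogamy_sd_within),
    stringsAsFactors = FALSE
  )
  attr(out, "plant_means") <- stats::setNames(plant_means, plant_ids)
  out
}

# One Mendelian gamete per locus from an unordered maternal pair.
draw_gamete <- function(pair) pair[sample.int(2L, 1L)]

# Draw a single offspring multilocus genotype (vector of length 2*n_loci).
draw_offspring <- function(mother, freqs, selfed) {
  n_loci <- length(freqs)
  g <- integer(2L * n_loci)
  for (l in seq_len(n_loci)) {
    cc <- locus_cols(l)
    m <- mother[cc]
    a <- draw_gamete(m)
    b <- if (selfed) draw_gamete(m) else {
      p <- freqs[[l]]
      as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
    }
    g[cc] <- c(a, b)
  }
  g
}

#' Simulate progeny arrays under the mixed-mating model
#'
#' Each offspring is selfed with probability `s_true[fam]` (both gametes
#' Mendelian from the mother) or outcrossed (one maternal gamete, one pollen
#' gamete from the population pool). Selfed zygotes are culled with
#' probability `delta_true` and redrawn, so each array reaches `n_progeny`
#' genotyped offspring; culling pushes the realized (genotyped) selfed
#' fraction below the primary rate `s_true` — the selfing-rate vs
#' primary-selfing-rate distinction the r correction undoes.
#'
#' @param config a [sim_config()].
#' @param maternal_genotypes genotype matrix of mothers
#'   (see [draw_maternal_genotypes()]).
#' @param s_true per-family primary selfing rates in `[0, 1]`.
#' @param freqs per-locus pollen-pool allele frequencies.
#' @return list with `arrays` (list of [progeny_array()]) and `truth`
#'   (data.frame: family, s_true, realized_selfed — genotyped selfed
#'   fraction after culling) plus `freqs` and `delta_true` attributes.
#' @export
simulate_progeny_arrays <- function(config, maternal_genotypes, s_true, freqs) {
  validate_sim_config(config)
  n_fam <- nrow(maternal_genotypes)
  stopifnot(length(s_true) == n_fam, all(s_true >= 0 & s_true <= 1))
  loci <- geno_loci(maternal_genotypes) %||% paste0("L", seq_along(freqs))
  null_allele <- NULL
  if (config$null_allele_rate > 0) {
    null_allele <- lapply(freqs, function(p) {
      if (stats::runif(1) < config$null_allele_rate) {
        as.integer(names(p)[which.min(p)])
      } else NA_integer_
    })
  }
  arrays <- vector("list", n_fam)
  realized <- numeric(n_fam)
  for (f in seq_len(n_fam)) {
    mom <- maternal_genotypes[f, ]
    off <- matrix(NA_integer_, config$n_progeny, 2L * length(freqs))
    n_self <- 0L
    for (i in seq_len(config$n_progeny)) {
      repeat {
        selfed <- stats::runif(1) < s_true[f]
        if (selfed && stats::runif(1) < config$delta_true) next  # culled
        break
      }
      if (selfed) n_self <- n_self + 1L
      off[i, ] <- draw_offspring(mom, freqs, selfed)
    }
    # silent (null) alleles: heterozygote carriers look homozygous for the
    # amplifying allele, null homozygotes fail entirely
    if (!is.null(null_allele)) {
      for (l in seq_along(freqs)) {
        na_code <- null_allele[[l]]
        if (is.na(na_code)) next
        cc <- locus_cols(l)
        both <- off[, cc[1L]] == na_code & off[, cc[2L]] == na_code
        off[both, cc] <- NA_integer_
        one1 <- off[, cc[1L]] == na_code & !both
        off[which(one1), cc[1L]] <- off[which(one1), cc[2L]]
        one2 <- off[, cc[2L]] == na_code & !both
        off[which(one2), cc[2L]] <- off[which(one2), cc[1L]]
      }
    }
    # missing calls, per offspring-locus
    if (config$missing_rate > 0) {
      for (l in seq_along(freqs)) {
        miss <- stats::runif(config$n_progeny) < config$missing_rate
        off[miss, locus_cols(l)] <- NA_integer_
      }
    }
    fam_id <- sprintf("%s_F%02d", config$population, f)
    arrays[[f]] <- progeny_array(fam_id, config$population, off, loci,
                                 mother = mom)
    realized[f] <- n_self / config$n_progeny
  }
  truth <- data.frame(
    family = vapply(arrays, function(a) a$family, character(1)),
    s_true = s_true, realized_selfed = realized,
    stringsAsFactors = FALSE
  )
  structure(list(arrays = arrays, truth = truth),
            freqs = freqs, delta_true = config$delta_true)
}

#' Simulate the paired self/outcross pollination experiment
#'
#' Per candidate mother, `fruits_per_treatment` flowers per treatment each
#' set a fruit with probability `fruit_set_prob`; mothers lacking a fruit in
#' either treatment are excluded (mirroring greenhouse attrition). Seed-set
#' is Beta-distributed with the self-treatment mean reduced by the factor
#' `1 - delta_true`; per-seed mass has the same distribution in both
#' treatments, so the fitness ratio ws/wo recovers `1 - delta_true` in
#' expectation.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (set for reproducible records).
#' @return data.frame: population, mother, treatment (`self`/`outcross`),
#'   fruit, seed_set, seed_mass.
#' @export
simulate_fitness_experiment <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (m in seq_len(config$n_mothers)) {
    mother_id <- sprintf("%s_D%03d", config$population, m)
    fruits <- list(self = integer(0), outcross = integer(0))
    for (tr in c("self", "outcross")) {
      set <- stats::runif(config$fruits_per_treatment) < config$fruit_set_prob
      fruits[[tr]] <- which(set)
    }
    if (!length(fruits$self) || !length(fruits$outcross)) next
    for (tr in c("self", "outcross")) {
      mu <- config$seedset_out_mean *
        (if (tr == "self") 1 - config$delta_true else 1)
      phi <- config$seedset_phi
      for (fr in fruits[[tr]]) {
        ss <- stats::rbeta(1, mu * phi, (1 - mu) * phi)
        sm <- max(stats::rnorm(1, config$seed_mass_mean, config$seed_mass_sd),
                  0.1)
        rows[[length(rows) + 1L]] <- data.frame(
          population = config$population, mother = mother_id, treatment = tr,
          fruit = sprintf("%s_%s%d", mother_id, substr(tr, 1, 1), fr),
          seed_set = ss, seed_mass = sm, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a complete study population
#'
#' Wires the pieces together under one seed: plant herkogamy, family selfing
#' rates from the logistic herkogamy link, allele frequencies, maternal
#' genotypes, progeny arrays with culling, and the crossing experiment.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical `(config, seed)` give identical output.
#' @return list: `herkogamy` (data.frame), `arrays`, `truth` (family-level
#'   data.frame with s_true, realized_selfed, plant_mean_herkogamy),
#'   `fitness` (data.frame), `freqs`, `maternal_genotypes`, `config`.
#' @export
simulate_population <- function(config, seed) {
  validate_sim_config(config)
  set.seed(as.integer(seed))
  herk <- simulate_herkogamy(config)
  plant_means <- attr(herk, "plant_means")
  s_true <- stats::plogis(config$selfing_intercept +
                            config$selfing_slope * plant_means)
  freqs <- draw_allele_frequencies(config)
  names(freqs) <- paste0("L", seq_len(config$n_loci))
  mothers <- draw_maternal_genotypes(freqs, config$n_families, config$adult_F)
  sim <- simulate_progeny_arrays(config, mothers, unname(s_true), freqs)
  fitness <- simulate_fitness_experiment(config)
  truth <- sim$truth
  truth$plant <- names(plant_means)
  truth$plant_mean_herkogamy <- unname(plant_means)
  list(herkogamy = herk, arrays = sim$arrays, truth = truth,
       fitness = fitness, freqs = freqs, maternal_genotypes = mothers,
       config = config)
}

#' Simulate the two-population study design
#'
#' @param seed integer seed.
#' @param config_cm,config_map per-population configurations.
#' @return named list of two [simulate_population()] results (`CM`, `Map`).
#' @export
simulate_study <- function(seed, config_cm = sim_config_cm(),
                           config_map = sim_config()) {
  seed <- as.integer(seed)
  list(CM = simulate_population(config_cm, seed),
       Map = simulate_population(config_map, seed + 1L))
}
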