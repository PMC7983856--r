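#' Inbreeding coefficient from genotypes
#'
#' Heterozygosity-deficit estimator: per polymorphic locus
#' `f_l = 1 - H_obs,l / H_exp,l` with
#' `H_exp = (2n/(2n-1)) (1 - sum p_hat^2)` (small-sample-corrected expected
#' heterozygosity), combined across loci as a ratio of sums
#' `F = 1 - sum(H_obs,l) / sum(H_exp,l)`. Monomorphic loci carry no
#' information about heterozygosity deficit and are excluded (and counted).
#' The ratio-of-sums form is stable for the small per-lineage samples this
#' summary is used on.
#'
#' @param genotypes a genotype matrix (see [genotype_matrix()]) with >= 2
#'   individuals.
#' @return list: `F`, `n_loci_used` (polymorphic loci), `n_monomorphic`,
#'   `H_obs`, `H_exp` (the summed components).
#' @export
inbreeding_coefficient <- function(genotypes) {
  n_loci <- ncol(genotypes) / 2L
  if (nrow(genotypes) < 2L) {
    stop("inbreeding coefficient needs >= 2 individuals", call. = FALSE)
  }
  hobs_sum <- 0; hexp_sum <- 0
  used <- 0L; mono <- 0L
  for (l in seq_len(n_loci)) {
    cc <- locus_cols(l)
    a1 <- genotypes[, cc[1L]]; a2 <- genotypes[, cc[2L]]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2L) next
    alle <- c(a1[ok], a2[ok])
    if (length(unique(alle)) < 2L) { mono <- mono + 1L; next }
    p <- as.numeric(table(alle)) / (2 * n)
    hexp <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    hobs <- mean(a1[ok] != a2[ok])
    hobs_sum <- hobs_sum + hobs
    hexp_sum <- hexp_sum + hexp
    used <- used + 1L
  }
  if (used == 0L) {
    stop("F undefined: all loci monomorphic or unscored", call. = FALSE)
  }
  list(F = 1 - hobs_sum / hexp_sum, n_loci_used = used, n_monomorphic = mono,
       H_obs = hobs_sum, H_exp = hexp_sum)
}

#' Equilibrium inbreeding coefficient from the outcrossing rate
#'
#' Under constant mixed mating the progeny-cohort inbreeding coefficient
#' converges to `Fe = (1 - tm) / (1 + tm)`, strictly decreasing in tm.
#'
#' @param tm multilocus outcrossing rate(s) in `[0, 1]`.
#' @return Fe in `[0, 1]`, vectorized over `tm`.
#' @export
equilibrium_inbreeding <- function(tm) {
  if (any(!is.finite(tm)) || any(tm < 0 | tm > 1)) {
    stop("tm must lie in [0, 1]", call. = FALSE)
  }
  (1 - tm) / (1 + tm)
}

#' Purging statistic Fe - F
#'
#' The gap between the equilibrium (progeny-cohort) inbreeding Fe implied by
#' the current mating system and the realized adult-cohort F. A large
#' positive gap indicates selection against inbred individuals between the
#' progeny and adult stages (purging); once that selection has run its
#' course the two coincide.
#'
#' @param Fe,F finite inbreeding coefficients.
#' @return `Fe - F`, vectorized.
#' @export
purging_statistic <- function(Fe, F) {
  if (any(!is.finite(Fe)) || any(!is.finite(F))) {
    stop("Fe and F must be finite", call. = FALSE)
  }
  Fe - F
}

#' Inbreeding summary for a set of families
#'
#' Per family: Fe from the family's tm, and F from the family's progeny
#' genotypes (note this progeny-based F is not an adult-cohort F; families
#' with too few polymorphic loci get `NA`). Population level: mean Fe minus
#' mean F, the default purging report.
#'
#' @param estimates data.frame from [estimate_mating()].
#' @param arrays the progeny arrays the estimates came from.
#' @return list: `families` (data.frame: population, family, tm, F, Fe,
#'   diff, n_loci_used) and `population` (data.frame: population, mean_F,
#'   mean_Fe, diff).
#' @export
inbreeding_summary <- function(estimates, arrays) {
  fam_ids <- vapply(arrays, function(a) a$family, character(1))
  Fvals <- rep(NA_real_, nrow(estimates))
  nloci <- rep(NA_integer_, nrow(estimates))
  for (i in seq_len(nrow(estimates))) {
    a <- arrays[[match(estimates$family[i], fam_ids)]]
    fi <- tryCatch(inbreeding_coefficient(a$offspring), error = function(e) NULL)
    if (!is.null(fi)) { Fvals[i] <- fi$F; nloci[i] <- fi$n_loci_used }
  }
  Fe <- equilibrium_inbreeding(estimates$tm)
  fams <- data.frame(
    population = estimates$population, family = estimates$family,
    tm = estimates$tm, F = Fvals, Fe = Fe,
    diff = ifelse(is.na(Fvals), NA_real_, purging_statistic(Fe, Fvals)),
    n_loci_used = nloci, stringsAsFactors = FALSE
  )
  pops <- do.call(rbind, lapply(split(fams, fams$population), function(d) {
    mF <- mean(d$F, na.rm = TRUE); mFe <- mean(d$Fe)
    data.frame(population = d$population[1L], mean_F = mF, mean_Fe = mFe,
               diff = purging_statistic(mFe, mF), stringsAsFactors = FALSE)
  }))
  rownames(pops) <- NULL
  list(families = fams, population = pops)
}
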