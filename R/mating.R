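#' Mixed-mating model likelihood kernels
#'
#' Under the mixed-mating model an offspring arises by self-fertilization of
#' its mother with probability s, or by outcrossing to a shared population
#' pollen pool with probability 1 - s. The two per-locus transition kernels
#' below are the building blocks of the multilocus likelihood.
#'
#' @name mating_model
NULL

# maternal gamete distribution: P(transmitting allele x)
maternal_gamete_prob <- function(mom, x) {
  0.5 * ((mom[1L] == x) + (mom[2L] == x))
}

#' Offspring genotype probability under selfing
#'
#' Probability of an unordered offspring genotype given self-fertilization
#' of the mother (both gametes Mendelian from the maternal pair).
#'
#' @param offspring,mother integer vectors `c(a, b)` of allele codes at one
#'   locus; neither may be missing.
#' @return probability in `[0, 1]` (0 for genotypes impossible under selfing).
#' @export
self_offspring_prob <- function(offspring, mother) {
  stopifnot(!anyNA(offspring), !anyNA(mother))
  pa <- maternal_gamete_prob(mother, offspring[1L])
  pb <- maternal_gamete_prob(mother, offspring[2L])
  if (offspring[1L] == offspring[2L]) pa * pb else 2 * pa * pb
}

#' Offspring genotype probability under outcrossing
#'
#' One gamete is maternal (Mendelian), the other is drawn from the pollen
#' pool frequencies.
#'
#' @param offspring,mother integer vectors `c(a, b)` at one locus.
#' @param pollen_freqs named numeric vector of pollen allele frequencies
#'   (names are allele codes).
#' @return probability in `[0, 1]` (0 when the offspring shares no allele
#'   with the mother).
#' @export
outcross_offspring_prob <- function(offspring, mother, pollen_freqs) {
  stopifnot(!anyNA(offspring), !anyNA(mother))
  pf <- function(x) {
    p <- pollen_freqs[as.character(x)]
    if (is.na(p)) 0 else unname(p)
  }
  a <- offspring[1L]; b <- offspring[2L]
  if (a == b) {
    maternal_gamete_prob(mother, a) * pf(a)
  } else {
    maternal_gamete_prob(mother, a) * pf(b) +
      maternal_gamete_prob(mother, b) * pf(a)
  }
}

#' Build the population pollen pool
#'
#' Pools allele counts from the (provided or inferred) maternal genotypes of
#' all families, then adds 0.5 to the count of every allele observed
#' anywhere in the population (mothers or offspring) and renormalizes.
#' Smoothing guarantees strictly positive outcross probability for every
#' allele any offspring carries, so the outcross kernel can only be zero
#' through a genuine mother-offspring mismatch.
#'
#' @param arrays list of [progeny_array()].
#' @param maternal_genotypes genotype matrix of the mothers (rows aligned
#'   with `arrays`).
#' @param smoothing additive count added per observed allele (default 0.5).
#' @return object of class `pollen_pool`: list of per-locus named frequency
#'   vectors.
#' @export
build_pollen_pool <- function(arrays, maternal_genotypes, smoothing = 0.5) {
  loci <- arrays[[1L]]$loci
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  for (l in seq_along(loci)) {
    mom_alleles <- stats::na.omit(c(maternal_genotypes[, locus_cols(l)]))
    off_alleles <- unlist(lapply(arrays, function(a) {
      stats::na.omit(c(a$offspring[, locus_cols(l)]))
    }))
    seen <- sort(unique(c(mom_alleles, off_alleles)))
    if (!length(seen)) {
      freqs[[l]] <- stats::setNames(numeric(0), character(0))
      next
    }
    counts <- table(factor(mom_alleles, levels = seen)) + smoothing
    p <- as.numeric(counts) / sum(counts)
    names(p) <- as.character(seen)
    freqs[[l]] <- p
  }
  structure(freqs, class = "pollen_pool")
}

# Simple allele frequencies from offspring counts (bootstrap starting pool
# for maternal inference, before mothers exist).
offspring_allele_freqs <- function(arrays) {
  loci <- arrays[[1L]]$loci
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  for (l in seq_along(loci)) {
    alle <- unlist(lapply(arrays, function(a) {
      stats::na.omit(c(a$offspring[, locus_cols(l)]))
    }))
    if (!length(alle)) {
      freqs[[l]] <- stats::setNames(numeric(0), character(0))
      next
    }
    tab <- table(alle)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    freqs[[l]] <- p
  }
  structure(freqs, class = "pollen_pool")
}

#' Infer the maternal multilocus genotype from a progeny array
#'
#' For each locus, every unordered pair of alleles observed in the family or
#' carried by the pollen pool is scored by the mixed-mating likelihood of
#' the whole offspring set at a fixed reference s = 0.5 (neutral between the
#' selfing and outcrossing kernels, so the inference does not lean on the
#' family's own, yet-unknown, selfing rate) times a Hardy-Weinberg prior
#' from the pollen frequencies. Ties break toward the higher-prior genotype,
#' then lexicographic allele order. A locus with no offspring data stays
#' missing. A maternal genotype provided on the array is used verbatim.
#'
#' @param array a [progeny_array()].
#' @param pollen_freqs a `pollen_pool`.
#' @param s_ref reference selfing rate used in scoring.
#' @return list: `genotype` (integer vector of length 2*n_loci) and
#'   `log_score` (per-locus log posterior score of the chosen genotype).
#' @export
infer_maternal_genotype <- function(array, pollen_freqs, s_ref = 0.5) {
  if (!is.null(array$mother)) {
    return(list(genotype = array$mother,
                log_score = rep(NA_real_, length(array$loci))))
  }
  n_loci <- length(array$loci)
  geno <- rep(NA_integer_, 2L * n_loci)
  score <- rep(NA_real_, n_loci)
  for (l in seq_len(n_loci)) {
    cc <- locus_cols(l)
    off <- array$offspring[, cc, drop = FALSE]
    off <- off[!is.na(off[, 1L]), , drop = FALSE]
    if (!nrow(off)) next
    p <- pollen_freqs[[l]]
    cand_alleles <- sort(unique(c(off[, 1L], off[, 2L],
                                  as.integer(names(p)[p > 0]))))
    pairs <- expand.grid(a = cand_alleles, b = cand_alleles)
    pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
    best <- NULL
    for (r in seq_len(nrow(pairs))) {
      mom <- c(pairs$a[r], pairs$b[r])
      pa <- p[as.character(mom[1L])]; pb <- p[as.character(mom[2L])]
      pa <- if (is.na(pa)) 0 else pa
      pb <- if (is.na(pb)) 0 else pb
      prior <- if (mom[1L] == mom[2L]) pa * pb else 2 * pa * pb
      if (prior <= 0) next
      ll <- log(prior)
      ok <- TRUE
      for (i in seq_len(nrow(off))) {
        mix <- s_ref * self_offspring_prob(off[i, ], mom) +
          (1 - s_ref) * outcross_offspring_prob(off[i, ], mom, p)
        if (mix <= 0) { ok <- FALSE; break }
        ll <- ll + log(mix)
      }
      if (!ok) next
      if (is.null(best) || ll > best$ll + 1e-12 ||
          (abs(ll - best$ll) <= 1e-12 && log(prior) > best$lprior + 1e-12)) {
        best <- list(mom = mom, ll = ll, lprior = log(prior))
      }
    }
    if (!is.null(best)) {
      geno[cc] <- best$mom
      score[l] <- best$ll
    }
  }
  list(genotype = geno, log_score = score)
}

# Per-offspring multilocus likelihood components for one family.
# Mismatch loci (outcross probability 0: offspring shares no maternal
# allele) are demoted to missing per offspring-locus and counted.
family_likelihoods <- function(array, maternal_genotype, pollen_freqs) {
  n <- nrow(array$offspring)
  n_loci <- length(array$loci)
  Ls <- rep(1, n); Lo <- rep(1, n)
  informative <- integer(n)
  n_mismatch <- 0L
  for (l in seq_len(n_loci)) {
    cc <- locus_cols(l)
    mom <- maternal_genotype[cc]
    if (anyNA(mom)) next
    p <- pollen_freqs[[l]]
    for (i in seq_len(n)) {
      off <- array$offspring[i, cc]
      if (anyNA(off)) next
      lo <- outcross_offspring_prob(off, mom, p)
      if (lo == 0) { n_mismatch <- n_mismatch + 1L; next }
      ls <- self_offspring_prob(off, mom)
      Ls[i] <- Ls[i] * ls
      Lo[i] <- Lo[i] * lo
      informative[i] <- informative[i] + 1L
    }
  }
  used <- informative > 0L
  list(Ls = Ls[used], Lo = Lo[used], n_used = sum(used),
       n_mismatch = n_mismatch)
}

# EM core on precomputed per-offspring likelihood products. The incomplete
# log-likelihood sum(log(Lo + s (Ls - Lo))) is concave in s, so the EM fixed
# point is the global maximizer.
em_core <- function(Ls, Lo, s_init = 0.5, tol = 1e-8, max_iter = 1000L) {
  eps <- 1e-9
  s <- min(max(s_init, eps), 1 - eps)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  ll <- NA_real_
  ll_trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    mix <- s * Ls + (1 - s) * Lo
    ll <- sum(log(mix))
    ll_trace[iter] <- ll
    z <- s * Ls / mix
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    s <- min(max(mean(z), eps), 1 - eps)
  }
  if (s < 1e-6) s <- 0
  if (s > 1 - 1e-6) s <- 1
  list(s = s, log_likelihood = ll, n_iterations = iter, converged = converged,
       ll_trace = ll_trace)
}

#' EM estimate of the family outcrossing rate
#'
#' E-step: posterior selfing probability per offspring
#' `z_i = s L_self,i / (s L_self,i + (1-s) L_out,i)` with the multilocus
#' likelihood products taken over non-missing loci (the EM handles missing
#' data by simply dropping those factors). M-step: `s <- mean(z_i)`.
#' Iterates until the log-likelihood change falls below `tol`. Offspring
#' loci sharing no allele with the mother are demoted to missing and counted
#' in `n_mismatch_loci` (a null-allele or scoring-error signal); this
#' estimator does not model null alleles. s is clamped away from the
#' boundary during iteration and snapped to exact 0/1 within 1e-6 at
#' convergence, so boundary families are reportable.
#'
#' @param array a [progeny_array()].
#' @param maternal_genotype integer vector of length `2 * n_loci` (from the
#'   array or [infer_maternal_genotype()]).
#' @param pollen_freqs a `pollen_pool`.
#' @param s_init starting selfing rate.
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class `mating_estimate`: family, population, tm, s,
#'   log_likelihood, n_iterations, converged, n_offspring_used,
#'   n_mismatch_loci, bootstrap_se / ci_low / ci_high (NA until
#'   [bootstrap_family()] fills them).
#' @export
em_estimate <- function(array, maternal_genotype, pollen_freqs,
                        s_init = 0.5, tol = 1e-8, max_iter = 1000L) {
  lk <- family_likelihoods(array, maternal_genotype, pollen_freqs)
  if (lk$n_used == 0L) {
    stop(sprintf("family %s: no informative offspring", array$family),
         call. = FALSE)
  }
  fit <- em_core(lk$Ls, lk$Lo, s_init = s_init, tol = tol,
                 max_iter = max_iter)
  structure(
    list(family = array$family, population = array$population,
         tm = 1 - fit$s, s = fit$s, log_likelihood = fit$log_likelihood,
         n_iterations = fit$n_iterations, converged = fit$converged,
         n_offspring_used = lk$n_used, n_mismatch_loci = lk$n_mismatch,
         bootstrap_se = NA_real_, ci_low = NA_real_, ci_high = NA_real_),
    class = "mating_estimate", ll_trace = fit$ll_trace
  )
}

#' @export
print.mating_estimate <- function(x, ...) {
  cat(sprintf(
    "<mating_estimate> %s/%s: tm = %.4f (s = %.4f)%s, logL = %.3f, %d offspring\n",
    x$population, x$family, x$tm, x$s,
    if (!is.na(x$bootstrap_se)) sprintf(" +- %.4f", x$bootstrap_se) else "",
    x$log_likelihood, x$n_offspring_used))
  invisible(x)
}

#' Family-level bootstrap of the outcrossing rate
#'
#' Resamples offspring with replacement within the family and re-runs the EM
#' per replicate (maternal genotype and pollen pool held fixed, keeping
#' families independent). SE is the sample standard deviation of the tm
#' replicates; the CI is the 2.5/97.5 percentile interval. Replicates with
#' zero informative offspring are redrawn (up to 10 retries, then dropped
#' with a warning).
#'
#' @param array a [progeny_array()].
#' @param maternal_genotype,pollen_freqs as in [em_estimate()].
#' @param B number of bootstrap replicates.
#' @param seed optional integer seed.
#' @param s_init,tol,max_iter passed to the EM.
#' @return the [em_estimate()] result with `bootstrap_se`, `ci_low`,
#'   `ci_high` filled (SE absent when `B < 2`), plus a `tm_replicates`
#'   attribute.
#' @export
bootstrap_family <- function(array, maternal_genotype, pollen_freqs,
                             B = 1000L, seed = NULL, s_init = 0.5,
                             tol = 1e-8, max_iter = 1000L) {
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  est <- em_estimate(array, maternal_genotype, pollen_freqs,
                     s_init = s_init, tol = tol, max_iter = max_iter)
  lk <- family_likelihoods(array, maternal_genotype, pollen_freqs)
  n <- lk$n_used
  tms <- rep(NA_real_, B)
  dropped <- 0L
  for (b in seq_len(B)) {
    fit <- NULL
    for (try in seq_len(10L)) {
      idx <- sample.int(n, n, replace = TRUE)
      Ls <- lk$Ls[idx]; Lo <- lk$Lo[idx]
      if (all(Ls == 0 & Lo == 0)) next
      fit <- em_core(Ls, Lo, s_init = s_init, tol = tol, max_iter = max_iter)
      break
    }
    if (is.null(fit)) { dropped <- dropped + 1L; next }
    tms[b] <- 1 - fit$s
  }
  if (dropped > 0L) {
    warning(sprintf("family %s: %d bootstrap replicate(s) dropped",
                    array$family, dropped))
  }
  tms <- tms[!is.na(tms)]
  if (length(tms) >= 2L) {
    est$bootstrap_se <- stats::sd(tms)
    qs <- stats::quantile(tms, c(0.025, 0.975), names = FALSE)
    est$ci_low <- qs[1L]; est$ci_high <- qs[2L]
  }
  attr(est, "tm_replicates") <- tms
  est
}

#' Estimate mating-system parameters for a set of progeny arrays
#'
#' Full per-population workflow: starting allele frequencies from offspring
#' counts, maternal genotypes taken from the arrays or inferred
#' ([infer_maternal_genotype()]), population pollen pool rebuilt from the
#' mothers with additive smoothing ([build_pollen_pool()]), then one EM fit
#' per family, optionally with a family-level bootstrap. Populations with
#' different locus subsets are handled by their own arrays' locus lists.
#'
#' @param arrays list of [progeny_array()] from one population.
#' @param B bootstrap replicates per family (0 to skip the bootstrap).
#' @param seed optional integer seed for the bootstrap.
#' @param smoothing pollen-pool additive smoothing.
#' @param s_init,tol,max_iter passed to the EM.
#' @return data.frame with one row per family: population, family, tm, s,
#'   se, ci_low, ci_high, loglik, iters, converged, n_offspring_used,
#'   n_mismatch_loci; the `pollen_pool` and per-family `estimates` objects
#'   ride along as attributes.
#' @export
estimate_mating <- function(arrays, B = 0L, seed = NULL, smoothing = 0.5,
                            s_init = 0.5, tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(arrays) >= 1L)
  init_pool <- offspring_allele_freqs(arrays)
  mothers <- matrix(NA_integer_, length(arrays),
                    2L * length(arrays[[1L]]$loci))
  for (i in seq_along(arrays)) {
    mothers[i, ] <- infer_maternal_genotype(arrays[[i]], init_pool)$genotype
  }
  pool <- build_pollen_pool(arrays, mothers, smoothing = smoothing)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ests <- vector("list", length(arrays))
  for (i in seq_along(arrays)) {
    ests[[i]] <- if (B >= 1L) {
      bootstrap_family(arrays[[i]], mothers[i, ], pool, B = B,
                       s_init = s_init, tol = tol, max_iter = max_iter)
    } else {
      em_estimate(arrays[[i]], mothers[i, ], pool,
                  s_init = s_init, tol = tol, max_iter = max_iter)
    }
  }
  out <- data.frame(
    population = vapply(ests, `[[`, character(1), "population"),
    family = vapply(ests, `[[`, character(1), "family"),
    tm = vapply(ests, `[[`, numeric(1), "tm"),
    s = vapply(ests, `[[`, numeric(1), "s"),
    se = vapply(ests, `[[`, numeric(1), "bootstrap_se"),
    ci_low = vapply(ests, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(ests, `[[`, numeric(1), "ci_high"),
    loglik = vapply(ests, `[[`, numeric(1), "log_likelihood"),
    iters = vapply(ests, `[[`, integer(1), "n_iterations"),
    converged = vapply(ests, `[[`, logical(1), "converged"),
    n_offspring_used = vapply(ests, `[[`, integer(1), "n_offspring_used"),
    n_mismatch_loci = vapply(ests, `[[`, integer(1), "n_mismatch_loci"),
    stringsAsFactors = FALSE
  )
  attr(out, "pollen_pool") <- pool
  attr(out, "estimates") <- ests
  attr(out, "maternal_genotypes") <- mothers
  out
}
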