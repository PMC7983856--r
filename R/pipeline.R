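#' Per-family supplementary-style report
#'
#' One row per family with the five family-level mating-system quantities:
#' herkogamy (plant mean), outcrossing rate tm, selfing rate s, primary
#' selfing rate r, and equilibrium inbreeding Fe, plus the population id.
#'
#' @param estimates data.frame from [estimate_mating()].
#' @param herkogamy herkogamy measurement data.frame; plant ids must match
#'   family ids (the maternal plant is the family).
#' @param r per-family primary selfing rates aligned with `estimates` rows.
#' @return data.frame: population, family, herkogamy, tm, s, r, Fe.
#' @export
report_supp4 <- function(estimates, herkogamy, r) {
  herk_mean <- stats::aggregate(herkogamy ~ plant, data = herkogamy,
                                FUN = mean)
  idx <- match(estimates$family, herk_mean$plant)
  if (anyNA(idx)) {
    warning("families without herkogamy measurements: ",
            paste(estimates$family[is.na(idx)], collapse = ", "))
  }
  data.frame(
    population = estimates$population,
    family = estimates$family,
    herkogamy = herk_mean$herkogamy[idx],
    tm = estimates$tm,
    s = estimates$s,
    r = r,
    Fe = equilibrium_inbreeding(estimates$tm),
    stringsAsFactors = FALSE
  )
}

#' Trait-parameter association matrix for one population
#'
#' Square matrix over (r, herkogamy, F, Fe, Fe - F) with regression
#' estimates above the diagonal and their SEs below. The r-herkogamy cell
#' uses beta regression with AIC link selection ([select_link()]); cells
#' pairing herkogamy or r with F, Fe or Fe - F use a Gaussian identity-link
#' model; F/Fe/Fe - F are deterministically entangled with each other so
#' those cells stay `na`, as does anything unestimable.
#'
#' @param supp4 data.frame from [report_supp4()].
#' @param inbreeding_families family-level data.frame from
#'   [inbreeding_summary()].
#' @return list: `matrix` (character, estimates above / SEs below the
#'   diagonal), `fits` (named list of `association_result`s), `aic_table`
#'   (link-selection table for the beta fit, or NULL).
#' @export
association_table <- function(supp4, inbreeding_families) {
  d <- merge(supp4, inbreeding_families[, c("family", "F", "diff")],
             by = "family", sort = FALSE)
  vars <- c("r", "herkogamy", "F", "Fe", "Fe-F")
  vals <- list(r = d$r, herkogamy = d$herkogamy, F = d$F, Fe = d$Fe,
               `Fe-F` = d$diff)
  m <- matrix("na", 5L, 5L, dimnames = list(vars, vars))
  diag(m) <- "-"
  fits <- list()
  aic_table <- NULL
  put <- function(i, j, est, se) {
    m[i, j] <<- sprintf("%.3f", est)
    m[j, i] <<- sprintf("%.3f", se)
  }
  ok <- stats::complete.cases(vals$r, vals$herkogamy)
  fit_rh <- tryCatch(
    select_link(vals$r[ok], vals$herkogamy[ok],
                response = "r", predictor = "herkogamy"),
    error = function(e) NULL)
  if (!is.null(fit_rh)) {
    put(1L, 2L, fit_rh$coefficients$estimate[2L], fit_rh$coefficients$se[2L])
    fits[["r~herkogamy"]] <- fit_rh
    aic_table <- fit_rh$aic_table
  }
  gauss_cell <- function(resp_name, i, pred_name, j) {
    yv <- vals[[resp_name]]; xv <- vals[[pred_name]]
    ok <- stats::complete.cases(yv, xv)
    fit <- tryCatch(gaussian_glm(yv[ok], xv[ok], response = resp_name,
                                 predictor = pred_name),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      put(min(i, j), max(i, j), fit$coefficients$estimate[2L],
          fit$coefficients$se[2L])
      fits[[paste0(resp_name, "~", pred_name)]] <<- fit
    }
  }
  # herkogamy as predictor of the inbreeding summaries
  gauss_cell("F", 3L, "herkogamy", 2L)
  gauss_cell("Fe", 4L, "herkogamy", 2L)
  gauss_cell("Fe-F", 5L, "herkogamy", 2L)
  # r as predictor of the inbreeding summaries
  gauss_cell("F", 3L, "r", 1L)
  gauss_cell("Fe", 4L, "r", 1L)
  gauss_cell("Fe-F", 5L, "r", 1L)
  list(matrix = m, fits = fits, aic_table = aic_table)
}

#' Population summary of mating-system parameters
#'
#' Population means of tm, s, r, F, Fe, the purging statistic
#' mean(Fe) - mean(F), delta, and r recomputed from the mean s
#' (`r_of_mean_s`) — reported alongside the mean of per-family r because
#' the two averaging orders differ slightly.
#'
#' @param supp4 data.frame from [report_supp4()].
#' @param inbreeding_pop population-level data.frame from
#'   [inbreeding_summary()].
#' @param deltas named numeric vector of per-population delta estimates.
#' @return data.frame, one row per population.
#' @export
population_summary <- function(supp4, inbreeding_pop, deltas) {
  do.call(rbind, lapply(split(supp4, supp4$population), function(d) {
    pop <- d$population[1L]
    ib <- inbreeding_pop[inbreeding_pop$population == pop, ]
    delta <- unname(deltas[pop])
    data.frame(
      population = pop,
      mean_tm = mean(d$tm), mean_s = mean(d$s), mean_r = mean(d$r),
      r_of_mean_s = primary_selfing_rate(mean(d$s), delta),
      mean_F = ib$mean_F, mean_Fe = ib$mean_Fe,
      Fe_minus_F = purging_statistic(ib$mean_Fe, ib$mean_F),
      delta = delta, n_families = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
}

run_stage <- function(name, runtimes, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  runtimes[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  assign("runtimes", runtimes, envir = parent.frame())
  res
}

#' Run the full mating-system pipeline
#'
#' Orchestrates simulate (or load) -> per-family EM estimation with
#' bootstrap -> inbreeding -> inbreeding depression -> primary selfing ->
#' associations, and writes a consolidated report directory: inputs (when
#' simulated), `estimates.tsv`, `inbreeding.tsv`, `delta.tsv`, `r.tsv`
#' (the supplementary-style per-family table), `table1_<pop>.tsv` and
#' `aic_table_<pop>.tsv`, `population_summary.tsv`, and `manifest.json`.
#' The run is a pure function of (inputs/configs, B, seed).
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for simulation and bootstrap.
#' @param configs list of [sim_config()] objects, one per population
#'   (simulation mode; ignored when `inputs` is given).
#' @param inputs optional list for real data: `progeny` (progeny-table TSV
#'   path) or `genepop` (named character vector, population -> GenePop
#'   path), plus `herkogamy` and `fitness` TSV paths.
#' @param B bootstrap replicates per family.
#' @return invisibly, a list with all in-memory results (`estimates`,
#'   `inbreeding`, `deltas`, `supp4`, `summary`, `tables`, `manifest`).
#' @export
run_pipeline <- function(outdir, seed = 1L,
                         configs = list(sim_config_cm(), sim_config()),
                         inputs = NULL, B = 200L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  runtimes <- list()
  warn_log <- character(0)
  withCallingHandlers({
    if (is.null(inputs)) {
      sims <- run_stage("simulate", runtimes, {
        out <- list()
        for (i in seq_along(configs)) {
          sim <- simulate_population(configs[[i]], seed + i - 1L)
          out[[sim$config$population]] <- sim
        }
        out
      })
      arrays_by_pop <- lapply(sims, `[[`, "arrays")
      herk <- do.call(rbind, lapply(sims, `[[`, "herkogamy"))
      fitness <- do.call(rbind, lapply(sims, `[[`, "fitness"))
      rownames(herk) <- rownames(fitness) <- NULL
      # persist simulated inputs so the run is auditable end to end
      all_arrays <- unlist(unname(arrays_by_pop), recursive = FALSE)
      for (pop in names(arrays_by_pop)) {
        write_genepop(arrays_to_genepop(arrays_by_pop[[pop]]),
                      file.path(outdir, paste0("genotypes_", pop, ".gen")))
        write_progeny_table(arrays_by_pop[[pop]],
                            file.path(outdir, paste0("progeny_", pop, ".tsv")))
      }
      write_tsv(herk, file.path(outdir, "herkogamy.tsv"))
      write_tsv(fitness, file.path(outdir, "fitness.tsv"))
      truth <- do.call(rbind, lapply(sims, function(s) {
        cbind(population = s$config$population, s$truth)
      }))
      rownames(truth) <- NULL
      write_tsv(truth, file.path(outdir, "simulated_truth.tsv"))
    } else {
      arrays_by_pop <- run_stage("load", runtimes, {
        if (!is.null(inputs$progeny)) {
          arr <- read_progeny_table(inputs$progeny)
          split(arr, vapply(arr, `[[`, character(1), "population"))
        } else if (!is.null(inputs$genepop)) {
          out <- list()
          for (pop in names(inputs$genepop)) {
            out[[pop]] <- genepop_to_arrays(read_genepop(inputs$genepop[[pop]]),
                                            population = pop)
          }
          out
        } else stop("inputs must provide 'progeny' or 'genepop'")
      })
      herk <- read_phenotype_table(inputs$herkogamy)
      fitness <- read_fitness_table(inputs$fitness)
    }

    estimates <- run_stage("estimate", runtimes, {
      do.call(rbind, lapply(names(arrays_by_pop), function(pop) {
        estimate_mating(arrays_by_pop[[pop]], B = B,
                        seed = seed + utils::head(utf8ToInt(pop), 1L))
      }))
    })
    write_tsv(estimates, file.path(outdir, "estimates.tsv"))

    ib <- run_stage("inbreeding", runtimes, {
      all_arrays <- unlist(unname(arrays_by_pop), recursive = FALSE)
      inbreeding_summary(estimates, all_arrays)
    })
    write_tsv(ib$families, file.path(outdir, "inbreeding.tsv"))

    deltas <- run_stage("depression", runtimes, {
      d <- vapply(unique(estimates$population), function(pop) {
        estimate_delta(fitness, population = pop)$delta
      }, numeric(1))
      stats::setNames(d, unique(estimates$population))
    })
    write_tsv(data.frame(population = names(deltas), delta = unname(deltas)),
              file.path(outdir, "delta.tsv"))

    supp4 <- run_stage("primary_selfing", runtimes, {
      r <- primary_selfing_rate(estimates$s, 0)  # placeholder, per-pop below
      for (pop in names(deltas)) {
        sel <- estimates$population == pop
        r[sel] <- primary_selfing_rate(estimates$s[sel], deltas[[pop]])
      }
      report_supp4(estimates, herk, r)
    })
    write_tsv(supp4, file.path(outdir, "r.tsv"))

    tables <- run_stage("associations", runtimes, {
      out <- list()
      for (pop in unique(supp4$population)) {
        tb <- association_table(supp4[supp4$population == pop, ],
                                ib$families[ib$families$population == pop, ])
        utils::write.table(tb$matrix,
                           file.path(outdir, paste0("table1_", pop, ".tsv")),
                           sep = "\t", quote = FALSE, col.names = NA)
        if (!is.null(tb$aic_table)) {
          write_tsv(tb$aic_table,
                    file.path(outdir, paste0("aic_table_", pop, ".tsv")))
        }
        out[[pop]] <- tb
      }
      out
    })

    summary_df <- population_summary(supp4, ib$population, deltas)
    write_tsv(summary_df, file.path(outdir, "population_summary.tsv"))

    input_files <- list.files(outdir, pattern = "\\.(tsv|gen)$",
                              full.names = TRUE)
    manifest <- list(
      tool = "matingkit",
      version = as.character(utils::packageVersion("matingkit")),
      seed = seed, B = B,
      file_digests = as.list(tools::md5sum(input_files)),
      runtimes_s = runtimes,
      n_warnings = length(warn_log),
      warnings = warn_log
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(estimates = estimates, inbreeding = ib, deltas = deltas,
                   supp4 = supp4, summary = summary_df, tables = tables,
                   manifest = manifest))
  }, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}
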