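#' Per-fruit fitness
#'
#' Fitness of a fruit is the product of its seed-set (seeds/ovules) and its
#' per-seed mass, combining offspring quantity and quality into one
#' maternal-fitness component.
#'
#' @param records data.frame with `seed_set` and `seed_mass` columns (see
#'   [read_fitness_table()]).
#' @return numeric vector of per-fruit fitness values.
#' @export
fruit_fitness <- function(records) {
  records$seed_set * records$seed_mass
}

#' Estimate cumulative inbreeding depression
#'
#' `delta = 1 - w_self / w_out` from paired self/outcross hand pollinations.
#' Only mothers with at least one fruit in each treatment enter the
#' estimate. By default `w_self` and `w_out` are means of per-fruit fitness
#' over all included fruits (fruit-level mean, well defined with unbalanced
#' fruit counts); `mother_level = TRUE` first averages within mother and
#' treatment, then across mothers. Negative delta (outbreeding depression)
#' is reported as-is.
#'
#' @param records fitness data.frame (see [read_fitness_table()]).
#' @param population optional population id to subset to.
#' @param mother_level average within mothers first?
#' @return object of class `depression_estimate`: population, w_self,
#'   w_out, delta, n_mothers, n_fruits, mother_level.
#' @export
estimate_delta <- function(records, population = NULL, mother_level = FALSE) {
  df <- records
  if (!is.null(population)) df <- df[df$population == population, , drop = FALSE]
  if (!nrow(df)) stop("no fitness records for population", call. = FALSE)
  pop <- unique(df$population)
  if (length(pop) > 1L) {
    stop("records span several populations; pass `population`", call. = FALSE)
  }
  has <- table(df$mother, df$treatment)
  if (!all(c("self", "outcross") %in% colnames(has))) {
    excluded <- rownames(has)
    stop("insufficient data: treatment(s) entirely absent; mothers excluded: ",
         paste(excluded, collapse = ", "), call. = FALSE)
  }
  keep <- rownames(has)[has[, "self"] >= 1L & has[, "outcross"] >= 1L]
  if (!length(keep)) {
    stop("insufficient data: no mother has a fruit in both treatments; ",
         "mothers excluded: ", paste(rownames(has), collapse = ", "),
         call. = FALSE)
  }
  df <- df[df$mother %in% keep, , drop = FALSE]
  df$w <- fruit_fitness(df)
  if (mother_level) {
    agg <- stats::aggregate(w ~ mother + treatment, data = df, FUN = mean)
    ws <- mean(agg$w[agg$treatment == "self"])
    wo <- mean(agg$w[agg$treatment == "outcross"])
  } else {
    ws <- mean(df$w[df$treatment == "self"])
    wo <- mean(df$w[df$treatment == "outcross"])
  }
  if (wo == 0) stop("delta undefined: mean outcross fitness is 0",
                    call. = FALSE)
  structure(
    list(population = pop, w_self = ws, w_out = wo, delta = 1 - ws / wo,
         n_mothers = length(keep), n_fruits = nrow(df),
         mother_level = mother_level),
    class = "depression_estimate"
  )
}

#' @export
print.depression_estimate <- function(x, ...) {
  cat(sprintf(
    "<depression_estimate> %s: delta = %.4f (w_self = %.3f, w_out = %.3f, %d mothers)\n",
    x$population, x$delta, x$w_self, x$w_out, x$n_mothers))
  invisible(x)
}

#' Primary selfing rate
#'
#' Corrects the marker-based selfing rate s for early inbreeding depression:
#' selfed zygotes die before genotyping at rate delta, so the genotyped s
#' underestimates the selfing fraction at fertilization. The correction is
#' `r = s / (1 - delta + s * delta)`; r = s when delta = 0 and r >= s for
#' delta in (0, 1).
#'
#' @param s selfing rate(s) in `[0, 1]`.
#' @param delta cumulative inbreeding depression, < 1.
#' @return primary selfing rate(s) r in `[0, 1]`, vectorized over `s`.
#' @export
primary_selfing_rate <- function(s, delta) {
  if (any(!is.finite(s)) || any(s < 0 | s > 1)) {
    stop("s must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(delta) || delta >= 1) {
    stop("delta must be finite and < 1", call. = FALSE)
  }
  s / (1 - delta + s * delta)
}

#' Invert the primary selfing correction
#'
#' Recovers the marker-based s from r and delta:
#' `s = r (1 - delta) / (1 - r delta)`.
#'
#' @param r primary selfing rate(s) in `[0, 1]`.
#' @param delta cumulative inbreeding depression, < 1.
#' @return s in `[0, 1]`.
#' @export
selfing_from_primary <- function(r, delta) {
  if (any(!is.finite(r)) || any(r < 0 | r > 1)) {
    stop("r must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(delta) || delta >= 1) {
    stop("delta must be finite and < 1", call. = FALSE)
  }
  r * (1 - delta) / (1 - r * delta)
}
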