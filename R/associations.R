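#' Association results
#'
#' Common container for the statistical layer: model family, link,
#' coefficient table (estimate, SE, p), precision phi (beta regression
#' only), log-likelihood, AIC (`2k - 2 logL` with k counting every fitted
#' parameter, phi included), n and residual df.
#'
#' @name associations
NULL

association_result <- function(response, predictors, family, link,
                               coefficients, loglik, aic, n, df,
                               phi = NA_real_, extra = list()) {
  structure(
    c(list(response = response, predictors = predictors, family = family,
           link = link, coefficients = coefficients, phi = phi,
           loglik = loglik, aic = aic, n = n, df = df), extra),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s ~ %s [%s, link = %s], AIC = %.2f, n = %d\n",
              x$response, paste(x$predictors, collapse = " + "),
              x$family, x$link, x$aic, x$n))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Herkogamy variance components
#'
#' One-way random-intercept model (plant as the random factor) fitted by
#' REML on possibly unbalanced flower counts; partitions phenotypic
#' variance into among-plant and within-plant (flower-to-flower)
#' components. A large among-plant share suggests genetically based
#' differences between plants in mean herkogamy.
#'
#' @param measurements data.frame with `plant` and `herkogamy` columns
#'   (see [read_phenotype_table()]).
#' @return list of class `variance_components`: sigma2_among,
#'   sigma2_within, proportion_among, n_plants, n_flowers, method.
#' @export
variance_components <- function(measurements) {
  df <- data.frame(plant = factor(measurements$plant),
                   y = measurements$herkogamy)
  counts <- table(df$plant)
  if (length(counts) < 2L) stop("need >= 2 plants", call. = FALSE)
  if (!any(counts >= 2L)) {
    stop("within-plant variance unidentifiable: every plant has one flower",
         call. = FALSE)
  }
  within_var <- stats::aggregate(y ~ plant, df,
                                 function(v) if (length(v) > 1) stats::var(v) else 0)
  if (max(within_var$y) < 1e-12) {
    s2a <- stats::var(stats::aggregate(y ~ plant, df, mean)$y)
    vc <- list(sigma2_among = s2a, sigma2_within = 0,
               proportion_among = if (s2a > 0) 1 else NA_real_,
               n_plants = length(counts), n_flowers = nrow(df),
               method = "degenerate")
    class(vc) <- "variance_components"
    return(vc)
  }
  fit <- nlme::lme(y ~ 1, random = ~ 1 | plant, data = df, method = "REML")
  vcmat <- nlme::VarCorr(fit)
  s2a <- max(as.numeric(vcmat["(Intercept)", "Variance"]), 0)
  s2w <- max(as.numeric(vcmat["Residual", "Variance"]), 0)
  vc <- list(sigma2_among = s2a, sigma2_within = s2w,
             proportion_among = s2a / (s2a + s2w),
             n_plants = length(counts), n_flowers = nrow(df),
             method = "REML (nlme::lme)")
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> among = %.3f, within = %.3f (among share %.1f%%), %d plants / %d flowers [%s]\n",
    x$sigma2_among, x$sigma2_within, 100 * x$proportion_among,
    x$n_plants, x$n_flowers, x$method))
  invisible(x)
}

beta_links <- list(
  logit = list(linkfun = stats::qlogis, linkinv = stats::plogis),
  log = list(linkfun = log, linkinv = exp),
  cloglog = list(linkfun = function(mu) log(-log(1 - mu)),
                 linkinv = function(eta) 1 - exp(-exp(eta)))
)

clamp01 <- function(x, eps = 1e-10) pmin(pmax(x, eps), 1 - eps)

beta_nll <- function(par, y, x, linkinv) {
  mu <- clamp01(linkinv(par[1L] + par[2L] * x))
  phi <- exp(par[3L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Compress boundary proportions into (0, 1)
#'
#' The beta likelihood is undefined at exact 0/1; when such values are
#' present the standard compression `y' = (y (n-1) + 0.5) / n` is applied.
#'
#' @param y proportions in `[0, 1]`.
#' @return list: `y` (possibly transformed) and `adjusted` (flag).
#' @export
compress_boundary <- function(y) {
  n <- length(y)
  if (any(y <= 0 | y >= 1)) {
    list(y = (y * (n - 1) + 0.5) / n, adjusted = TRUE)
  } else {
    list(y = y, adjusted = FALSE)
  }
}

#' Beta regression by maximum likelihood
#'
#' Mean-precision parametrization: `y ~ Beta(mu phi, (1 - mu) phi)` with
#' `mu = linkinv(b0 + b1 x)` and constant phi fitted on the log scale.
#' Boundary values are compressed first (see [compress_boundary()]). SEs
#' come from the inverse observed information at the optimum; p-values are
#' Wald. AIC counts three parameters (b0, b1, log phi).
#'
#' @param y response proportions in `[0, 1]`.
#' @param x numeric predictor.
#' @param link mean link: `"logit"`, `"log"` or `"cloglog"`.
#' @param response,predictor names used in the result.
#' @return an `association_result` (family `"beta"`), with
#'   `boundary_adjusted` flag.
#' @export
beta_regression <- function(y, x, link = "logit", response = "y",
                            predictor = "x") {
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    stop("y must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  link <- match.arg(link, names(beta_links))
  lk <- beta_links[[link]]
  cb <- compress_boundary(y)
  yy <- clamp01(cb$y)
  n <- length(yy)
  # start from a least-squares fit on the link scale
  eta0 <- lk$linkfun(yy)
  cf <- tryCatch(stats::coef(stats::lm(eta0 ~ x)), error = function(e) c(0, 0))
  if (anyNA(cf)) cf[is.na(cf)] <- 0
  start <- c(cf[1L], cf[2L], log(5))
  opt <- stats::optim(start, beta_nll, y = yy, x = x, linkinv = lk$linkinv,
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    h <- 1e-6
    g <- vapply(1:3, function(k) {
      dp <- opt$par; dp[k] <- dp[k] + h
      dm <- opt$par; dm[k] <- dm[k] - h
      (beta_nll(dp, yy, x, lk$linkinv) - beta_nll(dm, yy, x, lk$linkinv)) /
        (2 * h)
    }, numeric(1))
    stop(sprintf("beta regression (%s link) did not converge (gradient norm %.3g)",
                 link, sqrt(sum(g^2))), call. = FALSE)
  }
  hess <- stats::optimHess(opt$par, beta_nll, y = yy, x = x,
                           linkinv = lk$linkinv)
  vcov <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 3, 3))
  se <- unname(sqrt(pmax(diag(vcov), 0)))
  est <- unname(opt$par)
  z <- est[1:2] / se[1:2]
  pvals <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(
    term = c("(Intercept)", predictor),
    estimate = est[1:2], se = se[1:2], p = pvals,
    stringsAsFactors = FALSE
  )
  ll <- -opt$value
  association_result(
    response = response, predictors = predictor, family = "beta",
    link = link, coefficients = coefs, phi = exp(est[3L]),
    loglik = ll, aic = 2 * 3 - 2 * ll, n = n, df = n - 3L,
    extra = list(boundary_adjusted = cb$adjusted, vcov = vcov,
                 phi_se = exp(est[3L]) * se[3L])
  )
}

#' Fit beta regressions under several links and select by AIC
#'
#' @param y,x as in [beta_regression()].
#' @param links candidate mean links.
#' @param response,predictor names used in the results.
#' @return the minimum-AIC `association_result` (ties break toward logit),
#'   with the full AIC table in `$aic_table` (one row per link).
#' @export
select_link <- function(y, x, links = c("cloglog", "logit", "log"),
                        response = "y", predictor = "x") {
  fits <- list(); errs <- character(0)
  for (lnk in links) {
    f <- tryCatch(beta_regression(y, x, link = lnk, response = response,
                                  predictor = predictor),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("link %s excluded: %s", lnk, conditionMessage(f)))
      errs <- c(errs, lnk)
    } else {
      fits[[lnk]] <- f
    }
  }
  if (!length(fits)) {
    stop("all candidate links failed: ", paste(errs, collapse = ", "),
         call. = FALSE)
  }
  tab <- data.frame(
    link = names(fits),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  best_aic <- min(tab$aic)
  cand <- tab$link[tab$aic <= best_aic + 1e-8]
  pick <- if ("logit" %in% cand) "logit" else cand[1L]
  out <- fits[[pick]]
  out$aic_table <- tab
  out
}

#' Gaussian generalized linear model (identity link)
#'
#' Ordinary least-squares slope/intercept with t-based p-values; used for
#' responses not confined to (0, 1) such as F, Fe and Fe - F.
#'
#' @param y,x numeric response and predictor.
#' @param response,predictor names used in the result.
#' @return an `association_result` (family `"gaussian"`).
#' @export
gaussian_glm <- function(y, x, response = "y", predictor = "x") {
  if (length(y) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = c("(Intercept)", predictor),
    estimate = unname(sm[, 1L]), se = unname(sm[, 2L]), p = unname(sm[, 4L]),
    stringsAsFactors = FALSE
  )
  ll <- as.numeric(stats::logLik(fit))
  n <- length(y)
  association_result(
    response = response, predictors = predictor, family = "gaussian",
    link = "identity", coefficients = coefs, loglik = ll,
    aic = stats::AIC(fit), n = n, df = fit$df.residual
  )
}

#' Analysis of covariance
#'
#' Linear model `y ~ group + covariate` with marginal (Type-II) F-tests;
#' the interaction term is off by default.
#'
#' @param y numeric response.
#' @param group factor (>= 2 levels with >= 2 observations each).
#' @param covariate numeric covariate.
#' @param interaction include `group:covariate`?
#' @param response names used in the result.
#' @return an `association_result` (family `"ancova"`) with the Type-II
#'   ANOVA table in `$anova_table`.
#' @export
ancova <- function(y, group, covariate, interaction = FALSE,
                   response = "y") {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  df <- data.frame(y = y, group = group, covariate = covariate)
  form <- if (interaction) y ~ group * covariate else y ~ group + covariate
  fit <- stats::lm(form, data = df)
  at <- car::Anova(fit, type = 2)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                      se = sm[, 2L], p = sm[, 4L], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  association_result(
    response = response, predictors = c("group", "covariate"),
    family = "ancova", link = "identity", coefficients = coefs,
    loglik = as.numeric(stats::logLik(fit)), aic = stats::AIC(fit),
    n = length(y), df = fit$df.residual,
    extra = list(anova_table = as.data.frame(at))
  )
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return an `association_result` (family `"pearson"`) with the estimate as
#'   the single coefficient and t/df in `$statistic` / `$df`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  coefs <- data.frame(term = "cor", estimate = unname(ct$estimate),
                      se = NA_real_, p = ct$p.value, stringsAsFactors = FALSE)
  association_result(
    response = "y", predictors = "x", family = "pearson", link = "identity",
    coefficients = coefs, loglik = NA_real_, aic = NA_real_,
    n = length(x), df = unname(ct$parameter),
    extra = list(statistic = unname(ct$statistic))
  )
}
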