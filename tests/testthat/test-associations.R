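# Statistical layer: variance components, beta regression with link
# selection, Gaussian GLM, ANCOVA, correlations.

test_that("balanced-design REML equals the expected-mean-squares closed form", {
  set.seed(81)
  plant <- rep(sprintf("p%02d", 1:20), each = 5)
  y <- rep(rnorm(20, 0, sqrt(3)), each = 5) + rnorm(100, 0, 1)
  d <- data.frame(plant = plant, herkogamy = y)
  vc <- variance_components(d)
  ems <- ems_variance_components(y, plant)
  expect_equal(vc$sigma2_among, ems$sigma2_among, tolerance = 1e-6)
  expect_equal(vc$sigma2_within, ems$sigma2_within, tolerance = 1e-6)
  expect_equal(vc$proportion_among,
               ems$sigma2_among / (ems$sigma2_among + ems$sigma2_within),
               tolerance = 1e-6)
})

test_that("variance components handle degenerate and invalid designs", {
  d0 <- data.frame(plant = rep(c("a", "b"), each = 3),
                   herkogamy = rep(c(1, 5), each = 3))
  vc0 <- variance_components(d0)
  expect_equal(vc0$proportion_among, 1)
  expect_equal(vc0$sigma2_within, 0)
  d1 <- data.frame(plant = c("a", "b", "c"), herkogamy = c(1, 2, 3))
  expect_error(variance_components(d1), "unidentifiable")
  expect_error(variance_components(data.frame(plant = "a", herkogamy = 1)),
               ">= 2 plants")
})

test_that("beta regression recovers parameters and dominates a likelihood grid", {
  set.seed(82)
  n <- 400
  x <- rnorm(n, 0, 5)
  mu <- plogis(0.3 - 0.15 * x)
  phi <- 20
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  fit <- beta_regression(y, x, link = "logit")
  b1 <- fit$coefficients$estimate[2]
  se1 <- fit$coefficients$se[2]
  expect_lt(abs(b1 - (-0.15)), 2 * se1)
  expect_equal(fit$phi, phi, tolerance = 0.2 * phi)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
  # oracle dominance on a coarse lattice around truth
  grid <- expand.grid(b0 = seq(-0.5, 1, by = 0.1),
                      b1 = seq(-0.3, 0, by = 0.02),
                      phi = c(5, 10, 20, 40))
  grid_ll <- max(mapply(oracle_beta_ll, grid$b0, grid$b1, grid$phi,
                        MoreArgs = list(y = y, x = x, linkinv = plogis)))
  expect_gte(fit$loglik, grid_ll - 1e-4)
})

test_that("beta regression small-sample fit matches an exhaustive grid", {
  y <- c(0.2, 0.5, 0.7)
  x <- c(-1, 0, 1)
  fit <- beta_regression(y, x, link = "logit")
  grid <- expand.grid(b0 = seq(-1, 1, by = 0.05),
                      b1 = seq(0, 1.5, by = 0.05),
                      phi = exp(seq(log(0.5), log(60), length.out = 60)))
  ll <- mapply(oracle_beta_ll, grid$b0, grid$b1, grid$phi,
               MoreArgs = list(y = y, x = x, linkinv = plogis))
  expect_gte(fit$loglik, max(ll) - 1e-4)
})

test_that("boundary proportions are compressed only when present", {
  y <- c(0, 0.5, 1, 0.25)
  fit <- beta_regression(y, c(1, 2, 3, 4))
  expect_true(fit$boundary_adjusted)
  fit2 <- beta_regression(c(0.2, 0.5, 0.8), c(1, 2, 3))
  expect_false(fit2$boundary_adjusted)
  cb <- compress_boundary(c(0, 1, 0.5))
  expect_equal(cb$y, (c(0, 1, 0.5) * 2 + 0.5) / 3)
  expect_error(beta_regression(c(-0.1, 0.5), c(1, 2)), "\\[0, 1\\]")
})

test_that("near-constant response yields a flat beta fit", {
  set.seed(83)
  y <- rep(0.5, 50) + rnorm(50, 0, 1e-3)
  y <- pmin(pmax(y, 0.01), 0.99)
  x <- rnorm(50)
  fit <- beta_regression(y, x)
  expect_lt(abs(fit$coefficients$estimate[2]), 0.01)
})

test_that("AIC link selection finds the generating link and reports a table", {
  set.seed(84)
  n <- 1000
  x <- runif(n, 0, 4)
  mu <- exp(-0.2 - 0.5 * x)  # log mean link
  y <- rbeta(n, mu * 30, (1 - mu) * 30)
  picks <- character(5)
  for (i in 1:5) {
    idx <- sample.int(n, n, replace = TRUE)
    picks[i] <- select_link(y[idx], x[idx])$link
  }
  expect_gte(sum(picks == "log"), 3)
  fit <- select_link(y, x)
  expect_identical(nrow(fit$aic_table), 3L)
  expect_setequal(fit$aic_table$link, c("cloglog", "logit", "log"))
  # AIC selection invariant to response-order permutation
  set.seed(85)
  perm <- sample.int(n)
  expect_identical(select_link(y[perm], x[perm])$link, fit$link)
})

test_that("gaussian GLM recovers exact and simulated slopes", {
  x <- 1:10
  # exact line: lm warns about a perfect fit, which is the point here
  fit <- suppressWarnings(gaussian_glm(2 * x + 1, x))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-12)
  set.seed(86)
  xs <- rnorm(200)
  ys <- 0.5 + 1.7 * xs + rnorm(200)
  f2 <- gaussian_glm(ys, xs)
  expect_lt(abs(f2$coefficients$estimate[2] - 1.7), 2 * f2$coefficients$se[2])
  expect_error(gaussian_glm(ys, rep(1, 200)), "zero variance")
})

test_that("gaussian GLM p-values are calibrated under the null", {
  set.seed(87)
  pvals <- replicate(1000, {
    x <- rnorm(30)
    y <- rnorm(30)
    gaussian_glm(y, x)$coefficients$p[2]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
})

test_that("ANCOVA separates group shifts from covariate effects", {
  set.seed(88)
  n <- 60
  group <- rep(c("CM", "Map"), each = n / 2)
  cov <- rnorm(n)
  y <- 1.0 * cov + ifelse(group == "Map", 3, 0) + rnorm(n, 0, 0.5)
  fit <- ancova(y, group, cov)
  at <- fit$anova_table
  expect_lt(at["group", "Pr(>F)"], 1e-6)
  expect_lt(at["covariate", "Pr(>F)"], 1e-6)
  cov_slope <- fit$coefficients$estimate[fit$coefficients$term == "covariate"]
  expect_equal(cov_slope, 1.0, tolerance = 0.3)
  # identical groups: group F near 0
  y2 <- cov + rnorm(n, 0, 0.5)
  fit2 <- ancova(y2, group, cov)
  expect_gt(fit2$anova_table["group", "Pr(>F)"], 0.01)
  expect_error(ancova(y, rep("a", n), cov), ">= 2 groups")
})

test_that("pearson correlation reproduces exact and structural cases", {
  x <- 1:20
  fit <- pearson_correlation(x, -x)
  expect_equal(fit$coefficients$estimate, -1)
  expect_identical(fit$df, 18L)
  set.seed(89)
  xn <- rnorm(1000)
  f0 <- pearson_correlation(xn, rnorm(1000))
  expect_lt(abs(f0$coefficients$estimate), 0.1)
  # tm and r are near-perfectly anticorrelated through the correction
  tm <- seq(0.02, 0.98, length.out = 30)
  r <- primary_selfing_rate(1 - tm, 0.09)
  fr <- pearson_correlation(tm, r)
  expect_lte(fr$coefficients$estimate, -0.999)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
})
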