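test_that("Poisson offset fit matches the closed-form two-group MLE", {
  X <- cbind("(Intercept)" = 1, groupFEP = c(0, 0, 1))
  fit <- poisson_glm_offset(c(10, 20, 30), log(c(100, 200, 100)), X)
  expect_equal(unname(fit$coefficients),
               c(log(0.1), log(3)), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("rescaling exposures shifts only the intercept by -log(c)", {
  set.seed(31)
  n <- 60
  X <- cbind("(Intercept)" = 1, g = rbinom(n, 1, 0.5), z = rnorm(n))
  words <- sample(100:400, n, replace = TRUE)
  y <- rpois(n, exp(-3 + 0.4 * X[, "g"] + 0.1 * X[, "z"]) * words)
  f1 <- poisson_glm_offset(y, log(words), X)
  f2 <- poisson_glm_offset(y, log(words * 7), X)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] - log(7), tolerance = 1e-8)
  expect_equal(f1$coefficients[-1], f2$coefficients[-1], tolerance = 1e-8)
})

test_that("IRLS satisfies the score equations and agrees with stats::glm", {
  set.seed(32)
  for (i in 1:5) {
    n <- 80
    g <- factor(sample(c("NC", "FEP", "UHR"), n, replace = TRUE),
                levels = c("NC", "FEP", "UHR"))
    z <- rnorm(n)
    words <- sample(80:500, n, replace = TRUE)
    mu <- exp(-3.2 + 0.3 * (g == "FEP") - 0.2 * (g == "UHR") + 0.15 * z)
    y <- rpois(n, mu * words)
    X <- design_matrix(data.frame(group = g, z = z), covariates = "z")
    fit <- poisson_glm_offset(y, log(words), X)
    # score equations X'(y - mu) = 0 at the optimum
    expect_lt(max(abs(t(X) %*% (y - fit$fitted))), 1e-8)
    ref <- glm(y ~ g + scale(z, scale = FALSE), family = poisson,
               offset = log(words))
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-7)
    expect_equal(unname(fit$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
    expect_equal(fit$aic, AIC(ref), tolerance = 1e-6)
  }
})

test_that("an all-zero group is flagged as quasi-separated, not hidden", {
  X <- cbind("(Intercept)" = 1, groupFEP = rep(c(0, 1), each = 10))
  y <- c(rpois(10, 8) + 1, rep(0, 10))
  expect_warning(
    fit <- poisson_glm_offset(y, rep(log(200), 20), X),
    "quasi-separation")
  expect_true(fit$separation)
  expect_lt(fit$coefficients[["groupFEP"]], -10)
})

test_that("invalid designs and outcomes are rejected with named causes", {
  X <- cbind("(Intercept)" = 1, a = c(1, 2, 3), b = c(2, 4, 6))
  expect_error(poisson_glm_offset(c(1, 2, 3), rep(0, 3), X),
               "rank deficient.*b")
  X2 <- cbind("(Intercept)" = 1, a = c(1, 2, 0))
  expect_error(poisson_glm_offset(c(1.5, 2, 3), rep(0, 3), X2), "integers")
  expect_error(poisson_glm_offset(c(-1, 2, 3), rep(0, 3), X2),
               "non-negative")
})

test_that("model comparison implements LRT and AIC deltas for nested fits", {
  set.seed(33)
  n <- 150
  g <- rbinom(n, 1, 0.5)
  strong <- rnorm(n)
  words <- sample(100:300, n, replace = TRUE)
  y <- rpois(n, exp(-3 + 0.3 * g + 0.6 * strong) * words)
  Xf <- cbind("(Intercept)" = 1, g = g, strong = strong)
  Xr <- cbind("(Intercept)" = 1, g = g)
  full <- poisson_glm_offset(y, log(words), Xf)
  red <- poisson_glm_offset(y, log(words), Xr)
  cmp <- compare_models(full, red)
  expect_identical(cmp$df, 1L)
  expect_gt(cmp$lrt_stat, qchisq(0.999, 1))
  expect_gt(cmp$delta_aic, 0) # the strong covariate earns its parameter
  expect_equal(cmp$lrt_stat, 2 * (full$loglik - red$loglik))

  same <- compare_models(full, full)
  expect_equal(same$lrt_stat, 0)
  expect_equal(same$delta_aic, 0)
  expect_error(compare_models(red, full), "not nested")
  Xo <- cbind("(Intercept)" = 1, other = rnorm(n))
  other <- poisson_glm_offset(y, log(words), Xo)
  expect_error(compare_models(full, other), "not nested")
})

test_that("a null covariate's LRT is approximately chi-squared(1)", {
  set.seed(34)
  reps <- 200
  pvals <- replicate(reps, {
    n <- 120
    g <- rbinom(n, 1, 0.5)
    noise <- rnorm(n)
    words <- sample(100:300, n, replace = TRUE)
    y <- rpois(n, exp(-3 + 0.3 * g) * words)
    Xf <- cbind("(Intercept)" = 1, g = g, noise = noise)
    Xr <- cbind("(Intercept)" = 1, g = g)
    compare_models(poisson_glm_offset(y, log(words), Xf),
                   poisson_glm_offset(y, log(words), Xr))$p
  })
  rej <- mean(pvals < 0.05)
  expect_gt(rej, 0.01)
  expect_lt(rej, 0.11)
})

test_that("GEE equals OLS when every cluster is a singleton", {
  set.seed(35)
  n <- 90
  X <- cbind("(Intercept)" = 1, x = rnorm(n), z = rnorm(n))
  y <- drop(X %*% c(1, 0.5, -0.3)) + rnorm(n)
  fit <- gee_gaussian_exchangeable(y, X, cluster = seq_len(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit$coefficients), unname(ols$coefficients),
               tolerance = 1e-8)
  expect_equal(fit$rho, 0)
})

test_that("GEE recovers slope and working correlation on clustered data", {
  fits <- lapply(1:10, function(i) {
    d <- simulate_clustered_outcome(200, 4, beta = 0.5, rho = 0.4,
                                    sigma = 1, seed = 360 + i)
    gee_gaussian_exchangeable(d$y, d$X, d$cluster)
  })
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  expect_equal(mean(vapply(fits, `[[`, 0, "rho")), 0.4, tolerance = 0.05)
  expect_equal(mean(vapply(fits, function(f) f$coefficients[["x"]], 0)),
               0.5, tolerance = 0.05)
  fit <- fits[[1]]
  expect_true(all(fit$robust_se > 0))
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("sandwich covariance is invariant to cluster relabeling", {
  d <- simulate_clustered_outcome(50, 4, beta = 0.3, rho = 0.3, seed = 37)
  f1 <- gee_gaussian_exchangeable(d$y, d$X, d$cluster)
  relabeled <- paste0("c", rev(as.integer(factor(d$cluster))))
  f2 <- gee_gaussian_exchangeable(d$y, d$X, relabeled)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-10)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-10)
})

test_that("deviance GOF separates adequate from misspecified mean models", {
  set.seed(38)
  n_cl <- 100
  x <- rnorm(n_cl * 3)
  cl <- rep(seq_len(n_cl), each = 3)
  X <- cbind("(Intercept)" = 1, x = x)

  y_perfect <- drop(X %*% c(2, 1))
  fit_p <- gee_gaussian_exchangeable(y_perfect + rnorm(length(x), 0, 1e-8),
                                     X, cl)
  expect_lt(deviance_gof(fit_p)$deviance, 1e-10)

  y_ok <- drop(X %*% c(2, 1)) + rnorm(length(x))
  fit_ok <- gee_gaussian_exchangeable(y_ok, X, cl)
  gof_ok <- deviance_gof(fit_ok, sigma2 = 1)
  expect_gt(gof_ok$deviance_per_df, 0.8)
  expect_lt(gof_ok$deviance_per_df, 1.2)

  y_bad <- drop(X %*% c(2, 1)) + 3 * x^2 + rnorm(length(x))
  fit_bad <- gee_gaussian_exchangeable(y_bad, X, cl)
  expect_gt(deviance_gof(fit_bad, sigma2 = 1)$deviance_per_df, 5)
})

test_that("Spearman partial correlation behaves at its anchors", {
  set.seed(39)
  x <- rnorm(100)
  expect_equal(spearman_partial(x, x)$rho, 1)
  expect_equal(spearman_partial(x, x)$p, 0)

  # x and y driven by z alone (plus noise): controlling z kills the link
  z <- rnorm(300)
  x_z <- 2 * z + 0.2 * rnorm(300)
  y_z <- z^3 + 0.2 * rnorm(300)
  expect_gt(abs(spearman_partial(x_z, y_z)$rho), 0.7)
  pc <- spearman_partial(x_z, y_z, Z = cbind(z = z))
  expect_lt(abs(pc$rho), 0.12)
  # exactly rank-collinear input is degenerate and says so
  expect_error(spearman_partial(2 * z + 1, z^3, Z = cbind(z = z)),
               "collinear")

  # no covariates reduces to ordinary Spearman
  y <- x + rnorm(100)
  expect_equal(spearman_partial(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)

  expect_error(spearman_partial(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_partial(rnorm(5), rnorm(6)), "equal length")
})

test_that("partial-correlation p-values are near-uniform under the null", {
  set.seed(40)
  pvals <- replicate(150, {
    z <- rnorm(80)
    spearman_partial(rnorm(80) + 0.5 * z, rnorm(80) - 0.3 * z,
                     Z = cbind(z = z))$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.06)
})

test_that("BH q-values match the examples and brute force", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.5))$q, c(0.01, 0.5))
  expect_equal(bh_fdr(0.3)$q, 0.3)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:100) {
    p <- runif(sample(1:25, 1))
    r <- bh_fdr(p, family = "test")
    expect_equal(r$q, bh_brute_force(p), tolerance = 1e-12)
    expect_true(all(r$q >= r$p - 1e-15))
  }
})

test_that("fit q-values are BH within the non-intercept family", {
  set.seed(43)
  n <- 100
  X <- design_matrix(data.frame(group = sample(c("NC", "FEP", "UHR"), n,
                                               replace = TRUE),
                                age = rnorm(n, 22, 4)),
                     covariates = "age")
  words <- sample(100:300, n, replace = TRUE)
  y <- rpois(n, 0.05 * words)
  fit <- poisson_glm_offset(y, log(words), X)
  idx <- names(fit$p) != "(Intercept)"
  expect_true(is.na(fit$q[["(Intercept)"]]))
  expect_equal(unname(fit$q[idx]), bh_brute_force(unname(fit$p[idx])),
               tolerance = 1e-12)
})
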