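test_that("OLS reproduces exact fits and matches the closed-form oracle", {
  d <- tibble::tibble(ab = 1:10, longevity = 2 * (1:10) + 1)
  m <- fit_longevity_ols(d, ab)
  g <- suppressWarnings(glance(m)) # summary.lm warns on an exact fit
  expect_equal(g$r_squared, 1)
  expect_equal(g$slope, 2, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- rnorm(n, 1 + 0.5 * x, 2)
    m <- fit_longevity_ols(tibble::tibble(a = x, longevity = y), a)
    o <- ols_oracle(x, y)
    td <- tidy(m)
    expect_lt(max(abs(td$estimate - c(o$b0, o$b1))), 1e-10)
    expect_lt(abs(glance(m)$r_squared - o$r2), 1e-10)
    expect_lt(abs(glance(m)$p_value - o$p), 1e-10)
  }
  expect_error(fit_longevity_ols(tibble::tibble(a = rep(1, 5),
                                                longevity = rnorm(5)), a),
               "zero variance")
})

test_that("residuals sum to zero and missing predictors are dropped", {
  d <- tibble::tibble(a = c(rnorm(20), NA, -Inf), longevity = rnorm(22))
  m <- fit_longevity_ols(d, a)
  expect_equal(m$n, 20)
  expect_equal(m$n_dropped, 2)
  expect_lt(abs(sum(augment(m)$.resid)), 1e-10)
})

test_that("ANOVA matches the dummy-variable regression and the t-test", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    g <- sample(letters[1:k], 40, replace = TRUE)
    while (min(table(g)) < 2) g <- sample(letters[1:k], 40, replace = TRUE)
    y <- rnorm(40, as.integer(factor(g)))
    m <- longevity_anova(tibble::tibble(grp = g, longevity = y), grp)
    o <- anova_oracle(y, g)
    expect_lt(abs(glance(m)$f_stat - o$f), 1e-10)
    expect_lt(abs(glance(m)$p_value - o$p), 1e-10)
  }
  # two groups: F is the square of the equal-variance t statistic
  y <- rnorm(30); g <- rep(c("E", "C"), 15)
  m <- longevity_anova(tibble::tibble(g = g, longevity = y), g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(glance(m)$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)

  # equal group means give F = 0 exactly
  d0 <- tibble::tibble(g = rep(c("a", "b"), each = 3),
                       longevity = rep(c(1, 2, 3), 2))
  expect_equal(glance(longevity_anova(d0, g))$f_stat, 0)

  expect_error(
    longevity_anova(tibble::tibble(g = c("a", "a", "b"),
                                   longevity = rnorm(3)), g),
    "fewer than 2 members: b"
  )
})

test_that("slope test holds its nominal size under the null", {
  set.seed(11)
  reject <- vapply(1:500, function(i) {
    d <- tibble::tibble(a = rnorm(50), longevity = rnorm(50))
    glance(fit_longevity_ols(d, a))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})

test_that("residual diagnostics behave on known geometries", {
  # exact line: vanishing residuals
  d <- tibble::tibble(a = 1:20, longevity = 3 + 2 * (1:20))
  m <- fit_longevity_ols(d, a)
  expect_true(all(abs(augment(m)$.resid) < 1e-10))

  # quadratic truth fitted linearly: long same-sign residual runs
  set.seed(2)
  x <- seq(-3, 3, length.out = 80)
  dq <- tibble::tibble(a = x, longevity = x^2 + rnorm(80, 0, 0.1))
  diag_q <- residual_diagnostics(fit_longevity_ols(dq, a))
  expect_lt(diag_q$runs_z, -3)

  # well-specified homoscedastic model: tests quiet in >= 90% of seeds
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    d <- tibble::tibble(a = rnorm(60), longevity = 1 + 0.5 * rnorm(60))
    dg <- residual_diagnostics(fit_longevity_ols(d, a))
    dg$shapiro_p > 0.05 && dg$bp_p > 0.05
  }, logical(1))
  expect_gte(mean(flags), 0.85)
})

test_that("mixed model collapses to OLS when between-group variance is zero", {
  set.seed(3)
  d <- tibble::tibble(
    a = rnorm(200),
    biogeo = sample(c("E", "C"), 200, replace = TRUE),
    longevity = 5 + 1.2 * a + rnorm(200) # no group effect at all
  )
  expect_warning(
    m <- fit_longevity_mixed(d, a, biogeo),
    "singular"
  )
  expect_true(m$singular)
  g <- glance(m)
  expect_equal(g$group_sd, 0, tolerance = 1e-6)
  ols <- fit_longevity_ols(d, a)
  expect_equal(g$slope, glance(ols)$slope, tolerance = 1e-6)
  # ML fit with a zero variance component has the same log-likelihood
  expect_equal(g$log_lik, glance(ols)$log_lik, tolerance = 1e-6)
})

test_that("a real group offset is picked up by the grouped models", {
  set.seed(9)
  d <- tibble::tibble(
    a = rnorm(200),
    biogeo = sample(c("E", "C"), 200, replace = TRUE)
  )
  d$longevity <- 5 + 0.5 * d$a + ifelse(d$biogeo == "E", 3, 0) + rnorm(200, 0, 1)
  anc <- fit_longevity_mixed(d, a, biogeo, random = FALSE)
  coefs <- tidy(anc)
  offset <- coefs$estimate[grepl("^g", coefs$term)]
  expect_equal(abs(unname(offset)), 3, tolerance = 0.5)
  m <- fit_longevity_mixed(d, a, biogeo)
  expect_false(m$singular)
  expect_gt(glance(m)$group_sd, 0.5)
})

test_that("AICc arithmetic and limits are exact", {
  expect_equal(aicc(-10, k = 2, n = 10) - aicc(-10, k = 2, n = 10, correct = FALSE),
               12 / 7)
  expect_equal(aicc(-10, k = 3, n = 1e6), aicc(-10, k = 3, n = 1e6, correct = FALSE),
               tolerance = 1e-4)
  expect_error(aicc(-10, k = 4, n = 5), "n > k")
  # delta is invariant to shifting both log-likelihoods
  d1 <- aicc(-20, 3, 50) - aicc(-18, 4, 50)
  d2 <- aicc(-20 + 7, 3, 50) - aicc(-18 + 7, 4, 50)
  expect_equal(d1, d2)
})

test_that("model comparison prefers parsimony on null data", {
  set.seed(13)
  d <- tibble::tibble(a = rnorm(100), longevity = rnorm(100),
                      biogeo = sample(c("E", "C"), 100, replace = TRUE))
  ols <- fit_longevity_ols(d, a)
  expect_equal(compare_aicc(ols, ols)$delta_aicc, 0)

  # an uninformative extra parameter costs ~2 in AIC but earns back a
  # chi-square(1) of likelihood: the mean penalty is near 1
  deltas <- vapply(1:300, function(s) {
    set.seed(s)
    n <- 500
    x <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n, x)
    f1 <- lm(y ~ x); f2 <- lm(y ~ x + x2)
    aicc(as.numeric(logLik(f2)), attr(logLik(f2), "df"), n) -
      aicc(as.numeric(logLik(f1)), attr(logLik(f1), "df"), n)
  }, numeric(1))
  expect_equal(mean(deltas), 1, tolerance = 0.35)
  expect_gt(mean(deltas > 0), 0.7) # the simple model usually wins

  d2 <- d[1:60, ]
  ols2 <- fit_longevity_ols(d2, a)
  expect_error(compare_aicc(ols, ols2), "different numbers")
})
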