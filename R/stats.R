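#' Ordinary least-squares regression of longevity on an abundance metric
#'
#' Fits `longevity ~ predictor` by OLS, the core test of whether relative
#' abundance predicts stratigraphic longevity. Predictors are expected to be
#' natural-log-transformed percent abundances ([abundance_summary()]), which
#' de-skews the heavy right tail of abundance distributions. Rows with a
#' missing predictor or response are dropped (and counted in the result).
#'
#' @param data per-species tibble (e.g. from [species_table()]).
#' @param predictor,response unquoted column names; `response` defaults to
#'   `longevity`.
#' @param label optional model label carried into summaries.
#' @return An object of class `range_ols` wrapping the `lm` fit, with
#'   [tidy()], [glance()], [augment()] and [autoplot()] methods.
#' @export
fit_longevity_ols <- function(data, predictor, response = longevity,
                              label = NULL) {
  pred <- rlang::ensym(predictor)
  resp <- rlang::ensym(response)
  d <- data |>
    dplyr::select(x = !!pred, y = !!resp) |>
    dplyr::filter(is.finite(.data$x), is.finite(.data$y))
  n_dropped <- nrow(data) - nrow(d)
  if (nrow(d) < 3) abort("need at least 3 complete observations")
  if (var(d$x) == 0) abort("predictor has zero variance")
  fit <- lm(y ~ x, data = d)
  structure(
    list(
      fit = fit,
      label = label %||% paste0(rlang::as_string(resp), " ~ ",
                                rlang::as_string(pred)),
      predictor = rlang::as_string(pred),
      response = rlang::as_string(resp),
      n = nrow(d), n_dropped = n_dropped
    ),
    class = "range_ols"
  )
}

#' @export
print.range_ols <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<range_ols> %s  (n = %d%s)\n  slope = %.4g (p = %.3g), R^2 = %.4f, AICc = %.2f\n",
    x$label, x$n,
    if (x$n_dropped > 0) paste0(", ", x$n_dropped, " dropped") else "",
    g$slope, g$p_value, g$r_squared, g$aicc
  ))
  invisible(x)
}

#' @rdname fit_longevity_ols
#' @param x,object a `range_ols`.
#' @param ... unused.
#' @method tidy range_ols
#' @export
tidy.range_ols <- function(x, ...) {
  s <- unname(summary(x$fit)$coefficients)
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @rdname fit_longevity_ols
#' @method glance range_ols
#' @export
glance.range_ols <- function(x, ...) {
  s <- summary(x$fit)
  ll <- logLik(x$fit)
  k <- attr(ll, "df")
  tibble::tibble(
    label = x$label, n = x$n,
    slope = coef(x$fit)[["x"]],
    r_squared = s$r.squared,
    f_stat = unname(s$fstatistic[1]),
    p_value = s$coefficients["x", 4],
    sigma = s$sigma,
    log_lik = as.numeric(ll), k = k,
    aic = aicc(as.numeric(ll), k, x$n, correct = FALSE),
    aicc = aicc(as.numeric(ll), k, x$n)
  )
}

#' @rdname fit_longevity_ols
#' @method augment range_ols
#' @export
augment.range_ols <- function(x, ...) {
  mf <- x$fit$model
  fit_vals <- unname(fitted(x$fit))
  res_vals <- unname(resid(x$fit))
  tibble::tibble(x = mf$x, y = mf$y, .fitted = fit_vals, .resid = res_vals)
}

#' Residual diagnostics for a fitted regression
#'
#' Advisory checks that the regression assumptions hold: Shapiro-Wilk
#' normality of residuals, the Breusch-Pagan test for heteroscedasticity,
#' and a residual sign-runs count (fewer runs than expected flags a missed
#' nonlinear trend). These are reported, never used to gate an analysis.
#'
#' @param model a `range_ols` (or bare `lm`).
#' @return One-row tibble: `shapiro_w`, `shapiro_p`, `bp_stat`, `bp_p`,
#'   `n_sign_runs`, `expected_runs`, `runs_z` (negative = too few runs,
#'   i.e. residuals cluster by sign along the fitted axis).
#' @export
residual_diagnostics <- function(model) {
  fit <- if (inherits(model, "range_ols")) model$fit else model
  stopifnot(inherits(fit, "lm"))
  r <- resid(fit)[order(fitted(fit))]
  sw <- shapiro.test(r)
  bp <- lmtest::bptest(fit)
  s <- sign(r)
  s <- s[s != 0]
  runs <- 1L + sum(diff(s) != 0)
  n1 <- sum(s > 0); n2 <- sum(s < 0); nn <- n1 + n2
  mu <- 1 + 2 * n1 * n2 / nn
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  tibble::tibble(
    shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    bp_stat = unname(bp$statistic), bp_p = bp$p.value,
    n_sign_runs = runs, expected_runs = mu,
    runs_z = if (sigma2 > 0) (runs - mu) / sqrt(sigma2) else NA_real_
  )
}

#' One-way fixed-effects ANOVA of longevity across groups
#'
#' Tests whether species longevities differ among groups such as the
#' polycystine radiolarian orders (Collodaria / Nassellaria / Spumellaria)
#' or biogeographic categories (endemic / cosmopolitan). Classical one-way
#' ANOVA via [stats::aov()]; every group must contribute at least two
#' species.
#'
#' @param data per-species tibble.
#' @param group unquoted grouping column (e.g. `order_code`).
#' @param response unquoted response column, default `longevity`.
#' @return An object of class `range_anova` with [tidy()] and [glance()]
#'   methods; `$groups` holds per-group n and mean.
#' @export
longevity_anova <- function(data, group, response = longevity) {
  grp <- rlang::ensym(group)
  resp <- rlang::ensym(response)
  d <- data |>
    dplyr::select(g = !!grp, y = !!resp) |>
    dplyr::filter(!is.na(.data$g), is.finite(.data$y)) |>
    dplyr::mutate(g = factor(.data$g))
  sizes <- dplyr::count(d, .data$g)
  small <- sizes$g[sizes$n < 2]
  if (nlevels(d$g) < 2) abort("need at least 2 groups")
  if (length(small) > 0) {
    abort(paste0("group(s) with fewer than 2 members: ",
                 paste(small, collapse = ", ")))
  }
  fit <- aov(y ~ g, data = d)
  groups <- d |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     median = median(.data$y), sd = sd(.data$y),
                     .groups = "drop") |>
    dplyr::rename(group = "g")
  structure(
    list(fit = fit, groups = groups, group_var = rlang::as_string(grp),
         response = rlang::as_string(resp), n = nrow(d)),
    class = "range_anova"
  )
}

#' @export
print.range_anova <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<range_anova> %s by %s: F(%d, %d) = %.4g, p = %.4g\n",
              x$response, x$group_var, g$df_between, g$df_within,
              g$f_stat, g$p_value))
  invisible(x)
}

#' @rdname longevity_anova
#' @param x a `range_anova`.
#' @param ... unused.
#' @method tidy range_anova
#' @export
tidy.range_anova <- function(x, ...) {
  a <- summary(x$fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(a)), df = a$Df, sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`, statistic = a$`F value`, p.value = a$`Pr(>F)`
  )
}

#' @rdname longevity_anova
#' @method glance range_anova
#' @export
glance.range_anova <- function(x, ...) {
  a <- summary(x$fit)[[1]]
  tibble::tibble(
    f_stat = a$`F value`[1], p_value = a$`Pr(>F)`[1],
    df_between = a$Df[1], df_within = a$Df[2], n = x$n
  )
}

#' Linear mixed-effects model: abundance fixed, biogeography random
#'
#' Fits `response ~ predictor + (1 | group)` with `lme4`, combining an
#' abundance metric and a categorical biogeographic range class as joint
#' predictors of longevity. Estimation is by maximum likelihood (not REML)
#' so the fit's AICc is comparable with the abundance-only OLS model.
#' Random intercepts on a two-level factor are fragile: a singular fit
#' (between-category variance estimated at zero) is reported with a
#' warning, not an error, and the model is still returned. A fixed-effects
#' ANCOVA variant (`random = FALSE`) is available for sensitivity checks.
#'
#' @param data per-species tibble.
#' @param predictor unquoted fixed-effect column (e.g. `ln_mean_ra`).
#' @param group unquoted grouping column (e.g. `biogeo_code`).
#' @param response unquoted response, default `longevity`.
#' @param random fit the group as a random intercept (default) or as a
#'   fixed ANCOVA term.
#' @return An object of class `range_lmm` with [tidy()]/[glance()] methods.
#'   `$singular` flags a zero variance-component estimate.
#' @export
fit_longevity_mixed <- function(data, predictor, group, response = longevity,
                                random = TRUE) {
  pred <- rlang::ensym(predictor)
  grp <- rlang::ensym(group)
  resp <- rlang::ensym(response)
  d <- data |>
    dplyr::select(x = !!pred, g = !!grp, y = !!resp) |>
    dplyr::filter(is.finite(.data$x), is.finite(.data$y), !is.na(.data$g)) |>
    dplyr::mutate(g = factor(.data$g))
  if (nrow(d) < 10) abort("need at least 10 complete observations")
  if (nlevels(d$g) < 2) abort("grouping factor must have >= 2 levels")
  singular <- FALSE
  if (random) {
    fit <- suppressMessages(
      lme4::lmer(y ~ x + (1 | g), data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )
    singular <- lme4::isSingular(fit, tol = 1e-5)
    if (singular) {
      warn("singular mixed-model fit: between-group variance estimated at 0")
    }
  } else {
    fit <- lm(y ~ x + g, data = d)
  }
  structure(
    list(fit = fit, random = random, singular = singular, n = nrow(d),
         data = d,
         predictor = rlang::as_string(pred), group_var = rlang::as_string(grp),
         response = rlang::as_string(resp)),
    class = "range_lmm"
  )
}

#' @export
print.range_lmm <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<range_lmm> %s ~ %s + (1 | %s), ML%s\n  n = %d, slope = %.4g, group sd = %.4g, AICc = %.2f\n",
    x$response, x$predictor, x$group_var,
    if (x$singular) " [singular]" else "", x$n, g$slope, g$group_sd, g$aicc
  ))
  invisible(x)
}

#' @rdname fit_longevity_mixed
#' @param x a `range_lmm`.
#' @param ... unused.
#' @method tidy range_lmm
#' @export
tidy.range_lmm <- function(x, ...) {
  if (x$random) {
    s <- summary(x$fit)$coefficients
    fixed <- tibble::tibble(
      effect = "fixed", term = rownames(s),
      estimate = unname(s[, "Estimate"]),
      std.error = unname(s[, "Std. Error"]),
      statistic = unname(s[, "t value"])
    )
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    ran <- tibble::tibble(
      effect = "ran_pars",
      term = paste0("sd_", vc$grp),
      estimate = vc$sdcor, std.error = NA_real_, statistic = NA_real_
    )
    dplyr::bind_rows(fixed, ran)
  } else {
    s <- summary(x$fit)$coefficients
    tibble::tibble(
      effect = "fixed", term = rownames(s), estimate = unname(s[, 1]),
      std.error = unname(s[, 2]), statistic = unname(s[, 3])
    )
  }
}

#' @rdname fit_longevity_mixed
#' @method glance range_lmm
#' @export
glance.range_lmm <- function(x, ...) {
  ll <- logLik(x$fit)
  k <- attr(ll, "df")
  group_sd <- if (x$random) {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    vc$sdcor[vc$grp == "g"][1]
  } else NA_real_
  slope <- if (x$random) lme4::fixef(x$fit)[["x"]] else coef(x$fit)[["x"]]
  tibble::tibble(
    n = x$n, slope = slope, group_sd = group_sd,
    singular = x$singular, log_lik = as.numeric(ll), k = k,
    aic = aicc(as.numeric(ll), k, x$n, correct = FALSE),
    aicc = aicc(as.numeric(ll), k, x$n)
  )
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AIC = 2k - 2 logLik`; `AICc = AIC + 2k(k+1)/(n - k - 1)`, which
#' penalizes parameters more sharply when observations are few and
#' converges to plain AIC as `n` grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including the residual
#'   variance).
#' @param n number of observations; must exceed `k + 1`.
#' @param correct apply the small-sample correction (set `FALSE` for plain
#'   AIC).
#' @return The (corrected) AIC as a number.
#' @examples
#' aicc(-10, k = 2, n = 10) - aicc(-10, k = 2, n = 10, correct = FALSE) # 12/7
#' @export
aicc <- function(loglik, k, n, correct = TRUE) {
  if (correct && n <= k + 1) abort("AICc requires n > k + 1")
  2 * k - 2 * loglik + if (correct) 2 * k * (k + 1) / (n - k - 1) else 0
}

#' Compare two fitted models by AICc
#'
#' Computes `delta = AICc(complex) - AICc(simple)` for two models of the
#' same response vector; positive delta means the extra structure of the
#' complex model is not worth its parameters and the simple model is
#' preferred.
#'
#' @param simple,complex fitted `range_ols` / `range_lmm` objects.
#' @return One-row tibble: `aicc_simple`, `aicc_complex`, `delta_aicc`,
#'   `preferred`.
#' @export
compare_aicc <- function(simple, complex) {
  g1 <- glance(simple)
  g2 <- glance(complex)
  if (g1$n != g2$n) {
    abort(sprintf("models fit different numbers of observations (%d vs %d)",
                  g1$n, g2$n))
  }
  delta <- g2$aicc - g1$aicc
  tibble::tibble(
    aicc_simple = g1$aicc, aicc_complex = g2$aicc, delta_aicc = delta,
    preferred = if (delta > 0) "simple" else "complex"
  )
}
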