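#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test on a series in temporal (age) order.
#' The S statistic counts concordant minus discordant pairs; its variance is
#' tie-corrected and the two-sided p-value uses the normal approximation with
#' continuity correction. Kendall's tau is the tie-corrected (tau-b)
#' normalization of S against an untied time axis.
#'
#' @param y Numeric series ordered by age; `n >= 4`.
#' @return List with `s`, `tau`, `var_s`, `p_value`, `n`, and `all_tied`
#'   (`TRUE` when every value is identical, in which case `tau = 0`,
#'   `p = 1`).
#' @export
mann_kendall <- function(y) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4) stop("Mann-Kendall needs at least 4 observations")
  sgn <- sign(outer(y, y, "-"))
  s <- sum(sgn[lower.tri(sgn)])   # sum over i < j of sign(y_j - y_i)

  ties <- table(y)
  ties <- ties[ties > 1]
  if (length(ties) == n || all(y == y[1])) {
    return(list(s = 0L, tau = 0, var_s = 0, p_value = 1, n = n,
                all_tied = TRUE))
  }
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  d0 <- n * (n - 1) / 2
  tau <- s / sqrt((d0 - sum(ties * (ties - 1) / 2)) * d0)
  z <- if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  list(s = as.integer(s), tau = tau, var_s = var_s,
       p_value = 2 * stats::pnorm(-abs(z)), n = n, all_tied = FALSE)
}

#' Sen's slope and intercept
#'
#' Robust nonparametric regression line: the slope is the median of all
#' pairwise slopes between observations with distinct ages, and the
#' intercept is the median of `y - slope * x`.
#'
#' @param x Ages (or any ordinate) with at least 2 distinct values.
#' @param y Values, same length as `x`.
#' @return List with `slope`, `intercept`, `n`.
#' @export
sen_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("Sen slope undefined: all ages identical")
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  use <- lower.tri(dx) & dx != 0
  slope <- stats::median(dy[use] / dx[use])
  list(slope = slope, intercept = stats::median(y - slope * x),
       n = length(x))
}

#' Linear mixed trend of a response against stand age
#'
#' Fits `value ~ age` with a plot-level random intercept (REML), the model
#' for subplot-replicated responses along a chronosequence. When the
#' response is plot-level (one value per plot) the model reduces to ordinary
#' least squares. The association is reported as
#' `sign(slope) * sqrt(marginal R^2)`, the correlation attributable to the
#' fixed age effect. Singular random-effect fits degrade to OLS with a
#' warning rather than failing.
#'
#' @param values Response values (one per subplot or per plot).
#' @param ages Stand age for each value (years).
#' @param plot_ids Plot identifier for each value.
#' @return A `trend_result`: list with `method` (`"mixed_linear"`), `slope`,
#'   `intercept`, `association` (signed sqrt of marginal R^2), `p_value`
#'   (Wald normal approximation on the slope), `n`, `n_plots`, and the
#'   fitted `model`.
#' @export
mixed_trend <- function(values, ages, plot_ids) {
  stopifnot(length(values) == length(ages), length(ages) == length(plot_ids))
  dat <- data.frame(value = values, age = ages, plot = factor(plot_ids))
  dat <- dat[stats::complete.cases(dat), ]
  n_plots <- length(unique(dat$plot))
  if (n_plots < 3) stop("need at least 3 plots for a trend")

  plot_level <- !any(duplicated(dat$plot))
  if (plot_level) {
    m <- stats::lm(value ~ age, data = dat)
    cf <- stats::coef(m)
    se <- summary(m)$coefficients["age", "Std. Error"]
    r2m <- summary(m)$r.squared
  } else {
    m <- tryCatch(
      lme4::lmer(value ~ age + (1 | plot), data = dat, REML = TRUE),
      error = function(e) NULL)
    se <- if (!is.null(m) && !lme4::isSingular(m, tol = 1e-5)) {
      tryCatch(sqrt(diag(as.matrix(stats::vcov(m))))[["age"]],
               error = function(e) NULL)
    }
    if (is.null(se)) {
      warning("singular or failed mixed fit; falling back to OLS")
      return(.as_ols_trend(dat))
    }
    cf <- lme4::fixef(m)
    # marginal R^2: variance of the fixed-effect predictions over the total
    var_f <- stats::var(cf[["age"]] * dat$age)
    vc <- as.data.frame(lme4::VarCorr(m))
    r2m <- var_f / (var_f + sum(vc$vcov))
  }
  z <- cf[["age"]] / se
  structure(list(method = "mixed_linear",
                 slope = unname(cf[["age"]]), intercept = unname(cf[[1]]),
                 association = sign(cf[["age"]]) * sqrt(max(r2m, 0)),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n = nrow(dat), n_plots = n_plots, model = m),
            class = "trend_result")
}

.as_ols_trend <- function(dat) {
  m <- stats::lm(value ~ age, data = dat)
  cf <- stats::coef(m)
  structure(list(method = "mixed_linear",
                 slope = unname(cf[["age"]]), intercept = unname(cf[[1]]),
                 association = sign(cf[["age"]]) * sqrt(summary(m)$r.squared),
                 p_value = summary(m)$coefficients["age", "Pr(>|t|)"],
                 n = nrow(dat), n_plots = length(unique(dat$plot)),
                 model = m),
            class = "trend_result")
}

#' Parametric-assumption check for a fitted trend
#'
#' Tests the residuals of a linear (mixed) trend for normality
#' (Shapiro-Wilk) and for homoscedasticity against age (Breusch-Pagan),
#' both at `alpha = 0.05`. Failing either is the signal to switch to the
#' nonparametric Mann-Kendall + Sen route.
#'
#' @param residuals Model residuals.
#' @param ages Age covariate aligned with the residuals.
#' @param alpha Significance level (default 0.05).
#' @return List with `normal`, `homoscedastic`, `pass` (both true), and the
#'   two p-values.
#' @export
check_assumptions <- function(residuals, ages, alpha = 0.05) {
  stopifnot(length(residuals) == length(ages))
  if (length(residuals) < 3) stop("cannot test assumptions with n < 3")
  p_sw <- stats::shapiro.test(residuals)$p.value
  p_bp <- lmtest::bptest(stats::lm(residuals ~ ages))$p.value
  list(normal = p_sw >= alpha, homoscedastic = p_bp >= alpha,
       pass = p_sw >= alpha && p_bp >= alpha,
       p_shapiro = p_sw, p_breusch_pagan = unname(p_bp))
}

#' Trend of a chronosequence metric against stand age
#'
#' The full inference rule for one metric: fit the linear mixed (or OLS)
#' trend, check its parametric assumptions, and fall back to the
#' Mann-Kendall test with Sen's regression line when they fail. The
#' nonparametric route operates on plot-level means ordered by age.
#'
#' @param values Metric values.
#' @param ages Stand ages aligned with `values`.
#' @param plot_ids Plot identifiers aligned with `values`.
#' @param fallback `"auto"` (assumption-gated, the default), `"mk"` (force
#'   Mann-Kendall + Sen), or `"lmm"` (force the linear mixed route).
#' @return A `trend_result` with `method` either `"mixed_linear"` or
#'   `"mann_kendall_sen"`; the latter carries Kendall's tau as the
#'   association and Sen's slope/intercept.
#' @export
trend_with_age <- function(values, ages, plot_ids,
                           fallback = c("auto", "mk", "lmm")) {
  fallback <- match.arg(fallback)
  run_mk <- function() {
    pm <- stats::aggregate(list(value = values),
                           by = list(age = ages, plot = plot_ids), mean)
    pm <- pm[order(pm$age), ]
    mk <- mann_kendall(pm$value)
    sen <- sen_regression(pm$age, pm$value)
    structure(list(method = "mann_kendall_sen",
                   slope = sen$slope, intercept = sen$intercept,
                   association = mk$tau, p_value = mk$p_value,
                   n = mk$n, n_plots = nrow(pm), model = NULL),
              class = "trend_result")
  }
  if (fallback == "mk") return(run_mk())
  lt <- mixed_trend(values, ages, plot_ids)
  if (fallback == "lmm") return(lt)
  res <- if (inherits(lt$model, "merMod")) stats::residuals(lt$model)
         else stats::residuals(lt$model)
  chk <- tryCatch(check_assumptions(res, ages[stats::complete.cases(values, ages)]),
                  error = function(e) list(pass = TRUE))
  if (isTRUE(chk$pass)) lt else run_mk()
}

#' @export
print.trend_result <- function(x, ...) {
  lab <- if (x$method == "mixed_linear") "linear mixed trend"
         else "Mann-Kendall + Sen trend"
  stat <- if (x$method == "mixed_linear") "r" else "tau"
  cat(sprintf("%s: slope %.4g, intercept %.4g, %s = %.3f, p = %.3g (n = %d)\n",
              lab, x$slope, x$intercept, stat, x$association, x$p_value, x$n))
  invisible(x)
}

#' Select the two structural predictors for a path model
#'
#' Collinearity among structural attributes forbids using them all, so two
#' are chosen: first the attribute most strongly correlated (in absolute
#' value) with the light descriptor, then, among the rest, the attribute
#' least correlated with the first. Ties break by attribute name order.
#'
#' @param cor_with_light Named vector of Pearson correlations between each
#'   candidate attribute and the light descriptor.
#' @param cor_between Square correlation matrix among the candidates (row
#'   and column names matching `names(cor_with_light)`).
#' @return Character vector of length 2: the selected attribute names.
#' @export
select_predictors <- function(cor_with_light, cor_between) {
  nm <- names(cor_with_light)
  if (is.null(nm) || length(nm) < 2) stop("need at least 2 named candidates")
  o <- order(-abs(cor_with_light), nm)     # ties -> alphabetical
  first <- nm[o[1]]
  rest <- setdiff(nm, first)
  if (length(rest) == 1) return(c(first, rest))
  rr <- abs(cor_between[rest, first])
  second <- rest[order(rr, rest)][1]
  c(first, second)
}

#' Standardized path model of age, structure and light
#'
#' Encodes the causal chain age -> structure -> light as a set of
#' standardized component regressions: `s1 ~ age`, `s2 ~ age`, and
#' `light ~ s1 + s2` (with an additional direct `age` edge into the light
#' response when `include_age_edge = TRUE`, as drawn for the understorey
#' heterogeneity model). All variables are z-standardized so coefficients
#' are comparable path strengths; `R^2` is reported for the final light
#' response only.
#'
#' @param age,s1,s2,light Numeric vectors of equal length (complete cases
#'   used).
#' @param names Character vector of 4 variable labels (age, s1, s2, light).
#' @param log_transform Log-transform (natural log) all four variables
#'   before standardizing — used for the attenuation-rate model to improve
#'   normality. All values must be positive.
#' @param include_age_edge Include the direct age -> light edge.
#' @param alpha Significance level for edge flags (default 0.05).
#' @return A `path_result`: list with `edges` (data frame of from, to,
#'   standardized coefficient, p-value, significance flag), `r_squared` of
#'   the light response, `n`, and the selected labels.
#' @export
path_model <- function(age, s1, s2, light,
                       names = c("age", "s1", "s2", "light"),
                       log_transform = FALSE, include_age_edge = FALSE,
                       alpha = 0.05) {
  d <- data.frame(age = age, s1 = s1, s2 = s2, light = light)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 5) stop("too few complete cases for a path model")
  if (log_transform) {
    if (any(d <= 0))
      stop("log transform requires strictly positive values")
    d[] <- lapply(d, log)
  }
  if (abs(stats::cor(d$s1, d$s2)) > 0.99)
    stop("s1 and s2 are collinear (|r| > 0.99); choose different predictors")
  dz <- as.data.frame(scale(d))

  comp <- function(f) {
    m <- stats::lm(f, data = dz)
    s <- summary(m)$coefficients
    list(coef = s[-1, "Estimate"], p = s[-1, "Pr(>|t|)"],
         r2 = summary(m)$r.squared)
  }
  m1 <- comp(s1 ~ age)
  m2 <- comp(s2 ~ age)
  f3 <- if (include_age_edge) light ~ s1 + s2 + age else light ~ s1 + s2
  m3 <- comp(f3)

  edges <- data.frame(
    from = c(names[1], names[1], names[2], names[3],
             if (include_age_edge) names[1]),
    to = c(names[2], names[3], names[4], names[4],
           if (include_age_edge) names[4]),
    coefficient = unname(c(m1$coef, m2$coef, m3$coef["s1"], m3$coef["s2"],
                           if (include_age_edge) m3$coef["age"])),
    p_value = unname(c(m1$p, m2$p, m3$p["s1"], m3$p["s2"],
                       if (include_age_edge) m3$p["age"])))
  edges$significant <- edges$p_value < alpha
  structure(list(edges = edges, r_squared = m3$r2, n = nrow(d),
                 response = names[4], log_transform = log_transform),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat("Standardized path model for ", x$response,
      if (x$log_transform) " (log-transformed)" else "", "\n", sep = "")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s: beta = %+.3f (p = %.3g)%s\n",
                e$from, e$to, e$coefficient, e$p_value,
                if (e$significant) " *" else ""))
  }
  cat(sprintf("  R^2 (%s) = %.3f, n = %d\n", x$response, x$r_squared, x$n))
  invisible(x)
}
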