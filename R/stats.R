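#' Linear mixed-effects model for nested per-cell data
#'
#' Fits `response ~ fixed + (1 | grouping)` by REML (via lme4), the model
#' used to compare groups when repeated cells are measured within each
#' sample: the fixed effect is the group contrast and each sample
#' contributes a random intercept. Inference on the fixed effect uses a t
#' test with Satterthwaite denominator degrees of freedom (via lmerTest) by
#' default; with only a handful of samples per group the normal (Wald z)
#' approximation is markedly anticonservative, which null simulations at
#' the 5 + 5-sample design confirm. Wald z remains available as an option.
#' Boundary fits (zero random-intercept variance) are flagged, not errored:
#' they collapse to ordinary least squares.
#'
#' @param data data.frame in long or metrics-table form.
#' @param response response column name (or `"value"` for a metrics table
#'   filtered to one metric).
#' @param fixed fixed-factor column name (e.g. `"group"`).
#' @param grouping grouping column name (e.g. `"sample_id"`).
#' @param dfMethod `"satterthwaite"` (default) or `"wald"`.
#' @return list of class `"LMMFit"`: `fixed_intercept`, `fixed_effect`,
#'   `se`, `statistic` (t or z), `df` (`Inf` for Wald), `p_value`,
#'   `random_intercept_sd`, `residual_sd`, `n_obs`, `n_groups`, `singular`,
#'   `converged`, and the underlying `fit`.
#' @export
fitLMM <- function(data, response = "value", fixed = "group",
                   grouping = "sample_id",
                   dfMethod = c("satterthwaite", "wald")) {
  dfMethod <- match.arg(dfMethod)
  stopifnot(all(c(response, fixed, grouping) %in% names(data)))
  data <- data[stats::complete.cases(data[, c(response, fixed, grouping)]), ]
  if (nrow(data) < 2L) stop("need more than one observation")
  if (length(unique(data[[fixed]])) < 2L)
    stop("fixed factor must have >= 2 levels")
  if (length(unique(data[[grouping]])) < 2L)
    stop("grouping variable must have >= 2 levels")
  df <- data.frame(y = data[[response]],
                   x = factor(data[[fixed]]),
                   g = factor(data[[grouping]]))
  ctrl <- lme4::lmerControl(check.conv.singular =
                              lme4::.makeCC(action = "ignore", tol = 1e-4))
  if (dfMethod == "satterthwaite") {
    fit <- suppressMessages(lmerTest::lmer(y ~ x + (1 | g), data = df,
                                           REML = TRUE, control = ctrl))
    co <- stats::coef(summary(fit))
    est <- co[2L, "Estimate"]
    se <- co[2L, "Std. Error"]
    stat <- co[2L, "t value"]
    dfree <- co[2L, "df"]
    p <- co[2L, "Pr(>|t|)"]
  } else {
    fit <- suppressMessages(lme4::lmer(y ~ x + (1 | g), data = df,
                                       REML = TRUE, control = ctrl))
    co <- stats::coef(summary(fit))
    est <- co[2L, "Estimate"]
    se <- co[2L, "Std. Error"]
    stat <- est / se
    dfree <- Inf
    p <- 2 * stats::pnorm(-abs(stat))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_sd <- vc$sdcor[vc$grp == "g"]
  res_sd <- vc$sdcor[vc$grp == "Residual"]
  structure(list(
    fixed_intercept = co[1L, "Estimate"],
    fixed_effect = est, se = se, statistic = stat, df = dfree, p_value = p,
    random_intercept_sd = ri_sd, residual_sd = res_sd,
    n_obs = nrow(df), n_groups = nlevels(df$g),
    singular = lme4::isSingular(fit),
    converged = length(fit@optinfo$conv$lme4) == 0L,
    df_method = dfMethod,
    fixed_levels = levels(df$x), fit = fit), class = "LMMFit")
}

#' @export
print.LMMFit <- function(x, ...) {
  cat(sprintf(
    "LMM %s vs %s: effect %.4g (SE %.3g, t = %.2f, df = %.3g, p = %.3g)%s\n",
    x$fixed_levels[2L], x$fixed_levels[1L], x$fixed_effect, x$se,
    x$statistic, x$df,
    x$p_value, if (x$singular) " [boundary: zero random variance]" else ""))
  cat(sprintf("  random-intercept SD %.3g, residual SD %.3g, n = %d obs / %d groups\n",
              x$random_intercept_sd, x$residual_sd, x$n_obs, x$n_groups))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA F test of whether samples stem from different
#' populations.
#'
#' @param values numeric vector of observations.
#' @param groups factor of the same length.
#' @return list of class `"TestResult"`: `statistic` (F), `df` (k-1, N-k),
#'   `p_raw`, `method`.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 observations")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1L]]
  structure(list(statistic = s[1L, "F value"],
                 df = c(s[1L, "Df"], s[2L, "Df"]),
                 p_raw = s[1L, "Pr(>F)"], p_adjusted = NULL,
                 method = "one-way ANOVA"), class = "TestResult")
}

#' Welch's unequal-variances t-test
#'
#' Two-tailed t-test with the Welch-Satterthwaite degrees of freedom, used
#' to compare two groups without assuming equal variances.
#'
#' @param x,y numeric vectors (each with >= 2 values).
#' @return list of class `"TestResult"`: `statistic` (t), `df` (fractional),
#'   `p_raw`, `method`.
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs >= 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      stop("zero variance in both samples with equal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_raw = ht$p.value,
                 p_adjusted = NULL,
                 method = "Welch two-sample t-test"), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_raw,
              if (!is.null(x$p_adjusted))
                sprintf(" (adjusted %.4g)", x$p_adjusted) else ""))
  invisible(x)
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusts a vector of p-values by the Holm-Bonferroni step-down procedure
#' (monotonicity enforced, capped at 1); the input order is preserved.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
holmBonferroni <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm")
}
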