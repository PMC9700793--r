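#' One-way ANCOVA with covariates
#'
#' Linear model `y ~ covariates + group`; the group effect is tested by
#' comparing the full model against the model without group (Type II sum of
#' squares - with a single factor plus covariates this matches the common
#' statistical packages). Effect size is partial eta squared,
#' `SS_group / (SS_group + SS_residual)`.
#'
#' Constant covariates carry no information and are dropped with a message
#' (the test then reduces to a one-way ANOVA). Any remaining rank deficiency
#' is an error naming the collinear columns.
#'
#' @param y numeric response (e.g., mean P-RSF scores).
#' @param group factor or character of group labels (>= 2 levels present).
#' @param covariates data frame of numeric covariates (e.g., MoCA, IFS),
#'   complete cases required.
#' @return object of class `prsf_ancova`: list with `F`, `df_effect`,
#'   `df_error`, `p`, `eta_p2`, `ss_effect`, `ss_error`, `n`.
#' @export
ancova_one_way <- function(y, group, covariates = NULL) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2)
    abort("ANCOVA needs at least 2 groups", "prsf_stats_error")
  dat <- data.frame(.y = y, .group = group)
  cov_names <- character()
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates) || anyNA(y))
      abort("ANCOVA requires complete y and covariates", "prsf_stats_error")
    for (cn in names(covariates)) {
      if (stats::var(covariates[[cn]]) == 0) {
        message(sprintf("covariate '%s' is constant; dropped", cn))
        next
      }
      dat[[cn]] <- covariates[[cn]]
      cov_names <- c(cov_names, cn)
    }
  }
  if (nrow(dat) <= nlevels(group) + length(cov_names))
    abort("too few observations for the ANCOVA design", "prsf_stats_error")
  rhs_cov <- if (length(cov_names) > 0) paste(cov_names, collapse = " + ")
             else "1"
  full <- stats::lm(stats::as.formula(
    paste(".y ~", rhs_cov, "+ .group")), data = dat)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    abort(sprintf("singular ANCOVA design; collinear column(s): %s",
                  paste(bad, collapse = ", ")), "prsf_stats_error")
  }
  reduced <- stats::lm(stats::as.formula(
    paste(".y ~", rhs_cov)), data = dat)
  cmp <- stats::anova(reduced, full)
  ss_effect <- cmp$`Sum of Sq`[2]
  ss_error <- cmp$RSS[2]
  df_effect <- cmp$Df[2]
  df_error <- cmp$Res.Df[2]
  Fval <- cmp$F[2]
  # a group effect exactly zero gives F = 0, not NA
  if (is.na(Fval)) Fval <- 0
  structure(list(
    F = Fval, df_effect = df_effect, df_error = df_error,
    p = stats::pf(Fval, df_effect, df_error, lower.tail = FALSE),
    eta_p2 = ss_effect / (ss_effect + ss_error),
    ss_effect = ss_effect, ss_error = ss_error, n = nrow(dat)
  ), class = "prsf_ancova")
}

#' Partial eta squared from an F statistic
#'
#' For a single effect, `eta_p2 = F * df1 / (F * df1 + df2)` - algebraically
#' identical to `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic (non-negative).
#' @param df_effect,df_error degrees of freedom.
#' @return partial eta squared in \[0, 1\].
#' @export
partial_eta_squared <- function(f, df_effect, df_error) {
  stopifnot(all(f >= 0), all(df_effect > 0), all(df_error > 0))
  f * df_effect / (f * df_effect + df_error)
}

#' Chi-square test of two counts against an equal split
#'
#' Goodness-of-fit test of observed counts `(a, b)` against expected
#' `(a+b)/2` in each cell: `chi2 = (a-e)^2/e + (b-e)^2/e`, df = 1, upper-tail
#' p. This is the matching test used to compare paired text statistics (word
#' counts, verb counts, ...) between two stories.
#'
#' @param count_a,count_b non-negative integer counts, not both zero.
#' @return list with `chi2`, `df`, `p`.
#' @export
chisq_equal_expected <- function(count_a, count_b) {
  stopifnot(is_scalar_number(count_a), is_scalar_number(count_b),
            count_a >= 0, count_b >= 0)
  if (count_a + count_b == 0)
    abort("both counts are zero; the test is undefined", "prsf_stats_error")
  ht <- suppressWarnings(
    stats::chisq.test(c(count_a, count_b), p = c(0.5, 0.5), correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Distribution-gated correlation
#'
#' Pearson's correlation when both variables look normal (Shapiro-Wilk,
#' alpha = 0.05 on each), Spearman's otherwise. Both the coefficient and the
#' method actually used are returned, so reports can state which was applied.
#'
#' @param x,y paired numeric vectors, complete, n >= 4.
#' @param alpha normality-gate significance level.
#' @return list with `r`, `p`, `method` (`"pearson"` or `"spearman"`), `n`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4)
    abort("correlation needs at least 4 complete pairs", "prsf_stats_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    abort("zero variance in x or y; correlation undefined", "prsf_stats_error")
  normal <- stats::shapiro.test(x)$p.value > alpha &&
    stats::shapiro.test(y)$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ht$estimate), p = ht$p.value, method = method,
       n = length(x))
}
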