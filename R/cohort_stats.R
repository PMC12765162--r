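#' Welch two-sample t-test between amyloid (or other) groups
#'
#' Unequal-variance (Welch) two-sample t-test of an ASL metric between two
#' groups, with a toggle for the pooled-variance variant.
#'
#' @param metric Numeric vector.
#' @param group Factor or vector with exactly two levels; the mean
#'   difference is level1 minus level2 in level order.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
welch_t <- function(metric, group, var_equal = FALSE) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  keep <- is.finite(metric) & !is.na(g)
  metric <- metric[keep]; g <- droplevels(g[keep])
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  tt <- stats::t.test(metric[g == levels(g)[1]], metric[g == levels(g)[2]],
                      var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(diff(rev(tt$estimate))))
}

#' One-way ANOVA with Tukey HSD post-hoc tests
#'
#' One-way analysis of variance of a metric across k groups, followed by
#' Tukey Honestly Significant Difference pairwise comparisons (studentized
#' range adjustment).
#'
#' @param metric Numeric vector.
#' @param group Factor with >= 2 levels, each with >= 2 observations.
#' @return List with `F`, `p`, and `pairwise` (data frame: pair, diff,
#'   lwr, upr, p_adj).
#' @export
anova_tukey <- function(metric, group) {
  g <- factor(group)
  keep <- is.finite(metric) & !is.na(g)
  metric <- metric[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 observations")
  fit <- stats::aov(metric ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], pairwise = pairwise)
}

.as_cohort_factors <- function(table) {
  table$sex <- factor(table$sex, levels = c("female", "male"))
  table$cogstage <- factor(table$cogstage, levels = c("CN", "SCD", "MCI"))
  table$fazekas <- factor(table$fazekas, levels = c("0", "1", "2", "3"))
  table$amyloid <- factor(table$amyloid, levels = c("A-", "A+"))
  table
}

#' Staged linear models for cohort inference
#'
#' Fits the staged linear-model ladder on one ASL metric with treatment
#' coding and the conventional reference levels (female, CN, Fazekas 0,
#' A-). Stages: `crude` (the chosen group predictor alone), `age_sex` (the
#' group predictor plus age and sex), `full` (all covariates together:
#' amyloid + cognitive staging + Fazekas + age + sex), and
#' `age_sex_interaction` (`metric ~ age + sex + age:sex`, uncentered age).
#' Rows with missing values in any variable entering the stage's formula
#' are dropped and counted.
#'
#' @param table Cohort data frame with columns `age`, `sex`, `cogstage`,
#'   `fazekas`, `amyloid` and the metric column.
#' @param metric Name of the metric column (e.g. `"gm_tex"`).
#' @param stage One of `"crude"`, `"age_sex"`, `"full"`,
#'   `"age_sex_interaction"`.
#' @param predictor Group predictor for the `crude` and `age_sex` stages:
#'   `"amyloid"`, `"cogstage"` or `"fazekas"`. Ignored by the other
#'   stages.
#' @return An object of class `lm_result`: data frame of terms (term,
#'   estimate, se, t, p) with attributes `model` (label), `n` (rows used),
#'   `n_dropped`, `sigma` (residual sd), and `fit` (the underlying `lm`).
#' @export
staged_lm <- function(table, metric,
                      stage = c("full", "crude", "age_sex",
                                "age_sex_interaction"),
                      predictor = c("amyloid", "cogstage", "fazekas")) {
  stage <- match.arg(stage)
  predictor <- match.arg(predictor)
  table <- .as_cohort_factors(as.data.frame(table))
  rhs <- switch(stage,
    crude = predictor,
    age_sex = paste(predictor, "+ age + sex"),
    full = "amyloid + cogstage + fazekas + age + sex",
    age_sex_interaction = "age + sex + age:sex")
  fml <- stats::as.formula(paste(metric, "~", rhs))
  vars <- all.vars(fml)
  complete <- stats::complete.cases(table[, vars])
  dat <- table[complete, ]
  # factor levels with no observations would produce aliased columns
  aliased <- character(0)
  for (v in vars) {
    if (is.factor(dat[[v]])) {
      absent <- setdiff(levels(dat[[v]]), unique(as.character(dat[[v]])))
      if (length(absent)) aliased <- c(aliased, paste0(v, absent))
    }
  }
  if (length(aliased))
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    t = co[, 3], p = co[, 4], row.names = NULL)
  attr(out, "model") <- stage
  attr(out, "n") <- nrow(dat)
  attr(out, "n_dropped") <- sum(!complete)
  attr(out, "sigma") <- sm$sigma
  attr(out, "fit") <- fit
  class(out) <- c("lm_result", "data.frame")
  out
}

#' Extract one coefficient from an `lm_result`
#'
#' @param res An [staged_lm()] result.
#' @param term Coefficient name as produced by `lm` (e.g. `"cogstageMCI"`).
#' @return The estimate (numeric scalar).
#' @export
lm_term <- function(res, term) {
  i <- match(term, res$term)
  if (is.na(i)) stop("no term '", term, "' in model")
  res$estimate[i]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate adjustment for the regional analyses; the
#' family is all ROI x contrast p-values within one metric.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
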