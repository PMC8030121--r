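#' Inferential layer
#'
#' Case-versus-control comparisons of clinical variables and genetic scores
#' (unpaired t-test with pooled variance by default, or Wilcoxon rank-sum),
#' ordinary least-squares regressions of each glucose measure on each score
#' with optional mutual glucose adjustment, ANCOVA sensitivity analyses of
#' scores on case status adjusting for BMI/age, explicit Bonferroni
#' correction, and the power of a single-predictor test given the variance
#' it explains.
#'
#' @name grs_stats
NULL

#' Bonferroni correction
#'
#' @param p Raw P value(s) in \[0, 1\].
#' @param m Number of comparisons (>= 1).
#' @return `min(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Two-group test for one variable
#'
#' @param x,y Case and control values.
#' @param test `"t_test"` (two-sample, two-sided; pooled variance unless
#'   `welch = TRUE`) or `"wilcoxon"` (rank-sum, two-sided; exact enumeration
#'   when the combined sample is below 20 and tie-free, otherwise the normal
#'   approximation with tie and continuity correction).
#' @param m Bonferroni comparison count applied to the raw P.
#' @param welch Use the Welch unequal-variance t statistic.
#' @return List of class `grs_comparison`: test, statistic, p_raw, m,
#'   p_bonferroni, n_case, n_control. Two identical zero-variance groups
#'   give statistic 0 and p 1 rather than an error.
#' @export
two_group_test <- function(x, y, test = c("t_test", "wilcoxon"), m = 1,
                           welch = FALSE) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (test == "t_test") {
    if (length(x) < 2 || length(y) < 2)
      stop("t-test needs at least two observations per group", call. = FALSE)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate zero-variance design: no sampling noise to test against
      if (mean(x) == mean(y)) { stat <- 0; p <- 1 }
      else { stat <- sign(mean(x) - mean(y)) * Inf; p <- 0 }
    } else {
      ht <- stats::t.test(x, y, var.equal = !welch)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    if (length(x) < 1 || length(y) < 1)
      stop("rank-sum test needs at least one observation per group",
           call. = FALSE)
    exact <- (length(x) + length(y)) < 20 &&
      !any(duplicated(c(x, y)))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(test = test, statistic = stat, p_raw = p, m = m,
                 p_bonferroni = bonferroni(p, m),
                 n_case = length(x), n_control = length(y)),
            class = "grs_comparison")
}

#' @export
print.grs_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, raw P %.3g, Bonferroni (m=%d) P %.3g [n %d vs %d]\n",
              x$test, x$statistic, x$p_raw, x$m, x$p_bonferroni,
              x$n_case, x$n_control))
  invisible(x)
}

.check_collinear <- function(fit, data_names) {
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("collinear covariate(s): ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  invisible(fit)
}

#' Regress a glucose measure on a genetic score
#'
#' Ordinary least squares of one glucose outcome on one score, optionally
#' adjusted for the other glucose measures and/or covariates; complete cases
#' only. The coefficient is in mmol/L per one score unit, with a t-based
#' 95% confidence interval and two-sided P.
#'
#' @param outcome Numeric outcome (glucose, mmol/L).
#' @param gs Numeric score values (same length).
#' @param adjust_for Optional data frame / named list of covariate vectors
#'   (e.g. the other two glucose measures, or BMI and age).
#' @param m Bonferroni comparison count for the score coefficient's P.
#' @param outcome_name,gs_name Labels carried into the result.
#' @return List of class `grs_regression`: outcome, predictor, covariates,
#'   beta, ci_low, ci_high, p_raw, p_bonferroni, n, and the underlying `lm`
#'   fit.
#' @export
glucose_on_gs_regression <- function(outcome, gs, adjust_for = NULL, m = 1,
                                     outcome_name = "glucose",
                                     gs_name = "gs") {
  dat <- data.frame(.outcome = outcome, .gs = gs)
  covs <- character(0)
  if (!is.null(adjust_for)) {
    adjust_for <- as.data.frame(adjust_for)
    stopifnot(nrow(adjust_for) == length(outcome))
    covs <- names(adjust_for)
    dat <- cbind(dat, adjust_for)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= ncol(dat))
    stop("not enough complete cases for the requested model", call. = FALSE)
  fml <- stats::reformulate(c(".gs", covs), response = ".outcome")
  fit <- stats::lm(fml, data = dat)
  .check_collinear(fit)
  est <- summary(fit)$coefficients[".gs", ]
  ci <- stats::confint(fit, ".gs", level = 0.95)
  structure(list(outcome = outcome_name, predictor = gs_name,
                 covariates = covs,
                 beta = unname(est["Estimate"]),
                 ci_low = ci[1], ci_high = ci[2],
                 p_raw = unname(est["Pr(>|t|)"]),
                 p_bonferroni = bonferroni(unname(est["Pr(>|t|)"]), m),
                 n = nrow(dat), fit = fit),
            class = "grs_regression")
}

#' @export
print.grs_regression <- function(x, ...) {
  adj <- if (length(x$covariates)) paste(" |", paste(x$covariates, collapse = " + ")) else ""
  cat(sprintf("%s ~ %s%s: beta %.4f (95%% CI %.4f-%.4f), raw P %.3g, n %d\n",
              x$outcome, x$predictor, adj, x$beta, x$ci_low, x$ci_high,
              x$p_raw, x$n))
  invisible(x)
}

#' ANCOVA of a genetic score on case status
#'
#' Sensitivity analysis: linear model `score ~ group + covariates` on
#' complete cases; reports the group effect.
#'
#' @param gs Score values.
#' @param group Two-level factor or logical (case vs control).
#' @param covariates Optional data frame / named list (e.g. BMI, age).
#' @param m Bonferroni comparison count.
#' @return `grs_comparison` with the group-effect t statistic and P, plus
#'   the adjusted group difference as `estimate`.
#' @export
ancova_gs_by_group <- function(gs, group, covariates = NULL, m = 1) {
  group <- as.factor(group)
  dat <- data.frame(.gs = gs, .group = group)
  covs <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covs <- names(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.group <- droplevels(dat$.group)
  if (nlevels(dat$.group) < 2)
    stop("group is constant after complete-case filtering", call. = FALSE)
  fit <- stats::lm(stats::reformulate(c(".group", covs), response = ".gs"),
                   data = dat)
  .check_collinear(fit)
  cf <- summary(fit)$coefficients
  grow <- grep("^\\.group", rownames(cf))[1]
  structure(list(test = "ancova", statistic = unname(cf[grow, "t value"]),
                 estimate = unname(cf[grow, "Estimate"]),
                 p_raw = unname(cf[grow, "Pr(>|t|)"]), m = m,
                 p_bonferroni = bonferroni(unname(cf[grow, "Pr(>|t|)"]), m),
                 n_case = sum(dat$.group == levels(dat$.group)[2]),
                 n_control = sum(dat$.group == levels(dat$.group)[1]),
                 fit = fit),
            class = "grs_comparison")
}

#' Power of a single-predictor test from variance explained
#'
#' Power of the two-sided test of one regressor in simple linear regression
#' when the predictor explains a fraction `r2` of outcome variance, via the
#' noncentral F distribution with 1 and n-2 degrees of freedom and
#' noncentrality n * r2 / (1 - r2).
#'
#' @param n Sample size (>= 3).
#' @param r2 Fraction of variance explained, in \[0, 1).
#' @param alpha Test size.
#' @return Power in \[0, 1\]; equals `alpha` at `r2 = 0`.
#' @examples
#' power_variance_explained(2628, 0.06, 0.002)   # 1 to two decimals
#' @export
power_variance_explained <- function(n, r2, alpha = 0.05) {
  stopifnot(n >= 3, r2 >= 0, r2 < 1, alpha > 0, alpha < 1)
  ncp <- n * r2 / (1 - r2)
  crit <- stats::qf(1 - alpha, df1 = 1, df2 = n - 2)
  stats::pf(crit, df1 = 1, df2 = n - 2, ncp = ncp, lower.tail = FALSE)
}
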