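#' Fit the genetic-score / GDM-subgroup analysis
#'
#' The package's central fitting function. Given per-individual genotypes
#' and OGTT phenotypes it (i) builds the weighted FPG and T2D genetic scores
#' under the strict complete-data rule, (ii) assigns each pregnancy to a WHO
#' 2013 diagnostic subgroup, (iii) compares each case subgroup with controls
#' on clinical variables (rank-sum) and on the two scores (t-test), with
#' explicit Bonferroni multipliers, (iv) regresses each glucose measure on
#' each score with and without adjustment for the other two glucose
#' measures, and (v) runs ANCOVA sensitivity analyses of the scores on case
#' status adjusting for BMI and age where available.
#'
#' @param phenotypes Data frame `sample_id, fpg, glu_1h, glu_2h` with
#'   optional `bmi`, `age`, `sbp`.
#' @param genotypes Dosage matrix (samples x rsids, effect-allele coded)
#'   covering both panels, e.g. from [read_genotypes()] or a
#'   `synthetic_cohort`.
#' @param fpg_panel,t2d_panel Weight panels (defaults: the shipped
#'   post-exclusion panels).
#' @param control_2h_bound Control 2-hour bound, 7.8 mmol/L by default (8.5
#'   is the permissive alternative).
#' @param merge_combined See [assign_category()].
#' @param bonferroni_clinical,bonferroni_gs,bonferroni_regression Bonferroni
#'   multipliers for the clinical comparisons (default 24), the score mean
#'   comparisons (default 16) and the regression coefficients (default 24).
#'   These are reporting conventions, not inferred quantities.
#' @param welch Use Welch instead of pooled-variance t-tests.
#' @return An object of class `gdm_gs_fit` with components `scores`,
#'   `phenotypes` (classified), `group_table`, `comparisons` (data frame),
#'   `regressions` (data frame + fitted models), `ancova`, `n`.
#' @seealso [summary.gdm_gs_fit()], [plot.gdm_gs_fit()], [run_pipeline()]
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 400, seed = 7))
#' fit <- gdm_gs_fit(cohort$phenotypes, cohort$genotypes)
#' fit
#' @export
gdm_gs_fit <- function(phenotypes, genotypes,
                       fpg_panel = gdm_panel("FPG"),
                       t2d_panel = gdm_panel("T2D"),
                       control_2h_bound = 7.8, merge_combined = FALSE,
                       bonferroni_clinical = 24, bonferroni_gs = 16,
                       bonferroni_regression = 24, welch = FALSE) {
  if (inherits(phenotypes, "synthetic_cohort"))
    stop("pass cohort$phenotypes and cohort$genotypes separately",
         call. = FALSE)
  scores <- merge_scores(score_cohort(genotypes, fpg_panel),
                         score_cohort(genotypes, t2d_panel))
  ph <- classify_cohort(phenotypes, control_2h_bound, merge_combined)
  dat <- merge(ph, scores, by = "sample_id", sort = FALSE)
  group_table <- tabulate_groups(ph, scores)

  case_levels <- c("fasting_only", "one_hour_only", "two_hour_only",
                   "combined")
  ctrl <- dat[dat$category == "control", , drop = FALSE]
  clin_vars <- intersect(c("fpg", "glu_1h", "glu_2h", "age", "bmi", "sbp"),
                         names(dat))
  comparisons <- list()
  ancova <- list()
  for (g in case_levels) {
    cas <- dat[dat$category == g, , drop = FALSE]
    if (nrow(cas) < 2L || nrow(ctrl) < 2L) next
    for (v in clin_vars) {
      if (sum(!is.na(cas[[v]])) < 1 || sum(!is.na(ctrl[[v]])) < 1) next
      tg <- two_group_test(cas[[v]], ctrl[[v]], "wilcoxon",
                           m = bonferroni_clinical)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        variable = v, group = g, test = tg$test, statistic = tg$statistic,
        p_raw = tg$p_raw, m = tg$m, p_bonferroni = tg$p_bonferroni,
        n_case = tg$n_case, n_control = tg$n_control)
    }
    for (v in c("fpg_gs", "t2d_gs")) {
      if (sum(!is.na(cas[[v]])) < 2 || sum(!is.na(ctrl[[v]])) < 2) next
      tg <- two_group_test(cas[[v]], ctrl[[v]], "t_test", m = bonferroni_gs,
                           welch = welch)
      comparisons[[length(comparisons) + 1L]] <- data.frame(
        variable = v, group = g, test = tg$test, statistic = tg$statistic,
        p_raw = tg$p_raw, m = tg$m, p_bonferroni = tg$p_bonferroni,
        n_case = tg$n_case, n_control = tg$n_control)
      covs <- intersect(c("bmi", "age"), names(dat))
      if (length(covs) > 0L) {
        sub <- rbind(cas, ctrl)
        an <- try(ancova_gs_by_group(sub[[v]],
                                     factor(sub$category == g,
                                            levels = c(FALSE, TRUE),
                                            labels = c("control", "case")),
                                     sub[, covs, drop = FALSE],
                                     m = bonferroni_gs), silent = TRUE)
        if (!inherits(an, "try-error"))
          ancova[[paste(g, v, sep = ".")]] <- an
      }
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()

  glucose <- c(fasting = "fpg", one_hour = "glu_1h", two_hour = "glu_2h")
  regressions <- list(); reg_fits <- list()
  for (s in c("fpg_gs", "t2d_gs")) {
    for (o in names(glucose)) {
      others <- setdiff(unname(glucose), glucose[[o]])
      for (adjusted in c(FALSE, TRUE)) {
        adj <- if (adjusted) dat[, others, drop = FALSE] else NULL
        rr <- glucose_on_gs_regression(dat[[glucose[[o]]]], dat[[s]],
                                       adjust_for = adj,
                                       m = bonferroni_regression,
                                       outcome_name = o, gs_name = s)
        key <- paste(o, s, if (adjusted) "adjusted" else "unadjusted",
                     sep = ".")
        reg_fits[[key]] <- rr
        regressions[[length(regressions) + 1L]] <- data.frame(
          outcome = o, predictor = s, adjusted = adjusted,
          beta = rr$beta, ci_low = rr$ci_low, ci_high = rr$ci_high,
          p_raw = rr$p_raw, p_bonferroni = rr$p_bonferroni, n = rr$n)
      }
    }
  }
  regressions <- do.call(rbind, regressions)
  rownames(regressions) <- NULL

  structure(list(scores = scores, phenotypes = ph, data = dat,
                 group_table = group_table, comparisons = comparisons,
                 regressions = regressions, regression_fits = reg_fits,
                 ancova = ancova,
                 settings = list(control_2h_bound = control_2h_bound,
                                 merge_combined = merge_combined,
                                 bonferroni_clinical = bonferroni_clinical,
                                 bonferroni_gs = bonferroni_gs,
                                 bonferroni_regression = bonferroni_regression,
                                 welch = welch),
                 n = nrow(ph)),
            class = "gdm_gs_fit")
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Per-category score means with 95% confidence intervals
#'
#' The data behind the per-subgroup score plot: mean, SD, n and a t-based
#' 95% CI for each score in each diagnostic category, with raw-P
#' significance stars and a Bonferroni-survival flag for the comparison
#' with controls.
#'
#' @param fit A `gdm_gs_fit`.
#' @return Data frame.
#' @export
score_ci_table <- function(fit) {
  stopifnot(inherits(fit, "gdm_gs_fit"))
  rows <- list()
  for (g in .gdm_levels) {
    sub <- fit$data[fit$data$category == g, , drop = FALSE]
    for (v in c("fpg_gs", "t2d_gs")) {
      x <- sub[[v]][!is.na(sub[[v]])]
      n <- length(x)
      mu <- if (n) mean(x) else NA_real_
      s <- if (n > 1) stats::sd(x) else NA_real_
      half <- if (n > 1) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
      cmp <- fit$comparisons
      pr <- if (nrow(cmp)) cmp$p_raw[cmp$group == g & cmp$variable == v] else
        numeric(0)
      pb <- if (nrow(cmp)) cmp$p_bonferroni[cmp$group == g & cmp$variable == v] else
        numeric(0)
      rows[[length(rows) + 1L]] <- data.frame(
        category = g, score = v, n = n, mean = mu, sd = s,
        ci_low = mu - half, ci_high = mu + half,
        p_raw = if (length(pr)) pr else NA_real_,
        p_bonferroni = if (length(pb)) pb else NA_real_,
        stars = if (length(pr)) .stars(pr) else "",
        bonferroni_significant = if (length(pb)) pb < 0.05 else NA)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gdm_gs_fit <- function(x, ...) {
  cat("Genetic-score analysis of WHO 2013 GDM diagnostic subgroups\n")
  cat(sprintf("  %d pregnancies; control 2-hour bound %.1f mmol/L\n",
              x$n, x$settings$control_2h_bound))
  tab <- table(x$phenotypes$category)
  cat("  subgroups:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  cs <- sum(x$scores$fpg_complete & x$scores$t2d_complete, na.rm = TRUE)
  cat(sprintf("  complete scores (both panels): %d of %d\n", cs, x$n))
  invisible(x)
}

#' Summarise a fitted analysis
#'
#' @param object A `gdm_gs_fit`.
#' @param ... Unused.
#' @return The fit's report tables, invisibly printed: per-group score
#'   means/CIs, case-vs-control comparisons and the regression grid.
#' @export
summary.gdm_gs_fit <- function(object, ...) {
  out <- list(scores = score_ci_table(object),
              comparisons = object$comparisons,
              regressions = object$regressions,
              settings = object$settings, n = object$n)
  class(out) <- "summary.gdm_gs_fit"
  out
}

#' @export
print.summary.gdm_gs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Genetic-score analysis (n = %d)\n\n", x$n))
  cat("Per-subgroup score means (95% CI), vs controls:\n")
  print(format(x$scores, digits = digits), row.names = FALSE)
  cat(sprintf("\nRegressions of glucose (mmol/L) on scores (Bonferroni m = %d):\n",
              x$settings$bonferroni_regression))
  print(format(x$regressions, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Regression coefficients of a fitted analysis
#'
#' @param object A `gdm_gs_fit`.
#' @param ... Unused.
#' @return Named vector of glucose-on-score OLS coefficients (mmol/L per
#'   score unit), named `outcome.predictor.adjusted/unadjusted`.
#' @export
coef.gdm_gs_fit <- function(object, ...) {
  r <- object$regressions
  stats::setNames(r$beta, paste(r$outcome, r$predictor,
                                ifelse(r$adjusted, "adjusted",
                                       "unadjusted"), sep = "."))
}

#' Plot per-subgroup mean scores with 95% confidence intervals
#'
#' Two panels (FPG and T2D score): group means with error bars across the
#' diagnostic categories, starred by the raw P of the comparison with
#' controls (*, **, *** at 0.05/0.01/0.001).
#'
#' @param x A `gdm_gs_fit`.
#' @param ... Passed to `plot()`.
#' @return The [score_ci_table()] data, invisibly.
#' @export
plot.gdm_gs_fit <- function(x, ...) {
  tab <- score_ci_table(x)
  tab <- tab[tab$category != "unclassified" & tab$n > 0, , drop = FALSE]
  op <- graphics::par(mfrow = c(1, 2), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in c("fpg_gs", "t2d_gs")) {
    sub <- tab[tab$score == v, , drop = FALSE]
    idx <- seq_len(nrow(sub))
    ylim <- range(sub$ci_low, sub$ci_high, na.rm = TRUE)
    plot(idx, sub$mean, xlim = c(0.5, nrow(sub) + 0.5), ylim = ylim,
         pch = 19, xaxt = "n", xlab = "",
         ylab = sprintf("mean %s (95%% CI)",
                        toupper(sub("_gs", " GS", v))), ...)
    graphics::arrows(idx, sub$ci_low, idx, sub$ci_high, angle = 90,
                     code = 3, length = 0.04)
    graphics::axis(1, at = idx, labels = paste0(sub$category, sub$stars),
                   las = 2, cex.axis = 0.8)
  }
  invisible(tab)
}
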