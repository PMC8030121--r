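#' Synthetic cohorts
#'
#' Generates genotype-phenotype cohorts with the statistical structure the
#' analysis assumes, so the full pipeline can be exercised without
#' access-controlled pregnancy cohort data. Genotypes are independent
#' Hardy-Weinberg draws at the panel effect-allele frequencies (linkage
#' equilibrium; rsids shared between the two panels are drawn once and
#' reused). Fasting glucose is built as
#' `fpg_mean + centred FPG genetic value + T2D channel + Gaussian residual`,
#' with the residual variance solved so the FPG score explains exactly the
#' configured fraction of fasting-glucose variance; the regression slope of
#' fasting glucose on the FPG score is then the summed panel weight divided
#' by the SNP count, by construction. Post-load glucose gets its own linear
#' loadings on both genetic values plus residuals correlated with the
#' fasting residual. The type 2 diabetes genetic value enters every glucose
#' measure only through its component orthogonal to the FPG genetic value,
#' which keeps the fasting-on-FPG-score slope exact.
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Defaults describe a representative pregnancy cohort: n of 2,628; the FPG
#' score explaining 6% of fasting-glucose variance; fasting glucose centred
#' at 4.5 mmol/L; post-load means 7.1 and 5.8 mmol/L with total SDs 1.7 and
#' 1.3; residual correlations 0.5 between glucose measures; per-genotype
#' missingness 0.008.
#'
#' @param n_samples Cohort size.
#' @param cohort_style `"representative"` or `"case_control_3to1"`.
#' @param gs_variance_explained Fraction of fasting-glucose variance
#'   explained by the FPG score (default 0.06). `0` zeroes every genetic
#'   loading (the full null model, glucose independent of the scores);
#'   `NULL` keeps the loadings but fixes the total fasting SD at `fpg_sd`.
#' @param fpg_mean,fpg_sd Fasting glucose mean and (fallback) total SD,
#'   mmol/L.
#' @param glu_1h_mean,glu_1h_sd,glu_2h_mean,glu_2h_sd Post-load glucose
#'   means and total SDs, mmol/L.
#' @param glucose_correlations 3x3 positive-definite residual correlation
#'   matrix for (fasting, 1-hour, 2-hour).
#' @param fpg_gs_glucose_effects Marginal effect of the FPG score on the
#'   1-hour and 2-hour measures, mmol/L per score unit.
#' @param t2d_gs_glucose_effects Effect of the (orthogonalised) T2D score on
#'   (fasting, 1-hour, 2-hour), mmol/L per score unit.
#' @param missing_rate Per-genotype missing probability.
#' @param covariates Generate BMI/age/SBP columns.
#' @param bmi_fpg_effect BMI shift per mmol/L of fasting glucose above the
#'   mean (kg/m^2), giving cases a realistically higher BMI.
#' @param seed Integer seed; mandatory at simulation time.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2628,
                       cohort_style = c("representative",
                                        "case_control_3to1"),
                       gs_variance_explained = 0.06,
                       fpg_mean = 4.5, fpg_sd = 0.35,
                       glu_1h_mean = 7.1, glu_1h_sd = 1.7,
                       glu_2h_mean = 5.8, glu_2h_sd = 1.3,
                       glucose_correlations = matrix(c(1, 0.5, 0.5,
                                                       0.5, 1, 0.5,
                                                       0.5, 0.5, 1), 3, 3),
                       fpg_gs_glucose_effects = c(one_hour = 0.060,
                                                  two_hour = 0.032),
                       t2d_gs_glucose_effects = c(fasting = 0.008,
                                                  one_hour = 0.051,
                                                  two_hour = 0.034),
                       missing_rate = 0.008,
                       covariates = TRUE,
                       bmi_fpg_effect = 3,
                       seed = NULL) {
  cohort_style <- match.arg(cohort_style)
  stopifnot(n_samples >= 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(gs_variance_explained))
    stopifnot(gs_variance_explained >= 0, gs_variance_explained < 1)
  R <- glucose_correlations
  if (!isTRUE(all.equal(unname(diag(R)), rep(1, 3))) ||
      !isTRUE(all.equal(R, t(R))) || any(eigen(R)$values <= 0))
    stop("glucose_correlations must be a positive-definite correlation matrix",
         call. = FALSE)
  structure(list(n_samples = n_samples, cohort_style = cohort_style,
                 gs_variance_explained = gs_variance_explained,
                 fpg_mean = fpg_mean, fpg_sd = fpg_sd,
                 glu_1h_mean = glu_1h_mean, glu_1h_sd = glu_1h_sd,
                 glu_2h_mean = glu_2h_mean, glu_2h_sd = glu_2h_sd,
                 glucose_correlations = R,
                 fpg_gs_glucose_effects = fpg_gs_glucose_effects,
                 t2d_gs_glucose_effects = t2d_gs_glucose_effects,
                 missing_rate = missing_rate,
                 covariates = covariates,
                 bmi_fpg_effect = bmi_fpg_effect,
                 seed = seed),
            class = "sim_config")
}

#' Simulate Hardy-Weinberg genotypes for a panel
#'
#' Independent binomial(2, p) dosage draws per SNP at the panel
#' effect-allele frequencies.
#'
#' @param panel A `grs_panel` (all entries scoreable).
#' @param n Number of samples.
#' @param seed Integer seed (set when non-NULL).
#' @param missing_rate Per-genotype probability of a missing call.
#' @return Integer dosage matrix, samples x panel rsids.
#' @export
simulate_genotypes <- function(panel, n, seed = NULL, missing_rate = 0) {
  stopifnot(inherits(panel, "grs_panel"), all(panel$scoreable), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  gm <- vapply(panel$eaf, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1L) gm <- matrix(gm, nrow = 1L)
  dimnames(gm) <- list(sprintf("S%05d", seq_len(n)), panel$rsid)
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(gm)) < missing_rate, nrow = n)
    gm[drop] <- NA_integer_
  }
  gm
}

# Theoretical HWE/LE second moments of the raw genetic values of two panels
# that may share physical SNPs (same rsid -> same draw).
.genetic_moments <- function(fpg_panel, t2d_panel) {
  vf <- sum(2 * fpg_panel$eaf * (1 - fpg_panel$eaf) * fpg_panel$beta^2)
  vt <- sum(2 * t2d_panel$eaf * (1 - t2d_panel$eaf) * t2d_panel$beta^2)
  shared <- intersect(fpg_panel$rsid, t2d_panel$rsid)
  cft <- 0
  for (s in shared) {
    i <- match(s, fpg_panel$rsid); j <- match(s, t2d_panel$rsid)
    p <- fpg_panel$eaf[i]
    cft <- cft + 2 * p * (1 - p) * fpg_panel$beta[i] * t2d_panel$beta[j]
  }
  list(var_f = vf, var_t = vt, cov_ft = cft, shared = shared)
}

#' Simulate glucose phenotypes from genotypes
#'
#' Applies the generative model described under [synthetic] to a complete
#' (no-missingness) dosage matrix covering both panels.
#'
#' @param gm Complete dosage matrix covering both panels' rsids.
#' @param fpg_panel,t2d_panel The weight panels used for the genetic values.
#' @param cfg A [sim_config()].
#' @param seed Integer seed (set when non-NULL).
#' @return List: `phenotypes` (data frame sample_id, fpg, glu_1h, glu_2h and
#'   optional bmi, age, sbp) and `truth` (per-sample latent genetic values
#'   and true scores; written separately and never read by the pipeline).
#' @export
simulate_phenotypes <- function(gm, fpg_panel, t2d_panel, cfg,
                                seed = NULL) {
  assert_genotype_matrix(gm)
  if (anyNA(gm))
    stop("phenotype simulation requires complete genotypes; inject missingness afterwards",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gm)
  bf <- fpg_panel$beta; bt <- t2d_panel$beta
  nf <- nrow(fpg_panel); nt <- nrow(t2d_panel)
  kf <- nf / sum(bf); kt <- nt / sum(bt)
  g_f <- as.numeric(gm[, fpg_panel$rsid, drop = FALSE] %*% bf) -
    2 * sum(fpg_panel$eaf * bf)
  g_t <- as.numeric(gm[, t2d_panel$rsid, drop = FALSE] %*% bt) -
    2 * sum(t2d_panel$eaf * bt)
  mom <- .genetic_moments(fpg_panel, t2d_panel)
  # component of the T2D genetic value orthogonal to the FPG one, in T2D
  # score units
  gst_perp <- kt * (g_t - (mom$cov_ft / mom$var_f) * g_f)
  var_gst_perp <- kt^2 * (mom$var_t - mom$cov_ft^2 / mom$var_f)
  # gs_variance_explained = 0 is the full null model: every genetic loading
  # is zeroed and the configured total SDs are pure residual
  null_model <- !is.null(cfg$gs_variance_explained) &&
    cfg$gs_variance_explained == 0
  eT <- if (null_model) c(fasting = 0, one_hour = 0, two_hour = 0) else
    cfg$t2d_gs_glucose_effects
  eF <- cfg$fpg_gs_glucose_effects
  gf_coef <- if (null_model) 0 else 1
  b1 <- unname(eF["one_hour"]) * kf * gf_coef
  b2 <- unname(eF["two_hour"]) * kf * gf_coef
  var_f_tot <- if (!is.null(cfg$gs_variance_explained) &&
                   cfg$gs_variance_explained > 0)
    mom$var_f / cfg$gs_variance_explained else cfg$fpg_sd^2
  res_var <- c(
    var_f_tot - gf_coef * mom$var_f - eT["fasting"]^2 * var_gst_perp,
    cfg$glu_1h_sd^2 - b1^2 * mom$var_f - eT["one_hour"]^2 * var_gst_perp,
    cfg$glu_2h_sd^2 - b2^2 * mom$var_f - eT["two_hour"]^2 * var_gst_perp)
  if (any(res_var <= 0))
    stop("requested variance explained / loadings too large for the configured total variances",
         call. = FALSE)
  D <- diag(sqrt(res_var))
  Sigma <- D %*% cfg$glucose_correlations %*% D
  eps <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(Sigma)
  fpg <- cfg$fpg_mean + gf_coef * g_f + unname(eT["fasting"]) * gst_perp +
    eps[, 1]
  glu_1h <- cfg$glu_1h_mean + b1 * g_f + unname(eT["one_hour"]) * gst_perp +
    eps[, 2]
  glu_2h <- cfg$glu_2h_mean + b2 * g_f + unname(eT["two_hour"]) * gst_perp +
    eps[, 3]
  # glucose is physically positive; truncation is far in the tail
  fpg <- pmax(fpg, 0.1); glu_1h <- pmax(glu_1h, 0.1)
  glu_2h <- pmax(glu_2h, 0.1)
  phen <- data.frame(sample_id = rownames(gm), fpg = fpg, glu_1h = glu_1h,
                     glu_2h = glu_2h)
  if (isTRUE(cfg$covariates)) {
    phen$bmi <- exp(stats::rnorm(n, log(24), 0.16)) +
      cfg$bmi_fpg_effect * (fpg - cfg$fpg_mean)
    phen$age <- pmin(45L, pmax(18L, as.integer(round(stats::rnorm(n, 31, 5)))))
    phen$sbp <- round(stats::rnorm(n, 108, 8) + 5 * (fpg - cfg$fpg_mean))
  }
  truth <- data.frame(sample_id = rownames(gm), g_f = g_f, g_t = g_t,
                      gs_f_true = kf * g_f + 2 * nf * sum(fpg_panel$eaf * bf) / sum(bf),
                      gs_t_true = kt * g_t + 2 * nt * sum(t2d_panel$eaf * bt) / sum(bt),
                      slope_fpg_on_gs = sum(bf) / nf)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a full cohort
#'
#' Draws one physical genotype per distinct rsid across both panels,
#' builds phenotypes from the complete genotypes, then injects genotype
#' missingness, so missing calls never leak into the generative truth.
#'
#' @param cfg A [sim_config()]; `cfg$seed` (or `seed`) must be set.
#' @param fpg_panel,t2d_panel Weight panels (defaults: the shipped
#'   post-exclusion panels at their published index frequencies).
#' @param seed Overrides `cfg$seed`.
#' @return List of class `synthetic_cohort`: `genotypes` (dosage matrix with
#'   missingness), `phenotypes`, `truth`, `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            fpg_panel = gdm_panel("FPG"),
                            t2d_panel = gdm_panel("T2D"),
                            seed = cfg$seed) {
  if (is.null(seed))
    stop("a seed is mandatory: set cfg$seed or pass seed =", call. = FALSE)
  all_rsids <- unique(c(fpg_panel$rsid, t2d_panel$rsid))
  freq <- c(stats::setNames(fpg_panel$eaf, fpg_panel$rsid),
            stats::setNames(t2d_panel$eaf, t2d_panel$rsid))
  shared <- intersect(fpg_panel$rsid, t2d_panel$rsid)
  for (s in shared) {
    fa <- fpg_panel$eaf[match(s, fpg_panel$rsid)]
    ta <- t2d_panel$eaf[match(s, t2d_panel$rsid)]
    ea <- fpg_panel$effect_allele[match(s, fpg_panel$rsid)]
    et <- t2d_panel$effect_allele[match(s, t2d_panel$rsid)]
    if (fa != ta || ea != et)
      stop("shared SNP ", s, " has conflicting frequency or effect allele between panels",
           call. = FALSE)
  }
  set.seed(seed)
  n <- cfg$n_samples
  gm <- vapply(freq[all_rsids], function(p) stats::rbinom(n, 2L, p),
               integer(n))
  if (n == 1L) gm <- matrix(gm, nrow = 1L)
  dimnames(gm) <- list(sprintf("S%05d", seq_len(n)), all_rsids)
  sim <- simulate_phenotypes(gm, fpg_panel, t2d_panel, cfg)
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(gm)) < cfg$missing_rate,
                   nrow = nrow(gm))
    gm[drop] <- NA_integer_
  }
  out <- list(genotypes = gm, phenotypes = sim$phenotypes,
              truth = sim$truth, config = cfg, seed = seed)
  class(out) <- "synthetic_cohort"
  if (cfg$cohort_style == "case_control_3to1")
    out <- sample_cohort(out, "case_control_3to1")
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d SNPs (seed %s)\n",
              nrow(x$genotypes), ncol(x$genotypes), format(x$seed)))
  invisible(x)
}

#' Subsample a cohort to a study design
#'
#' `"representative"` returns the cohort unchanged. `"case_control_3to1"`
#' keeps every WHO 2013 case (any glucose threshold met) and draws exactly
#' three controls per case from the pool of non-cases satisfying the
#' original control screen (fasting < 5.6 mmol/L and/or 2-hour < 7.8
#' mmol/L); it errors, reporting the deficit, if the pool is too small.
#'
#' @param cohort A `synthetic_cohort`.
#' @param style Sampling design.
#' @param seed Optional seed for the control draw.
#' @return A `synthetic_cohort` restricted to the sampled individuals.
#' @export
sample_cohort <- function(cohort, style = c("representative",
                                            "case_control_3to1"),
                          seed = NULL) {
  style <- match.arg(style)
  if (style == "representative") return(cohort)
  if (!is.null(seed)) set.seed(seed)
  ph <- cohort$phenotypes
  case <- ph$fpg >= 5.1 | ph$glu_1h >= 10.0 | ph$glu_2h >= 8.5
  pool <- !case & (ph$fpg < 5.6 | ph$glu_2h < 7.8)
  n_cases <- sum(case)
  if (n_cases == 0L) stop("no cases in the cohort", call. = FALSE)
  need <- 3L * n_cases
  if (sum(pool) < need)
    stop(sprintf("control pool too small: need %d controls (3 per case), have %d (deficit %d)",
                 need, sum(pool), need - sum(pool)), call. = FALSE)
  controls <- sample(which(pool), need)
  keep <- sort(c(which(case), controls))
  out <- cohort
  out$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  out$phenotypes <- ph[keep, , drop = FALSE]
  out$truth <- cohort$truth[keep, , drop = FALSE]
  out
}

.config_hash <- function(cfg) {
  s <- paste(names(unlist(cfg)), format(unlist(cfg), digits = 10),
             collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)))
}

#' Write a synthetic cohort to disk
#'
#' Writes `genotypes.tsv`, `phenotypes.csv` and `truth.csv` (the latter is
#' generative truth, never read back by the pipeline). Each file records the
#' seed and a config hash in a leading comment line.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# seed=%s config_hash=%s", format(cohort$seed),
                   .config_hash(cohort$config))
  gpath <- file.path(dir, "genotypes.tsv")
  writeLines(stamp, gpath)
  out <- data.frame(sample_id = rownames(cohort$genotypes),
                    cohort$genotypes, check.names = FALSE)
  suppressWarnings(utils::write.table(out, gpath, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA",
                                      append = TRUE))
  for (nm in c("phenotypes", "truth")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(cohort[[nm]], path, sep = ",",
                                        quote = FALSE, row.names = FALSE,
                                        na = "NA", append = TRUE))
  }
  invisible(dir)
}
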