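#' End-to-end pipeline
#'
#' Orchestrates simulate (or load) -> HWE QC -> score -> classify ->
#' analyse, writing self-describing text artifacts to a run directory:
#' `qc_hwe.tsv`, `scores.csv`, `categories.csv`, `table3_like.tsv`
#' (per-subgroup clinical and score summaries), `table4_like.tsv` (the
#' glucose-on-score regression grid), `figure3_like.tsv` (per-subgroup score
#' means with 95% CIs and significance markers) and `run_log.txt` with the
#' seed, a config hash and the n bookkeeping at every filter. Re-running
#' with the same configuration reproduces every artifact byte for byte
#' (no timestamps are written).
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir Run directory to create.
#' @param seed Integer seed (mandatory when simulating).
#' @param sim A [sim_config()] to generate the cohort, or `NULL` to read
#'   `genotypes`/`phenotypes` from disk.
#' @param genotypes,phenotypes Paths to a dosage TSV and phenotype CSV
#'   (used when `sim` is `NULL`).
#' @param fpg_panel,t2d_panel Paths to panel TSVs (defaults: shipped
#'   post-exclusion panels).
#' @param cohort Cohort label for proxy resolution (`"DIP"` keeps index
#'   SNPs; `"HAPO"` substitutes proxies).
#' @param hwe_alpha Familywise threshold for the HWE screen.
#' @param control_2h_bound,merge_combined See [assign_category()].
#' @param bonferroni_clinical,bonferroni_gs,bonferroni_regression
#'   Correction multipliers, see [gdm_gs_fit()].
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = NULL, sim = sim_config(seed = seed),
                       genotypes = NULL, phenotypes = NULL,
                       fpg_panel = NULL, t2d_panel = NULL,
                       cohort = "DIP", hwe_alpha = 0.05,
                       control_2h_bound = 7.8, merge_combined = FALSE,
                       bonferroni_clinical = 24, bonferroni_gs = 16,
                       bonferroni_regression = 24) {
  cfg <- list(out_dir = out_dir, seed = seed, sim = sim,
              genotypes = genotypes, phenotypes = phenotypes,
              fpg_panel = fpg_panel, t2d_panel = t2d_panel,
              cohort = cohort, hwe_alpha = hwe_alpha,
              control_2h_bound = control_2h_bound,
              merge_combined = merge_combined,
              bonferroni_clinical = bonferroni_clinical,
              bonferroni_gs = bonferroni_gs,
              bonferroni_regression = bonferroni_regression)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (is.character(cfg)) {
    doc <- yaml::read_yaml(cfg)
    sim <- if (!is.null(doc$sim)) do.call(sim_config, doc$sim) else NULL
    doc$sim <- NULL
    cfg <- do.call(run_config, c(doc, list(sim = sim)))
  }
  stopifnot(inherits(cfg, "run_config"))
  for (f in c("genotypes", "phenotypes", "fpg_panel", "t2d_panel")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config path does not exist (", f, "): ", cfg[[f]],
           call. = FALSE)
  }
  if (is.null(cfg$sim) && (is.null(cfg$genotypes) || is.null(cfg$phenotypes)))
    stop("config must provide either a sim block or genotype+phenotype paths",
         call. = FALSE)
  if (!is.null(cfg$sim) && is.null(cfg$sim$seed) && is.null(cfg$seed))
    stop("a seed is mandatory when simulating", call. = FALSE)
  cfg
}

#' Read a phenotype CSV
#'
#' Columns `sample_id, fpg, glu_1h, glu_2h` and optionally `bmi, age, sbp`;
#' `NA` or empty cells for missing; leading `#` comment lines ignored.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, comment.char = "#", na.strings = c("", "NA"))
  req <- c("sample_id", "fpg", "glu_1h", "glu_2h")
  missing_cols <- setdiff(req, names(ph))
  if (length(missing_cols) > 0L)
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ph$sample_id <- as.character(ph$sample_id)
  ph
}

#' Run the full pipeline
#'
#' @param cfg A [run_config()] or the path to its YAML serialisation.
#' @return The run directory path, invisibly, with the fitted
#'   [gdm_gs_fit()] object attached as attribute `fit`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

  stage <- "input"
  res <- tryCatch({
    fpg <- if (is.null(cfg$fpg_panel)) gdm_panel("FPG") else
      load_panel(cfg$fpg_panel, "FPG")
    t2d <- if (is.null(cfg$t2d_panel)) gdm_panel("T2D") else
      load_panel(cfg$t2d_panel, "T2D")
    fpg <- resolve_proxies(fpg, cfg$cohort)
    t2d <- resolve_proxies(t2d, cfg$cohort)

    if (!is.null(cfg$sim)) {
      stage <- "simulate"
      seed <- cfg$sim$seed %||% cfg$seed
      cohort <- simulate_cohort(cfg$sim, fpg, t2d, seed = seed)
      write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
      gm <- cohort$genotypes
      ph <- cohort$phenotypes
      say("simulated cohort: %d samples (seed %s, style %s)",
          nrow(gm), format(seed), cfg$sim$cohort_style)
    } else {
      stage <- "read"
      gm <- read_genotypes(cfg$genotypes, "tsv",
                           panel = .union_panel(fpg, t2d))
      ph <- read_phenotypes(cfg$phenotypes)
      seed <- cfg$seed
      say("read %d samples from %s", nrow(gm), cfg$genotypes)
    }

    stage <- "qc_hwe"
    screen <- hwe_screen(gm, alpha = cfg$hwe_alpha)
    write_hwe_screen(screen, file.path(cfg$out_dir, "qc_hwe.tsv"))
    say("HWE screen: %d SNPs tested, %d excluded (Bonferroni alpha %.3g)",
        nrow(screen$results), sum(screen$results$excluded), cfg$hwe_alpha)
    if (nrow(screen$rules) > 0L) {
      fpg <- apply_exclusions(fpg, screen$rules[screen$rules$rsid %in% fpg$rsid, ])
      t2d <- apply_exclusions(t2d, screen$rules[screen$rules$rsid %in% t2d$rsid, ])
      say("panels after HWE exclusions: FPG %d SNPs, T2D %d SNPs",
          nrow(fpg), nrow(t2d))
    }

    stage <- "analyse"
    fit <- suppressMessages(
      gdm_gs_fit(ph, gm, fpg, t2d,
                 control_2h_bound = cfg$control_2h_bound,
                 merge_combined = cfg$merge_combined,
                 bonferroni_clinical = cfg$bonferroni_clinical,
                 bonferroni_gs = cfg$bonferroni_gs,
                 bonferroni_regression = cfg$bonferroni_regression))
    say("scores: FPG complete %d / incomplete %d; T2D complete %d / incomplete %d",
        sum(fit$scores$fpg_complete), sum(!fit$scores$fpg_complete),
        sum(fit$scores$t2d_complete), sum(!fit$scores$t2d_complete))
    tab <- table(fit$phenotypes$category)
    say("subgroups: %s", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = ", "))

    stage <- "write"
    utils::write.csv(fit$scores, file.path(cfg$out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE, na = "NA")
    utils::write.csv(fit$phenotypes[, c("sample_id", "category")],
                     file.path(cfg$out_dir, "categories.csv"),
                     row.names = FALSE, quote = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA")
    wt(fit$group_table, "table3_like.tsv")
    wt(fit$regressions, "table4_like.tsv")
    wt(score_ci_table(fit), "figure3_like.tsv")
    # the output location is not part of the scientific configuration
    hash_cfg <- cfg; hash_cfg$out_dir <- NULL
    say("config_hash=%s seed=%s", .config_hash(hash_cfg), format(seed))
    writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
    fit
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  out <- cfg$out_dir
  attr(out, "fit") <- res
  invisible(out)
}

# minimal combined panel for reading a genotype file covering both panels
.union_panel <- function(fpg, t2d) {
  both <- rbind(as.data.frame(fpg), as.data.frame(t2d))
  both <- both[!duplicated(both$rsid), , drop = FALSE]
  new_grs_panel(both, "union")
}

#' Human-readable run report
#'
#' Summarises a completed run directory: per-category score means with 95%
#' CIs, raw-P significance markers (* < 0.05, ** < 0.01, *** < 0.001) and a
#' Bonferroni-survival annotation, one block per score. Categories with no
#' members are rendered with n = 0.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Character vector of report lines (also written to `report.txt`
#'   in the run directory), invisibly.
#' @export
make_report <- function(run_dir) {
  f3 <- file.path(run_dir, "figure3_like.tsv")
  if (!file.exists(f3))
    stop("run directory incomplete: missing ", f3, call. = FALSE)
  tab <- utils::read.delim(f3)
  lines <- c("Mean genetic score by GDM diagnostic category",
             "=============================================")
  for (v in unique(tab$score)) {
    lines <- c(lines, "", sprintf("%s:", toupper(sub("_gs", " GS", v))))
    sub <- tab[tab$score == v, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      r <- sub[i, ]
      lines <- c(lines, if (r$n == 0)
        sprintf("  %-14s n=0", r$category)
        else sprintf("  %-14s n=%-5d mean %6.2f (95%% CI %6.2f-%6.2f) %s%s",
                     r$category, r$n, r$mean, r$ci_low, r$ci_high,
                     if (is.na(r$stars) || is.null(r$stars)) "" else r$stars,
                     if (isTRUE(r$bonferroni_significant))
                       " [Bonferroni-significant]" else ""))
    }
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
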