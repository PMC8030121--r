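#' SNP weight panels
#'
#' A panel is an ordered table of weighted variants used to build a genetic
#' score: one row per SNP with its rsid, an optional proxy actually genotyped
#' in one cohort, alleles, effect-allele frequency and a positive per-allele
#' weight aligned to the trait-raising (or risk) allele. The package ships two
#' curated panels: 15 fasting-plasma-glucose SNPs (weights in mmol/L per
#' allele) and 38 type 2 diabetes SNPs (weights are log odds ratios), together
#' with the pre-exclusion candidate lists (16 and 41 SNPs).
#'
#' @name grs_panel
NULL

.panel_columns <- c("rsid", "proxy_rsid", "proxy_effect_allele",
                    "proxy_other_allele", "proxy_eaf", "chrom", "pos",
                    "locus", "effect_allele", "other_allele", "eaf", "beta",
                    "source")

.valid_bases <- c("A", "C", "G", "T")

new_grs_panel <- function(entries, name) {
  structure(entries, name = name, class = c("grs_panel", "data.frame"))
}

#' @export
print.grs_panel <- function(x, ...) {
  ns <- sum(x$scoreable)
  cat(sprintf("<grs_panel> %s: %d SNPs (%d scoreable), sum of weights %.3f\n",
              attr(x, "name"), nrow(x), ns, sum(x$beta[x$scoreable])))
  print.data.frame(x[, c("rsid", "proxy_rsid", "locus", "effect_allele",
                         "other_allele", "eaf", "beta")], ...)
  invisible(x)
}

validate_panel_entries <- function(entries, strict = TRUE) {
  req <- setdiff(.panel_columns, c("proxy_effect_allele", "proxy_other_allele",
                                   "proxy_eaf"))
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols) > 0L)
    stop("panel file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(entries) == 0L)
    stop("panel file contains no SNP rows", call. = FALSE)
  dup <- entries$rsid[duplicated(entries$rsid)]
  if (length(dup) > 0L)
    stop("duplicate rsid in panel: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  scoreable <- !is.na(entries$beta) & !is.na(entries$eaf) &
    !is.na(entries$effect_allele) & !is.na(entries$other_allele)
  bad_row <- function(i, what) {
    stop(sprintf("invalid panel row %d (%s): %s", i, entries$rsid[i], what),
         call. = FALSE)
  }
  for (i in seq_len(nrow(entries))) {
    if (!scoreable[i]) {
      if (strict)
        bad_row(i, "incomplete entry (missing beta, frequency or alleles); use strict = FALSE for candidate files")
      next
    }
    if (!entries$effect_allele[i] %in% .valid_bases)
      bad_row(i, paste("effect allele not in A/C/G/T:", entries$effect_allele[i]))
    if (!entries$other_allele[i] %in% .valid_bases)
      bad_row(i, paste("other allele not in A/C/G/T:", entries$other_allele[i]))
    if (entries$effect_allele[i] == entries$other_allele[i])
      bad_row(i, "effect and other allele are identical")
    if (entries$beta[i] <= 0)
      bad_row(i, paste("beta must be positive (weights are aligned to the raising/risk allele):", entries$beta[i]))
    if (entries$eaf[i] <= 0 || entries$eaf[i] >= 1)
      bad_row(i, paste("effect-allele frequency must lie strictly in (0,1):", entries$eaf[i]))
    if (!is.na(entries$proxy_rsid[i]) && nzchar(entries$proxy_rsid[i])) {
      if (is.na(entries$proxy_effect_allele[i]) ||
          is.na(entries$proxy_other_allele[i]) || is.na(entries$proxy_eaf[i]))
        bad_row(i, "proxy rsid given without proxy alleles/frequency")
      if (entries$proxy_eaf[i] <= 0 || entries$proxy_eaf[i] >= 1)
        bad_row(i, "proxy effect-allele frequency must lie strictly in (0,1)")
    }
  }
  entries$scoreable <- scoreable
  entries
}

#' Load a SNP weight panel from TSV
#'
#' Reads a tab-separated panel file (UTF-8, header row) and validates every
#' entry: alleles in A/C/G/T and distinct, positive weights, frequencies
#' strictly inside (0,1), unique rsids. Empty cells encode absent values
#' (e.g. no proxy).
#'
#' @param path Path to the panel TSV.
#' @param name Panel name, `"FPG"` or `"T2D"`; controls units metadata only.
#' @param strict If `TRUE` (default) every row must be scoreable (complete
#'   beta/frequency/alleles). Candidate files listing excluded SNPs whose
#'   weights were never published are loaded with `strict = FALSE`; such rows
#'   are flagged non-scoreable.
#' @return A `grs_panel`: a data frame of validated entries with a
#'   `scoreable` flag, carrying the panel name as an attribute.
#' @examples
#' fpg <- gdm_panel("FPG")
#' nrow(fpg)   # 15
#' @export
load_panel <- function(path, name = c("FPG", "T2D"), strict = TRUE) {
  name <- match.arg(name)
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  entries <- utils::read.delim(path, sep = "\t", header = TRUE,
                               colClasses = "character",
                               na.strings = c("", "NA"),
                               quote = "", fileEncoding = "UTF-8")
  if (nrow(entries) == 0L)
    stop("panel file contains no SNP rows: ", path, call. = FALSE)
  for (col in c("proxy_eaf", "eaf", "beta")) {
    if (col %in% names(entries)) {
      val <- suppressWarnings(as.numeric(entries[[col]]))
      bad <- which(!is.na(entries[[col]]) & is.na(val))
      if (length(bad) > 0L)
        stop(sprintf("malformed numeric value in column '%s', row %d (%s)",
                     col, bad[1], entries$rsid[bad[1]]), call. = FALSE)
      entries[[col]] <- val
    }
  }
  entries <- validate_panel_entries(entries, strict = strict)
  new_grs_panel(entries, name)
}

#' Shipped panel files
#'
#' Convenience access to the packaged weight panels and candidate lists.
#'
#' @param name `"FPG"` or `"T2D"`.
#' @param candidates If `TRUE`, return the pre-exclusion candidate panel
#'   (16 FPG / 41 T2D SNPs, with non-scoreable sentinel rows for the SNPs
#'   whose weights were never published).
#' @return A `grs_panel`.
#' @export
gdm_panel <- function(name = c("FPG", "T2D"), candidates = FALSE) {
  name <- match.arg(name)
  stem <- if (candidates) "%s_candidates.tsv" else "%s_panel.tsv"
  path <- system.file("extdata", sprintf(stem, tolower(name)),
                      package = "grsgdm", mustWork = TRUE)
  load_panel(path, name, strict = !candidates)
}

#' Path to a shipped panel or exclusion file
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path.
#' @export
panel_file <- function(file) {
  system.file("extdata", file, package = "grsgdm", mustWork = TRUE)
}

#' Write a panel back to TSV
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` reproduces the
#' panel field for field.
#'
#' @param panel A `grs_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "grs_panel"))
  out <- as.data.frame(panel)[, .panel_columns]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclusion rules
#'
#' A rule names a SNP to drop from a panel and the reason: `hwe_failure`
#' (deviation from Hardy-Weinberg equilibrium at Bonferroni-corrected
#' P < 0.05), `bmi_primary_effect` (variant acts primarily through BMI) or
#' `other`.
#'
#' @param rsid Character vector of rsids.
#' @param reason Reason per rsid (recycled), from the closed set.
#' @param note Free-text note per rsid (recycled).
#' @return A data frame of class `exclusion_rules`.
#' @export
exclusion_rules <- function(rsid, reason = "other", note = "") {
  reason <- rep_len(reason, length(rsid))
  ok <- reason %in% c("hwe_failure", "bmi_primary_effect", "other")
  if (!all(ok))
    stop("unknown exclusion reason(s): ",
         paste(unique(reason[!ok]), collapse = ", "), call. = FALSE)
  structure(data.frame(rsid = rsid, reason = reason,
                       note = rep_len(note, length(rsid)),
                       stringsAsFactors = FALSE),
            class = c("exclusion_rules", "data.frame"))
}

#' Read exclusion rules from YAML
#'
#' Expects a top-level `exclusions` key holding a list of `rsid`/`reason`
#' (optional `note`) entries.
#'
#' @param path YAML file path.
#' @return An `exclusion_rules` data frame.
#' @export
read_exclusion_rules <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$exclusions))
    stop("no 'exclusions' key in ", path, call. = FALSE)
  exclusion_rules(
    rsid = vapply(doc$exclusions, function(e) e$rsid, character(1)),
    reason = vapply(doc$exclusions, function(e) e$reason %||% "other",
                    character(1)),
    note = vapply(doc$exclusions, function(e) e$note %||% "", character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply exclusion rules to a panel
#'
#' Removes the named SNPs and returns a new panel; the input is unchanged.
#' Idempotent for a fixed rule set. With the shipped candidate panels this
#' reproduces the published post-QC panels: 16 FPG candidates minus the HWE
#' failure gives 15 SNPs; 41 T2D candidates minus two HWE failures and the
#' BMI-primary variant gives 38.
#'
#' @param panel A `grs_panel`.
#' @param rules An `exclusion_rules` data frame (or anything with `rsid` and
#'   `reason` columns).
#' @param on_missing What to do when a rule names an rsid absent from the
#'   panel: `"fail"` (default) or `"warn"` (drop the rule with a warning).
#' @return The filtered `grs_panel`, with an `exclusion_log` attribute
#'   recording what was removed and why.
#' @export
apply_exclusions <- function(panel, rules, on_missing = c("fail", "warn")) {
  stopifnot(inherits(panel, "grs_panel"))
  on_missing <- match.arg(on_missing)
  if (is.null(rules) || nrow(rules) == 0L)
    return(panel)
  absent <- setdiff(rules$rsid, panel$rsid)
  if (length(absent) > 0L) {
    msg <- paste("exclusion rule names rsid(s) absent from panel:",
                 paste(absent, collapse = ", "))
    if (on_missing == "fail") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    rules <- rules[rules$rsid %in% panel$rsid, , drop = FALSE]
  }
  keep <- !(panel$rsid %in% rules$rsid)
  log <- merge(data.frame(rsid = panel$rsid[!keep]), as.data.frame(rules),
               by = "rsid", sort = FALSE)
  out <- new_grs_panel(panel[keep, , drop = FALSE], attr(panel, "name"))
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- log
  out
}

.revcomp <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Substitute proxy SNPs for one cohort
#'
#' Some panel SNPs were genotyped through a high-LD proxy in the HAPO-style
#' cohort. For that cohort the rsid, alleles and effect-allele frequency are
#' replaced by the proxy's values while the published weight is retained
#' unchanged; for other cohorts the panel is returned as is. Panel size and
#' all betas are invariant.
#'
#' @param panel A `grs_panel`.
#' @param cohort Cohort label; `"HAPO"` triggers substitution, anything else
#'   (e.g. `"DIP"`) is the identity.
#' @return A `grs_panel` keyed by the rsids actually genotyped.
#' @export
resolve_proxies <- function(panel, cohort = "DIP") {
  stopifnot(inherits(panel, "grs_panel"))
  if (!identical(toupper(cohort), "HAPO"))
    return(panel)
  has_proxy <- !is.na(panel$proxy_rsid) & nzchar(panel$proxy_rsid)
  out <- panel
  out$rsid[has_proxy] <- panel$proxy_rsid[has_proxy]
  out$effect_allele[has_proxy] <- panel$proxy_effect_allele[has_proxy]
  out$other_allele[has_proxy] <- panel$proxy_other_allele[has_proxy]
  out$eaf[has_proxy] <- panel$proxy_eaf[has_proxy]
  out$proxy_rsid[has_proxy] <- NA_character_
  out$proxy_effect_allele[has_proxy] <- NA_character_
  out$proxy_other_allele[has_proxy] <- NA_character_
  out$proxy_eaf[has_proxy] <- NA_real_
  if (anyDuplicated(out$rsid))
    stop("proxy substitution produced duplicate rsids", call. = FALSE)
  out
}
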