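#' Weighted genetic scores
#'
#' The score for one individual is the weighted sum of effect-allele counts,
#' rescaled by the panel size over the summed weights:
#' \deqn{GS = N \frac{\sum_i a_i \beta_i}{\sum_i \beta_i}}
#' where \eqn{a_i \in \{0,1,2\}} counts effect alleles at SNP i,
#' \eqn{\beta_i > 0} is its weight and N is the number of SNPs in the panel.
#' The rescaling makes the score unit-agnostic with range \[0, 2N\]; an
#' individual heterozygous everywhere scores exactly N. Scores are computed
#' only for individuals with a called genotype at every panel SNP
#' (strict complete-data rule); anyone with a missing call gets a null
#' score.
#'
#' @name scoring
NULL

#' Compute the weighted score for one individual
#'
#' @param dosages Named vector of effect-allele counts (0/1/2, NA for
#'   missing), keyed by the panel's rsids.
#' @param panel A `grs_panel` (all entries scoreable).
#' @return List: `score` (numeric or NA if incomplete), `n_snps_used`,
#'   `complete` flag.
#' @examples
#' fpg <- gdm_panel("FPG")
#' d <- setNames(rep(1, nrow(fpg)), fpg$rsid)
#' compute_score(d, fpg)$score   # all-heterozygous scores exactly N = 15
#' @export
compute_score <- function(dosages, panel) {
  stopifnot(inherits(panel, "grs_panel"))
  if (any(!panel$scoreable))
    stop("panel contains non-scoreable entries; apply exclusions first",
         call. = FALSE)
  absent <- setdiff(panel$rsid, names(dosages))
  if (length(absent) > 0L)
    stop("dosage vector missing panel SNP(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  a <- dosages[panel$rsid]
  if (any(!is.na(a) & !(a %in% c(0, 1, 2))))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (anyNA(a))
    return(list(score = NA_real_, n_snps_used = sum(!is.na(a)),
                complete = FALSE))
  n <- nrow(panel)
  list(score = n * sum(a * panel$beta) / sum(panel$beta),
       n_snps_used = n, complete = TRUE)
}

#' Score every sample in a cohort
#'
#' Vectorised form of [compute_score()]: requires the genotype matrix to
#' cover all panel SNPs, and applies the complete-data rule per sample.
#'
#' @param gm Dosage matrix (samples x rsids).
#' @param panel A `grs_panel`.
#' @return Data frame: `sample_id`, `score` (NA when incomplete),
#'   `n_snps_used`, `complete`; panel name in attribute `panel`. A summary
#'   of complete/incomplete counts is reported via `message`.
#' @export
score_cohort <- function(gm, panel) {
  assert_genotype_matrix(gm)
  stopifnot(inherits(panel, "grs_panel"))
  if (any(!panel$scoreable))
    stop("panel contains non-scoreable entries; apply exclusions first",
         call. = FALSE)
  absent <- setdiff(panel$rsid, colnames(gm))
  if (length(absent) > 0L)
    stop("genotype matrix missing panel SNP(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (nrow(gm) == 0L) {
    out <- data.frame(sample_id = character(0), score = numeric(0),
                      n_snps_used = integer(0), complete = logical(0))
    attr(out, "panel") <- attr(panel, "name")
    return(out)
  }
  a <- gm[, panel$rsid, drop = FALSE]
  n <- nrow(panel)
  n_used <- rowSums(!is.na(a))
  complete <- n_used == n
  raw <- a %*% panel$beta
  score <- ifelse(complete, n * as.numeric(raw) / sum(panel$beta), NA_real_)
  message(sprintf("%s scores: %d complete, %d incomplete of %d samples",
                  attr(panel, "name"), sum(complete), sum(!complete),
                  nrow(gm)))
  out <- data.frame(sample_id = rownames(gm), score = score,
                    n_snps_used = as.integer(n_used), complete = complete,
                    row.names = NULL)
  attr(out, "panel") <- attr(panel, "name")
  out
}

#' Theoretical score moments under Hardy-Weinberg equilibrium
#'
#' Closed-form population mean and SD of the weighted score when genotypes
#' are independent binomial(2, p) draws at the panel frequencies:
#' mean \eqn{2N\sum p\beta/\sum\beta}, variance
#' \eqn{(N/\sum\beta)^2 \sum 2p(1-p)\beta^2}.
#'
#' @param panel A `grs_panel`.
#' @return List with `mean` and `sd`.
#' @export
score_moments <- function(panel) {
  stopifnot(inherits(panel, "grs_panel"), all(panel$scoreable))
  n <- nrow(panel); b <- panel$beta; p <- panel$eaf
  list(mean = 2 * n * sum(p * b) / sum(b),
       sd = (n / sum(b)) * sqrt(sum(2 * p * (1 - p) * b^2)))
}

#' Merge per-panel score tables into one cohort table
#'
#' @param fpg_scores,t2d_scores Outputs of [score_cohort()] for the FPG and
#'   T2D panels.
#' @return Data frame `sample_id, fpg_gs, t2d_gs, fpg_complete,
#'   t2d_complete`.
#' @export
merge_scores <- function(fpg_scores, t2d_scores) {
  out <- merge(
    data.frame(sample_id = fpg_scores$sample_id, fpg_gs = fpg_scores$score,
               fpg_complete = fpg_scores$complete),
    data.frame(sample_id = t2d_scores$sample_id, t2d_gs = t2d_scores$score,
               t2d_complete = t2d_scores$complete),
    by = "sample_id", all = TRUE, sort = FALSE)
  out[match(fpg_scores$sample_id, out$sample_id), , drop = FALSE]
}
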