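#' Hardy-Weinberg equilibrium QC
#'
#' Each panel SNP is tested for deviation from Hardy-Weinberg proportions
#' (expected genotype fractions p^2, 2pq, q^2 with the allele frequency
#' estimated from the counts themselves). The default test is the 1-df
#' Pearson goodness-of-fit chi-square without continuity correction; an
#' exact test conditioning on the observed allele counts is available for
#' small samples. SNPs whose Bonferroni-corrected P falls below the
#' threshold are emitted as `hwe_failure` exclusion rules. Monomorphic SNPs
#' are flagged and never excluded: the test is undefined there and exclusion
#' would silently shrink the panel.
#'
#' @name qc_hwe
NULL

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' @param n_hom_effect Count of effect-allele homozygotes.
#' @param n_het Heterozygote count.
#' @param n_hom_other Other-allele homozygote count.
#' @return List with `chi2`, `p` (upper-tail, 1 df) and `monomorphic` flag.
#'   Monomorphic input gives `chi2 = 0`, `p = 1`.
#' @examples
#' hwe_chi2(25, 50, 25)$p   # exact HWE proportions -> 1
#' @export
hwe_chi2 <- function(n_hom_effect, n_het, n_hom_other) {
  if (min(n_hom_effect, n_het, n_hom_other) < 0)
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_hom_effect + n_het + n_hom_other
  if (n < 1) stop("at least one genotyped sample required", call. = FALSE)
  p <- (2 * n_hom_effect + n_het) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  expct <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  obs <- c(n_hom_effect, n_het, n_hom_other)
  chi2 <- sum((obs - expct)^2 / expct)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Exact Hardy-Weinberg test from genotype counts
#'
#' Two-sided exact test conditioning on the observed allele counts: sums the
#' probabilities of all heterozygote counts no more likely than the observed
#' one.
#'
#' @inheritParams hwe_chi2
#' @return List with `p` and `monomorphic` flag.
#' @export
hwe_exact <- function(n_hom_effect, n_het, n_hom_other) {
  if (min(n_hom_effect, n_het, n_hom_other) < 0)
    stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_hom_effect + n_het + n_hom_other
  if (n < 1) stop("at least one genotyped sample required", call. = FALSE)
  n_a <- 2 * n_hom_effect + n_het        # rarer-or-not effect alleles
  if (n_a == 0 || n_a == 2 * n)
    return(list(p = 1, monomorphic = TRUE))
  n_minor <- min(n_a, 2 * n - n_a)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_het = h | allele counts) up to a common constant
  logp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((2 * n - n_minor - hets) / 2 + 1) +
    hets * log(2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- n_het
  p <- sum(prob[prob <= prob[match(obs, hets)] + 1e-12])
  list(p = min(1, p), monomorphic = FALSE)
}

#' Screen a genotype matrix for HWE deviation
#'
#' One test per SNP, Bonferroni-corrected over the number of SNPs tested
#' (`m = ncol(gm)`), matching a per-panel screen of the candidate SNP set.
#'
#' @param gm Dosage matrix (samples x SNPs, effect-allele coded).
#' @param alpha Familywise threshold on the Bonferroni-corrected P
#'   (default 0.05).
#' @param test `"chi2"` (default) or `"exact"`.
#' @return List with `results` (data frame: rsid, genotype counts, chi2,
#'   p_raw, p_bonferroni, monomorphic, excluded) and `rules` (the
#'   `hwe_failure` [exclusion_rules()] for the excluded SNPs).
#' @export
hwe_screen <- function(gm, alpha = 0.05, test = c("chi2", "exact")) {
  assert_genotype_matrix(gm)
  test <- match.arg(test)
  if (nrow(gm) == 0L || ncol(gm) == 0L)
    stop("empty genotype matrix", call. = FALSE)
  m <- ncol(gm)
  res <- lapply(colnames(gm), function(rsid) {
    d <- gm[, rsid]
    counts <- c(n_hom_effect = sum(d == 2L, na.rm = TRUE),
                n_het = sum(d == 1L, na.rm = TRUE),
                n_hom_other = sum(d == 0L, na.rm = TRUE))
    h <- hwe_chi2(counts[1], counts[2], counts[3])
    if (test == "exact" && !h$monomorphic)
      h$p <- hwe_exact(counts[1], counts[2], counts[3])$p
    data.frame(rsid = rsid, t(counts),
               chi2 = h$chi2, p_raw = h$p,
               p_bonferroni = min(1, m * h$p),
               monomorphic = h$monomorphic)
  })
  res <- do.call(rbind, res)
  res$excluded <- !res$monomorphic & res$p_bonferroni < alpha
  rules <- if (any(res$excluded))
    exclusion_rules(res$rsid[res$excluded], "hwe_failure",
                    sprintf("HWE deviation, Bonferroni-corrected P = %.3g (m = %d)",
                            res$p_bonferroni[res$excluded], m))
  else exclusion_rules(character(0))
  list(results = res, rules = rules)
}

#' Write an HWE screen to TSV
#' @param screen Result of [hwe_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hwe_screen <- function(screen, path) {
  utils::write.table(screen$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
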