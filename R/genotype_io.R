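#' Genotype input and QC metrics
#'
#' Genotypes are held as an integer matrix of effect-allele dosages: rows are
#' samples, columns are panel rsids, cells in \{0, 1, 2, NA\}. Input comes
#' from a dosage TSV (already effect-allele coded) or from a VCF, in which
#' case calls are re-oriented to the panel's effect allele, trying the
#' alleles as written first and their reverse complements second.
#' Palindromic (A/T or C/G) variants cannot be strand-resolved from alleles
#' alone; the default policy refuses them, see `palindrome_policy`.
#'
#' @name genotype_io
NULL

assert_genotype_matrix <- function(gm) {
  if (!is.matrix(gm) ||
      (nrow(gm) > 0L && is.null(rownames(gm))) ||
      (ncol(gm) > 0L && is.null(colnames(gm))))
    stop("genotypes must be a matrix with sample rownames and rsid colnames",
         call. = FALSE)
  vals <- gm[!is.na(gm)]
  if (length(vals) > 0L && !all(vals %in% c(0L, 1L, 2L)))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  invisible(gm)
}

.is_palindromic <- function(a1, a2) identical(unname(.revcomp(a1)), a2)

# Decide, for one biallelic site, whether the file ALT allele carries the
# panel effect allele. Returns +1 (ALT = effect), -1 (REF = effect) or stops.
.orient_alleles <- function(rsid, ref, alt, ea, oa, policy, alt_freq = NA,
                            panel_eaf = NA) {
  if (!all(c(ref, alt) %in% .valid_bases))
    stop("non-SNP or multi-allelic record at ", rsid, call. = FALSE)
  if (.is_palindromic(ea, oa)) {
    if (!setequal(c(ref, alt), c(ea, oa)))
      stop(sprintf("alleles at palindromic SNP %s (%s/%s in file) do not match panel %s/%s",
                   rsid, ref, alt, ea, oa), call. = FALSE)
    if (policy == "fail")
      stop(sprintf("palindromic SNP cannot be strand-resolved under policy 'fail': %s (%s/%s)",
                   rsid, ea, oa), call. = FALSE)
    if (policy == "trust")
      return(if (alt == ea) 1L else -1L)
    # freq: pick the orientation whose implied effect-allele frequency is
    # closer to the panel frequency
    if (is.na(alt_freq) || is.na(panel_eaf))
      stop("frequency-based palindrome resolution needs observed and panel frequencies at ",
           rsid, call. = FALSE)
    return(if (abs(alt_freq - panel_eaf) <= abs((1 - alt_freq) - panel_eaf))
      1L else -1L)
  }
  if (alt == ea && ref == oa) return(1L)
  if (alt == oa && ref == ea) return(-1L)
  rref <- unname(.revcomp(ref)); ralt <- unname(.revcomp(alt))
  if (ralt == ea && rref == oa) return(1L)
  if (ralt == oa && rref == ea) return(-1L)
  stop(sprintf("alleles at %s (%s/%s in file) match neither panel alleles %s/%s nor their complements",
               rsid, ref, alt, ea, oa), call. = FALSE)
}

#' Read genotypes aligned to a panel
#'
#' @param path Genotype file.
#' @param format `"tsv"` for a dosage table (first column `sample_id`, one
#'   column per rsid, cells 0/1/2 counting effect alleles, empty or NA for
#'   missing) or `"vcf"` for a VCF v4.2 subset (GT field only, rsid-keyed
#'   matching).
#' @param panel A `grs_panel`, already proxy-resolved for the cohort.
#' @param palindrome_policy How to orient A/T and C/G variants read from VCF:
#'   `"fail"` (default; hard error listing the SNP), `"freq"` (choose the
#'   orientation whose implied effect-allele frequency is closer to the
#'   panel frequency) or `"trust"` (accept REF/ALT as written).
#' @return Integer dosage matrix, samples x panel SNPs, restricted to and
#'   ordered as the panel's scoreable rsids. SNPs present in the file but
#'   not in the panel are ignored (count reported via message).
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), panel,
                           palindrome_policy = c("fail", "freq", "trust")) {
  format <- match.arg(format)
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(panel, "grs_panel"))
  want <- panel$rsid[panel$scoreable]
  if (format == "tsv") {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             check.names = FALSE, comment.char = "#",
                             na.strings = c("", "NA", "./."))
    if (!"sample_id" %in% names(tab))
      stop("dosage TSV must have a 'sample_id' first column", call. = FALSE)
    ignored <- setdiff(setdiff(names(tab), "sample_id"), want)
    if (length(ignored) > 0L)
      message(length(ignored), " genotyped SNP(s) not in the panel were ignored")
    absent <- setdiff(want, names(tab))
    if (length(absent) > 0L)
      stop("panel SNP(s) absent from genotype file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    gm <- as.matrix(tab[, want, drop = FALSE])
    storage.mode(gm) <- "numeric"
    bad <- gm[!is.na(gm) & !(gm %in% c(0, 1, 2))]
    if (length(bad) > 0L)
      stop("dosage TSV cells must be 0, 1, 2 or NA; found ",
           paste(utils::head(unique(bad), 3), collapse = ", "),
           call. = FALSE)
    storage.mode(gm) <- "integer"
    rownames(gm) <- as.character(tab$sample_id)
    return(assert_genotype_matrix(gm))
  }
  # VCF path
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix),
                 dimnames = list(fix[, "ID"], names(gt)))
  ids <- fix[, "ID"]
  ignored <- sum(!ids %in% want)
  if (ignored > 0L)
    message(ignored, " VCF record(s) not in the panel were ignored")
  absent <- setdiff(want, ids)
  if (length(absent) > 0L)
    stop("panel SNP(s) absent from VCF: ", paste(absent, collapse = ", "),
         call. = FALSE)
  samples <- colnames(gt)
  gm <- matrix(NA_integer_, nrow = length(samples), ncol = length(want),
               dimnames = list(samples, want))
  for (rsid in want) {
    k <- which(ids == rsid)[1]
    row <- panel[panel$rsid == rsid, ]
    g <- gt[k, ]
    # count ALT alleles from the GT string; "." anywhere -> missing
    alt_count <- ifelse(is.na(g) | grepl("\\.", g),
                        NA_integer_,
                        vapply(strsplit(gsub("\\|", "/", g), "/"),
                               function(x) sum(x == "1"), integer(1)))
    alt_freq <- if (all(is.na(alt_count))) NA_real_ else
      mean(alt_count, na.rm = TRUE) / 2
    sgn <- .orient_alleles(rsid, fix[k, "REF"], fix[k, "ALT"],
                           row$effect_allele, row$other_allele,
                           palindrome_policy, alt_freq, row$eaf)
    gm[, rsid] <- if (sgn == 1L) alt_count else 2L - alt_count
  }
  assert_genotype_matrix(gm)
}

#' Write a dosage matrix to TSV
#'
#' Round-trips exactly through [read_genotypes()] with `format = "tsv"`.
#'
#' @param gm Dosage matrix (samples x rsids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  assert_genotype_matrix(gm)
  out <- data.frame(sample_id = rownames(gm), gm, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Per-SNP call rates
#'
#' @param gm Dosage matrix.
#' @return List with `per_snp_call_rate` (named fraction per SNP, called /
#'   total samples) and `median_call_rate` (median over SNPs).
#' @export
call_rates <- function(gm) {
  if (is.matrix(gm) && nrow(gm) == 0L)
    stop("call rates are undefined for zero samples", call. = FALSE)
  assert_genotype_matrix(gm)
  per_snp <- colMeans(!is.na(gm))
  list(per_snp_call_rate = per_snp,
       median_call_rate = stats::median(per_snp))
}

#' Concordance between duplicate samples
#'
#' Fraction of jointly-called genotype calls that agree, pooled over the
#' supplied duplicate pairs. Pairs with no jointly-called genotypes are
#' flagged and excluded from the pooled fraction.
#'
#' @param gm Dosage matrix.
#' @param pairs Two-column matrix/data frame of sample ids, or a list of
#'   length-2 id vectors.
#' @return Pooled concordance fraction, with attributes `n_duplicate_pairs`
#'   (pairs contributing), `n_compared` (jointly-called genotypes pooled) and
#'   `dropped_pairs` (indices of degenerate pairs).
#' @export
duplicate_concordance <- function(gm, pairs) {
  assert_genotype_matrix(gm)
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  absent <- setdiff(unique(c(pairs)), rownames(gm))
  if (length(absent) > 0L)
    stop("duplicate pair member(s) absent from genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  agree <- 0L; total <- 0L; dropped <- integer(0); used <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- gm[pairs[i, 1], ]; b <- gm[pairs[i, 2], ]
    joint <- !is.na(a) & !is.na(b)
    if (!any(joint)) { dropped <- c(dropped, i); next }
    agree <- agree + sum(a[joint] == b[joint])
    total <- total + sum(joint)
    used <- used + 1L
  }
  if (length(dropped) > 0L)
    warning("pair(s) with no jointly-called genotypes excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  if (total == 0L)
    stop("no jointly-called genotypes in any duplicate pair", call. = FALSE)
  structure(agree / total, n_duplicate_pairs = used, n_compared = total,
            dropped_pairs = dropped)
}

#' Genotyping QC report
#'
#' Bundles the genotyping quality metrics: per-SNP and median call rate and,
#' when duplicate pairs are supplied, pooled duplicate concordance.
#'
#' @param gm Dosage matrix.
#' @param pairs Optional duplicate sample pairs (see
#'   [duplicate_concordance()]).
#' @return List of class `grs_qc_report`.
#' @export
qc_report <- function(gm, pairs = NULL) {
  cr <- call_rates(gm)
  rep <- list(per_snp_call_rate = cr$per_snp_call_rate,
              median_call_rate = cr$median_call_rate,
              duplicate_concordance = NA_real_,
              n_duplicate_pairs = 0L)
  if (!is.null(pairs)) {
    dc <- duplicate_concordance(gm, pairs)
    rep$duplicate_concordance <- as.numeric(dc)
    rep$n_duplicate_pairs <- attr(dc, "n_duplicate_pairs")
  }
  structure(rep, class = "grs_qc_report")
}

#' @export
print.grs_qc_report <- function(x, ...) {
  cat(sprintf("<grs_qc_report> %d SNPs, median call rate %.3f\n",
              length(x$per_snp_call_rate), x$median_call_rate))
  if (!is.na(x$duplicate_concordance))
    cat(sprintf("  duplicate concordance %.4f over %d pair(s)\n",
                x$duplicate_concordance, x$n_duplicate_pairs))
  invisible(x)
}
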