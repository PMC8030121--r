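vcf_panel <- function() {
  df <- tiny_panel_df()
  df$proxy_rsid <- NA; df$proxy_effect_allele <- NA
  df$proxy_other_allele <- NA; df$proxy_eaf <- NA
  tiny_panel(df)
}

test_that("VCF dosages count effect alleles whatever the representation", {
  p <- vcf_panel()   # effect alleles A(rs1), C(rs2), G(rs3)
  samples <- c("s1", "s2")
  # rs2: REF=T ALT=C (effect = ALT); rs1: REF=A ALT=G (effect = REF);
  # rs3 via strand complement: file C/T == complement of G/A
  vcf <- write_tiny_vcf(list(
    list(chrom = "1", pos = 100, id = "rs1", ref = "A", alt = "G",
         gt = c("0/0", "0/1")),
    list(chrom = "2", pos = 200, id = "rs2", ref = "T", alt = "C",
         gt = c("0/1", "1/1")),
    list(chrom = "3", pos = 300, id = "rs3", ref = "C", alt = "T",
         gt = c("./.", "1|0"))), samples)
  gm <- read_genotypes(vcf, "vcf", p)
  expect_identical(gm["s1", ], c(rs1 = 2L, rs2 = 1L, rs3 = NA))
  expect_identical(gm["s2", ], c(rs1 = 1L, rs2 = 2L, rs3 = 1L))

  # swapped REF/ALT with genotype indices updated is representation-invariant
  vcf2 <- write_tiny_vcf(list(
    list(chrom = "1", pos = 100, id = "rs1", ref = "A", alt = "G",
         gt = c("0/0", "0/1")),
    list(chrom = "2", pos = 200, id = "rs2", ref = "C", alt = "T",
         gt = c("1/0", "0/0")),
    list(chrom = "3", pos = 300, id = "rs3", ref = "C", alt = "T",
         gt = c("./.", "0|1"))), samples)
  gm2 <- read_genotypes(vcf2, "vcf", p)
  expect_identical(gm, gm2)
})

test_that("mismatched alleles and palindromic SNPs are refused by name", {
  df <- tiny_panel_df()[1, ]
  df[c("proxy_rsid", "proxy_effect_allele", "proxy_other_allele")] <- NA
  df$proxy_eaf <- NA
  p <- tiny_panel(df)
  vcf <- write_tiny_vcf(list(
    list(chrom = "1", pos = 100, id = "rs1", ref = "A", alt = "C",
         gt = c("0/1"))), "s1")
  expect_error(read_genotypes(vcf, "vcf", p), "rs1.*neither panel alleles")

  # palindromic A/T panel SNP: default policy is a hard error naming it
  dfp <- df
  dfp$effect_allele <- "A"; dfp$other_allele <- "T"; dfp$eaf <- 0.2
  pp <- tiny_panel(dfp)
  vcfp <- write_tiny_vcf(list(
    list(chrom = "1", pos = 100, id = "rs1", ref = "T", alt = "A",
         gt = c("0/1", "1/1", "0/0", "0/0", "0/0"))),
    paste0("s", 1:5))
  expect_error(read_genotypes(vcfp, "vcf", pp), "palindromic SNP.*rs1")
  # freq policy: observed ALT(A) frequency 0.3 is nearer panel eaf 0.2 than
  # 0.7, so ALT carries the effect allele
  gm <- read_genotypes(vcfp, "vcf", pp, palindrome_policy = "freq")
  expect_identical(unname(gm[, "rs1"]), c(1L, 2L, 0L, 0L, 0L))
  # trust policy accepts REF/ALT as written
  gm2 <- read_genotypes(vcfp, "vcf", pp, palindrome_policy = "trust")
  expect_identical(gm, gm2)
})

test_that("dosage TSV round-trips exactly and rejects bad cells", {
  p <- vcf_panel()
  gm <- dosage_matrix(c(0, 1, 2, NA, 2, 0), c("a", "b"),
                      c("rs1", "rs2", "rs3"))
  f <- tempfile(fileext = ".tsv")
  write_genotypes(gm, f)
  expect_identical(read_genotypes(f, "tsv", p), gm)

  bad <- readLines(f)
  bad[2] <- sub("\t0\t", "\t7\t", bad[2])
  writeLines(bad, f)
  expect_error(read_genotypes(f, "tsv", p), "0, 1, 2 or NA")

  # a panel SNP absent from the file is an error before any scoring
  f2 <- tempfile(fileext = ".tsv")
  write_genotypes(gm[, 1:2], f2)
  expect_error(read_genotypes(f2, "tsv", p), "absent.*rs3")
})

test_that("call rates follow the definition and its boundaries", {
  gm <- dosage_matrix(c(rep(1L, 99), NA, rep(NA, 100)),
                      paste0("s", 1:100), c("rs1", "rs2"))
  cr <- call_rates(gm)
  expect_equal(unname(cr$per_snp_call_rate), c(0.99, 0))
  expect_equal(cr$median_call_rate, 0.495)
  expect_error(call_rates(gm[0, , drop = FALSE]), "zero samples")
  # permutation invariance over samples
  perm <- sample(nrow(gm))
  expect_equal(call_rates(gm[perm, ]), cr)
})

test_that("missingness at rate 0.008 gives a median call rate near 0.992", {
  set.seed(11)
  p <- gdm_panel("FPG")
  gm <- simulate_genotypes(p, 4000, missing_rate = 0.008)
  cr <- call_rates(gm)
  # binomial error at n = 4000: 3 * sqrt(0.008 * 0.992 / 4000) ~ 0.0042
  expect_lt(abs(cr$median_call_rate - 0.992), 0.005)
})

test_that("duplicate concordance pools joint calls and flags degenerate pairs", {
  base <- c(0L, 1L, 2L, 1L, 0L)
  gm <- rbind(s1 = base, s1b = base,
              s2 = c(0L, 1L, 2L, 1L, 0L), s2b = c(0L, 1L, 2L, 1L, 1L),
              s3 = base, s3b = rep(NA_integer_, 5))
  colnames(gm) <- paste0("rs", 1:5)
  expect_equal(as.numeric(duplicate_concordance(gm, list(c("s1", "s1b")))), 1)
  d <- duplicate_concordance(gm, list(c("s1", "s1b"), c("s2", "s2b")))
  expect_equal(as.numeric(d), 9 / 10)
  expect_warning(
    d2 <- duplicate_concordance(gm, list(c("s1", "s1b"), c("s3", "s3b"))),
    "no jointly-called")
  expect_equal(as.numeric(d2), 1)
  expect_equal(attr(d2, "n_duplicate_pairs"), 1L)
  expect_error(duplicate_concordance(gm, list(c("s1", "nope"))), "absent")
  # disagreement at 1 of 50 joint calls -> 0.98
  g2 <- rbind(a = rep(1L, 50), b = c(rep(1L, 49), 2L))
  colnames(g2) <- paste0("rs", 1:50)
  expect_equal(as.numeric(duplicate_concordance(g2, list(c("a", "b")))),
               0.98)
})

test_that("qc_report bundles call rates and concordance", {
  gm <- dosage_matrix(rep(1L, 6), c("s1", "s1b"), c("rs1", "rs2", "rs3"))
  rep <- qc_report(gm, pairs = list(c("s1", "s1b")))
  expect_s3_class(rep, "grs_qc_report")
  expect_equal(rep$median_call_rate, 1)
  expect_equal(rep$duplicate_concordance, 1)
  expect_equal(rep$n_duplicate_pairs, 1L)
})
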