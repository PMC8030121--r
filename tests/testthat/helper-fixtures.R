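# In-code fixtures: tiny panels, dosage tables and VCF text built at test
# time; nothing binary is stored.

tiny_panel_df <- function() {
  data.frame(
    rsid = c("rs1", "rs2", "rs3"),
    proxy_rsid = c(NA, "rs2p", NA),
    proxy_effect_allele = c(NA, "T", NA),
    proxy_other_allele = c(NA, "G", NA),
    proxy_eaf = c(NA, 0.4, NA),
    chrom = c("1", "2", "3"),
    pos = c(100L, 200L, 300L),
    locus = c("L1", "L2", "L3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.5, 0.7),
    beta = c(0.10, 0.20, 0.40),
    source = "test",
    stringsAsFactors = FALSE
  )
}

write_panel_df <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

tiny_panel <- function(df = tiny_panel_df(), name = "FPG", strict = TRUE) {
  load_panel(write_panel_df(df), name, strict = strict)
}

# minimal VCF with GT-only records; alleles and genotypes given per SNP
write_tiny_vcf <- function(records, samples,
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

dosage_matrix <- function(values, samples, rsids) {
  matrix(as.integer(values), nrow = length(samples),
         dimnames = list(samples, rsids))
}

expect_error_matching <- function(expr, pattern) {
  expect_error(expr, regexp = pattern)
}
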