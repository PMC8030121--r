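test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_samples = 300, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  c2 <- simulate_cohort(sim_config(n_samples = 300, seed = 100))
  expect_false(identical(a$phenotypes$fpg, c2$phenotypes$fpg))
  expect_error(simulate_cohort(sim_config(n_samples = 10)),
               "seed is mandatory")
})

test_that("genotypes follow Hardy-Weinberg proportions at the panel eaf", {
  p <- gdm_panel("T2D")
  gm <- simulate_genotypes(p, 100000, seed = 7, missing_rate = 0)
  # expected genotype fractions at the shipped index frequency
  i <- p$eaf[match("rs7903146", p$rsid)]
  d <- gm[, "rs7903146"]
  obs <- c(mean(d == 2), mean(d == 1), mean(d == 0))
  expct <- c(i^2, 2 * i * (1 - i), (1 - i)^2)
  se <- sqrt(expct * (1 - expct) / 100000)
  expect_true(all(abs(obs - expct) < 4 * se))
  # empirical allele frequencies track eaf across the whole panel
  freqs <- colMeans(gm) / 2
  expect_lt(max(abs(freqs - p$eaf)), 4 * sqrt(0.25 / (2 * 100000)) + 0.002)
})

test_that("shared SNPs between panels are drawn once", {
  cfg <- sim_config(n_samples = 50, seed = 4)
  co <- simulate_cohort(cfg)
  fpg <- gdm_panel("FPG"); t2d <- gdm_panel("T2D")
  shared <- intersect(fpg$rsid, t2d$rsid)
  expect_gt(length(shared), 0)
  # each rsid appears exactly once in the matrix
  expect_equal(ncol(co$genotypes),
               length(unique(c(fpg$rsid, t2d$rsid))))
  expect_false(anyDuplicated(colnames(co$genotypes)) > 0)
})

test_that("the FPG score explains the configured variance fraction", {
  cfg <- sim_config(n_samples = 50000, missing_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)
  gs <- suppressMessages(score_cohort(co$genotypes[, gdm_panel("FPG")$rsid],
                                      gdm_panel("FPG")))$score
  r2 <- summary(lm(co$phenotypes$fpg ~ gs))$r.squared
  expect_gt(r2, 0.05)
  expect_lt(r2, 0.07)
  # and the regression slope approaches sum(beta)/N
  target <- sum(gdm_panel("FPG")$beta) / nrow(gdm_panel("FPG"))
  slope <- coef(lm(co$phenotypes$fpg ~ gs))[2]
  se <- summary(lm(co$phenotypes$fpg ~ gs))$coefficients[2, 2]
  expect_lt(abs(slope - target), 3 * se)
  expect_equal(unique(co$truth$slope_fpg_on_gs), target)
})

test_that("variance explained of zero is the full null model", {
  cfg <- sim_config(n_samples = 20000, gs_variance_explained = 0,
                    missing_rate = 0, seed = 33)
  co <- simulate_cohort(cfg)
  gs <- suppressMessages(score_cohort(co$genotypes[, gdm_panel("FPG")$rsid],
                                      gdm_panel("FPG")))$score
  fit <- summary(lm(co$phenotypes$fpg ~ gs))
  expect_gt(fit$coefficients[2, 4], 0.001)   # no detectable association
  expect_lt(abs(fit$coefficients[2, 1]), 3 * fit$coefficients[2, 2])
  expect_lt(abs(sd(co$phenotypes$fpg) - cfg$fpg_sd), 0.01)
})

test_that("post-load glucose totals match the configured moments", {
  cfg <- sim_config(n_samples = 50000, missing_rate = 0, seed = 55,
                    covariates = FALSE)
  co <- simulate_cohort(cfg)
  ph <- co$phenotypes
  expect_lt(abs(mean(ph$glu_1h) - 7.1), 0.03)
  expect_lt(abs(sd(ph$glu_1h) - 1.7), 0.03)
  expect_lt(abs(mean(ph$glu_2h) - 5.8), 0.03)
  expect_lt(abs(sd(ph$glu_2h) - 1.3), 0.03)
  expect_lt(abs(mean(ph$fpg) - 4.5), 0.01)
  expect_false("bmi" %in% names(ph))
  # covariates on: BMI is elevated in hyperglycaemic pregnancies
  cfg2 <- sim_config(n_samples = 20000, missing_rate = 0, seed = 56)
  ph2 <- simulate_cohort(cfg2)$phenotypes
  expect_gt(cor(ph2$bmi, ph2$fpg), 0.2)
  expect_true(all(ph2$age >= 18 & ph2$age <= 45))
})

test_that("phenotype simulation refuses incomplete genotypes", {
  p <- gdm_panel("FPG")
  gm <- simulate_genotypes(p, 50, seed = 2, missing_rate = 0.2)
  expect_error(simulate_phenotypes(gm, p, gdm_panel("T2D"), sim_config()),
               "complete genotypes")
  # impossible variance demands are refused, not silently clipped
  expect_error(
    simulate_cohort(sim_config(n_samples = 100, glu_1h_sd = 0.01, seed = 1)),
    "too large")
})

test_that("case-control sampling keeps all cases with exactly 3:1 controls", {
  cfg <- sim_config(n_samples = 20000, seed = 61)
  co <- simulate_cohort(cfg)
  samp <- sample_cohort(co, "case_control_3to1", seed = 62)
  ph <- samp$phenotypes
  case <- ph$fpg >= 5.1 | ph$glu_1h >= 10.0 | ph$glu_2h >= 8.5
  full_case <- with(co$phenotypes,
                    fpg >= 5.1 | glu_1h >= 10.0 | glu_2h >= 8.5)
  expect_equal(sum(case), sum(full_case))
  expect_equal(sum(!case), 3 * sum(case))
  # representative style is the identity
  expect_identical(sample_cohort(co, "representative"), co)
  # deficit: a cohort that is almost all cases cannot find 3 controls each
  hot <- simulate_cohort(sim_config(n_samples = 200, fpg_mean = 6.5,
                                    seed = 63))
  expect_error(sample_cohort(hot, "case_control_3to1"), "deficit")
})

test_that("write_cohort stamps files and round-trips through the readers", {
  cfg <- sim_config(n_samples = 40, seed = 77)
  co <- simulate_cohort(cfg)
  d <- tempfile()
  write_cohort(co, d)
  gl <- readLines(file.path(d, "genotypes.tsv"), n = 1)
  expect_match(gl, "^# seed=77 config_hash=[0-9a-f]+$")
  gm <- suppressMessages(read_genotypes(file.path(d, "genotypes.tsv"),
                                        "tsv", gdm_panel("FPG")))
  expect_identical(gm, co$genotypes[, gdm_panel("FPG")$rsid])
  ph <- read_phenotypes(file.path(d, "phenotypes.csv"))
  expect_equal(ph$fpg, co$phenotypes$fpg, tolerance = 1e-10)
  expect_equal(ph$sample_id, co$phenotypes$sample_id)
})
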