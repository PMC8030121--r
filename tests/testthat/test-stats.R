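test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.002, 24), 0.048)
  expect_equal(bonferroni(0.2, 24), 1)
  expect_equal(bonferroni(c(0.001, 0.5), 16), c(0.016, 1))
  # monotone in both arguments
  p <- runif(50)
  expect_true(all(bonferroni(p, 24) >= bonferroni(p, 16)))
  expect_true(all(bonferroni(sort(p), 8) == sort(bonferroni(p, 8))))
  expect_error(bonferroni(-0.1, 2), "p >= 0")
  expect_error(bonferroni(0.5, 0), "m >= 1")
})

test_that("two-group t test behaves at the degenerate corners", {
  same <- c(1, 2, 3, 4)
  r <- two_group_test(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 1)
  # antisymmetry of the statistic
  x <- c(5.1, 4.9, 5.4); y <- c(4.2, 4.4, 4.0)
  a <- two_group_test(x, y); b <- two_group_test(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_raw, b$p_raw)
  # zero variance in both groups, different means
  z <- two_group_test(c(2, 2), c(1, 1))
  expect_equal(z$statistic, Inf)
  expect_equal(z$p_raw, 0)
  expect_error(two_group_test(1, c(1, 2)), "at least two")
})

test_that("pooled t test equals the lm on a binary predictor (property)", {
  set.seed(91)
  for (i in 1:5) {
    x <- rnorm(12, 1); y <- rnorm(15)
    r <- two_group_test(x, y)
    fit <- summary(lm(v ~ g, data.frame(v = c(x, y),
                                        g = rep(1:0, c(12, 15)))))
    expect_equal(r$p_raw, fit$coefficients["g", "Pr(>|t|)"],
                 tolerance = 1e-10)
    expect_equal(abs(r$statistic), abs(fit$coefficients["g", "t value"]),
                 tolerance = 1e-10)
  }
  # Welch flag changes the statistic under unequal variances
  x <- rnorm(10, sd = 4); y <- rnorm(40, sd = 0.5)
  expect_false(isTRUE(all.equal(two_group_test(x, y)$p_raw,
                                two_group_test(x, y, welch = TRUE)$p_raw)))
})

test_that("rank-sum p agrees with full permutation enumeration", {
  set.seed(17)
  x <- round(rnorm(6, 1), 3); y <- round(rnorm(6), 3)
  stopifnot(!any(duplicated(c(x, y))))           # tie-free by construction
  r <- two_group_test(x, y, test = "wilcoxon")   # exact branch: n = 12 < 20
  v <- c(x, y)
  # enumerate all choose(12,6) = 924 assignments of the case labels
  obs <- sum(rank(v)[1:6])
  perms <- combn(12, 6, function(ix) sum(rank(v)[ix]))
  p_perm <- mean(abs(perms - mean(perms)) >= abs(obs - mean(perms)) - 1e-9)
  expect_lt(abs(r$p_raw - p_perm), 0.02)
  expect_equal(r$m, 1)
})

test_that("regression recovers an exact linear relation", {
  gs <- c(10, 12, 14, 16, 18, 20)
  # a whisper of noise keeps summary.lm quiet about a perfect fit
  out <- 4.0 + 0.030 * gs + c(1, -1, 1, -1, 1, -1) * 1e-11
  r <- glucose_on_gs_regression(out, gs)
  expect_equal(r$beta, 0.030, tolerance = 1e-9)
  expect_lt(r$ci_high - r$ci_low, 1e-9)
  expect_equal(r$n, 6)
  # sample-order invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  r2 <- glucose_on_gs_regression(out[perm], gs[perm])
  expect_equal(r2$beta, r$beta)
  expect_equal(r2$p_raw, r$p_raw)
  # complete cases only
  out_na <- out; out_na[2] <- NA
  expect_equal(glucose_on_gs_regression(out_na, gs)$n, 5)
})

test_that("regression rejects collinear adjustment sets by name", {
  set.seed(8)
  gs <- rnorm(30); out <- 4 + 0.03 * gs + rnorm(30, sd = 0.1)
  expect_error(
    glucose_on_gs_regression(out, gs,
                             adjust_for = list(a = gs * 2, b = rnorm(30))),
    "collinear")
  # independent covariate leaves the slope essentially unchanged
  cov <- rnorm(30)
  r0 <- glucose_on_gs_regression(out, gs)
  r1 <- glucose_on_gs_regression(out, gs, adjust_for = list(z = cov))
  expect_lt(abs(r0$beta - r1$beta), 0.05)
  expect_error(glucose_on_gs_regression(out[1:2], gs[1:2],
                                        adjust_for = list(z = cov[1:2])),
               "not enough complete cases")
})

test_that("ANCOVA reports the group effect and flags confounded designs", {
  set.seed(12)
  n <- 200
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  gs <- 15 + 1.5 * grp + rnorm(n, sd = 2)
  cov <- rnorm(n)
  a <- ancova_gs_by_group(gs, grp, covariates = list(bmi = cov))
  expect_s3_class(a, "grs_comparison")
  expect_lt(a$p_raw, 0.01)
  expect_equal(a$estimate, 1.5, tolerance = 0.7)
  # covariate that recodes the group exactly -> collinear error
  expect_error(ancova_gs_by_group(gs, grp,
                                  covariates = list(g = as.numeric(grp))),
               "collinear")
  expect_error(ancova_gs_by_group(gs, rep(TRUE, n)), "constant")
})

test_that("ANCOVA null rejection rate is close to nominal", {
  set.seed(40)
  reps <- 400
  hits <- 0L
  for (i in seq_len(reps)) {
    grp <- rep(c(TRUE, FALSE), each = 30)
    gs <- rnorm(60)
    if (ancova_gs_by_group(gs, grp)$p_raw < 0.05) hits <- hits + 1L
  }
  # 3 sigma band around 0.05 at 400 reps: +/- 0.033
  expect_lt(abs(hits / reps - 0.05), 0.035)
})

test_that("power from variance explained matches theory and simulation", {
  # r2 = 0 degenerates to the test size
  expect_equal(power_variance_explained(100, 0, 0.05), 0.05,
               tolerance = 1e-10)
  # monotone in n and in r2
  expect_gt(power_variance_explained(500, 0.02), power_variance_explained(100, 0.02))
  expect_gt(power_variance_explained(200, 0.06), power_variance_explained(200, 0.01))
  p_an <- power_variance_explained(849, 0.06, 0.002)
  # Monte Carlo check of the analytic value
  set.seed(3)
  reps <- 600
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(849)
    y <- sqrt(0.06) * x + sqrt(0.94) * rnorm(849)
    r <- cor(x, y)
    tstat <- r * sqrt(847 / (1 - r^2))
    if (2 * pt(-abs(tstat), 847) < 0.002) rej <- rej + 1L
  }
  mc <- rej / reps
  expect_lt(abs(mc - p_an), 3 * sqrt(p_an * (1 - p_an) / reps) + 0.01)
  # the design actually used: essentially certain detection
  expect_equal(round(power_variance_explained(2628, 0.06, 0.002), 2), 1)
})
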