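light_mcmc <- function(seed) mcmc_config(seed = seed, chains = 2,
                                         n_adapt = 300, n_burn = 500,
                                         n_iter = 1000)

test_that("the paired model recovers a planted effect with patient clustering", {
  d <- generate_hierarchical_dataset(20, 2, true_effect = 10, between_sd = 3,
                                     within_sd = 4, seed = 14)
  f <- fit_paired_mixed(d, mcmc = mcmc_config(seed = 3))
  expect_s3_class(f, "paired_bmm")
  expect_lt(abs(f$effect_mean - 10) / 10, 0.2)
  expect_true(f$cri_low <= 10 && f$cri_high >= 10)
  expect_gt(f$cri_low, 0)
  expect_true(f$converged)
  expect_lte(f$cri_low, f$effect_mean)
  expect_lte(f$effect_mean, f$cri_high)
  expect_named(coef(f)[1:2], c("intercept", "treatment_effect"))
})

test_that("identical outcomes give a near-zero effect with a tight interval", {
  d <- generate_hierarchical_dataset(6, 2, 0, 0, 0, alpha = 3, seed = 2)
  d$outcome <- 3
  f <- suppressWarnings(fit_paired_mixed(d, mcmc = light_mcmc(1)))
  expect_lt(abs(f$effect_mean), 0.01)
  expect_lt(f$cri_high - f$cri_low, 0.05)
})

test_that("degenerate designs are rejected", {
  d <- generate_hierarchical_dataset(5, 2, 1, 1, 1, seed = 3)
  expect_error(fit_paired_mixed(d[d$patient_id == "p01", ]), "2 patients")
  expect_error(fit_paired_mixed(rbind(d, d[1, ])), "at most one row")
  unpaired <- d
  unpaired <- unpaired[!(unpaired$period == "treatment"), ]
  unpaired$period[seq(1, 5)] <- "treatment"   # no unit retains both periods
  expect_error(fit_paired_mixed(unpaired[!duplicated(
    unpaired[, c("unit_id", "period")]), ]), "overlap")
})

test_that("the same seed reproduces the posterior summary exactly", {
  d <- generate_hierarchical_dataset(8, 2, 5, 2, 3, seed = 7)
  f1 <- fit_paired_mixed(d, mcmc = light_mcmc(11))
  f2 <- fit_paired_mixed(d, mcmc = light_mcmc(11))
  expect_identical(f1$effect_mean, f2$effect_mean)
  expect_identical(f1$cri_low, f2$cri_low)
  expect_identical(f1$icc_adjusted, f2$icc_adjusted)
})

test_that("credible intervals tighten as the number of patients grows", {
  d10 <- generate_hierarchical_dataset(10, 2, 5, 2, 4, seed = 19)
  d100 <- generate_hierarchical_dataset(100, 2, 5, 2, 4, seed = 19)
  f10 <- suppressWarnings(fit_paired_mixed(d10, mcmc = light_mcmc(4)))
  f100 <- suppressWarnings(fit_paired_mixed(d100, mcmc = light_mcmc(4)))
  expect_lt(f100$cri_high - f100$cri_low, f10$cri_high - f10$cri_low)
  expect_lt(abs(f100$effect_mean - 5), abs(f10$effect_mean - 5) + 0.5)
})

test_that("baseline adjustment terms enter the design as specified", {
  d <- generate_hierarchical_dataset(10, 2, 5, 2, 3, seed = 23)
  f_c <- suppressWarnings(fit_paired_mixed(d, adjust_baseline = "continuous",
                                           mcmc = light_mcmc(5)))
  expect_true("post_x_baseline_continuous" %in% f_c$fixed$term)
  d$baseline_covariate <- rep(rep(c(0, 2), 10), 2)
  f_b <- suppressWarnings(fit_paired_mixed(d, adjust_baseline = "binary",
                                           mcmc = light_mcmc(5)))
  expect_true("post_x_baseline_binary" %in% f_b$fixed$term)
  d$seizure_freq <- as.numeric(factor(d$patient_id)) * 2
  f_e <- suppressWarnings(fit_paired_mixed(d, extra_fixed = "seizure_freq",
                                           mcmc = light_mcmc(5)))
  expect_true("seizure_freq" %in% f_e$fixed$term)
  expect_error(fit_paired_mixed(d, extra_fixed = "nope"), "not found")
})

test_that("adjusted ICC tracks the planted variance ratio", {
  d0 <- generate_hierarchical_dataset(30, 2, 5, between_sd = 0,
                                      within_sd = 3, seed = 31)
  f0 <- suppressWarnings(fit_paired_mixed(d0, mcmc = light_mcmc(6)))
  expect_lt(compute_icc(f0), 0.12)
  d9 <- generate_hierarchical_dataset(30, 2, 5, between_sd = 3,
                                      within_sd = 1, seed = 31)
  f9 <- suppressWarnings(fit_paired_mixed(d9, mcmc = light_mcmc(6)))
  expect_gt(compute_icc(f9), 0.75)
})

test_that("rmcorr reproduces the ANCOVA arithmetic and its invariances", {
  # 44 observations over 11 subjects: df = 44 - 11 - 1 = 32
  set.seed(61)
  subj <- rep(1:11, each = 4)
  x <- rnorm(44)
  y <- 0.8 * x + rnorm(44, sd = 0.5) + subj
  r <- rmcorr(x, y, subj)
  expect_equal(r$df, 32)
  expect_equal(r$n_subjects, 11)
  # invariant to arbitrary per-subject offsets in y
  r2 <- rmcorr(x, y + 100 * subj, subj)
  expect_equal(r2$r, r$r, tolerance = 1e-12)
  # perfect within-subject relation: r = 1 with a degenerate interval
  yp <- 2 * x + 10 * subj
  rp <- rmcorr(x, yp, subj)
  expect_equal(rp$r, 1)
  expect_equal(c(rp$ci_low, rp$ci_high), c(1, 1))
  expect_error(rmcorr(rep(1, 44), y, subj), "constant")
  expect_error(rmcorr(x[1:4], y[1:4], rep(1, 4)), "subjects")
})

test_that("rmcorr confidence intervals follow the Fisher transform", {
  ci <- rmcorr_ci(0.82, 32)
  expect_equal(round(ci, 2), c(0.67, 0.91))
  expect_equal(rmcorr_ci(-0.82, 32), -rev(rmcorr_ci(0.82, 32)))
  expect_error(rmcorr_ci(0.5, 1), "df")
})

test_that("forest tables collect effects across outcomes", {
  d <- generate_hierarchical_dataset(8, 2, 5, 2, 3, seed = 71)
  f <- suppressWarnings(fit_paired_mixed(d, mcmc = light_mcmc(7)))
  ft <- forest_table(list(duration = f, count = f))
  expect_equal(ft$outcome, c("duration", "count"))
  expect_equal(ft$effect, rep(f$effect_mean, 2))
})
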