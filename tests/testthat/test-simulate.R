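test_that("LD panel has block AR(1) structure and honours its preconditions", {
  p0 <- simulate_ld_panel(1, 3, rho = 0, seed = 1)
  expect_equal(unname(p0$r), diag(3))

  p9 <- simulate_ld_panel(1, 3, rho = 0.9, seed = 1)
  expect_equal(p9$r[1, 3], 0.81)
  expect_true(isSymmetric(p9$r))
  expect_equal(unname(diag(p9$r)), rep(1, 3))

  p2 <- simulate_ld_panel(2, 2, rho = 0.5, seed = 1)
  # cross-block correlation zero and blocks > 500 kb apart
  expect_equal(p2$r[1, 3], 0)
  expect_gt(min(p2$snps$pos[3:4]) - max(p2$snps$pos[1:2]), 5e5)
  expect_true(all(p2$snps$maf > 0 & p2$snps$maf <= 0.5))
  expect_true(all(diff(p2$snps$pos) > 0))

  expect_error(simulate_ld_panel(0, 3), "integer")
  expect_error(simulate_ld_panel(1, 3, rho = 1), "range")
  expect_error(simulate_ld_panel(1, 3, maf_range = c(0, 0.6)), "interval")
})

test_that("same seed gives bit-identical generator output", {
  a <- simulate_ld_panel(2, 2, rho = 0.5, seed = 1)
  b <- simulate_ld_panel(2, 2, rho = 0.5, seed = 1)
  expect_identical(a, b)

  tr <- sim_truth(0.1, rep(0.1, 4), n_exp = 1e4, n_out = 1e4, seed = 3)
  expect_identical(simulate_gwas_pair(a, tr), simulate_gwas_pair(a, tr))

  expect_identical(simulate_cohort(50, seed = 5), simulate_cohort(50, seed = 5))
  # and a different seed changes the draw
  expect_false(identical(simulate_cohort(50, seed = 5), simulate_cohort(50, seed = 6)))
})

test_that("GWAS standard errors follow 1/sqrt(2 f (1-f) n)", {
  panel <- simulate_ld_panel(1, 1, rho = 0, maf_range = c(0.5, 0.5), seed = 1)
  tr <- sim_truth(0, 0.3, n_exp = 20000, n_out = 20000, seed = 1)
  pair <- simulate_gwas_pair(panel, tr)
  expect_equal(pair$exposure$se, 1 / sqrt(0.5 * 20000))

  # empirical SD of beta-hat over replicates matches the analytic SE within 10%
  betas <- vapply(1:1000, function(s) {
    t <- sim_truth(0, 0.3, n_exp = 20000, n_out = 20000, seed = s)
    simulate_gwas_pair(panel, t)$exposure$beta
  }, numeric(1))
  expect_lt(abs(sd(betas) / pair$exposure$se[1] - 1), 0.1)
})

test_that("null outcome effects vanish as the outcome sample grows", {
  panel <- simulate_ld_panel(5, 1, rho = 0, seed = 2)
  tr <- sim_truth(0, rep(0.2, 5), n_exp = 2e4, n_out = 1e10, seed = 2)
  pair <- simulate_gwas_pair(panel, tr)
  expect_true(all(abs(pair$outcome$beta) < 1e-3))
})

test_that("simulated pairs carry a recoverable causal effect", {
  h <- sim_independent_pair(k = 10, theta = 0.2, n_exp = 2e5, n_out = 2e5, seed = 7)
  fit <- mr_ivw(h)
  expect_lt(abs(fit$estimate - 0.2), 3 * fit$se)
})

test_that("allele corruption is representation-only and harmonization undoes it", {
  panel <- simulate_ld_panel(10, 1, rho = 0, seed = 4)
  tr <- sim_truth(0.2, rep(0.1, 10), n_exp = 5e4, n_out = 5e4, seed = 4)
  clean <- simulate_gwas_pair(panel, tr, swap_frac = 0, flip_frac = 0)
  messy <- simulate_gwas_pair(panel, tr, swap_frac = 0.5, flip_frac = 0.3)
  expect_false(identical(clean$outcome$beta, messy$outcome$beta))
  h_clean <- suppressMessages(harmonize(clean$exposure, clean$outcome))
  h_messy <- suppressMessages(harmonize(messy$exposure, messy$outcome))
  expect_equal(h_messy$beta_out, h_clean$beta_out)
})

test_that("cohort generator honours the structural model and the early fraction", {
  exact <- simulate_cohort(200, intercept = 50, beta_metab = 4, beta_bmi = 0,
                           noise_sd = 0, early_fraction = 0, seed = 3)
  fit <- lm(age_at_event ~ metabolite, data = exact)
  expect_equal(unname(coef(fit)), c(50, 4), tolerance = 1e-10)

  none_early <- simulate_cohort(500, early_fraction = 0, noise_sd = 0,
                                beta_metab = 1, beta_bmi = 0, seed = 8)
  expect_true(all(none_early$age_at_event >= 45))

  noisy <- simulate_cohort(1000, beta_metab = 4, beta_bmi = 0, noise_sd = 2,
                           early_fraction = 0, seed = 3)
  co <- summary(lm(age_at_event ~ metabolite + bmi, data = noisy))$coefficients
  expect_lt(abs(co["metabolite", "Estimate"] - 4),
            3 * co["metabolite", "Std. Error"])
})

test_that("study generator marks the causal metabolites and nulls correctly", {
  st <- simulate_study(n_metabolites = 6, n_causal = 2, seed = 11)
  expect_length(st$exposures, 6)
  expect_equal(sum(st$truth$theta != 0), 2)
  # each metabolite's significant SNPs live in its own blocks
  iv1 <- dplyr::filter(st$exposures[[1]], p <= 5e-8)
  expect_true(all(st$panel$snps$block[match(iv1$snp, st$panel$snps$snp)] %in% 1:3))
})
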