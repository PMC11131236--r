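test_that("Cochran's Q matches hand arithmetic and boundary cases", {
  # identical ratios: Q = 0, p = 1
  h <- make_harmonized(c(0.1, 0.2), c(0.05, 0.10), se_out = 0.02)
  q <- cochran_q(h)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
  expect_equal(q$df, 1L)

  # ratios 0 and 1 with unit ratio weights around estimate 0.5: Q = 0.5
  h2 <- make_harmonized(c(1, 1), c(0, 1), se_out = 1)
  expect_equal(cochran_q(h2)$q, 0.5)

  # Egger route needs three SNPs
  expect_match(cochran_q(h, "egger")$note, "not computable")
  h3 <- make_harmonized(c(0.1, 0.2, 0.3), 0.05 + 0.5 * c(0.1, 0.2, 0.3),
                        se_out = 0.02)
  qe <- cochran_q(h3, "egger")
  expect_equal(qe$q, 0, tolerance = 1e-16)
  expect_equal(qe$df, 1L)
})

test_that("Q null rejection is calibrated on homogeneous simulations", {
  # theta = 0 so the first-order ratio weights are exact; at theta != 0 the
  # neglected exposure-side variance makes Q anti-conservative by design
  rej <- vapply(1:400, function(s) {
    h <- sim_independent_pair(k = 20, theta = 0, seed = s + 5000)
    cochran_q(h)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("the pleiotropy outlier test flags an injected outlier", {
  h <- sim_independent_pair(k = 11, theta = 0.2, seed = 11)
  # inject a direct effect ~10x the causal path on SNP 11
  h$beta_out[11] <- h$beta_out[11] + 10 * 0.2 * h$beta_exp[11]
  pres <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_lt(pres$global_p, 0.05)
  expect_true(pres$outliers$flagged[11])
  expect_false(any(pres$outliers$flagged[1:10]))

  # removing the outlier moves the estimate toward the truth and reduces Q
  expect_lt(abs(pres$corrected$estimate - 0.2), abs(pres$raw$estimate - 0.2))
  expect_lt(mr_ivw(h[-11, ])$q, mr_ivw(h)$q)

  # minimum attainable global p is 1/(n_sim + 1)
  expect_gte(pres$global_p, 1 / 1001)
})

test_that("the outlier test is order-invariant at fixed seed and marks small sets", {
  h <- sim_independent_pair(k = 8, theta = 0.1, seed = 3)
  a <- mr_presso(h, n_sim = 400, seed = 9)
  b <- mr_presso(h[sample(8), ], n_sim = 400, seed = 9)
  expect_equal(a$global_p, b$global_p)

  nc <- mr_presso(h[1:3, ])
  expect_true(is.na(nc$global_p))
  expect_match(nc$note, "not computable")
})

test_that("Steiger directionality favours the exposure under the forward model", {
  h <- sim_independent_pair(k = 10, theta = 0.2, n_exp = 5e4, n_out = 5e4, seed = 2)
  st <- steiger_filter(h)
  expect_true(all(st$correct_direction))
  expect_true(attr(st, "verdict"))
  expect_true(all(st$r2_exp > st$r2_out))

  # equality boundary: flag false, p = 1
  hb <- make_harmonized(0.1, 0.1, se_exp = 0.01, se_out = 0.01)
  stb <- steiger_filter(hb)
  expect_false(stb$correct_direction)
  expect_equal(stb$p, 1)

  # definitional ordering via the variance-explained route
  hd <- make_harmonized(0.224, 0.0158, eaf = 0.5)  # r2 ~ 0.025 vs 1.2e-4
  std <- steiger_filter(hd)
  expect_true(std$correct_direction)

  # invariant to joint allele flips (beta signs flip, eaf complements)
  hf <- h
  hf$beta_exp <- -hf$beta_exp
  hf$beta_out <- -hf$beta_out
  hf$eaf <- 1 - hf$eaf
  expect_equal(steiger_filter(hf)$correct_direction, st$correct_direction)
  expect_equal(steiger_filter(hf)$p, st$p)
})

test_that("reverse MR finds no effect when causality runs metabolite -> outcome", {
  # strong forward effect; the outcome's own GWAS signal comes only through
  # the metabolite path, so reversing roles yields instruments whose effect
  # on the metabolite is fully mediated -- the reverse estimate reflects
  # theta's inverse path and must shrink toward 0 as theta is small
  st <- simulate_study(n_metabolites = 3, n_causal = 1, theta = 0.15,
                       n_out = 5e5, seed = 31)
  res <- suppressMessages(suppressWarnings(
    reverse_mr(st$outcome, st$exposures[[3]], st$panel, n_boot = 50)))
  # metabolite 3 is null: no reverse causal path at all
  ivw_row <- res[res$method == "ivw", ]
  expect_lt(abs(ivw_row$estimate), 3 * ivw_row$se)
  expect_setequal(res$method, c("ivw", "egger", "weighted_median", "weighted_mode"))

  # with fewer than 3 reverse instruments the extra estimators are marked
  st2 <- simulate_study(n_metabolites = 2, n_causal = 1, theta = 0.3,
                        blocks_per_metabolite = 2, seed = 32)
  res2 <- suppressMessages(suppressWarnings(
    reverse_mr(st2$outcome, st2$exposures[[2]], st2$panel, n_boot = 50)))
  k_rev <- res2$n_snp[res2$method == "ivw"]
  if (k_rev < 3) {
    expect_match(res2$note[res2$method == "egger"], "not computable")
  }
  expect_true(nrow(res2) >= 1)
})
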