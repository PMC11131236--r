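test_that("Wald ratio follows the first-order delta method", {
  r <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$estimate, 0)
  rn <- wald_ratio(-0.1, 0.01, 0.05, 0.02)
  expect_equal(rn$estimate, -0.5)
  expect_equal(rn$se, 0.2)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "Degenerate")
})

test_that("IVW matches the closed-form WLS oracle and its ratio-mean identity", {
  # two-SNP worked example: estimate = (0.02 + 0.04) / (0.04 + 0.16) = 0.3
  h <- make_harmonized(c(0.2, 0.4), c(0.1, 0.1), se_out = 0.1)
  expect_equal(mr_ivw(h)$estimate, 0.3)

  # identical ratios: Q = 0 and the random-effects SE equals the fixed SE
  h2 <- make_harmonized(c(0.1, 0.2), c(0.05, 0.10), se_out = 0.02)
  f_fixed <- mr_ivw(h2, "fixed")
  f_rand <- mr_ivw(h2, "multiplicative_random")
  expect_equal(f_rand$estimate, 0.5)
  expect_equal(f_rand$q, 0, tolerance = 1e-24)
  expect_equal(f_rand$se, f_fixed$se)

  # single SNP falls back to the Wald ratio exactly
  h1 <- make_harmonized(0.1, 0.05, se_out = 0.02)
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  i1 <- mr_ivw(h1)
  expect_equal(i1$estimate, w$estimate)
  expect_equal(i1$se, w$se)
  expect_equal(i1$n_snp, 1L)
})

test_that("IVW equals the weighted mean of Wald ratios to 1e-12 on random sets", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(2:15, 1)
    h <- make_harmonized(runif(k, 0.05, 0.5) * sample(c(-1, 1), k, TRUE),
                         rnorm(k, 0, 0.1), se_out = runif(k, 0.005, 0.05))
    expect_equal(mr_ivw(h)$estimate,
                 oracle_ivw(h$beta_exp, h$beta_out, h$se_out),
                 tolerance = 1e-12)
  }
})

test_that("estimators are invariant to joint sign flips of (bx, by)", {
  set.seed(7)
  h <- make_harmonized(runif(8, 0.05, 0.3), rnorm(8, 0.05, 0.02),
                       se_exp = 0.01, se_out = 0.02)
  flip <- h
  s <- rep(c(1, -1), 4)
  flip$beta_exp <- s * flip$beta_exp
  flip$beta_out <- s * flip$beta_out
  expect_equal(mr_ivw(flip)$estimate, mr_ivw(h)$estimate)
  expect_equal(mr_egger(flip)$estimate, mr_egger(h)$estimate)
  expect_equal(mr_egger(flip)$intercept, mr_egger(h)$intercept)
  expect_equal(mr_weighted_median(flip, n_boot = 50)$estimate,
               mr_weighted_median(h, n_boot = 50)$estimate)
  expect_equal(mr_weighted_mode(flip, n_boot = 50)$estimate,
               mr_weighted_mode(h, n_boot = 50)$estimate)
})

test_that("Egger recovers exact linear structure and marks small sets", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_harmonized(bx, 0.1 + 0.5 * bx, se_out = 0.02)
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e$q, 0, tolerance = 1e-18)

  h0 <- make_harmonized(bx, 0.5 * bx, se_out = 0.02)
  e0 <- suppressWarnings(mr_egger(h0))
  expect_equal(e0$intercept, 0, tolerance = 1e-10)
  expect_equal(e0$estimate, 0.5, tolerance = 1e-10)

  small <- mr_egger(make_harmonized(c(0.1, 0.2), c(0.05, 0.1)))
  expect_true(is.na(small$estimate))
  expect_match(small$note, "not computable")
})

test_that("Egger intercept stays null without pleiotropy on seeded batches", {
  hits <- vapply(1:200, function(s) {
    h <- sim_independent_pair(k = 20, theta = 0.2, seed = s)
    mr_egger(h)$intercept_p < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.90)
})

test_that("weighted median interpolates the cumulative-weight crossing", {
  # equal weights, odd count: plain median
  h <- make_harmonized(rep(0.1, 3), 0.1 * c(1, 2, 3), se_out = 0.01)
  expect_equal(mr_weighted_median(h, n_boot = 50)$estimate, 2)

  # outlier-robust
  h2 <- make_harmonized(rep(0.1, 3), 0.1 * c(1, 2, 100), se_out = 0.01)
  expect_equal(mr_weighted_median(h2, n_boot = 50)$estimate, 2)

  # hand-evaluated interpolation with unequal weights: bx = {sqrt(2), 1, 1}
  # at equal outcome SEs gives normalized weights {0.5, 0.25, 0.25} on
  # ratios {1, 2, 2}
  h4 <- make_harmonized(c(sqrt(2), 1, 1), c(sqrt(2), 2, 2), se_out = 1)
  # weights {0.5, 0.25, 0.25}; ratios {1, 2, 2}; cw = {0.25, 0.625, 0.875}
  # crossing between ratio 1 and 2: 1 + (0.5-0.25)/(0.625-0.25) = 1.667
  expect_equal(mr_weighted_median(h4, n_boot = 50)$estimate, 1 + 0.25 / 0.375,
               tolerance = 1e-10)
})

test_that("weighted mode finds the dominant ratio cluster", {
  h <- make_harmonized(rep(0.1, 5), rep(0.1 * 0.4, 5))
  expect_equal(mr_weighted_mode(h, n_boot = 50)$estimate, 0.4)

  h2 <- make_harmonized(rep(0.1, 4), 0.1 * c(0.4, 0.4, 0.4, 5), se_out = 0.01)
  expect_equal(mr_weighted_mode(h2, bandwidth_factor = 0.5, n_boot = 50)$estimate,
               0.4, tolerance = 0.02)

  # bimodal with the heavier-weighted cluster at 0.2: grid-density oracle
  bx <- c(0.4, 0.4, 0.4, 0.1, 0.1)
  by <- bx * c(0.2, 0.2, 0.2, 0.9, 0.9)
  h3 <- make_harmonized(bx, by, se_out = 0.02)
  ratios <- by / bx
  w <- bx^2 / 0.02^2; w <- w / sum(w)
  bw_cand <- c(sd(ratios), mad(ratios))
  hbw <- 0.9 * min(bw_cand[bw_cand > 0]) * 5^(-1 / 5)
  grid <- seq(min(ratios) - 3 * hbw, max(ratios) + 3 * hbw, length.out = 512)
  dens <- vapply(grid, function(x) sum(w * dnorm(x - ratios, sd = hbw)), numeric(1))
  expect_equal(mr_weighted_mode(h3, n_boot = 50)$estimate, grid[which.max(dens)])
  expect_lt(abs(mr_weighted_mode(h3, n_boot = 50)$estimate - 0.2), 0.05)
})

test_that("multivariable IVW solves exact systems and reduces to univariable", {
  bx_m <- c(0.2, 0.3, 0.1, 0.4)
  bx_b <- c(0.1, -0.2, 0.3, 0.05)
  d <- tibble::tibble(beta_metabolite = bx_m, beta_bmi = bx_b,
                      beta_out = 0.3 * bx_m + 0.1 * bx_b, se_out = 0.02)
  fit <- mr_mvmr(d, c("beta_metabolite", "beta_bmi"))
  expect_equal(fit$estimate, c(0.3, 0.1), tolerance = 1e-10)

  # BMI column all zero collapses to the univariable IVW on the same SNPs
  d0 <- d
  d0$beta_bmi <- 0
  d0$beta_out <- 0.3 * bx_m + rnorm(4, 0, 0.001)
  fit0 <- mr_mvmr(d0[c("beta_metabolite", "beta_out", "se_out")],
                  "beta_metabolite")
  uni <- mr_ivw(tibble::tibble(beta_exp = bx_m, se_exp = 0.01,
                               beta_out = d0$beta_out, se_out = 0.02))
  expect_equal(fit0$estimate, uni$estimate, tolerance = 1e-10)

  # too few instruments -> not-computable marker rows
  nc <- mr_mvmr(d[1:2, ], c("beta_metabolite", "beta_bmi"))
  expect_true(all(is.na(nc$estimate)))
  expect_match(nc$note[1], "not computable")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.05, 6)), rep(0.05, 6))
  # step-up with monotonicity on a mixed vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  m <- length(p)
  manual <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(fdr_adjust(p), manual)
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
})
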