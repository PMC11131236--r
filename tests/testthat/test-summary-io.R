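test_that("reading a TSV validates records and drops invariant violations", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- make_stats(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, -0.1), se = 0.02)
  readr::write_tsv(d, tmp)
  got <- read_summary_stats(tmp)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_dropped"), 0)
  # read twice -> identical records
  expect_equal(got, read_summary_stats(tmp), ignore_attr = TRUE)

  d$se[2] <- 0
  readr::write_tsv(d, tmp)
  expect_message(got <- read_summary_stats(tmp), "Dropped 1")
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "n_dropped"), 1)

  # inconsistent p is rejected too
  d <- make_stats("rs1", beta = 5, se = 0.02)
  d$p <- 0.5
  readr::write_tsv(d, tmp)
  expect_message(got <- read_summary_stats(tmp), "Dropped 1")
  expect_equal(nrow(got), 0)
})

test_that("dialect mapping renames arbitrary column headers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  d <- make_stats(c("rs1", "rs2"), beta = c(0.1, 0.2), se = 0.02)
  names(d) <- c("rsid", "chrom", "bp", "A1", "A2", "freq", "b", "stderr",
                "pval", "samples", "trait")
  readr::write_tsv(d, tmp)
  dia <- list(snp = "rsid", chr = "chrom", pos = "bp", ea = "A1", oa = "A2",
              eaf = "freq", beta = "b", se = "stderr", p = "pval", n = "samples")
  got <- read_summary_stats(tmp, dialect = dia, trait = "met_x")
  expect_equal(got$snp, c("rs1", "rs2"))
  expect_equal(got$trait, c("met_x", "met_x"))

  # a YAML dialect file works identically
  ytmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(dia, ytmp)
  expect_equal(read_summary_stats(tmp, dialect = ytmp)$beta, c(0.1, 0.2))

  expect_error(read_summary_stats(tmp, dialect = dia[-1]), "missing key")
  dia$snp <- "nope"
  expect_error(read_summary_stats(tmp, dialect = dia), "lacks mapped column")
})

test_that("missing and empty files raise format errors", {
  expect_error(read_summary_stats("does-not-exist.tsv"), "not found")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(make_stats("rs1", 0.1, 0.02)[0, ], tmp)
  expect_error(read_summary_stats(tmp), "Empty")
})

test_that("harmonize aligns swapped, strand-flipped and palindromic records", {
  expo <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "G")
  # swapped alleles: sign flips, frequency complements
  outc <- make_stats("rs1", beta = -0.05, se = 0.01, ea = "G", oa = "A", eaf = 0.7)
  h <- harmonize(expo, outc)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$effect_allele, "A")

  # strand flip, same orientation: T/C complements to A/G -> kept as is
  outc2 <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "T", oa = "C")
  expect_equal(harmonize(expo, outc2)$beta_out, 0.05)

  # palindromic with ambiguous frequency in both studies: dropped
  expo_p <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T", eaf = 0.5)
  outc_p <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T", eaf = 0.5)
  expect_error(suppressMessages(harmonize(expo_p, outc_p)), "No overlapping")

  # palindromic but clearly oriented by frequency on opposite sides of 0.5
  expo_p2 <- make_stats("rs1", beta = 0.1, se = 0.01, ea = "A", oa = "T", eaf = 0.1)
  outc_p2 <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "T", eaf = 0.9)
  h2 <- suppressMessages(harmonize(expo_p2, outc_p2))
  expect_equal(h2$beta_out, -0.05)

  # allele mismatch (not explicable by swap or strand) is dropped
  outc3 <- make_stats("rs1", beta = 0.05, se = 0.01, ea = "A", oa = "C")
  expect_error(suppressMessages(harmonize(expo, outc3)), "No overlapping")
})

test_that("harmonize is idempotent and invariant to outcome allele flips", {
  panel <- simulate_ld_panel(6, 1, rho = 0, seed = 9)
  tr <- sim_truth(0.2, rep(0.1, 6), n_exp = 5e4, n_out = 5e4, seed = 9)
  pair <- simulate_gwas_pair(panel, tr, swap_frac = 0.3, flip_frac = 0.2)
  h1 <- suppressMessages(harmonize(pair$exposure, pair$outcome))

  # idempotence: re-harmonizing the aligned pair changes nothing
  aligned_out <- dplyr::transmute(
    h1, snp, chr, pos, effect_allele, other_allele, eaf,
    beta = beta_out, se = se_out, p = p_out, n = n_out)
  h2 <- harmonize(pair$exposure, aligned_out)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$effect_allele, h1$effect_allele)

  # flipping every outcome record jointly yields an identical harmonized set
  flipped <- pair$outcome
  tmpa <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmpa
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h3 <- suppressMessages(harmonize(pair$exposure, flipped))
  expect_equal(h3, h1)
})

test_that("proxy search picks maximal r2 with distance then id tie-breaks", {
  panel <- simulate_ld_panel(1, 4, rho = 0.9, seed = 1)
  ids <- panel$snps$snp
  # outcome lacks the query SNP (first in the block) but has its neighbours
  outc <- make_stats(ids[2:4], beta = c(0.05, 0.04, 0.03), se = 0.01,
                     ea = panel$snps$effect_allele[2:4],
                     oa = panel$snps$other_allele[2:4])
  outc$pos <- panel$snps$pos[2:4]
  hit <- find_proxy(ids[1], outc, panel, r2_min = 0.8)
  expect_equal(hit$proxy_snp, ids[2])  # r = 0.9 is the strongest neighbour
  expect_equal(hit$beta, 0.05)         # positive r: orientation unchanged
  expect_equal(hit$snp, ids[1])

  # threshold excludes everything
  expect_null(find_proxy(ids[1], outc, panel, r2_min = 0.99))

  # equal r2 at different distances: nearer candidate wins
  panel2 <- simulate_ld_panel(1, 3, rho = 0.9, seed = 2)
  panel2$r[1, 3] <- panel2$r[3, 1] <- 0.9  # tie with SNP 2
  ids2 <- panel2$snps$snp
  outc2 <- make_stats(ids2[2:3], beta = c(0.1, 0.2), se = 0.01,
                      ea = panel2$snps$effect_allele[2:3],
                      oa = panel2$snps$other_allele[2:3])
  outc2$pos <- panel2$snps$pos[2:3]
  expect_equal(find_proxy(ids2[1], outc2, panel2)$proxy_snp, ids2[2])

  # r2_min = 1 returns only perfect proxies
  expect_null(find_proxy(ids2[1], outc2, panel2, r2_min = 1))
  panel2$r[1, 2] <- panel2$r[2, 1] <- 1
  expect_equal(find_proxy(ids2[1], outc2, panel2, r2_min = 1)$proxy_snp, ids2[2])
})

test_that("harmonize_with_proxies substitutes missing outcome instruments", {
  panel <- simulate_ld_panel(2, 3, rho = 0.95, seed = 3)
  tr <- sim_truth(0.2, rep(0.1, 6), n_exp = 5e4, n_out = 5e4, seed = 3)
  pair <- simulate_gwas_pair(panel, tr, swap_frac = 0, flip_frac = 0)
  expo <- pair$exposure[c(1, 4), ]           # one instrument per block
  outc <- pair$outcome[-c(1, 4), ]           # both missing from the outcome
  h <- suppressMessages(harmonize_with_proxies(expo, outc, panel))
  expect_equal(nrow(h), 2)
  expect_true(all(h$proxy))
  expect_true(all(h$proxy_snp %in% outc$snp))
  # exposure effects carried over unchanged
  expect_equal(h$beta_exp, expo$beta)
})
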