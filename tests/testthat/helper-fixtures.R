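# Shared fixtures and independent oracles used across the suite.

# Minimal harmonized table from raw effect vectors.
make_harmonized <- function(bx, by, se_exp = 0.01, se_out = 0.02,
                            eaf = 0.3, n_exp = 20000, n_out = 100000) {
  k <- length(bx)
  tibble::tibble(
    snp = sprintf("rs%06d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    eaf = rep_len(eaf, k),
    beta_exp = bx, se_exp = rep_len(se_exp, k), p_exp = NA_real_,
    n_exp = rep_len(n_exp, k),
    beta_out = by, se_out = rep_len(se_out, k), p_out = NA_real_,
    n_out = rep_len(n_out, k),
    proxy = FALSE, proxy_snp = NA_character_
  )
}

# Hand-constructed summary-stat tibble.
make_stats <- function(snp, beta, se, eaf = 0.3, ea = "A", oa = "G",
                       chr = 1L, pos = NULL, n = 20000, trait = "trait") {
  k <- length(snp)
  pos <- pos %||% (seq_len(k) * 5000L)
  tibble::tibble(
    snp = snp, chr = rep_len(chr, k), pos = pos,
    effect_allele = rep_len(ea, k), other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    p = 2 * pnorm(-abs(beta / rep_len(se, k))), n = rep_len(n, k),
    trait = trait
  )
}

# Closed-form oracle: IVW as the inverse-variance-weighted mean of per-SNP
# Wald ratios with weights bx^2 / by_se^2 (independent of the WLS route).
oracle_ivw <- function(bx, by, se_out) {
  ratios <- by / bx
  w <- bx^2 / se_out^2
  sum(w * ratios) / sum(w)
}

# Brute-force hypergeometric upper tail: enumerate all C(N, n) selections
# from a universe with K marked elements; P(overlap >= k).
oracle_hyper_tail <- function(N, K, n, k) {
  sels <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(sels, 2, function(s) sum(s %in% marked) >= k)
  mean(hits)
}

# Simulate one independent-instrument study and return the harmonized table
# (used by recovery/calibration tests). True per-SNP effects vary across
# instruments, as in real metabolite GWAS; Egger is unidentified when all
# true effects coincide.
sim_independent_pair <- function(k = 10, theta = 0.2, alpha = 0,
                                 n_exp = 50000, n_out = 100000,
                                 effect_range = c(0.05, 0.25), seed = 1) {
  panel <- simulate_ld_panel(k, 1, rho = 0, seed = seed)
  b <- withr::with_seed(seed + 10^6, runif(k, effect_range[1], effect_range[2]))
  truth <- sim_truth(theta, b, pleiotropy = alpha,
                     n_exp = n_exp, n_out = n_out, seed = seed)
  pair <- simulate_gwas_pair(panel, truth, swap_frac = 0, flip_frac = 0)
  suppressMessages(harmonize(pair$exposure, pair$outcome))
}
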