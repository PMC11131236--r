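#' Ground truth for a simulated exposure/outcome GWAS pair
#'
#' Bundles the structural parameters of the linear causal model the simulator
#' draws from: a metabolite with per-SNP effects `snp_effects` (SD of
#' metabolite per effect allele), a causal effect `theta` of the metabolite on
#' the outcome (years per SD), and optional per-SNP direct (pleiotropic)
#' effects on the outcome (years per allele) that bypass the metabolite.
#'
#' @param theta Causal effect of the metabolite on the outcome (years per SD).
#' @param snp_effects Numeric vector of true per-SNP effects on the metabolite.
#' @param pleiotropy Per-SNP direct effects on the outcome; recycled to the
#'   length of `snp_effects` (default 0, i.e. no exclusion-restriction
#'   violation).
#' @param n_exp,n_out GWAS sample sizes for the exposure and outcome studies.
#' @param seed Integer seed; together with the panel it fully determines the
#'   simulated summary statistics.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(theta, snp_effects, pleiotropy = 0, n_exp, n_out, seed = 1L) {
  theta <- check_number(theta, "theta")
  n_exp <- check_count(n_exp, "n_exp")
  n_out <- check_count(n_out, "n_out")
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.numeric(snp_effects) || length(snp_effects) < 1L) {
    abort("`snp_effects` must be a non-empty numeric vector.")
  }
  if (length(pleiotropy) == 1L) pleiotropy <- rep(pleiotropy, length(snp_effects))
  if (length(pleiotropy) != length(snp_effects)) {
    abort("`pleiotropy` must have length 1 or length(snp_effects).")
  }
  structure(
    list(theta = theta, snp_effects = as.numeric(snp_effects),
         pleiotropy = as.numeric(pleiotropy),
         n_exp = n_exp, n_out = n_out, seed = seed),
    class = "sim_truth"
  )
}

#' Simulate a block-structured LD reference panel
#'
#' Generates a stand-in for an external LD reference (such as a 1000
#' Genomes-derived panel): SNP metadata (position, alleles, minor allele
#' frequency) plus a pairwise correlation matrix. LD follows a block-diagonal
#' AR(1) structure: within a block, `r` between SNPs `i` and `j` is
#' `rho^|i - j|`; across blocks it is exactly zero, and blocks are placed more
#' than 500 kb apart so distance-windowed operations (clumping, region
#' extraction) treat them as independent loci.
#'
#' @param n_blocks Number of independent LD blocks.
#' @param block_size SNPs per block.
#' @param rho Within-block AR(1) correlation, `0 <= rho < 1`.
#' @param maf_range Interval within (0, 0.5] from which minor allele
#'   frequencies are drawn uniformly.
#' @param seed Integer seed.
#' @param chromosome Chromosome label assigned to all SNPs.
#' @param snp_spacing_bp Base-pair spacing between adjacent SNPs in a block.
#' @param block_gap_bp Gap between the last SNP of one block and the first of
#'   the next; must exceed 500 kb so blocks are unambiguous loci.
#' @param palindromic_frac Fraction of SNPs assigned strand-ambiguous (A/T or
#'   C/G) allele pairs, to exercise harmonization.
#' @return An `ld_panel`: a list with `snps` (tibble of SNP metadata) and `r`
#'   (named correlation matrix).
#' @examples
#' panel <- simulate_ld_panel(2, 3, rho = 0.5, seed = 1)
#' panel$r
#' @export
simulate_ld_panel <- function(n_blocks, block_size, rho = 0,
                              maf_range = c(0.05, 0.5), seed = 1L,
                              chromosome = 1L, snp_spacing_bp = 5000,
                              block_gap_bp = 1e6, palindromic_frac = 0) {
  n_blocks <- check_count(n_blocks, "n_blocks")
  block_size <- check_count(block_size, "block_size")
  rho <- check_number(rho, "rho", lower = 0, upper = 1, inclusive_upper = FALSE)
  check_number(palindromic_frac, "palindromic_frac", lower = 0, upper = 1)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an interval within (0, 0.5].")
  }
  if (block_gap_bp <= 5e5) abort("`block_gap_bp` must exceed 500 kb.")
  seed <- check_count(seed, "seed", min = 0L)

  m <- n_blocks * block_size
  block <- rep(seq_len(n_blocks), each = block_size)
  within <- sequence(rep(block_size, n_blocks))
  pos <- (block - 1L) * (block_gap_bp + block_size * snp_spacing_bp) +
    within * snp_spacing_bp

  withr::with_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    # non-palindromic allele pairs by default; a configurable fraction is
    # strand-ambiguous to exercise the frequency-based harmonization rule
    pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    idx <- sample.int(length(pairs), m, replace = TRUE)
    ea <- vapply(pairs[idx], `[`, "", 1L)
    oa <- vapply(pairs[idx], `[`, "", 2L)
    if (palindromic_frac > 0) {
      is_pal <- runif(m) < palindromic_frac
      pidx <- sample.int(length(pal_pairs), sum(is_pal), replace = TRUE)
      ea[is_pal] <- vapply(pal_pairs[pidx], `[`, "", 1L)
      oa[is_pal] <- vapply(pal_pairs[pidx], `[`, "", 2L)
    }
  })

  ids <- sprintf("rs%06d", seq_len(m))
  r <- matrix(0, m, m, dimnames = list(ids, ids))
  for (b in seq_len(n_blocks)) {
    sel <- which(block == b)
    d <- abs(outer(seq_along(sel), seq_along(sel), "-"))
    r[sel, sel] <- rho^d
  }

  snps <- tibble::tibble(
    snp = ids, chr = as.integer(chromosome), pos = as.integer(pos),
    effect_allele = ea, other_allele = oa, maf = maf, block = block
  )
  structure(list(snps = snps, r = r), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d SNPs in %d block(s)\n",
              nrow(x$snps), length(unique(x$snps$block))))
  print(x$snps, n = 5)
  invisible(x)
}

# Per-SNP GWAS standard error for a standardized trait:
# se = 1 / sqrt(2 f (1 - f) n).
gwas_se <- function(maf, n) {
  1 / sqrt(2 * maf * (1 - maf) * n)
}

#' Simulate an exposure/outcome GWAS summary-statistics pair
#'
#' Draws per-SNP association estimates for a metabolite (exposure) and a
#' downstream outcome directly on the summary-statistic scale, under the
#' linear structural model encoded in a [sim_truth()]: the marginal exposure
#' mean is `R b` (LD-smeared true effects), the marginal outcome mean is
#' `R (theta * b + alpha)`, and sampling noise is multivariate normal with
#' correlation `R` and per-SNP standard deviations `1/sqrt(2 f (1-f) n)`
#' (standardized-trait GWAS standard errors). For an LD-free panel this
#' reduces to independent `beta_hat_j ~ N(b_j, se_j^2)` draws. P-values come
#' from the two-sided normal test. A configurable fraction of outcome records
#' is emitted with swapped or strand-flipped allele labels (a pure
#' representation change) to exercise harmonization.
#'
#' @param panel An [`ld_panel`][simulate_ld_panel].
#' @param truth A [sim_truth()] whose `snp_effects` length matches the panel.
#' @param swap_frac Fraction of outcome records emitted with effect/other
#'   alleles swapped (beta negated, frequency complemented).
#' @param flip_frac Fraction of outcome records emitted on the opposite strand
#'   (both alleles complemented).
#' @param exposure_label,outcome_label Trait labels.
#' @return A list with tibbles `exposure` and `outcome`, each one GWAS record
#'   per panel SNP (columns snp, chr, pos, effect_allele, other_allele, eaf,
#'   beta, se, p, n, trait).
#' @export
simulate_gwas_pair <- function(panel, truth, swap_frac = 0.1, flip_frac = 0.05,
                               exposure_label = "metabolite",
                               outcome_label = "outcome") {
  stopifnot(inherits(panel, "ld_panel"), inherits(truth, "sim_truth"))
  m <- nrow(panel$snps)
  if (length(truth$snp_effects) != m) {
    abort("length(truth$snp_effects) must equal the number of panel SNPs.")
  }
  check_number(swap_frac, "swap_frac", lower = 0, upper = 1)
  check_number(flip_frac, "flip_frac", lower = 0, upper = 1)

  f <- panel$snps$maf
  se_exp <- gwas_se(f, truth$n_exp)
  se_out <- gwas_se(f, truth$n_out)
  R <- panel$r
  mean_exp <- drop(R %*% truth$snp_effects)
  mean_out <- drop(R %*% (truth$theta * truth$snp_effects + truth$pleiotropy))
  L <- chol(R)  # R is block AR(1) with rho < 1, hence positive definite

  withr::with_seed(truth$seed, {
    z_exp <- drop(crossprod(L, rnorm(m)))
    z_out <- drop(crossprod(L, rnorm(m)))
    beta_exp <- mean_exp + se_exp * z_exp
    beta_out <- mean_out + se_out * z_out
    corrupt <- runif(m)
  })

  base <- panel$snps[c("snp", "chr", "pos", "effect_allele", "other_allele")]
  exposure <- tibble::tibble(
    base, eaf = f, beta = beta_exp, se = se_exp,
    p = two_sided_p(beta_exp / se_exp), n = truth$n_exp, trait = exposure_label
  )
  outcome <- tibble::tibble(
    base, eaf = f, beta = beta_out, se = se_out,
    p = two_sided_p(beta_out / se_out), n = truth$n_out, trait = outcome_label
  )

  # representation-only corruption of the outcome records
  swap <- corrupt < swap_frac
  flip <- corrupt >= swap_frac & corrupt < swap_frac + flip_frac
  if (any(swap)) {
    ea <- outcome$effect_allele[swap]
    outcome$effect_allele[swap] <- outcome$other_allele[swap]
    outcome$other_allele[swap] <- ea
    outcome$beta[swap] <- -outcome$beta[swap]
    outcome$eaf[swap] <- 1 - outcome$eaf[swap]
  }
  if (any(flip)) {
    outcome$effect_allele[flip] <- complement_allele(outcome$effect_allele[flip])
    outcome$other_allele[flip] <- complement_allele(outcome$other_allele[flip])
  }

  list(exposure = exposure, outcome = outcome)
}

#' Simulate an individual-level validation cohort
#'
#' Generates a birth-cohort-style table for observational validation: a
#' standardized metabolite level, a BMI z-score, and an age at event (e.g. age
#' at menopause) generated as
#' `age = intercept + beta_metab * metab + beta_bmi * bmi + noise`.
#' A fraction of subjects is drawn with an event age below 45 years to
#' exercise the early-event exclusion rule, and childhood BMI z-score columns
#' at ages 7/8/9/11 carry missingness to exercise adjacent-age imputation.
#'
#' @param n Number of subjects.
#' @param intercept Mean event age (years) at covariate zero.
#' @param beta_metab Effect of the metabolite on event age (years per unit).
#' @param beta_bmi Effect of BMI on event age (years per z).
#' @param noise_sd Residual SD (years).
#' @param early_fraction Fraction of subjects redrawn with event age < 45.
#' @param missing_frac Missingness rate applied independently to the childhood
#'   BMI z-score columns.
#' @param seed Integer seed.
#' @return A tibble with columns `metabolite`, `bmi`, `age_at_event`, `event`,
#'   and `bmi_z_age7/8/9/11`.
#' @export
simulate_cohort <- function(n, intercept = 50, beta_metab = 0.5, beta_bmi = -0.5,
                            noise_sd = 4, early_fraction = 0.1,
                            missing_frac = 0.2, seed = 1L) {
  n <- check_count(n, "n")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(early_fraction, "early_fraction", lower = 0, upper = 1)
  check_number(missing_frac, "missing_frac", lower = 0, upper = 1)
  seed <- check_count(seed, "seed", min = 0L)

  withr::with_seed(seed, {
    metab <- rnorm(n)
    bmi <- rnorm(n)
    age <- intercept + beta_metab * metab + beta_bmi * bmi +
      if (noise_sd > 0) rnorm(n, sd = noise_sd) else 0
    early <- runif(n) < early_fraction
    age[early] <- runif(sum(early), 40, 44.99)
    # childhood BMI z trajectories tracking adult BMI with occasional dropout
    bmi_z <- vapply(c(7, 8, 9, 11), function(a) 0.6 * bmi + rnorm(n, sd = 0.8),
                    numeric(n))
    miss <- matrix(runif(n * 4) < missing_frac, n, 4)
    bmi_z[miss] <- NA_real_
  })

  tibble::tibble(
    metabolite = metab, bmi = bmi, age_at_event = age, event = TRUE,
    bmi_z_age7 = bmi_z[, 1], bmi_z_age8 = bmi_z[, 2],
    bmi_z_age9 = bmi_z[, 3], bmi_z_age11 = bmi_z[, 4]
  )
}

#' Simulate a full metabolome-wide MR study
#'
#' Builds the complete input bundle [run_pipeline()] consumes: an LD panel,
#' one exposure GWAS per metabolite (each metabolite's instruments live in its
#' own LD blocks, one causal SNP per block), a single outcome GWAS whose
#' per-SNP effects aggregate every metabolite's contribution, a metabolite-set
#' annotation table in which one set collects the causal metabolites, and a
#' validation cohort. A known subset of metabolites carries a true causal
#' effect `theta` on the outcome; the rest are null.
#'
#' @param n_metabolites Number of metabolite exposures.
#' @param n_causal Number of metabolites with a true causal effect.
#' @param theta True causal effect (years per SD) for causal metabolites.
#' @param blocks_per_metabolite LD blocks (hence clumped instruments) per
#'   metabolite.
#' @param block_size SNPs per block.
#' @param rho Within-block LD.
#' @param snp_effect True per-SNP effect of each causal variant on its
#'   metabolite (SD per allele).
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param pleiotropy Optional per-metabolite direct effect added to each of
#'   its causal SNPs' outcome effects (years per allele); scalar, recycled.
#' @param seed Integer seed.
#' @return A list with `panel`, `exposures` (named list of summary-stat
#'   tibbles), `outcome`, `truth` (tibble of per-metabolite ground truth),
#'   `set_db`, `cohort`.
#' @export
simulate_study <- function(n_metabolites = 50, n_causal = 5, theta = 0.2,
                           blocks_per_metabolite = 3, block_size = 3,
                           rho = 0.5, snp_effect = 0.15,
                           n_exp = 50000, n_out = 100000,
                           pleiotropy = 0, seed = 1L) {
  n_metabolites <- check_count(n_metabolites, "n_metabolites")
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_metabolites) abort("`n_causal` cannot exceed `n_metabolites`.")
  seed <- check_count(seed, "seed", min = 0L)

  n_blocks <- n_metabolites * blocks_per_metabolite
  panel <- simulate_ld_panel(n_blocks, block_size, rho = rho, seed = seed)
  m <- nrow(panel$snps)
  met_of_block <- rep(seq_len(n_metabolites), each = blocks_per_metabolite)
  met_of_snp <- met_of_block[panel$snps$block]
  causal_snp <- panel$snps$block != dplyr::lag(panel$snps$block, default = 0L)
  labels <- sprintf("met_%03d", seq_len(n_metabolites))

  thetas <- rep(0, n_metabolites)
  thetas[seq_len(n_causal)] <- theta
  alpha_m <- rep(pleiotropy, length.out = n_metabolites)

  # one outcome GWAS aggregating all metabolites' causal paths
  b_total <- ifelse(causal_snp, snp_effect, 0)
  outcome_direct <- b_total * thetas[met_of_snp] +
    ifelse(causal_snp, alpha_m[met_of_snp], 0)
  f <- panel$snps$maf
  se_exp <- gwas_se(f, n_exp)
  se_out <- gwas_se(f, n_out)
  R <- panel$r
  L <- chol(R)
  mean_out <- drop(R %*% outcome_direct)

  withr::with_seed(seed, {
    beta_out <- mean_out + se_out * drop(crossprod(L, rnorm(m)))
    z_exp <- matrix(rnorm(m * n_metabolites), m, n_metabolites)
  })
  z_exp <- crossprod(L, z_exp)

  base <- panel$snps[c("snp", "chr", "pos", "effect_allele", "other_allele")]
  outcome <- tibble::tibble(
    base, eaf = f, beta = beta_out, se = se_out,
    p = two_sided_p(beta_out / se_out), n = n_out, trait = "outcome"
  )

  exposures <- lapply(seq_len(n_metabolites), function(i) {
    b_i <- ifelse(met_of_snp == i & causal_snp, snp_effect, 0)
    mean_i <- drop(R %*% b_i)
    beta_i <- mean_i + se_exp * z_exp[, i]
    tibble::tibble(
      base, eaf = f, beta = beta_i, se = se_exp,
      p = two_sided_p(beta_i / se_exp), n = n_exp, trait = labels[i]
    )
  })
  names(exposures) <- labels

  truth <- tibble::tibble(
    metabolite = labels, theta = thetas,
    n_causal_snps = blocks_per_metabolite, pleiotropy = alpha_m
  )

  # annotation: one set holding the causal metabolites (padded with nulls),
  # plus random sets over the remainder
  withr::with_seed(seed + 1L, {
    causal_set <- labels[seq_len(max(n_causal, 1L))]
    pad <- sample(setdiff(labels, causal_set), min(3L, n_metabolites - length(causal_set)))
    other <- replicate(3, sample(labels, min(8L, n_metabolites)), simplify = FALSE)
  })
  set_db <- dplyr::bind_rows(
    tibble::tibble(set_id = "SET_CAUSAL", set_name = "true-effect cluster",
                   metabolite_id = unique(c(causal_set, pad))),
    purrr::imap_dfr(other, function(members, i) {
      tibble::tibble(set_id = sprintf("SET_%02d", i),
                     set_name = sprintf("random set %d", i),
                     metabolite_id = members)
    })
  )

  cohort <- simulate_cohort(1000, beta_metab = 0.5, seed = seed + 2L)

  list(panel = panel, exposures = exposures, outcome = outcome,
       truth = truth, set_db = set_db, cohort = cohort)
}
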