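# Approximate-Bayes-factor colocalization under the single-causal-variant
# assumption: per-SNP Wakefield log-ABFs, the five-hypothesis posterior
# (H0 neither / H1 exposure only / H2 outcome only / H3 both via distinct
# variants / H4 both via one shared variant), and the per-metabolite verdict
# over its instrument regions.

#' Extract a shared colocalization region around a lead SNP
#'
#' Restricts both studies to SNPs within `half_width` of the lead SNP's
#' position (on the lead's chromosome), applies the minor-allele-frequency
#' filter to both, intersects the SNP sets and harmonizes alleles. A region
#' with fewer than two shared SNPs is skipped (returns `NULL` with a
#' message).
#'
#' @param exposure,outcome Full summary-statistics tibbles.
#' @param lead Lead SNP id (must be present in the exposure).
#' @param half_width Half-width of the window in bp; the default 500 kb gives
#'   a 1 Mb total span.
#' @param maf_min Minimum minor allele frequency applied in both studies
#'   (default 0.01).
#' @return A harmonized region tibble (attributes `lead`, `half_width`) or
#'   `NULL` when the region is not analyzable.
#' @export
extract_region <- function(exposure, outcome, lead, half_width = 5e5,
                           maf_min = 0.01) {
  check_columns(exposure, c("snp", "chr", "pos", "eaf", "beta", "se"), "`exposure`")
  check_columns(outcome, c("snp", "chr", "pos", "eaf", "beta", "se"), "`outcome`")
  if (!lead %in% exposure$snp) abort(sprintf("Lead SNP %s absent from exposure.", lead))
  check_number(maf_min, "maf_min", lower = 0, upper = 0.5)

  lead_rec <- exposure[exposure$snp == lead, ][1, ]
  in_window <- function(x) {
    x$chr == lead_rec$chr & abs(x$pos - lead_rec$pos) <= half_width &
      pmin(x$eaf, 1 - x$eaf) > maf_min
  }
  exp_r <- exposure[in_window(exposure), , drop = FALSE]
  out_r <- outcome[in_window(outcome), , drop = FALSE]
  shared <- intersect(exp_r$snp, out_r$snp)
  if (length(shared) < 2L) {
    inform(sprintf("extract_region: region at %s skipped (%d shared SNP(s)).",
                   lead, length(shared)))
    return(NULL)
  }
  region <- harmonize(exp_r[exp_r$snp %in% shared, ],
                      out_r[out_r$snp %in% shared, ])
  attr(region, "lead") <- lead
  attr(region, "half_width") <- half_width
  region
}

#' Wakefield approximate log Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a normal effect prior
#' with standard deviation `prior_sd`, the shrinkage fraction is
#' `r = prior_sd^2 / (prior_sd^2 + se^2)` and
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)` with `z = beta / se`.
#' Vectorized; positive values favour association.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param prior_sd Prior effect SD (default 0.15, the quantitative-trait
#'   convention).
#' @return Log approximate Bayes factor(s).
#' @export
log_abf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0)) abort("`se` must be positive.")
  check_number(prior_sd, "prior_sd", lower = 0, inclusive_lower = FALSE)
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Approximate-Bayes-factor colocalization of two traits in one region
#'
#' Single-causal-variant colocalization over a shared, allele-harmonized SNP
#' set. Per-SNP log-ABFs are computed for each trait and combined over the
#' causal-configuration enumeration: H0 (neither trait associated), H1
#' (exposure only), H2 (outcome only), H3 (both, two distinct causal
#' variants), H4 (both, one shared causal variant). Configuration sums are
#' weighted by the priors `p1`, `p2`, `p12` per causal configuration and
#' normalized in log space, so 50-SNP regions with strong signals do not
#' overflow. Posteriors sum to one.
#'
#' @param region A harmonized region (from [extract_region()] or any tibble
#'   with beta_exp/se_exp/beta_out/se_out and optionally snp).
#' @param p1,p2 Prior probabilities that a given SNP is causal for the
#'   exposure / outcome only (defaults 1e-4).
#' @param p12 Prior probability that a given SNP is causal for both
#'   (default 1e-5).
#' @param prior_sd_exp,prior_sd_out Effect-prior SDs per trait (default
#'   0.15).
#' @return A one-row tibble: region lead (when available), nsnps, pp_h0 ..
#'   pp_h4, the priors, and a list column `snp_h4` holding the per-SNP
#'   contribution to the H4 configuration sum.
#' @export
coloc_abf <- function(region, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd_exp = 0.15, prior_sd_out = 0.15) {
  check_columns(region, c("beta_exp", "se_exp", "beta_out", "se_out"), "`region`")
  n <- nrow(region)
  if (n < 1L) abort("`region` must contain at least one SNP.")
  check_number(p1, "p1", lower = 0, inclusive_lower = FALSE)
  check_number(p2, "p2", lower = 0, inclusive_lower = FALSE)
  check_number(p12, "p12", lower = 0)
  if (p12 > min(p1, p2)) {
    warn("p12 exceeds min(p1, p2); shared-variant prior larger than marginal priors.")
  }

  l1 <- log_abf(region$beta_exp, region$se_exp, prior_sd_exp)
  l2 <- log_abf(region$beta_out, region$se_out, prior_sd_out)
  ls1 <- log_sum_exp(l1)
  ls2 <- log_sum_exp(l2)
  ls12 <- log_sum_exp(l1 + l2)
  # sum over i != j of ABF1_i * ABF2_j = (sum_i)(sum_j) - sum_i (diagonal)
  ls3 <- log_diff_exp(ls1 + ls2, ls12)

  lh <- c(
    h0 = 0,
    h1 = log(p1) + ls1,
    h2 = log(p2) + ls2,
    h3 = log(p1) + log(p2) + ls3,
    h4 = if (p12 > 0) log(p12) + ls12 else -Inf
  )
  denom <- log_sum_exp(lh)
  pp <- setNames(exp(unname(lh) - denom), names(lh))

  snp_h4 <- tibble::tibble(
    snp = if ("snp" %in% names(region)) region$snp else as.character(seq_len(n)),
    h4_contribution = exp(l1 + l2 - ls12)
  )
  tibble::tibble(
    lead = attr(region, "lead") %||% NA_character_,
    nsnps = n,
    pp_h0 = unname(pp["h0"]), pp_h1 = unname(pp["h1"]), pp_h2 = unname(pp["h2"]),
    pp_h3 = unname(pp["h3"]), pp_h4 = unname(pp["h4"]),
    p1 = p1, p2 = p2, p12 = p12,
    snp_h4 = list(snp_h4)
  )
}

#' Per-metabolite colocalization verdict
#'
#' A metabolite is called colocalized when the shared-causal-variant
#' posterior PP(H4) exceeds `h4_threshold` (strictly) in at least one of its
#' instrument regions.
#'
#' @param results Tibble of [coloc_abf()] rows with a `metabolite` column.
#' @param h4_threshold Posterior threshold (default 0.8, strict `>`).
#' @return Tibble with one row per metabolite: n_regions, max_pp_h4,
#'   colocalized.
#' @export
coloc_verdict <- function(results, h4_threshold = 0.8) {
  check_number(h4_threshold, "h4_threshold", lower = 0, upper = 1)
  if (nrow(results) == 0L) {
    return(tibble::tibble(metabolite = character(0), n_regions = integer(0),
                          max_pp_h4 = numeric(0), colocalized = logical(0)))
  }
  check_columns(results, c("metabolite", "pp_h4"), "`results`")
  dplyr::summarise(
    dplyr::group_by(results, .data$metabolite),
    n_regions = dplyr::n(),
    max_pp_h4 = max(.data$pp_h4),
    colocalized = max(.data$pp_h4) > h4_threshold,
    .groups = "drop"
  )
}
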