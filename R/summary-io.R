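#' Default column mapping for summary-statistics files
#'
#' Maps the canonical internal column names to the names found in a file.
#' Override entries (or supply a YAML file with the same keys) to ingest
#' other dialects.
#'
#' @return Named list with keys snp, chr, pos, ea, oa, eaf, beta, se, p, n.
#' @export
default_dialect <- function() {
  list(snp = "snp", chr = "chr", pos = "pos", ea = "effect_allele",
       oa = "other_allele", eaf = "eaf", beta = "beta", se = "se",
       p = "p", n = "n")
}

required_dialect_keys <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

#' Read GWAS summary statistics from a tab-separated file
#'
#' Reads a header-bearing TSV of per-SNP association records, renames columns
#' according to a dialect mapping, and validates every record against the
#' summary-statistics invariants: single-base A/C/G/T alleles, `se > 0`,
#' `eaf` in (0, 1), `p` in (0, 1], and consistency of `p` with `|beta/se|`
#' under the normal approximation (within 10% on the log10 scale). Rows
#' failing any invariant are dropped with a reported count.
#'
#' @param path Path to a TSV file with a header row; positions are 1-based.
#' @param dialect A named list mapping canonical keys (see
#'   [default_dialect()]) to the file's column names, or the path of a YAML
#'   file containing such a mapping.
#' @param trait Optional trait label attached to the records.
#' @param check_p Validate p-values against the normal approximation
#'   (default TRUE).
#' @return A tibble of validated records with canonical column names; the
#'   number of dropped rows is available as `attr(x, "n_dropped")`.
#' @export
read_summary_stats <- function(path, dialect = default_dialect(), trait = NULL,
                               check_p = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (is.character(dialect) && length(dialect) == 1L) {
    dialect <- yaml::read_yaml(dialect)
  }
  missing_keys <- setdiff(required_dialect_keys, names(dialect))
  if (length(missing_keys) > 0L) {
    abort(sprintf("Dialect is missing key(s): %s.", paste(missing_keys, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("Empty summary-statistics file: %s", path))
  cols <- unlist(dialect[required_dialect_keys])
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("File %s lacks mapped column(s): %s.",
                  path, paste(missing_cols, collapse = ", ")))
  }
  canon <- c(snp = "snp", chr = "chr", pos = "pos", ea = "effect_allele",
             oa = "other_allele", eaf = "eaf", beta = "beta", se = "se",
             p = "p", n = "n")
  out <- raw[cols]
  names(out) <- unname(canon[required_dialect_keys])
  out <- tibble::as_tibble(out)
  if (!is.null(trait)) out$trait <- trait
  validate_summary_stats(out, check_p = check_p, source = path)
}

# Row-wise invariant enforcement shared by readers and the simulators' output
# contract. Returns the surviving records with attr n_dropped.
validate_summary_stats <- function(x, check_p = TRUE, source = "input") {
  bases <- c("A", "C", "G", "T")
  ok <- x$effect_allele %in% bases & x$other_allele %in% bases &
    x$effect_allele != x$other_allele &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$eaf) & x$eaf > 0 & x$eaf < 1 &
    !is.na(x$p) & x$p > 0 & x$p <= 1 &
    !is.na(x$beta)
  if (check_p) {
    # log-scale normal p to avoid underflow for extreme z
    log10_p_norm <- (log(2) + pnorm(-abs(x$beta / x$se), log.p = TRUE)) / log(10)
    consistent <- abs(log10(x$p) - log10_p_norm) <=
      pmax(0.1 * abs(log10_p_norm), 0.05)
    ok <- ok & (is.na(consistent) | consistent)
  }
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d record(s) failing summary-statistics invariants (%s).",
                   n_dropped, source))
  }
  out <- x[ok, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics to a tab-separated file
#'
#' @param stats A summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats, path, progress = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome effects to a shared effect allele
#'
#' Joins two summary-statistics tables on SNP id and expresses both effects
#' for the exposure's effect allele. Outcome records with swapped alleles
#' have their beta negated and frequency complemented; records reported on
#' the opposite strand are complemented and then matched. Palindromic (A/T or
#' C/G) SNPs cannot be oriented by alleles alone: they are kept only when the
#' minor-allele frequency is below `palindrome_maf_limit` in *both* studies,
#' with the orientation inferred from which side of 0.5 each frequency falls;
#' otherwise they are dropped as ambiguous. SNPs with irreconcilable alleles
#' or no partner are excluded.
#'
#' @param exposure,outcome Summary-statistics tibbles (canonical columns).
#' @param palindrome_maf_limit Frequency threshold below which a palindromic
#'   SNP is considered orientable (default 0.42).
#' @return A harmonized tibble with one row per retained SNP: columns snp,
#'   chr, pos, effect_allele, other_allele, eaf, beta_exp, se_exp, p_exp,
#'   n_exp, beta_out, se_out, p_out, n_out, proxy, proxy_snp.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.42) {
  check_columns(exposure, c("snp", "effect_allele", "other_allele", "eaf",
                            "beta", "se", "p", "n"), "`exposure`")
  check_columns(outcome, c("snp", "effect_allele", "other_allele", "eaf",
                           "beta", "se", "p", "n"), "`outcome`")
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    abort("Both `exposure` and `outcome` must be non-empty.")
  }
  check_number(palindrome_maf_limit, "palindrome_maf_limit", lower = 0, upper = 0.5)

  j <- dplyr::inner_join(
    dplyr::rename_with(exposure, ~ paste0(.x, "_exp"),
                       -dplyr::any_of(c("snp", "chr", "pos"))),
    dplyr::rename_with(outcome, ~ paste0(.x, "_out"),
                       -dplyr::any_of(c("snp", "chr", "pos"))),
    by = "snp", suffix = c("", "_outside")
  )
  if (nrow(j) == 0L) abort("No overlapping SNPs between exposure and outcome.")

  ea_e <- j$effect_allele_exp; oa_e <- j$other_allele_exp
  ea_o <- j$effect_allele_out; oa_o <- j$other_allele_out
  pal <- is_palindromic(ea_e, oa_e)

  same <- ea_o == ea_e & oa_o == oa_e
  swapped <- ea_o == oa_e & oa_o == ea_e
  flip_same <- complement_allele(ea_o) == ea_e & complement_allele(oa_o) == oa_e
  flip_swap <- complement_allele(ea_o) == oa_e & complement_allele(oa_o) == ea_e

  keep <- logical(nrow(j))
  flip_sign <- logical(nrow(j))

  np <- !pal
  keep[np & (same | swapped | flip_same | flip_swap)] <- TRUE
  flip_sign[np & (swapped | flip_swap) & !(same | flip_same)] <- TRUE

  if (any(pal)) {
    # for palindromic SNPs every allele configuration is self-consistent;
    # orientation must come from the allele frequencies of both studies
    maf_e <- pmin(j$eaf_exp, 1 - j$eaf_exp)
    maf_o <- pmin(j$eaf_out, 1 - j$eaf_out)
    orientable <- pal & (same | swapped | flip_same | flip_swap) &
      maf_e < palindrome_maf_limit & maf_o < palindrome_maf_limit
    agree <- (j$eaf_exp - 0.5) * (j$eaf_out - 0.5) > 0
    keep[orientable] <- TRUE
    flip_sign[orientable & !agree] <- TRUE
  }

  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    inform(sprintf("harmonize: dropped %d SNP(s) (ambiguous or mismatched alleles).",
                   n_dropped))
  }
  j <- j[keep, , drop = FALSE]
  if (nrow(j) == 0L) abort("No overlapping SNPs after harmonization.")
  sgn <- flip_sign[keep]

  out <- tibble::tibble(
    snp = j$snp,
    chr = if ("chr" %in% names(j)) j$chr else NA_integer_,
    pos = if ("pos" %in% names(j)) j$pos else NA_integer_,
    effect_allele = j$effect_allele_exp,
    other_allele = j$other_allele_exp,
    eaf = j$eaf_exp,
    beta_exp = j$beta_exp, se_exp = j$se_exp, p_exp = j$p_exp, n_exp = j$n_exp,
    beta_out = ifelse(sgn, -j$beta_out, j$beta_out),
    se_out = j$se_out, p_out = j$p_out, n_out = j$n_out,
    proxy = FALSE, proxy_snp = NA_character_
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Find an LD proxy for a SNP missing from the outcome GWAS
#'
#' Searches the LD panel for the outcome-present SNP in highest LD with the
#' query (ties broken by smaller base-pair distance, then lexicographic id)
#' and returns the proxy's outcome record re-keyed to the query SNP. The
#' outcome effect is oriented by the sign of the panel correlation `r`
#' between the two SNPs' effect alleles (after aligning the outcome record to
#' the panel's allele coding), so the returned effect is expressed per copy
#' of the query SNP's effect allele.
#'
#' @param snp Query SNP id (present in the panel, absent from the outcome).
#' @param outcome Outcome summary-statistics tibble.
#' @param panel An [`ld_panel`][simulate_ld_panel].
#' @param r2_min Minimum squared correlation for an acceptable proxy
#'   (default 0.8).
#' @return A one-row tibble (snp, effect_allele, other_allele, eaf, beta, se,
#'   p, n, proxy_snp, r, r2) or `NULL` when no proxy reaches `r2_min`.
#' @export
find_proxy <- function(snp, outcome, panel, r2_min = 0.8) {
  stopifnot(inherits(panel, "ld_panel"))
  if (!snp %in% panel$snps$snp) abort(sprintf("SNP %s is not in the panel.", snp))
  check_number(r2_min, "r2_min", lower = 0, upper = 1)

  candidates <- intersect(panel$snps$snp, outcome$snp)
  candidates <- setdiff(candidates, snp)
  if (length(candidates) == 0L) return(NULL)

  r <- panel$r[snp, candidates]
  r2 <- r^2
  eligible <- r2 >= r2_min & r2 > 0
  if (!any(eligible)) return(NULL)

  meta <- panel$snps
  qpos <- meta$pos[meta$snp == snp]
  cand <- tibble::tibble(
    proxy_snp = candidates[eligible], r = r[eligible], r2 = r2[eligible],
    dist = abs(meta$pos[match(candidates[eligible], meta$snp)] - qpos)
  )
  cand <- dplyr::arrange(cand, dplyr::desc(.data$r2), .data$dist, .data$proxy_snp)
  best <- cand[1, ]

  rec <- outcome[outcome$snp == best$proxy_snp, ][1, ]
  # align the outcome record to the panel's allele coding for the proxy SNP
  pmeta <- meta[meta$snp == best$proxy_snp, ]
  beta <- rec$beta; eaf <- rec$eaf
  if (rec$effect_allele == pmeta$other_allele && rec$other_allele == pmeta$effect_allele) {
    beta <- -beta; eaf <- 1 - eaf
  } else if (complement_allele(rec$effect_allele) == pmeta$other_allele &&
             complement_allele(rec$other_allele) == pmeta$effect_allele) {
    beta <- -beta; eaf <- 1 - eaf
  }
  # orient onto the query SNP's effect allele via the signed correlation
  s <- unname(sign(best$r))
  qmeta <- meta[meta$snp == snp, ]
  tibble::tibble(
    snp = snp, chr = qmeta$chr, pos = qmeta$pos,
    effect_allele = qmeta$effect_allele, other_allele = qmeta$other_allele,
    eaf = if (s >= 0) eaf else 1 - eaf,
    beta = s * beta, se = rec$se, p = rec$p, n = rec$n,
    proxy_snp = best$proxy_snp, r = best$r, r2 = best$r2
  )
}

#' Harmonize with proxy substitution for missing outcome SNPs
#'
#' Convenience wrapper used by the pipeline: instrument SNPs present in both
#' studies are harmonized directly; instruments missing from the outcome are
#' replaced, where possible, by an LD proxy (the exposure effect is carried
#' over unchanged, per the two-sample design).
#'
#' @inheritParams harmonize
#' @inheritParams find_proxy
#' @param panel LD panel used for proxy search; `NULL` disables proxying.
#' @return A harmonized tibble; proxied rows have `proxy = TRUE` and carry
#'   the source SNP id in `proxy_snp`.
#' @export
harmonize_with_proxies <- function(exposure, outcome, panel = NULL,
                                   r2_min = 0.8, palindrome_maf_limit = 0.42) {
  missing_snps <- setdiff(exposure$snp, outcome$snp)
  proxies <- NULL
  if (!is.null(panel) && length(missing_snps) > 0L) {
    in_panel <- intersect(missing_snps, panel$snps$snp)
    proxies <- purrr::map_dfr(in_panel, function(s) {
      rec <- find_proxy(s, outcome, panel, r2_min = r2_min)
      if (is.null(rec)) return(tibble::tibble())
      rec
    })
  }
  outcome_aug <- outcome
  if (!is.null(proxies) && nrow(proxies) > 0L) {
    outcome_aug <- dplyr::bind_rows(
      outcome,
      dplyr::mutate(proxies[intersect(names(proxies), names(outcome))],
                    trait = outcome$trait[1] %||% NA_character_)
    )
  }
  h <- harmonize(exposure, outcome_aug, palindrome_maf_limit = palindrome_maf_limit)
  if (!is.null(proxies) && nrow(proxies) > 0L) {
    idx <- match(h$snp, proxies$snp)
    h$proxy <- !is.na(idx)
    h$proxy_snp <- ifelse(h$proxy, proxies$proxy_snp[idx], NA_character_)
  }
  h
}
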