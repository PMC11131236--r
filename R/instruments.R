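#' Select genome-wide-significant instruments
#'
#' Retains the records strongly associated with the exposure at or below the
#' significance threshold (default genome-wide, `5e-8`; the boundary value is
#' included), sorted by ascending p-value as required by greedy clumping.
#'
#' @param stats Summary-statistics tibble.
#' @param p_threshold Inclusion threshold on the association p-value.
#' @return The selected records, sorted by ascending `p`.
#' @export
select_instruments <- function(stats, p_threshold = 5e-8) {
  check_columns(stats, "p", "`stats`")
  check_number(p_threshold, "p_threshold", lower = 0, upper = 1,
               inclusive_lower = FALSE, inclusive_upper = FALSE)
  dplyr::arrange(dplyr::filter(stats, .data$p <= p_threshold), .data$p)
}

#' Greedy LD clumping
#'
#' Standard greedy clumping: keep the most significant SNP, discard every SNP
#' within `window_kb` of it whose panel r-squared with it is at or above
#' `r2_threshold`, and recurse on the remainder. The window is interpreted as
#' +/- `window_kb` around the index SNP. SNPs absent from the panel are
#' dropped with a warning rather than assumed independent.
#'
#' @param snps Tibble of candidate records (columns snp, chr, pos, p), sorted
#'   by ascending p (re-sorted defensively).
#' @param panel An [`ld_panel`][simulate_ld_panel].
#' @param r2_threshold Squared-correlation threshold at or above which a
#'   nearby SNP is removed (default 0.001).
#' @param window_kb Half-window in kilobases (default 500).
#' @return The pairwise-independent subset, sorted by ascending p.
#' @export
clump_instruments <- function(snps, panel, r2_threshold = 0.001, window_kb = 500) {
  stopifnot(inherits(panel, "ld_panel"))
  check_columns(snps, c("snp", "chr", "pos", "p"), "`snps`")
  check_number(r2_threshold, "r2_threshold", lower = 0, upper = 1)
  check_number(window_kb, "window_kb", lower = 0)
  if (nrow(snps) == 0L) return(snps)

  in_panel <- snps$snp %in% panel$snps$snp
  if (any(!in_panel)) {
    warn(sprintf("clump_instruments: dropping %d SNP(s) absent from the LD panel.",
                 sum(!in_panel)))
    snps <- snps[in_panel, , drop = FALSE]
  }
  if (nrow(snps) == 0L) return(snps)
  snps <- dplyr::arrange(snps, .data$p, .data$snp)

  window_bp <- window_kb * 1000
  keep <- character(0)
  remaining <- snps
  while (nrow(remaining) > 0L) {
    index <- remaining[1, ]
    keep <- c(keep, index$snp)
    r2 <- panel$r[index$snp, remaining$snp]^2
    near <- remaining$chr == index$chr &
      abs(remaining$pos - index$pos) <= window_bp
    prune <- near & r2 >= r2_threshold
    prune[1] <- TRUE
    remaining <- remaining[!prune, , drop = FALSE]
  }
  snps[match(keep, snps$snp), , drop = FALSE]
}

#' Variance in the exposure explained by a SNP
#'
#' The standard approximation for a standardized trait,
#' `r2 = 2 * beta^2 * f * (1 - f)`, where `beta` is the per-allele effect on
#' the SD scale and `f` the effect-allele frequency. Vectorized.
#'
#' @param beta Per-allele effect estimate (SD scale).
#' @param eaf Effect-allele frequency in (0, 1).
#' @return The per-SNP r-squared.
#' @export
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1, na.rm = TRUE)) abort("`eaf` must lie in (0, 1).")
  2 * beta^2 * eaf * (1 - eaf)
}

#' Instrument-strength F-statistic
#'
#' Global F-statistic of a set of `k` independent instruments explaining a
#' total fraction `r2_total` of the exposure variance in a sample of size
#' `n`: `F = (R2 / k) / ((1 - R2) / (n - k - 1))`. Values below 10
#' conventionally flag weak instruments.
#'
#' @param r2_total Total variance explained, in `[0, 1)`; for clumped,
#'   near-independent instruments this is the sum of per-SNP
#'   [variance_explained()].
#' @param n Exposure GWAS sample size (`n > k + 1`).
#' @param k Number of instruments.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  check_number(r2_total, "r2_total", lower = 0, upper = 1, inclusive_upper = FALSE)
  k <- check_count(k, "k")
  if (n <= k + 1) abort("`n` must exceed k + 1 for the F-statistic.")
  (r2_total / k) / ((1 - r2_total) / (n - k - 1))
}

#' Build a per-metabolite instrument set
#'
#' Applies significance selection and LD clumping to one exposure GWAS and
#' annotates the surviving instruments with per-SNP variance explained, the
#' global R-squared (sum over the near-independent members) and the global
#' F-statistic.
#'
#' @param stats Exposure summary-statistics tibble.
#' @param panel LD panel for clumping.
#' @param metabolite Label for the exposure (defaults to the `trait` column).
#' @param p_threshold,r2_threshold,window_kb Selection and clumping
#'   parameters (paper-standard defaults).
#' @return A tibble of instruments (or zero rows when none pass) with
#'   attributes `metabolite`, `r2_total`, `f_stat`, `k`, `n`; also exposed via
#'   columns `r2` (per SNP), and summary columns on `glance_instruments()`.
#' @export
build_instrument_set <- function(stats, panel, metabolite = NULL,
                                 p_threshold = 5e-8, r2_threshold = 0.001,
                                 window_kb = 500) {
  metabolite <- metabolite %||% (if ("trait" %in% names(stats)) stats$trait[1] else NA_character_)
  sel <- select_instruments(stats, p_threshold)
  iv <- clump_instruments(sel, panel, r2_threshold, window_kb)
  if (nrow(iv) > 0L) {
    iv$r2 <- variance_explained(iv$beta, iv$eaf)
    r2_total <- min(sum(iv$r2), 1 - 1e-12)
    n <- iv$n[1]
    f <- if (n > nrow(iv) + 1) f_statistic(r2_total, n, nrow(iv)) else NA_real_
  } else {
    iv$r2 <- numeric(0)
    r2_total <- 0; f <- NA_real_; n <- NA_real_
  }
  structure(iv, metabolite = metabolite, r2_total = r2_total,
            f_stat = f, k = nrow(iv), n = if (nrow(iv)) iv$n[1] else NA_real_,
            class = c("instrument_set", class(iv)))
}

#' One-row summary of an instrument set
#'
#' @param set An instrument set from [build_instrument_set()].
#' @return Tibble with metabolite, k, n, r2_total, f_stat.
#' @export
glance_instruments <- function(set) {
  tibble::tibble(
    metabolite = attr(set, "metabolite"),
    k = attr(set, "k"),
    n = attr(set, "n"),
    r2_total = attr(set, "r2_total"),
    f_stat = attr(set, "f_stat")
  )
}

#' Filter out weak instrument sets
#'
#' Retains the instrument sets whose global F-statistic is at least `f_min`
#' (the conventional threshold 10; sets exactly at the boundary are kept,
#' those below are excluded). Exclusions are reported.
#'
#' @param sets A list of instrument sets.
#' @param f_min Minimum acceptable F-statistic (default 10).
#' @return The retained subset of `sets`.
#' @export
filter_weak <- function(sets, f_min = 10) {
  if (length(sets) == 0L) return(sets)
  f <- vapply(sets, function(s) attr(s, "f_stat") %||% NA_real_, numeric(1))
  keep <- !is.na(f) & f >= f_min
  if (any(!keep)) {
    inform(sprintf("filter_weak: excluded %d instrument set(s) with F < %g.",
                   sum(!keep), f_min))
  }
  sets[keep]
}
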