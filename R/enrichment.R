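# Hypergeometric over-representation analysis of prioritized metabolites
# against annotated metabolite sets, and the observational validation
# utilities (z-scoring, adjacent-age BMI imputation, linear regression
# models with early-event exclusion).

#' Hypergeometric over-representation analysis
#'
#' For each annotated set, tests whether the selected metabolites overlap the
#' set more than expected by chance: with universe size `N`, set size `K`
#' (restricted to the universe), selection size `n` and overlap `k`, the
#' one-tailed p-value is `P(X >= k)` for `X ~ hypergeometric(N, K, n)`
#' (computed with `stats::phyper`). Benjamini-Hochberg q-values are added
#' across sets.
#'
#' @param selected Character vector of selected metabolite ids (must be a
#'   subset of `universe`).
#' @param db Annotation tibble with columns `set_id`, `metabolite_id` and
#'   optionally `set_name`.
#' @param universe Character vector of all tested metabolite ids.
#' @return Tibble with one row per set: set_id, set_name, overlap k, set size
#'   K, selected n, universe N, p, q. Empty selection yields an empty result.
#' @export
hypergeom_ora <- function(selected, db, universe) {
  check_columns(db, c("set_id", "metabolite_id"), "`db`")
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`.")
  }
  if (length(selected) == 0L) {
    return(tibble::tibble(set_id = character(0), set_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0), q = numeric(0)))
  }
  if (!"set_name" %in% names(db)) db$set_name <- db$set_id
  N <- length(universe)
  n <- length(selected)
  out <- dplyr::summarise(
    dplyr::group_by(db, .data$set_id, .data$set_name),
    K = length(intersect(unique(.data$metabolite_id), universe)),
    k = length(intersect(unique(.data$metabolite_id), selected)),
    .groups = "drop"
  )
  out$n <- n
  out$N <- N
  out$p <- phyper(out$k - 1, out$K, N - out$K, n, lower.tail = FALSE)
  out$q <- fdr_adjust(out$p)
  dplyr::arrange(out[c("set_id", "set_name", "k", "K", "n", "N", "p", "q")],
                 .data$p)
}

#' Combine set-level p-values with Fisher's method
#'
#' Aggregate view over an ORA result family (an approximate stand-in for
#' pathway-level p-value combination): `-2 sum(log p)` referred to a
#' chi-square with 2m degrees of freedom.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return A one-row tibble (statistic, df, p).
#' @export
fisher_combine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) == 0L) abort("No p-values to combine.")
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  tibble::tibble(statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE))
}

#' Z-score standardization
#'
#' Standardizes measurements to mean 0 and SD 1 over the non-missing entries
#' (sample SD, n - 1 denominator); missing values propagate.
#'
#' @param values Numeric vector with at least two non-missing values and
#'   nonzero SD.
#' @return Standardized vector of the same length.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) abort("Need at least 2 non-missing values to standardize.")
  s <- sd(values[ok])
  if (s == 0) abort("Cannot standardize a constant vector (zero SD).")
  (values - mean(values[ok])) / s
}

#' Impute missing age-8 BMI z-scores from adjacent ages
#'
#' Missing age-8 values are filled from the age-7 measurement when present,
#' else from the age-9 measurement; subjects missing all three remain
#' missing (and are excluded from BMI-adjusted models downstream).
#'
#' @param data Cohort tibble containing the three columns.
#' @param target,lower,upper Column names for the age-8, age-7 and age-9
#'   z-scores.
#' @return `data` with the target column completed where possible.
#' @export
impute_adjacent <- function(data, target = "bmi_z_age8",
                            lower = "bmi_z_age7", upper = "bmi_z_age9") {
  check_columns(data, c(target, lower, upper), "`data`")
  data[[target]] <- dplyr::coalesce(data[[target]], data[[lower]], data[[upper]])
  data
}

#' Observational validation regression
#'
#' Ordinary least squares of the outcome (age at event, years) on a
#' metabolite plus optional covariates over complete cases, reporting the
#' slope on the metabolite term. When `exclude_early` is set, subjects whose
#' outcome falls below `early_cutoff` (default 45 years, the early-menopause
#' definition) are removed before fitting.
#'
#' @param cohort Cohort tibble.
#' @param metabolite Name of the metabolite column.
#' @param outcome Name of the outcome column (default `"age_at_event"`).
#' @param covariates Character vector of covariate column names.
#' @param exclude_early Drop subjects with outcome below `early_cutoff`?
#' @param early_cutoff Exclusion threshold in years (default 45).
#' @return One-row tibble: metabolite, outcome, model (covariate-adjusted or
#'   unadjusted), excluded_early, beta, se, p, n.
#' @export
linear_validation <- function(cohort, metabolite, outcome = "age_at_event",
                              covariates = character(), exclude_early = FALSE,
                              early_cutoff = 45) {
  check_columns(cohort, c(metabolite, outcome, covariates), "`cohort`")
  d <- cohort[c(outcome, metabolite, covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (exclude_early) d <- d[d[[outcome]] >= early_cutoff, , drop = FALSE]
  if (nrow(d) < length(covariates) + 2L) {
    abort("Too few complete cases for the requested model.")
  }
  fml <- stats::reformulate(c(metabolite, covariates), response = outcome)
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) abort("Rank-deficient design in validation regression.")
  co <- summary(fit)$coefficients
  tibble::tibble(
    metabolite = metabolite, outcome = outcome,
    model = if (length(covariates)) paste0("adjusted(", paste(covariates, collapse = "+"), ")") else "unadjusted",
    excluded_early = exclude_early,
    beta = co[metabolite, "Estimate"], se = co[metabolite, "Std. Error"],
    p = co[metabolite, "Pr(>|t|)"], n = nrow(d)
  )
}
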