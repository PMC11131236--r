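# Causal-effect estimators for two-sample MR: Wald ratio, IVW, MR-Egger,
# weighted median, weighted mode, multivariable IVW, and BH-FDR adjustment.
# All estimators take a harmonized tibble (beta_exp/se_exp/beta_out/se_out)
# and return a one-row result tibble so outputs can be bound into the
# per-(metabolite, outcome, method) results table.

mr_result_row <- function(method, n_snp, estimate = NA_real_, se = NA_real_,
                          p = NA_real_, exposure = NA_character_,
                          outcome = NA_character_, note = NA_character_, ...) {
  ci <- ci_bounds(estimate, se)
  tibble::tibble(
    exposure = exposure, outcome = outcome, method = method,
    n_snp = as.integer(n_snp), estimate = estimate, se = se,
    ci_lower = ci$lower, ci_upper = ci$upper, p = p, note = note, ...
  )
}

labels_of <- function(data) {
  list(
    exposure = if ("exposure" %in% names(data)) data$exposure[1] else NA_character_,
    outcome = if ("outcome" %in% names(data)) data$outcome[1] else NA_character_
  )
}

#' Wald ratio estimate from a single instrument
#'
#' Per-SNP causal estimate: the outcome effect divided by the exposure
#' effect, with the first-order delta-method standard error
#' `se = by_se / |bx|` and a two-sided normal p-value.
#'
#' @param bx,bx_se Exposure effect and its SE (SE unused by the first-order
#'   approximation but accepted for a uniform signature).
#' @param by,by_se Outcome effect and its SE.
#' @return A one-row result tibble (method `"wald"`).
#' @export
wald_ratio <- function(bx, bx_se, by, by_se) {
  if (any(bx == 0)) abort("Degenerate instrument: exposure effect is zero.")
  estimate <- by / bx
  se <- by_se / abs(bx)
  mr_result_row("wald", 1L, estimate = estimate, se = se,
                p = two_sided_p(estimate / se))
}

#' Inverse-variance-weighted MR estimate
#'
#' Meta-analyzes per-SNP Wald ratios as a weighted regression of the outcome
#' effects on the exposure effects through the origin with weights
#' `1/se_out^2`: `estimate = sum(w bx by) / sum(w bx^2)`. The fixed-effect SE
#' is `sqrt(1 / sum(w bx^2))`; the default multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q/(k-1)))` where `Q` is Cochran's Q, so
#' the interval is never narrower than the fixed-effect one. With a single
#' SNP the function falls back to the Wald ratio (with a note).
#'
#' @param data Harmonized tibble (columns beta_exp, se_exp, beta_out,
#'   se_out).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return A one-row result tibble (method `"ivw"`; also columns q, q_df,
#'   q_p).
#' @export
mr_ivw <- function(data, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  lab <- labels_of(data)
  k <- nrow(data)
  if (k == 0L) {
    return(mr_result_row("ivw", 0L, exposure = lab$exposure, outcome = lab$outcome,
                         note = "no instruments", q = NA_real_, q_df = NA_integer_,
                         q_p = NA_real_))
  }
  if (k == 1L) {
    res <- wald_ratio(data$beta_exp, data$se_exp, data$beta_out, data$se_out)
    res$exposure <- lab$exposure; res$outcome <- lab$outcome
    res$method <- "ivw"
    res$note <- "single instrument: Wald ratio"
    res$q <- NA_real_; res$q_df <- NA_integer_; res$q_p <- NA_real_
    return(res)
  }
  bx <- data$beta_exp; by <- data$beta_out
  w <- 1 / data$se_out^2
  estimate <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - estimate * bx)^2)
  scale <- if (effects_model == "multiplicative_random") max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scale
  mr_result_row("ivw", k, estimate = estimate, se = se,
                p = two_sided_p(estimate / se),
                exposure = lab$exposure, outcome = lab$outcome,
                q = q, q_df = k - 1L, q_p = pchisq(q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with a
#' free intercept (weights `1/se_out^2`), after orienting each pair so the
#' exposure effect is non-negative. The slope estimates the causal effect
#' under the InSIDE assumption; an intercept that deviates from zero
#' (p < 0.05) flags directional pleiotropy. Standard errors use the same
#' residual-scale floor-at-1 convention as [mr_ivw()]; p-values use the
#' two-sided normal reference, as for IVW. Requires at least three
#' instruments; with fewer a not-computable marker row is returned.
#'
#' @inheritParams mr_ivw
#' @return A one-row result tibble (method `"egger"`; also columns
#'   intercept, intercept_se, intercept_p, q, q_df, q_p).
#' @export
mr_egger <- function(data) {
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  lab <- labels_of(data)
  k <- nrow(data)
  if (k < 3L) {
    return(mr_result_row("egger", k, exposure = lab$exposure, outcome = lab$outcome,
                         note = "not computable: fewer than 3 instruments",
                         intercept = NA_real_, intercept_se = NA_real_,
                         intercept_p = NA_real_, q = NA_real_,
                         q_df = NA_integer_, q_p = NA_real_))
  }
  s <- ifelse(data$beta_exp < 0, -1, 1)
  bx <- s * data$beta_exp
  by <- s * data$beta_out
  w <- 1 / data$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  floor_scale <- max(1, sigma)
  co <- sm$coefficients
  se_unscaled <- co[, "Std. Error"] / sigma
  se_used <- se_unscaled * floor_scale
  est <- co[, "Estimate"]
  # two-sided normal reference, matching the IVW convention; the floor-at-1
  # residual scale already guards the underdispersed case
  pvals <- two_sided_p(est / se_used)
  q <- sum(w * stats::residuals(fit)^2)
  mr_result_row("egger", k, estimate = unname(est["bx"]), se = unname(se_used["bx"]),
                p = unname(pvals["bx"]), exposure = lab$exposure, outcome = lab$outcome,
                intercept = unname(est["(Intercept)"]),
                intercept_se = unname(se_used["(Intercept)"]),
                intercept_p = unname(pvals["(Intercept)"]),
                q = q, q_df = k - 2L,
                q_p = pchisq(q, k - 2, lower.tail = FALSE))
}

# Per-SNP Wald ratios and their first-order variances.
ratio_table <- function(data) {
  tibble::tibble(
    ratio = data$beta_out / data$beta_exp,
    ratio_se = data$se_out / abs(data$beta_exp)
  )
}

weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  b <- ratios[o]
  w <- weights[o] / sum(weights)
  cw <- cumsum(w) - 0.5 * w  # standardized cumulative weight at each ratio
  if (cw[1] >= 0.5) return(b[1])
  below <- max(which(cw < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) * (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

# Parametric bootstrap over the summary statistics; returns the SD of the
# statistic computed by `point_fun(bx, by)` across n_boot redraws.
bootstrap_se <- function(data, point_fun, n_boot, seed) {
  k <- nrow(data)
  withr::with_seed(seed, {
    bx <- matrix(rnorm(n_boot * k, rep(data$beta_exp, each = n_boot),
                       rep(data$se_exp, each = n_boot)), n_boot, k)
    by <- matrix(rnorm(n_boot * k, rep(data$beta_out, each = n_boot),
                       rep(data$se_out, each = n_boot)), n_boot, k)
  })
  est <- vapply(seq_len(n_boot), function(i) point_fun(bx[i, ], by[i, ]), numeric(1))
  sd(est)
}

#' Weighted-median MR estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' median: the ratio at which the standardized cumulative weight crosses 0.5,
#' linearly interpolated between the bracketing ratios. Consistent when at
#' least half the weight comes from valid instruments. The SE comes from a
#' seeded parametric bootstrap of the summary statistics.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap.
#' @return A one-row result tibble (method `"weighted_median"`).
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = 1L) {
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  lab <- labels_of(data)
  k <- nrow(data)
  if (k < 3L) {
    return(mr_result_row("weighted_median", k, exposure = lab$exposure,
                         outcome = lab$outcome,
                         note = "not computable: fewer than 3 instruments"))
  }
  point <- function(bx, by) {
    r <- by / bx
    w <- bx^2 / data$se_out^2  # 1 / first-order ratio variance
    weighted_median_point(r, w)
  }
  estimate <- point(data$beta_exp, data$beta_out)
  se <- bootstrap_se(data, point, n_boot, seed)
  mr_result_row("weighted_median", k, estimate = estimate, se = se,
                p = two_sided_p(estimate / se),
                exposure = lab$exposure, outcome = lab$outcome)
}

# Modified Silverman bandwidth on the ratio scale (Hartwig-style):
# 0.9 * min(sd, mad) * k^(-1/5), ignoring a zero component when the other is
# positive.
mode_bandwidth <- function(ratios, bandwidth_factor) {
  s <- sd(ratios)
  m <- mad(ratios)
  cand <- c(s, m)
  cand <- cand[cand > 0]
  if (length(cand) == 0L) return(0)
  bandwidth_factor * 0.9 * min(cand) * length(ratios)^(-1 / 5)
}

weighted_mode_point <- function(ratios, weights, bandwidth_factor) {
  h <- mode_bandwidth(ratios, bandwidth_factor)
  if (h == 0) return(ratios[1])  # all ratios identical
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 512)
  dens <- vapply(grid, function(x) sum(weights * dnorm(x - ratios, sd = h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode MR estimate
#'
#' Estimates the causal effect as the mode of the per-SNP Wald-ratio
#' distribution: a Gaussian-kernel density over the ratios weighted by their
#' inverse variances, with bandwidth `bandwidth_factor` times a modified
#' Silverman rule (`0.9 min(sd, mad) k^{-1/5}`); the estimate is the density
#' argmax. Consistent when the largest group of instruments sharing a ratio
#' is valid. The SE comes from a seeded parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth
#'   (default 1).
#' @return A one-row result tibble (method `"weighted_mode"`).
#' @export
mr_weighted_mode <- function(data, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  lab <- labels_of(data)
  k <- nrow(data)
  if (k < 3L) {
    return(mr_result_row("weighted_mode", k, exposure = lab$exposure,
                         outcome = lab$outcome,
                         note = "not computable: fewer than 3 instruments"))
  }
  point <- function(bx, by) {
    r <- by / bx
    w <- bx^2 / data$se_out^2
    weighted_mode_point(r, w / sum(w), bandwidth_factor)
  }
  estimate <- point(data$beta_exp, data$beta_out)
  se <- bootstrap_se(data, point, n_boot, seed)
  mr_result_row("weighted_mode", k, estimate = estimate, se = se,
                p = two_sided_p(estimate / se),
                exposure = lab$exposure, outcome = lab$outcome)
}

#' Multivariable IVW MR
#'
#' Estimates conditional causal effects of several exposures (e.g. a
#' metabolite and BMI) jointly: weighted least squares of the outcome effects
#' on the matrix of exposure effects with no intercept and weights
#' `1/se_out^2`. Requires more instruments than exposures; otherwise a
#' not-computable marker row per exposure is returned. Standard errors use
#' the residual-scale floor-at-1 convention.
#'
#' @param data Tibble with one row per instrument: outcome columns
#'   `beta_out`, `se_out` and one exposure-beta column per exposure.
#' @param exposure_cols Names of the exposure-beta columns, in reporting
#'   order.
#' @param outcome Optional outcome label.
#' @return A result tibble with one row per exposure (method `"mvmr"`).
#' @export
mr_mvmr <- function(data, exposure_cols, outcome = NA_character_) {
  check_columns(data, c(exposure_cols, "beta_out", "se_out"), "`data`")
  k <- nrow(data)
  p_exp <- length(exposure_cols)
  if (k <= p_exp) {
    return(purrr::map_dfr(exposure_cols, function(cn) {
      mr_result_row("mvmr", k, exposure = cn, outcome = outcome,
                    note = "not computable: instruments <= exposures")
    }))
  }
  X <- as.matrix(data[exposure_cols])
  y <- data$beta_out
  w <- 1 / data$se_out^2
  fit <- lm(y ~ 0 + X, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  floor_scale <- max(1, sigma)
  co <- sm$coefficients
  est <- co[, "Estimate"]
  se_used <- co[, "Std. Error"] / sigma * floor_scale
  purrr::map_dfr(seq_along(exposure_cols), function(i) {
    mr_result_row("mvmr", k, estimate = unname(est[i]), se = unname(se_used[i]),
                  p = two_sided_p(est[i] / se_used[i]),
                  exposure = exposure_cols[i], outcome = outcome)
  })
}

#' Build a multivariable MR design table
#'
#' Assembles the joint instrument table [mr_mvmr()] consumes from
#' per-exposure harmonized sets: the union of their instruments, each row
#' carrying every exposure's effect at that SNP (from the exposures' full
#' summary statistics) and the harmonized outcome effect.
#'
#' @param instruments Named list of instrument SNP-id character vectors, one
#'   per exposure.
#' @param exposures Named list of full exposure summary-statistics tibbles
#'   (same names).
#' @param outcome Outcome summary-statistics tibble.
#' @param panel Optional LD panel used to clump the union set.
#' @param r2_threshold,window_kb Clumping parameters for the union set.
#' @return A tibble with columns snp, `beta_<exposure>` per exposure,
#'   beta_out, se_out; SNPs missing from any study are dropped.
#' @export
mvmr_design <- function(instruments, exposures, outcome, panel = NULL,
                        r2_threshold = 0.001, window_kb = 500) {
  stopifnot(is.list(instruments), is.list(exposures),
            all(names(instruments) %in% names(exposures)))
  union_snps <- unique(unlist(instruments))
  first <- exposures[[1]]
  cand <- dplyr::filter(first, .data$snp %in% union_snps)
  if (!is.null(panel) && nrow(cand) > 1L) {
    # keep the union pairwise independent; rank by the first exposure's p
    cand <- clump_instruments(cand, panel, r2_threshold, window_kb)
  }
  snps <- cand$snp
  h0 <- harmonize(dplyr::filter(first, .data$snp %in% snps), outcome)
  out <- tibble::tibble(snp = h0$snp, beta_out = h0$beta_out, se_out = h0$se_out)
  for (nm in names(exposures)) {
    hx <- harmonize(dplyr::filter(first, .data$snp %in% out$snp), exposures[[nm]])
    out[[paste0("beta_", nm)]] <- hx$beta_out[match(out$snp, hx$snp)]
  }
  out[complete.cases(out), , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with monotonicity enforcement, as implemented by
#' `stats::p.adjust(method = "BH")`. The family is all metabolites tested
#' against one outcome.
#'
#' @param pvalues Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1))) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}
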