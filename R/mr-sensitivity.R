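# Heterogeneity, pleiotropy-outlier and directionality diagnostics:
# Cochran's Q, the residual-sum-of-squares pleiotropy outlier test
# (MR-PRESSO-style), Steiger filtering, and the bidirectional-MR driver.

#' Cochran's Q heterogeneity test
#'
#' For the IVW model, `Q = sum(w_j (ratio_j - estimate)^2)` over the per-SNP
#' Wald ratios with first-order inverse-variance weights
#' `w_j = bx_j^2 / se_out_j^2` (algebraically identical to the weighted
#' regression residual sum of squares), referred to a chi-square with k - 1
#' degrees of freedom. For the Egger model, Ruecker's Q' on the
#' intercept-adjusted residuals with k - 2 degrees of freedom.
#'
#' @param data Harmonized tibble.
#' @param method `"ivw"` (default) or `"egger"`.
#' @return A one-row tibble (method, q, df, p); with too few instruments the
#'   values are NA and `note` explains why.
#' @export
cochran_q <- function(data, method = c("ivw", "egger")) {
  method <- match.arg(method)
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  k <- nrow(data)
  need <- if (method == "ivw") 2L else 3L
  if (k < need) {
    return(tibble::tibble(method = method, q = NA_real_, df = NA_integer_,
                          p = NA_real_,
                          note = sprintf("not computable: fewer than %d instruments", need)))
  }
  fit <- if (method == "ivw") mr_ivw(data, "fixed") else mr_egger(data)
  tibble::tibble(method = method, q = fit$q, df = fit$q_df, p = fit$q_p,
                 note = NA_character_)
}

#' Residual-sum-of-squares pleiotropy outlier test (MR-PRESSO-style)
#'
#' Detects horizontal-pleiotropy outliers by comparing the observed weighted
#' residual sum of squares of leave-one-out IVW predictions with its
#' parametric-simulation null. For each SNP j the IVW slope is re-fit without
#' it; the observed statistic is `RSS = sum_j w_j (by_j - slope_(-j) bx_j)^2`
#' with `w_j = 1/se_out_j^2`. Under the null, `n_sim` datasets are redrawn
#' from the estimated sampling distributions (`bx* ~ N(bx, se_exp)`,
#' `by* ~ N(slope_(-j) bx, se_out)`) and the statistic recomputed identically;
#' the global p-value is the rank-based tail probability with the +1
#' correction (minimum attainable `1/(n_sim + 1)`). Per-SNP outlier p-values
#' compare each SNP's residual contribution with its simulated distribution
#' at the Bonferroni-corrected `alpha_outlier`; because the leave-one-out
#' slopes remain contaminated while a strong outlier is still in the set,
#' flagging is iterative -- the single most extreme SNP is removed and the
#' test refit until no SNP exceeds the threshold. The reported per-SNP
#' p-values are from the first round; the outlier-corrected estimate is the
#' IVW fit after removing all flagged SNPs.
#'
#' @param data Harmonized tibble with at least four instruments.
#' @param n_sim Number of null simulations (default 1000).
#' @param seed Seed for the simulations.
#' @param alpha_outlier Per-test outlier significance level before Bonferroni
#'   (default 0.05).
#' @return An object of class `mr_presso`: list with `global_p`, `rss_obs`,
#'   `outliers` (per-SNP tibble with p and flag), `corrected` (IVW result
#'   after outlier removal), `raw` (IVW on all SNPs), `n_sim`.
#' @export
mr_presso <- function(data, n_sim = 1000, seed = 1L, alpha_outlier = 0.05) {
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  k <- nrow(data)
  if (k < 4L) {
    out <- list(global_p = NA_real_, rss_obs = NA_real_,
                outliers = tibble::tibble(index = integer(0), snp = character(0),
                                          p = numeric(0), flagged = logical(0)),
                corrected = NULL, raw = NULL, n_sim = n_sim,
                note = "not computable: fewer than 4 instruments")
    class(out) <- "mr_presso"
    return(out)
  }
  n_sim <- check_count(n_sim, "n_sim")
  seed <- check_count(seed, "seed", min = 0L)
  check_number(alpha_outlier, "alpha_outlier", lower = 0, upper = 1)

  first <- presso_round(data, n_sim, seed)

  # iterative flagging: the per-SNP test compares each residual with its
  # simulated null, but the leave-one-out slopes stay contaminated while a
  # strong outlier remains in the set -- so flag the single most extreme
  # SNP below the Bonferroni threshold, refit without it, and repeat
  flagged <- logical(k)
  active <- rep(TRUE, k)
  rr <- first
  repeat {
    n_act <- sum(active)
    extreme <- which(rr$p_j < alpha_outlier / n_act)
    if (length(extreme) == 0L || n_act <= 4L) break
    worst <- extreme[order(rr$p_j[extreme], -rr$rss_j[extreme])][1]
    flagged[which(active)[worst]] <- TRUE
    active[which(active)[worst]] <- FALSE
    rr <- presso_round(data[active, , drop = FALSE], n_sim, seed)
  }

  outliers <- tibble::tibble(
    index = seq_len(k),
    snp = if ("snp" %in% names(data)) data$snp else as.character(seq_len(k)),
    p = first$p_j, flagged = flagged
  )
  corrected <- suppressMessages(
    if (any(flagged)) mr_ivw(data[!flagged, , drop = FALSE]) else mr_ivw(data))
  out <- list(global_p = first$global_p, rss_obs = first$rss_obs,
              outliers = outliers, corrected = corrected,
              raw = suppressMessages(mr_ivw(data)), n_sim = n_sim,
              note = NA_character_)
  class(out) <- "mr_presso"
  out
}

# One simulation round of the RSS test; returns the global p, the observed
# RSS, and per-SNP residuals and p-values in the input row order.
presso_round <- function(data, n_sim, seed) {
  k <- nrow(data)
  # canonical internal ordering so the simulated null (hence the p-values)
  # does not depend on the row order of the input at a fixed seed
  ord <- order(data$beta_exp, data$beta_out, data$se_out, data$se_exp)
  bx <- data$beta_exp[ord]; by <- data$beta_out[ord]
  se_x <- data$se_exp[ord]; se_y <- data$se_out[ord]
  w <- 1 / se_y^2

  loo_slope <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  th <- loo_slope(bx, by)
  rss_j <- w * (by - th * bx)^2
  rss_obs <- sum(rss_j)

  withr::with_seed(seed, {
    bx_s <- matrix(rnorm(n_sim * k, rep(bx, each = n_sim), rep(se_x, each = n_sim)),
                   n_sim, k)
    by_s <- matrix(rnorm(n_sim * k, rep(th * bx, each = n_sim), rep(se_y, each = n_sim)),
                   n_sim, k)
  })
  W <- matrix(w, n_sim, k, byrow = TRUE)
  sxy_s <- rowSums(W * bx_s * by_s)
  sxx_s <- rowSums(W * bx_s^2)
  th_s <- (sxy_s - W * bx_s * by_s) / (sxx_s - W * bx_s^2)  # n_sim x k LOO slopes
  rss_sj <- W * (by_s - th_s * bx_s)^2
  rss_s <- rowSums(rss_sj)

  global_p <- (1 + sum(rss_s >= rss_obs)) / (n_sim + 1)
  p_sorted <- (1 + colSums(rss_sj >= matrix(rss_j, n_sim, k, byrow = TRUE))) / (n_sim + 1)
  p_j <- numeric(k); p_j[ord] <- p_sorted
  rss_back <- numeric(k); rss_back[ord] <- rss_j
  list(global_p = global_p, rss_obs = rss_obs, p_j = p_j, rss_j = rss_back)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("<mr_presso>\n")
  if (!is.na(x$note %||% NA)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf("  global p = %.4g (RSS = %.4g, %d simulations)\n",
                x$global_p, x$rss_obs, x$n_sim))
    cat(sprintf("  outliers flagged: %d of %d\n",
                sum(x$outliers$flagged), nrow(x$outliers)))
  }
  invisible(x)
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outliers

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_p = x$global_p, rss_obs = x$rss_obs,
    n_outliers = sum(x$outliers$flagged), n_snp = nrow(x$outliers),
    corrected_estimate = if (!is.null(x$corrected)) x$corrected$estimate else NA_real_,
    n_sim = x$n_sim
  )
}

#' Steiger directionality filtering
#'
#' Checks, per SNP, that the instrument explains more variance in the
#' exposure than in the outcome — the direction the causal model presumes.
#' Variance explained is `2 beta^2 f (1 - f)` on standardized effects; when
#' the frequency is missing, the fallback `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta/se` is used. The test p-value compares the two correlations via
#' Fisher's z with the independent-samples standard error.
#'
#' @param data Harmonized tibble.
#' @param n_exp,n_out Study sample sizes; taken from `data`'s n_exp/n_out
#'   columns when omitted.
#' @return Per-SNP tibble (snp, r2_exp, r2_out, correct_direction, p); the
#'   aggregate all-SNPs-pass verdict is in `attr(x, "verdict")`.
#' @export
steiger_filter <- function(data, n_exp = NULL, n_out = NULL) {
  check_columns(data, c("beta_exp", "se_exp", "beta_out", "se_out"), "`data`")
  n_exp <- n_exp %||% (if ("n_exp" %in% names(data)) data$n_exp else NULL)
  n_out <- n_out %||% (if ("n_out" %in% names(data)) data$n_out else NULL)
  if (is.null(n_exp) || is.null(n_out)) {
    abort("Sample sizes are required (columns n_exp/n_out or arguments).")
  }
  k <- nrow(data)
  n_exp <- rep(n_exp, length.out = k)
  n_out <- rep(n_out, length.out = k)

  r2_from <- function(beta, se, n) {
    if ("eaf" %in% names(data) && all(!is.na(data$eaf))) {
      pmin(2 * beta^2 * data$eaf * (1 - data$eaf), 1 - 1e-12)
    } else {
      t2 <- (beta / se)^2
      t2 / (t2 + n - 2)
    }
  }
  r2_exp <- r2_from(data$beta_exp, data$se_exp, n_exp)
  r2_out <- r2_from(data$beta_out, data$se_out, n_out)

  z_e <- atanh(sqrt(r2_exp))
  z_o <- atanh(sqrt(r2_out))
  stat <- (z_e - z_o) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  out <- tibble::tibble(
    snp = if ("snp" %in% names(data)) data$snp else as.character(seq_len(k)),
    r2_exp = r2_exp, r2_out = r2_out,
    correct_direction = r2_exp > r2_out,
    p = two_sided_p(stat)
  )
  attr(out, "verdict") <- all(out$correct_direction)
  out
}

#' Bidirectional (reverse) MR
#'
#' Re-runs the two-sample analysis with the roles swapped: the original
#' outcome becomes the exposure (instruments selected at the genome-wide
#' threshold and clumped) and the metabolite becomes the outcome. Returns
#' IVW, MR-Egger, weighted-median and weighted-mode results; estimators whose
#' instrument requirements are unmet return not-computable marker rows.
#'
#' @param outcome_as_exposure Summary statistics of the trait now acting as
#'   exposure.
#' @param metabolite_as_outcome Summary statistics of the metabolite now
#'   acting as outcome.
#' @param panel LD panel for clumping and proxies.
#' @param p_threshold,r2_threshold,window_kb Instrument-selection parameters.
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @return A result tibble with one row per method.
#' @export
reverse_mr <- function(outcome_as_exposure, metabolite_as_outcome, panel,
                       p_threshold = 5e-8, r2_threshold = 0.001,
                       window_kb = 500, n_boot = 1000, seed = 1L) {
  set <- build_instrument_set(outcome_as_exposure, panel,
                              p_threshold = p_threshold,
                              r2_threshold = r2_threshold, window_kb = window_kb)
  if (nrow(set) == 0L) {
    return(mr_result_row("ivw", 0L,
                         exposure = attr(set, "metabolite"),
                         note = "no instruments for the reverse direction"))
  }
  h <- harmonize_with_proxies(as.data.frame(set), metabolite_as_outcome, panel)
  h$exposure <- outcome_as_exposure$trait[1] %||% "outcome"
  h$outcome <- metabolite_as_outcome$trait[1] %||% "metabolite"
  dplyr::bind_rows(
    mr_ivw(h),
    mr_egger(h),
    mr_weighted_median(h, n_boot = n_boot, seed = seed),
    mr_weighted_mode(h, n_boot = n_boot, seed = seed)
  )
}
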