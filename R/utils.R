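# Internal numeric and validation helpers shared across modules.

# log(sum(exp(x))) without overflow; returns -Inf for an empty or all -Inf input.
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamps tiny negative differences to -Inf.
log_diff_exp <- function(a, b) {
  if (b == -Inf) return(a)
  if (a <= b) return(-Inf)
  a + log1p(-exp(b - a))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  # keep counts beyond integer range (e.g. huge GWAS n) as doubles
  if (x <= .Machine$integer.max) as.integer(x) else as.numeric(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         inclusive_lower = TRUE, inclusive_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (inclusive_lower) x >= lower else x > lower) &&
    (if (inclusive_upper) x <= upper else x < upper)
  if (!ok) abort(sprintf("`%s` must be a single number in the documented range.", name))
  as.numeric(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# DNA complement for single-base alleles.
complement_allele <- function(a) {
  unname(c(A = "T", T = "A", C = "G", G = "C")[a])
}

is_palindromic <- function(ea, oa) {
  oa == complement_allele(ea)
}

# 95% normal CI bounds around an estimate.
ci_bounds <- function(estimate, se) {
  z <- qnorm(0.975)
  list(lower = estimate - z * se, upper = estimate + z * se)
}

two_sided_p <- function(z) {
  2 * pnorm(-abs(z))
}
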