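# Orchestration of the full metabolome-wide MR study: instruments ->
# harmonization (with proxies) -> MR -> FDR prioritization -> sensitivity ->
# MVMR -> colocalization -> reverse MR -> enrichment -> validation, with a
# run manifest tracking the per-stage funnel counts.

#' Study configuration
#'
#' Collects every numeric analysis choice with field-standard defaults:
#' genome-wide instrument threshold `p_iv = 5e-8`, clumping `r2 < 0.001`
#' within a 500 kb window, proxy `r2 > 0.8`, weak-instrument cut `F < 10`,
#' FDR 0.05, colocalization priors `p1 = p2 = 1e-4`, `p12 = 1e-5` with an H4
#' verdict threshold of 0.8, region MAF floor 0.01, and an early-menopause
#' exclusion cutoff of 45 years.
#'
#' @param p_iv,clump_r2,window_kb,proxy_r2,f_min,fdr,h4,maf_min,early_cutoff
#'   Thresholds (see description).
#' @param p1,p2,p12 Colocalization priors.
#' @param coloc_half_width Region half-width in bp (1 Mb total span).
#' @param palindrome_maf_limit Harmonization ambiguity limit.
#' @param presso_n_sim Simulations for the pleiotropy outlier test.
#' @param n_boot Bootstrap replicates for median/mode estimators.
#' @param seed Seed driving every stochastic stage.
#' @param sensitivity_all Run sensitivity/coloc on all metabolites rather
#'   than only FDR-passing ones (default FALSE, the study design).
#' @return A `study_config` list.
#' @export
study_config <- function(p_iv = 5e-8, clump_r2 = 0.001, window_kb = 500,
                         proxy_r2 = 0.8, f_min = 10, fdr = 0.05, h4 = 0.8,
                         maf_min = 0.01, early_cutoff = 45,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         coloc_half_width = 5e5, palindrome_maf_limit = 0.42,
                         presso_n_sim = 1000, n_boot = 500, seed = 1L,
                         sensitivity_all = FALSE) {
  check_number(p_iv, "p_iv", lower = 0, upper = 1, inclusive_lower = FALSE)
  check_number(clump_r2, "clump_r2", lower = 0, upper = 1)
  check_number(proxy_r2, "proxy_r2", lower = 0, upper = 1)
  check_number(fdr, "fdr", lower = 0, upper = 1)
  check_number(h4, "h4", lower = 0, upper = 1)
  check_number(maf_min, "maf_min", lower = 0, upper = 0.5)
  cfg <- list(p_iv = p_iv, clump_r2 = clump_r2, window_kb = window_kb,
              proxy_r2 = proxy_r2, f_min = f_min, fdr = fdr, h4 = h4,
              maf_min = maf_min, early_cutoff = early_cutoff,
              p1 = p1, p2 = p2, p12 = p12,
              coloc_half_width = coloc_half_width,
              palindrome_maf_limit = palindrome_maf_limit,
              presso_n_sim = presso_n_sim, n_boot = n_boot,
              seed = check_count(seed, "seed", min = 0L),
              sensitivity_all = sensitivity_all)
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys match [study_config()] arguments.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals[intersect(names(vals), names(formals(study_config)))])
}

#' Run the full metabolome-wide MR pipeline
#'
#' Executes the study stages in order: per-metabolite instrument selection
#' (significance filter, LD clumping, F-statistic strength filter),
#' harmonization against the outcome with LD-proxy substitution, MR
#' estimation (IVW, Wald for single-instrument metabolites), FDR
#' prioritization across all tested metabolites, sensitivity diagnostics on
#' prioritized metabolites with multiple instruments (Cochran's Q, Egger
#' intercept, pleiotropy outlier test, Steiger directionality), multivariable
#' MR with BMI for prioritized metabolites with at least three instruments,
#' per-instrument-region colocalization of prioritized metabolites,
#' reverse-direction MR for colocalized metabolites, over-representation
#' analysis of colocalized metabolites against the annotation table, and the
#' observational validation regressions. Stages with zero eligible inputs
#' are skipped with a recorded reason; the run manifest logs every stage's
#' inclusion/exclusion counts.
#'
#' @param study A list with elements `exposures` (named list of
#'   summary-statistics tibbles), `outcome` (summary-statistics tibble),
#'   `panel` (LD panel), and optionally `bmi` (BMI exposure summary
#'   statistics), `set_db` (annotation tibble), `cohort` (validation
#'   cohort tibble), `outcome_label`.
#' @param config A [study_config()].
#' @return An object of class `mr_study`: a list of result tibbles
#'   (`instruments`, `mr`, `sensitivity`, `mvmr`, `coloc`, `coloc_verdict`,
#'   `reverse_mr`, `ora`, `validation`), the `manifest`, the `config` and
#'   funnel `counts`.
#' @export
run_pipeline <- function(study, config = study_config()) {
  stopifnot(is.list(study), !is.null(study$exposures), !is.null(study$outcome))
  outcome_label <- study$outcome_label %||%
    (if ("trait" %in% names(study$outcome)) study$outcome$trait[1] else "outcome")
  manifest <- list()
  note_stage <- function(stage, n_in, n_out, note = "") {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, n_in = as.integer(n_in), n_out = as.integer(n_out),
      note = note)
  }

  ## 1. instruments ---------------------------------------------------------
  sets <- purrr::imap(study$exposures, function(stats, name) {
    build_instrument_set(stats, study$panel, metabolite = name,
                         p_threshold = config$p_iv,
                         r2_threshold = config$clump_r2,
                         window_kb = config$window_kb)
  })
  has_iv <- vapply(sets, nrow, integer(1)) > 0L
  note_stage("instrument_selection", length(sets), sum(has_iv),
             "metabolites with >= 1 genome-wide-significant clumped IV")
  sets <- sets[has_iv]
  strong <- suppressMessages(filter_weak(sets, config$f_min))
  note_stage("strength_filter", length(sets), length(strong),
             sprintf("F >= %g", config$f_min))
  instruments <- purrr::imap_dfr(strong, function(s, name) {
    dplyr::mutate(tibble::as_tibble(s), metabolite = name,
                  r2_total = attr(s, "r2_total"), f_stat = attr(s, "f_stat"),
                  .before = 1)
  })

  ## 2. harmonization with proxies ------------------------------------------
  harmonized <- purrr::imap(strong, function(s, name) {
    h <- tryCatch(
      suppressMessages(harmonize_with_proxies(
        tibble::as_tibble(s), study$outcome, study$panel,
        r2_min = config$proxy_r2,
        palindrome_maf_limit = config$palindrome_maf_limit)),
      error = function(e) NULL)
    if (!is.null(h)) {
      h$exposure <- name
      h$outcome <- outcome_label
    }
    h
  })
  harmonized <- purrr::compact(harmonized)
  note_stage("harmonization", length(strong), length(harmonized),
             "metabolites with >= 1 harmonized instrument in the outcome")

  ## 3. MR + 4. FDR ---------------------------------------------------------
  if (length(harmonized) == 0L) {
    mr <- mr_result_row("ivw", 0L)[0, ]
    mr$fdr_q <- numeric(0)
    prioritized <- character(0)
    note_stage("mr_estimation", 0, 0, "skipped: no harmonized metabolites")
  } else {
    mr <- purrr::map_dfr(harmonized, function(h) suppressMessages(mr_ivw(h)))
    mr$fdr_q <- fdr_adjust(mr$p)
    prioritized <- mr$exposure[!is.na(mr$fdr_q) & mr$fdr_q <= config$fdr]
    note_stage("mr_estimation", length(harmonized), nrow(mr), "IVW/Wald per metabolite")
    note_stage("fdr_prioritization", nrow(mr), length(prioritized),
               sprintf("FDR q <= %g", config$fdr))
  }

  ## 5. sensitivity ----------------------------------------------------------
  sens_pool <- if (isTRUE(config$sensitivity_all)) names(harmonized) else prioritized
  sens_sets <- harmonized[intersect(names(harmonized), sens_pool)]
  sens_sets <- sens_sets[vapply(sens_sets, nrow, integer(1)) >= 2L]
  sensitivity <- purrr::imap_dfr(sens_sets, function(h, name) {
    k <- nrow(h)
    qi <- cochran_q(h, "ivw")
    eg <- if (k >= 3) mr_egger(h) else NULL
    pr <- mr_presso(h, n_sim = config$presso_n_sim, seed = config$seed)
    st <- steiger_filter(h)
    tibble::tibble(
      metabolite = name, outcome = outcome_label, n_snp = k,
      q = qi$q, q_df = qi$df, q_p = qi$p,
      egger_intercept = if (!is.null(eg)) eg$intercept else NA_real_,
      egger_intercept_p = if (!is.null(eg)) eg$intercept_p else NA_real_,
      presso_global_p = pr$global_p,
      presso_n_outliers = sum(pr$outliers$flagged),
      steiger_verdict = attr(st, "verdict"),
      steiger_min_p = suppressWarnings(min(st$p))
    )
  })
  note_stage("sensitivity", length(sens_pool), nrow(sensitivity),
             "prioritized metabolites with >= 2 instruments")

  ## 6. MVMR with BMI --------------------------------------------------------
  mvmr <- tibble::tibble()
  mv_pool <- intersect(prioritized,
                       names(harmonized)[vapply(harmonized, nrow, integer(1)) >= 3L])
  if (!is.null(study$bmi) && length(mv_pool) > 0L) {
    bmi_set <- build_instrument_set(study$bmi, study$panel, metabolite = "bmi",
                                    p_threshold = config$p_iv,
                                    r2_threshold = config$clump_r2,
                                    window_kb = config$window_kb)
    mvmr <- purrr::map_dfr(mv_pool, function(name) {
      design <- tryCatch(suppressMessages(mvmr_design(
        list(metabolite = harmonized[[name]]$snp, bmi = bmi_set$snp),
        list(metabolite = study$exposures[[name]], bmi = study$bmi),
        study$outcome, panel = study$panel,
        r2_threshold = config$clump_r2, window_kb = config$window_kb)),
        error = function(e) NULL)
      if (is.null(design) || nrow(design) == 0L) return(tibble::tibble())
      res <- mr_mvmr(design, c("beta_metabolite", "beta_bmi"),
                     outcome = outcome_label)
      res$metabolite <- name
      res
    })
    note_stage("mvmr", length(mv_pool),
               length(unique(if ("metabolite" %in% names(mvmr)) mvmr$metabolite else character(0))),
               "prioritized metabolites with >= 3 instruments, BMI-adjusted")
  } else {
    note_stage("mvmr", length(mv_pool), 0,
               if (is.null(study$bmi)) "skipped: no BMI exposure supplied"
               else "skipped: no eligible metabolites")
  }

  ## 7. colocalization -------------------------------------------------------
  coloc <- tibble::tibble()
  coloc_skipped <- character(0)
  if (length(prioritized) > 0L) {
    coloc <- purrr::map_dfr(prioritized, function(name) {
      leads <- harmonized[[name]]$snp[!harmonized[[name]]$proxy]
      purrr::map_dfr(leads, function(lead) {
        region <- tryCatch(
          suppressMessages(extract_region(
            study$exposures[[name]], study$outcome, lead,
            half_width = config$coloc_half_width, maf_min = config$maf_min)),
          error = function(e) NULL)
        if (is.null(region)) return(tibble::tibble())
        res <- coloc_abf(region, p1 = config$p1, p2 = config$p2, p12 = config$p12)
        res$metabolite <- name
        res
      })
    })
    coloc_skipped <- setdiff(prioritized,
      unique(if ("metabolite" %in% names(coloc)) coloc$metabolite else character(0)))
  }
  verdicts <- if (nrow(coloc) > 0L) coloc_verdict(coloc, config$h4) else
    tibble::tibble(metabolite = character(0), n_regions = integer(0),
                   max_pp_h4 = numeric(0), colocalized = logical(0))
  colocalized <- verdicts$metabolite[verdicts$colocalized]
  note_stage("colocalization", length(prioritized), length(colocalized),
             sprintf("metabolites with max PP(H4) > %g; %d skipped (no analyzable region)",
                     config$h4, length(coloc_skipped)))

  ## 8. reverse MR -----------------------------------------------------------
  reverse <- tibble::tibble()
  if (length(colocalized) > 0L) {
    reverse <- purrr::map_dfr(colocalized, function(name) {
      res <- tryCatch(
        suppressMessages(suppressWarnings(reverse_mr(
          study$outcome, study$exposures[[name]], study$panel,
          p_threshold = config$p_iv, r2_threshold = config$clump_r2,
          window_kb = config$window_kb, n_boot = config$n_boot,
          seed = config$seed))),
        error = function(e) tibble::tibble())
      if (nrow(res) > 0L) res$metabolite <- name
      res
    })
    note_stage("reverse_mr", length(colocalized),
               length(unique(if ("metabolite" %in% names(reverse)) reverse$metabolite else character(0))),
               "outcome as exposure")
  } else {
    note_stage("reverse_mr", 0, 0, "skipped: no colocalized metabolites")
  }

  ## 9. enrichment -----------------------------------------------------------
  ora <- tibble::tibble()
  if (!is.null(study$set_db) && length(colocalized) > 0L) {
    universe <- unique(mr$exposure)
    annotated <- intersect(colocalized, unique(study$set_db$metabolite_id))
    if (length(annotated) > 0L) {
      ora <- hypergeom_ora(annotated, study$set_db, universe)
      note_stage("enrichment", length(colocalized), nrow(ora),
                 sprintf("%d colocalized metabolites with identifiers", length(annotated)))
    } else {
      note_stage("enrichment", length(colocalized), 0,
                 "skipped: no colocalized metabolites with identifiers")
    }
  } else {
    note_stage("enrichment", length(colocalized), 0,
               "skipped: no annotation table or no colocalized metabolites")
  }

  ## 10. validation ----------------------------------------------------------
  validation <- tibble::tibble()
  if (!is.null(study$cohort)) {
    cohort <- impute_adjacent(study$cohort)
    grid <- expand.grid(adjust = c(FALSE, TRUE), excl = c(FALSE, TRUE))
    validation <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      linear_validation(
        cohort, "metabolite",
        covariates = if (grid$adjust[i]) "bmi_z_age8" else character(),
        exclude_early = grid$excl[i], early_cutoff = config$early_cutoff)
    })
    note_stage("validation", nrow(study$cohort), nrow(validation),
               "observational models (unadjusted/adjusted x all/late-event)")
  } else {
    note_stage("validation", 0, 0, "skipped: no cohort supplied")
  }

  n_tested <- nrow(mr)
  n_prior <- length(prioritized)
  n_coloc <- length(colocalized)
  n_skip <- length(coloc_skipped)
  counts <- tibble::tibble(
    tested = n_tested,
    prioritized = n_prior,
    non_prioritized = n_tested - n_prior,
    colocalized = n_coloc,
    non_colocalized = n_prior - n_coloc - n_skip,
    coloc_skipped = n_skip
  )

  structure(list(
    instruments = instruments, mr = mr, sensitivity = sensitivity,
    mvmr = mvmr, coloc = coloc, coloc_verdict = verdicts,
    reverse_mr = reverse, ora = ora, validation = validation,
    manifest = dplyr::bind_rows(manifest), counts = counts,
    config = config, config_hash = rlang::hash(config),
    prioritized = prioritized, colocalized = colocalized
  ), class = "mr_study")
}

#' @export
print.mr_study <- function(x, ...) {
  cat("<mr_study>\n")
  cat(sprintf("  tested: %d  prioritized: %d  colocalized: %d\n",
              x$counts$tested, x$counts$prioritized, x$counts$colocalized))
  cat("  tables:", paste(names(x)[vapply(x, is.data.frame, logical(1))],
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a result bundle to tab-separated files
#'
#' One TSV per non-empty result table plus a plain-text run manifest
#' recording the configuration hash, seed and per-stage counts. List columns
#' (per-SNP colocalization contributions) are dropped from the serialized
#' tables.
#'
#' @param bundle An `mr_study` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Tibble manifest of written files (file, n_rows), invisibly.
#' @export
write_results <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "mr_study"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("Cannot create output directory %s.", outdir))
  tables <- c("instruments", "mr", "sensitivity", "mvmr", "coloc",
              "coloc_verdict", "reverse_mr", "ora", "validation", "manifest")
  written <- purrr::map_dfr(tables, function(nm) {
    tab <- bundle[[nm]]
    tab <- tab[!vapply(tab, is.list, logical(1))]
    path <- file.path(outdir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, path, progress = FALSE)
    tibble::tibble(file = basename(path), n_rows = nrow(tab))
  })
  writeLines(c(
    sprintf("config_hash: %s", bundle$config_hash),
    sprintf("seed: %d", bundle$config$seed),
    sprintf("tested: %d", bundle$counts$tested),
    sprintf("prioritized: %d", bundle$counts$prioritized),
    sprintf("colocalized: %d", bundle$counts$colocalized),
    sprintf("tables: %s", paste(written$file, collapse = ", "))
  ), file.path(outdir, "run_manifest.txt"))
  invisible(written)
}
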