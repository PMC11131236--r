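# broom-style accessors and ggplot2 visualisations for pipeline results.

#' @method tidy mr_study
#' @export
tidy.mr_study <- function(x, ...) {
  x$mr
}

#' @method glance mr_study
#' @export
glance.mr_study <- function(x, ...) {
  dplyr::bind_cols(x$counts, tibble::tibble(config_hash = x$config_hash))
}

#' Forest plot of MR estimates
#'
#' Point estimates with 95% confidence intervals, one row per metabolite,
#' prioritized metabolites highlighted.
#'
#' @param mr_table An MR results tibble (e.g. `tidy()` of an `mr_study`)
#'   with columns exposure, estimate, ci_lower, ci_upper and optionally
#'   fdr_q.
#' @param fdr Highlighting threshold on `fdr_q` (default 0.05).
#' @return A ggplot object.
#' @export
plot_forest <- function(mr_table, fdr = 0.05) {
  check_columns(mr_table, c("exposure", "estimate", "ci_lower", "ci_upper"),
                "`mr_table`")
  d <- dplyr::filter(mr_table, !is.na(.data$estimate))
  d$prioritized <- if ("fdr_q" %in% names(d)) !is.na(d$fdr_q) & d$fdr_q <= fdr else FALSE
  d$exposure <- stats::reorder(d$exposure, d$estimate)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$exposure,
                                  colour = .data$prioritized)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper), height = 0.2) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#B2182B"),
                                 name = "FDR-prioritized") +
    ggplot2::labs(x = "Causal estimate (years per SD of metabolite)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked posterior-probability plot for colocalization results
#'
#' @param coloc_table A tibble of [coloc_abf()] rows with a `metabolite`
#'   column.
#' @return A ggplot object.
#' @export
plot_coloc <- function(coloc_table) {
  check_columns(coloc_table, c("metabolite", "lead", paste0("pp_h", 0:4)),
                "`coloc_table`")
  long <- tidyr::pivot_longer(
    coloc_table[c("metabolite", "lead", paste0("pp_h", 0:4))],
    dplyr::starts_with("pp_"), names_to = "hypothesis", values_to = "pp")
  long$hypothesis <- toupper(sub("pp_", "", long$hypothesis))
  long$region <- paste(long$metabolite, long$lead, sep = " / ")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pp, y = .data$region,
                                     fill = .data$hypothesis)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "Posterior probability", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_study
#' @export
autoplot.mr_study <- function(object, ...) {
  plot_forest(object$mr, fdr = object$config$fdr)
}
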