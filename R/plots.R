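# ggplot2 views of the main result types. Each autoplot returns a ggplot the
# caller can restyle.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs facet_wrap theme_minimal scale_y_continuous
NULL

#' Plot a convergence series
#'
#' Pearson correlation between consecutive tumor samples against the relapse
#' number, one line per patient; rising lines show the progressive
#' convergence of the methylome over serial relapses.
#'
#' @param object A `meth_convergence` tibble ([convergence_series()] or the
#'   pipeline's `convergence` element).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_convergence <- function(object, ...) {
  ggplot(object, aes(x = .data$to_timepoint, y = .data$pearson_r,
                     group = .data$patient_id, colour = .data$patient_id)) +
    geom_line() +
    geom_point(aes(shape = .data$fallback_used)) +
    scale_y_continuous(limits = c(NA, 1)) +
    labs(x = "relapse number", y = "Pearson r vs previous sample",
         colour = "patient", shape = "fallback pair") +
    theme_minimal()
}

#' Plot per-patient trajectory category fractions
#'
#' Stacked bars of the seven dynamic DMC categories (plus the excluded
#' polarity-switch class) per patient.
#'
#' @param object A `meth_categories` tibble ([category_fractions()]).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_categories <- function(object, ...) {
  ggplot(object, aes(x = .data$patient_id, y = .data$fraction,
                     fill = .data$category)) +
    geom_col() +
    facet_wrap(~subtype, scales = "free_x") +
    labs(x = NULL, y = "fraction of classified DMCs", fill = "category") +
    theme_minimal()
}

#' Plot methylation-expression integration results
#'
#' Scatter of the per-gene Pearson correlation between DMR methylation and
#' expression against the DEG log2 fold change; concordant (anticorrelated,
#' direction-matched) genes are highlighted.
#'
#' @param object A `meth_integration` tibble ([integrate_expression()]).
#' @param degs The matching [call_degs()] table (for fold changes).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_integration <- function(object, degs, ...) {
  dat <- as_tibble(object) |>
    left_join(degs |> select("gene_id", "log2_fold_change"), by = "gene_id") |>
    filter(.data$evaluated)
  ggplot(dat, aes(x = .data$pearson_r, y = .data$log2_fold_change,
                  colour = .data$concordant)) +
    geom_point() +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "Pearson r (DMR methylation vs expression)",
         y = "log2 fold change (tumor vs normal)",
         colour = "concordant") +
    theme_minimal()
}
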