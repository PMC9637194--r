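#' @importFrom broom tidy glance
NULL

#' Tidy a pipeline result into its candidate table
#'
#' @param x A `relapse_pipeline`.
#' @param ... Ignored.
#' @return The candidate-call tibble (one row per driver/booster/predictor
#'   site with evidence columns).
#' @exportS3Method broom::tidy
tidy.relapse_pipeline <- function(x, ...) {
  as_tibble(x$candidates)
}

#' One-row pipeline overview
#'
#' @param x A `relapse_pipeline`.
#' @param ... Ignored.
#' @return A one-row tibble with headline counts: tested sites, DMC
#'   comparisons, candidates by kind, mean convergence r, mean PDOX fidelity.
#' @exportS3Method broom::glance
glance.relapse_pipeline <- function(x, ...) {
  n_kind <- function(k) sum(x$candidates$kind == k)
  tibble(
    n_sites_tested = x$summary$n_sites_tested,
    n_comparisons = length(unique(x$dmc_calls$sample_id)),
    n_drivers = n_kind("driver"),
    n_boosters = n_kind("booster"),
    n_predictors = n_kind("predictor"),
    mean_convergence_r = mean(x$convergence$pearson_r),
    mean_pdox_fidelity = if (nrow(x$fidelity) > 0) {
      mean(x$fidelity$pearson_r)
    } else {
      NA_real_
    }
  )
}

#' @export
broom::tidy

#' @export
broom::glance

#' @export
ggplot2::autoplot
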