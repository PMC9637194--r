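#' Configuration for the synthetic relapse cohort generator
#'
#' Bundles and validates every knob of [simulate_cohort()]. The defaults
#' describe the study conditions the pipeline is designed around: two
#' molecular subtypes (supratentorial RELA-fusion and posterior fossa group A),
#' five serially relapsing patients per subtype with relapse counts of
#' 7, 2, 1, 4, 1 (RELA) and 3, 2, 1, 2, 3 (PFA), one additional non-recurrent
#' primary per subtype, RRBS-scale coverage, and planted driver / booster /
#' predictor / switch methylation signals arranged in promoter-sized clusters.
#'
#' @param n_patients_per_subtype Recurring patients per subtype.
#' @param n_relapses_per_patient Named list with elements `RELA` and `PFA`,
#'   each an integer vector of per-patient relapse counts (length
#'   `n_patients_per_subtype`). A single unnamed vector is recycled to both
#'   subtypes.
#' @param n_sites Number of CpG sites in the simulated genome.
#' @param n_chroms Number of chromosomes the sites are spread over.
#' @param mean_coverage Mean sequencing depth per site per sample
#'   (reads; Poisson).
#' @param n_driver_sites,n_booster_sites,n_predictor_sites,n_switch_sites
#'   Total planted sites of each kind, split evenly over subtype and
#'   direction and laid out in clusters of `cluster_size` adjacent CpGs.
#' @param delta_driver,delta_booster Planted methylation-ratio shift for
#'   driver and booster sites, in (0, 1].
#' @param delta_predictor Planted shift for predictor sites; at least 0.8 so
#'   that planted predictors clear the top-candidate ranking threshold.
#' @param convergence_rate Mixing weight in \[0, 1\] pulling each relapse's
#'   epigenetic drift field toward the patient's attractor profile; positive
#'   values make consecutive-relapse correlation increase over serial
#'   recurrences.
#' @param pdox_noise_sd Gaussian noise (ratio scale) added to the matched
#'   patient sample when deriving each PDOX methylome, truncated to \[0, 1\].
#' @param n_genes Number of genes in the annotation / expression matrix.
#' @param frac_genes_methylation_coupled Probability that the gene placed at
#'   a planted driver/booster/predictor cluster is expression-coupled to its
#'   promoter methylation.
#' @param include_nonrecurrent_primary Add one non-recurrent primary tumor
#'   per subtype (required by the predictor discovery procedure).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @param n_normals_per_tissue Normal reference samples per tissue
#'   (cerebrum for RELA, cerebellum for PFA).
#' @param frac_cpa_sites Additional non-CpG (CpA) sites, as a fraction of
#'   `n_sites`; tumors carry a globally reduced CpA methylation level.
#' @param cpa_tumor_factor Multiplicative reduction of CpA methylation in
#'   tumors relative to normal tissue.
#' @param cluster_size CpGs per planted cluster (adjacent sites ~60 bp apart).
#' @param drift_sd Standard deviation of the per-patient epigenetic drift
#'   field applied to background CpGs (ratio scale).
#' @param expr_mean_log,expr_sd_log Log-normal parameters of baseline gene
#'   expression means.
#' @param expr_slope Natural-log fold change of a coupled gene's expression
#'   per unit promoter methylation change (negative: hypermethylation
#'   represses).
#' @param nb_size Negative-binomial size (inverse dispersion) of expression
#'   counts.
#'
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_sites = 2000, seed = 7)
#' cfg$n_driver_sites
cohort_config <- function(n_patients_per_subtype = 5,
                          n_relapses_per_patient = list(
                            RELA = c(7L, 2L, 1L, 4L, 1L),
                            PFA = c(3L, 2L, 1L, 2L, 3L)
                          ),
                          n_sites = 50000,
                          n_chroms = 20,
                          mean_coverage = 50,
                          n_driver_sites = 300,
                          n_booster_sites = 300,
                          n_predictor_sites = 200,
                          n_switch_sites = 200,
                          delta_driver = 0.5,
                          delta_booster = 0.5,
                          delta_predictor = 0.8,
                          convergence_rate = 0.6,
                          pdox_noise_sd = 0.05,
                          n_genes = 1000,
                          frac_genes_methylation_coupled = 0.5,
                          include_nonrecurrent_primary = TRUE,
                          seed = 1,
                          n_normals_per_tissue = 5,
                          frac_cpa_sites = 0.05,
                          cpa_tumor_factor = 0.4,
                          cluster_size = 5,
                          drift_sd = 0.25,
                          expr_mean_log = log(500),
                          expr_sd_log = 1,
                          expr_slope = -2,
                          nb_size = 10) {
  if (is.numeric(n_relapses_per_patient)) {
    n_relapses_per_patient <- list(
      RELA = as.integer(n_relapses_per_patient),
      PFA = as.integer(n_relapses_per_patient)
    )
  }
  cfg <- structure(
    list(
      n_patients_per_subtype = as.integer(n_patients_per_subtype),
      n_relapses_per_patient = lapply(n_relapses_per_patient, as.integer),
      n_sites = as.integer(n_sites),
      n_chroms = as.integer(n_chroms),
      mean_coverage = mean_coverage,
      n_driver_sites = as.integer(n_driver_sites),
      n_booster_sites = as.integer(n_booster_sites),
      n_predictor_sites = as.integer(n_predictor_sites),
      n_switch_sites = as.integer(n_switch_sites),
      delta_driver = delta_driver,
      delta_booster = delta_booster,
      delta_predictor = delta_predictor,
      convergence_rate = convergence_rate,
      pdox_noise_sd = pdox_noise_sd,
      n_genes = as.integer(n_genes),
      frac_genes_methylation_coupled = frac_genes_methylation_coupled,
      include_nonrecurrent_primary = isTRUE(include_nonrecurrent_primary),
      seed = as.integer(seed),
      n_normals_per_tissue = as.integer(n_normals_per_tissue),
      frac_cpa_sites = frac_cpa_sites,
      cpa_tumor_factor = cpa_tumor_factor,
      cluster_size = as.integer(cluster_size),
      drift_sd = drift_sd,
      expr_mean_log = expr_mean_log,
      expr_sd_log = expr_sd_log,
      expr_slope = expr_slope,
      nb_size = nb_size
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) {
    abort(paste0("invalid cohort_config field `", field, "`: ", why),
          class = "methrelapse_config_error")
  }
  pos_int <- function(field, min = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v < min) {
      bad(field, paste("must be a single integer >=", min))
    }
  }
  pos_int("n_patients_per_subtype")
  pos_int("n_sites")
  pos_int("n_chroms")
  pos_int("n_genes")
  pos_int("n_normals_per_tissue")
  pos_int("cluster_size", min = 3L)
  for (f in c("n_driver_sites", "n_booster_sites",
              "n_predictor_sites", "n_switch_sites")) {
    if (cfg[[f]] < 0) bad(f, "must be nonnegative")
  }
  if (!setequal(names(cfg$n_relapses_per_patient), c("RELA", "PFA"))) {
    bad("n_relapses_per_patient", "must be a list with elements RELA and PFA")
  }
  for (st in c("RELA", "PFA")) {
    v <- cfg$n_relapses_per_patient[[st]]
    if (length(v) != cfg$n_patients_per_subtype || any(v < 1)) {
      bad("n_relapses_per_patient",
          paste0(st, " must give >=1 relapse for each of ",
                 cfg$n_patients_per_subtype, " patients"))
    }
  }
  if (cfg$mean_coverage <= 0) bad("mean_coverage", "must be positive")
  unit <- function(field, lo = 0, hi = 1, lo_open = FALSE) {
    v <- cfg[[field]]
    if (length(v) != 1 || is.na(v) || v > hi || v < lo ||
        (lo_open && v == lo)) {
      bad(field, paste0("must lie in ", if (lo_open) "(" else "[",
                        lo, ", ", hi, "]"))
    }
  }
  unit("delta_driver", lo_open = TRUE)
  unit("delta_booster", lo_open = TRUE)
  unit("delta_predictor", lo = 0.8)
  unit("convergence_rate")
  unit("frac_genes_methylation_coupled")
  unit("frac_cpa_sites")
  unit("cpa_tumor_factor")
  if (cfg$pdox_noise_sd < 0) bad("pdox_noise_sd", "must be nonnegative")
  planted <- cfg$n_driver_sites + cfg$n_booster_sites +
    cfg$n_predictor_sites + cfg$n_switch_sites
  if (planted > cfg$n_sites) {
    bad("n_sites", "planted site counts exceed n_sites")
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  patients/subtype:", x$n_patients_per_subtype,
      "(+1 non-recurrent)"[x$include_nonrecurrent_primary], "\n")
  cat("  relapses RELA:", paste(x$n_relapses_per_patient$RELA, collapse = ","),
      " PFA:", paste(x$n_relapses_per_patient$PFA, collapse = ","), "\n")
  cat("  sites:", x$n_sites, " coverage:", x$mean_coverage, "x\n")
  cat("  planted driver/booster/predictor/switch:",
      x$n_driver_sites, x$n_booster_sites,
      x$n_predictor_sites, x$n_switch_sites, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
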