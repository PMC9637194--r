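#' Pipeline thresholds and parameters
#'
#' Collects every tunable threshold of the end-to-end analysis with the
#' canonical defaults: coverage of at least five reads, DMC calling at
#' |delta| >= 0.2 and q <= 0.05, the stricter cross-patient consistency
#' filter at mean |delta| > 0.3, the predictor top-candidate threshold at
#' mean |delta| >= 0.8, a +/- 5 kb TSS window, DMR merging at gap <= 300 bp
#' and >= 3 member DMCs, and DEG calling at FDR <= 0.05 with fold change
#' >= 2 (|log2FC| >= 1).
#'
#' @param min_reads Coverage filter (reads).
#' @param dmc_delta,dmc_q Per-sample DMC thresholds.
#' @param driver_delta Strict mean-|delta| consistency threshold.
#' @param predictor_delta Inclusive predictor ranking threshold.
#' @param tss_window TSS window half-width (bp).
#' @param dmr_max_gap,dmr_min_dmcs DMR merging parameters.
#' @param deg_q,deg_log2fc DEG thresholds.
#' @param top_k Number of top-variable CpGs to report (capped at the
#'   eligible count).
#' @param seed Recorded for provenance; the pipeline itself is deterministic.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_reads = 5L, dmc_delta = 0.2, dmc_q = 0.05,
                            driver_delta = 0.3, predictor_delta = 0.8,
                            tss_window = 5000L, dmr_max_gap = 300L,
                            dmr_min_dmcs = 3L, deg_q = 0.05, deg_log2fc = 1,
                            top_k = 2000L, seed = 1L) {
  cfg <- list(min_reads = as.integer(min_reads), dmc_delta = dmc_delta,
              dmc_q = dmc_q, driver_delta = driver_delta,
              predictor_delta = predictor_delta,
              tss_window = as.integer(tss_window),
              dmr_max_gap = as.integer(dmr_max_gap),
              dmr_min_dmcs = as.integer(dmr_min_dmcs),
              deg_q = deg_q, deg_log2fc = deg_log2fc,
              top_k = as.integer(top_k), seed = as.integer(seed))
  stopifnot(cfg$min_reads >= 1, cfg$dmc_delta >= 0, cfg$dmc_delta <= 1,
            cfg$dmc_q > 0, cfg$dmc_q <= 1, cfg$driver_delta >= 0,
            cfg$driver_delta <= 1, cfg$predictor_delta >= 0,
            cfg$predictor_delta <= 1, cfg$tss_window >= 0,
            cfg$dmr_max_gap >= 1, cfg$dmr_min_dmcs >= 1, cfg$deg_q > 0,
            cfg$deg_q <= 1, cfg$deg_log2fc >= 0, cfg$top_k >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' Run the full longitudinal methylation analysis
#'
#' Executes every stage in dependency order on a cohort (simulated via
#' [simulate_cohort()] or read from disk via [read_cohort()]): coverage
#' filtering and per-sample DMC calling against the matched normal,
#' trajectory classification and category fractions, cross-patient shared
#' consistent-DMC sets with UpSet-style tallies, driver / booster / predictor
#' discovery, PDOX preservation filtering and summary, DMR merging and TSS
#' gene assignment for driver and booster candidates, DEG calling and
#' methylation-expression integration, and the cohort metrics (convergence
#' series, PDOX global fidelity, top-variable CpGs, CpG/CpA context means).
#'
#' @param cohort A `meth_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @return An object of class `relapse_pipeline`: a list of result tibbles
#'   plus a JSON-ready `summary` list. See the vignette for a tour.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  validate_sample_sheet(cohort$samples)
  sheet <- cohort$samples
  cfg <- config

  cpg <- lapply(cohort$methylation, function(tbl)
    filter_coverage(tbl[tbl$context == "CpG", , drop = FALSE],
                    cfg$min_reads))

  test_samples <- sheet |>
    filter(.data$role %in% c("primary", "relapse", "pdox"))
  dmc_calls <- map_dfr(seq_len(nrow(test_samples)), function(i) {
    s <- test_samples$sample_id[i]
    call_dmcs(cpg[[s]], cpg[[test_samples$matched_normal_id[i]]],
              delta_min = cfg$dmc_delta, q_max = cfg$dmc_q) |>
      mutate(sample_id = s)
  })
  tumor_calls <- dmc_calls |>
    filter(.data$sample_id %in%
             (sheet |> filter(.data$role %in% c("primary", "relapse")) |>
                pull("sample_id")))

  trajectories <- build_state_sequences(tumor_calls, sheet)
  fractions <- category_fractions(trajectories)

  subtypes <- sort(unique(stats::na.omit(sheet$subtype)))
  shared_sets <- lapply(setNames(subtypes, subtypes), function(st) {
    pats <- trajectories |>
      filter(.data$subtype == st) |> distinct(.data$patient_id) |>
      pull("patient_id")
    lapply(setNames(c("ConsistentHyper", "ConsistentHypo"),
                    c("Hyper", "Hypo")), function(cat) {
      sets <- lapply(setNames(pats, pats), function(p)
        trajectories$site_id[trajectories$patient_id == p &
                               trajectories$covered &
                               trajectories$category == cat])
      if (length(sets) >= 2) intersect_patients(sets) else NULL
    })
  })

  candidates <- map_dfr(subtypes, function(st) {
    bind_rows(
      find_drivers(trajectories, tumor_calls, sheet, st,
                   delta_min = cfg$driver_delta),
      find_boosters(trajectories, tumor_calls, sheet, st),
      tryCatch(
        find_predictors(tumor_calls, sheet, st,
                        delta_top = cfg$predictor_delta),
        methrelapse_missing_reference = function(e) {
          warn(conditionMessage(e))
          candidate_skeleton()
        })
    )
  })
  candidates <- pdox_filter(candidates, dmc_calls, sheet)
  preservation <- preservation_summary(candidates)

  dmrs <- candidates |>
    filter(.data$kind %in% c("driver", "booster")) |>
    group_by(kind = .data$kind, subtype = .data$subtype) |>
    reframe({
      inp <- pick("chrom", "start", "end", "direction", "mean_delta") |>
        rename(delta = "mean_delta") |>
        arrange_sites()
      merge_dmrs(inp, max_gap = cfg$dmr_max_gap, min_dmcs = cfg$dmr_min_dmcs)
    })
  gene_hits <- if (nrow(dmrs) > 0) {
    dmrs |>
      group_by(.data$kind, .data$subtype) |>
      reframe(
        assign_genes(pick(dplyr::everything()), cohort$genes,
                     window = cfg$tss_window) |>
          left_join(pick(dplyr::everything()) |>
                      select("dmr_id", "site_ids"), by = "dmr_id")
      )
  } else {
    tibble(kind = character(), subtype = character(), dmr_id = character(),
           gene_id = character(), chrom = character(), distance = integer(),
           direction = character(), mean_delta = numeric(),
           site_ids = character())
  }

  tissue_of <- c(RELA = "normal_cerebrum", PFA = "normal_cerebellum")
  degs <- lapply(setNames(subtypes, subtypes), function(st) {
    tum <- sheet |>
      filter(.data$subtype == st, .data$role %in% c("primary", "relapse")) |>
      pull("sample_id")
    norm <- sheet |>
      filter(.data$role == tissue_of[[st]]) |> pull("sample_id")
    if (length(tum) < 2 || length(norm) < 2) return(NULL)
    cols <- c(tum, norm)
    call_degs(cohort$expression[c("gene_id", cols)],
              setNames(rep(c("tumor", "normal"),
                           c(length(tum), length(norm))), cols),
              q_max = cfg$deg_q, lfc_min = cfg$deg_log2fc)
  })

  integration <- map_dfr(subtypes, function(st) {
    hits <- gene_hits |> filter(.data$subtype == st)
    if (nrow(hits) == 0 || is.null(degs[[st]])) return(tibble())
    tum <- sheet |>
      filter(.data$subtype == st, .data$role %in% c("primary", "relapse")) |>
      pull("sample_id")
    norm <- sheet |> filter(.data$role == tissue_of[[st]]) |>
      pull("sample_id")
    cols <- c(tum, norm)
    meth <- dmr_gene_methylation(hits, cohort$methylation[cols],
                                 min_reads = cfg$min_reads)
    cpm <- cpm_normalize(cohort$expression[c("gene_id", cols)])
    expr <- bind_cols(cpm[1], as_tibble(log2(as.matrix(cpm[-1]) + 1)))
    integrate_expression(hits, degs[[st]], meth, expr) |>
      mutate(subtype = st)
  })
  class(integration) <- unique(c("meth_integration", class(integration)))

  patients <- sheet |>
    filter(.data$role %in% c("primary", "relapse")) |>
    count(.data$patient_id) |>
    filter(.data$n >= 2) |>
    pull("patient_id")
  convergence <- map_dfr(patients, function(p)
    convergence_series(cpg, sheet, p, min_reads = cfg$min_reads))
  class(convergence) <- unique(c("meth_convergence", class(convergence)))

  pdox_sheet <- sheet |> filter(.data$role == "pdox")
  fidelity <- map_dfr(seq_len(nrow(pdox_sheet)), function(i) {
    global_fidelity(cohort$methylation[[pdox_sheet$pdox_of[i]]],
                    cohort$methylation[[pdox_sheet$sample_id[i]]],
                    min_reads = cfg$min_reads) |>
      mutate(sample_id = pdox_sheet$sample_id[i],
             pdox_of = pdox_sheet$pdox_of[i])
  })

  context_summary <- imap_dfr(cohort$methylation, function(tbl, s) {
    tibble(sample_id = s,
           mean_cpg = summarize_context(tbl, "CpG", cfg$min_reads),
           mean_cpa = suppressWarnings(
             summarize_context(tbl, "CpA", cfg$min_reads)))
  }) |>
    left_join(sheet |> select("sample_id", "role", "subtype"),
              by = "sample_id")

  ratios <- ratio_matrix(cpg, min_reads = cfg$min_reads)
  n_eligible <- sum(stats::complete.cases(
    ratios[setdiff(names(ratios), c("site_id", "chrom", "start"))]))
  top_var <- top_variable_cpgs(ratios, min(cfg$top_k, n_eligible))

  summary <- list(
    schema_version = "1.0",
    n_samples = nrow(sheet),
    n_sites_tested = length(unique(tumor_calls$site_id)),
    category_fractions = as.data.frame(fractions),
    shared_set_sizes = imap_dfr(shared_sets, function(dirs, st)
      imap_dfr(dirs, function(ix, dir)
        tibble(subtype = st, direction = dir,
               n_shared = if (is.null(ix)) NA_integer_
                          else length(ix$shared)))) |>
      as.data.frame(),
    candidate_counts = candidates |>
      count(.data$kind, .data$subtype, .data$direction) |>
      as.data.frame(),
    preservation = as.data.frame(preservation),
    convergence = convergence |>
      select("patient_id", "from_sample", "to_sample", "pearson_r",
             "fallback_used") |>
      as.data.frame(),
    pdox_fidelity = as.data.frame(fidelity),
    n_top_variable = nrow(top_var)
  )

  structure(
    list(dmc_calls = dmc_calls, trajectories = trajectories,
         category_fractions = fractions, shared_sets = shared_sets,
         candidates = candidates, preservation = preservation,
         dmrs = dmrs, gene_hits = gene_hits, degs = degs,
         integration = integration, convergence = convergence,
         fidelity = fidelity, context_summary = context_summary,
         top_variable = top_var, summary = summary, config = cfg),
    class = "relapse_pipeline"
  )
}

#' @export
print.relapse_pipeline <- function(x, ...) {
  cat("<relapse_pipeline>\n")
  cat("  DMC comparisons:", length(unique(x$dmc_calls$sample_id)), "\n")
  cat("  candidates:",
      paste(capture_counts(x$candidates), collapse = ", "), "\n")
  cat("  convergence pairs:", nrow(x$convergence), "\n")
  invisible(x)
}

capture_counts <- function(candidates) {
  if (nrow(candidates) == 0) return("none")
  cc <- candidates |> count(.data$kind)
  paste0(cc$n, " ", cc$kind)
}

#' Write every pipeline output table plus a summary JSON
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(tbl, name) {
    readr::write_tsv(as_tibble(tbl), file.path(dir, paste0(name, ".tsv")))
  }
  w(pipeline$dmc_calls, "dmc_calls")
  w(pipeline$trajectories, "trajectories")
  w(pipeline$category_fractions, "category_fractions")
  w(pipeline$candidates, "candidates")
  w(pipeline$preservation, "preservation")
  w(pipeline$dmrs, "dmrs")
  w(pipeline$gene_hits, "gene_hits")
  for (st in names(pipeline$degs)) {
    if (!is.null(pipeline$degs[[st]])) {
      w(pipeline$degs[[st]], paste0("degs_", st))
    }
  }
  w(pipeline$integration, "integration")
  w(pipeline$convergence, "convergence")
  w(pipeline$fidelity, "pdox_fidelity")
  w(pipeline$context_summary, "context_summary")
  w(pipeline$top_variable, "top_variable_cpgs")
  jsonlite::write_json(pipeline$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
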