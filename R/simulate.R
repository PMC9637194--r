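#' Simulate a serially relapsing tumor methylation cohort
#'
#' Generates a complete synthetic cohort with planted ground truth:
#' per-sample CpG (and CpA) methylation count tables, a sample sheet covering
#' normal tissues, primaries, serial relapses, a non-recurrent primary per
#' subtype and matched PDOX samples, a gene annotation, an expression count
#' matrix negatively coupled to promoter methylation, and truth tables naming
#' every planted signal.
#'
#' The generative model:
#' \itemize{
#'   \item Normal-tissue CpG methylation is drawn from a bimodal beta mixture
#'     (0.55 Beta(1,10) + 0.45 Beta(10,1)), mimicking the low/high modes of
#'     real CpG methylation; CpA sites are lowly methylated (Beta(2,30)).
#'   \item Planted sites come in clusters of adjacent CpGs and are shifted by
#'     a fixed delta: \emph{driver} sites in the primary and every relapse of
#'     every patient of the subtype (including the non-recurrent primary);
#'     \emph{booster} sites in every relapse but not the primary;
#'     \emph{predictor} sites (|delta| >= 0.8) in recurring patients'
#'     primaries and all their relapses but not in the non-recurrent primary;
#'     \emph{switch} sites at a random half of timepoints.
#'   \item Background CpGs carry a patient-specific epigenetic drift field
#'     that mixes toward a per-patient attractor at each relapse
#'     (`u_t = (1 - rate) * u_(t-1) + rate * attractor`), so consecutive
#'     relapses grow more correlated.
#'   \item Read counts are Poisson totals with binomial methylated reads;
#'     PDOX methylomes are the matched patient sample plus truncated Gaussian
#'     noise; expression counts are negative binomial with coupled genes'
#'     means scaled by `exp(slope * promoter methylation change)`.
#' }
#'
#' @param config A [cohort_config()].
#' @return An object of class `meth_cohort`: a list with elements
#'   `methylation` (named list of per-sample site tibbles), `samples`
#'   (sample sheet tibble), `genes` (gene annotation tibble), `expression`
#'   (gene-by-sample count tibble), `truth` (list of `sites`, `genes`,
#'   `attractors` tibbles), `true_ratios` (latent design ratio matrix,
#'   sites x samples) and `config`.
#' @export
#' @examples
#' co <- simulate_cohort(cohort_config(n_sites = 1000, n_genes = 100,
#'                                     seed = 42))
#' names(co$methylation)[1:4]
#' dplyr::count(co$truth$sites, label)
simulate_cohort <- function(config = cohort_config()) {
  cfg <- validate_cohort_config(config)
  set.seed(cfg$seed)

  layout <- layout_sites(cfg)
  sites <- layout$sites
  sheet <- build_sample_sheet(cfg)
  base <- draw_baseline(sites, cfg)
  true_ratios <- build_true_ratios(sites, base, sheet, cfg)
  methylation <- draw_counts(sites, true_ratios, cfg)
  genes <- place_genes(sites, layout$clusters, cfg)
  expression <- draw_expression(genes, sites, base, true_ratios, sheet, cfg)

  sgn <- ifelse(sites$direction %in% "hyper", 1,
                ifelse(sites$direction %in% "hypo", -1, 0))
  truth_sites <- sites |>
    mutate(
      normal_ratio = base,
      design_tumor_ratio = clamp01(base + sgn * coalesce(.data$delta, 0))
    ) |>
    select("site_id", "chrom", "start", "end", "context", "label",
           "subtype", "direction", "delta", "cluster_id",
           "normal_ratio", "design_tumor_ratio")

  truth_genes <- genes |>
    mutate(label = case_when(
      .data$coupled & .data$direction == "hyper" ~ "hyper_down",
      .data$coupled & .data$direction == "hypo" ~ "hypo_up",
      TRUE ~ "unlinked"
    )) |>
    select("gene_id", "label", "cluster_id", "kind", "subtype", "coupled")

  attractors <- sheet |>
    filter(.data$role %in% c("primary", "relapse")) |>
    transmute(.data$sample_id, attractor_id = .data$patient_id)

  structure(
    list(
      methylation = methylation,
      samples = sheet,
      genes = genes |>
        select("gene_id", "chrom", "tss", "strand"),
      expression = expression,
      truth = list(sites = truth_sites, genes = truth_genes,
                   attractors = attractors),
      true_ratios = true_ratios,
      config = cfg
    ),
    class = "meth_cohort"
  )
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat("<meth_cohort>\n")
  cat("  samples:", nrow(x$samples),
      sprintf("(%d tumor, %d normal, %d pdox)",
              sum(x$samples$role %in% c("primary", "relapse")),
              sum(startsWith(x$samples$role, "normal")),
              sum(x$samples$role == "pdox")), "\n")
  cat("  sites:", nrow(x$methylation[[1]]), "\n")
  if (!is.null(x$truth)) {
    cat("  planted sites:", sum(x$truth$sites$label != "baseline"), "\n")
  }
  cat("  genes:", nrow(x$genes), "\n")
  invisible(x)
}

# ---- internals --------------------------------------------------------------

layout_sites <- function(cfg) {
  kinds <- tibble(
    kind = c("driver", "booster", "predictor", "switch"),
    n_kind = c(cfg$n_driver_sites, cfg$n_booster_sites,
               cfg$n_predictor_sites, cfg$n_switch_sites),
    delta = c(cfg$delta_driver, cfg$delta_booster,
              cfg$delta_predictor, cfg$delta_driver)
  )
  strata <- tidyr::crossing(kinds,
                            subtype = c("RELA", "PFA"),
                            direction = c("hyper", "hypo")) |>
    mutate(n_clusters = (.data$n_kind %/% 4L) %/% cfg$cluster_size)
  clusters <- strata[rep(seq_len(nrow(strata)), strata$n_clusters),
                     c("kind", "subtype", "direction", "delta")]
  clusters$cluster_id <- sprintf("cl%04d", seq_len(nrow(clusters)))

  n_planted <- nrow(clusters) * cfg$cluster_size
  n_bg <- cfg$n_sites - n_planted
  if (n_bg < 0) {
    abort("invalid cohort_config field `n_sites`: too small for planted clusters",
          class = "methrelapse_config_error")
  }
  n_cpa <- round(cfg$frac_cpa_sites * cfg$n_sites)

  units <- tibble(
    type = c(rep("bg", n_bg), rep("cpa", n_cpa),
             rep("cluster", nrow(clusters))),
    cluster_row = c(rep(NA_integer_, n_bg + n_cpa), seq_len(nrow(clusters)))
  )
  units <- units[sample.int(nrow(units)), ]
  units$chrom <- paste0("chr", rep_len(seq_len(cfg$n_chroms), nrow(units)))
  units$width <- ifelse(units$type == "cluster",
                        (cfg$cluster_size - 1L) * 60L + 2L, 2L)
  units$gap <- as.integer(round(runif(nrow(units), 500, 1500)))
  units <- units |>
    group_by(.data$chrom) |>
    mutate(unit_start = cumsum(.data$gap) +
             cumsum(dplyr::lag(.data$width, default = 0L))) |>
    ungroup()

  n_per_unit <- ifelse(units$type == "cluster", cfg$cluster_size, 1L)
  sites <- units[rep(seq_len(nrow(units)), n_per_unit), ]
  sites$start <- sites$unit_start +
    unlist(lapply(n_per_unit, function(k) seq(0L, by = 60L, length.out = k)))
  sites$end <- sites$start + 2L
  sites$context <- ifelse(sites$type == "cpa", "CpA", "CpG")

  sites <- sites |>
    left_join(clusters |> mutate(cluster_row = dplyr::row_number()),
              by = "cluster_row") |>
    mutate(
      label = case_when(
        .data$kind %in% c("driver", "booster", "predictor") ~
          paste0(.data$kind, "_", .data$direction),
        .data$kind == "switch" ~ "switch",
        TRUE ~ "baseline"
      )
    ) |>
    arrange_sites() |>
    mutate(site_id = site_id(.data$chrom, .data$start)) |>
    select("site_id", "chrom", "start", "end", "context", "label",
           "kind", "subtype", "direction", "delta", "cluster_id")

  planted <- sites |> filter(!is.na(.data$cluster_id))
  cluster_pos <- if (nrow(planted) == 0) {
    tibble(cluster_id = character(), kind = character(),
           subtype = character(), direction = character(),
           chrom = character(), cluster_start = integer(),
           cluster_end = integer())
  } else {
    planted |>
      group_by(.data$cluster_id, .data$kind, .data$subtype, .data$direction,
               .data$chrom) |>
      summarise(cluster_start = min(.data$start),
                cluster_end = max(.data$end), .groups = "drop")
  }

  list(sites = sites, clusters = cluster_pos)
}

build_sample_sheet <- function(cfg) {
  tissue_of <- c(RELA = "cerebrum", PFA = "cerebellum")
  normals <- map_dfr(c("RELA", "PFA"), function(st) {
    tis <- tissue_of[[st]]
    tibble(
      sample_id = paste0("NORM_", tis, "_", seq_len(cfg$n_normals_per_tissue)),
      patient_id = paste0("ND_", tis, "_", seq_len(cfg$n_normals_per_tissue)),
      subtype = NA_character_,
      role = paste0("normal_", tis),
      timepoint = NA_integer_,
      matched_normal_id = NA_character_,
      pdox_of = NA_character_,
      recurred = NA
    )
  }) |> distinct()

  tumors <- map_dfr(c("RELA", "PFA"), function(st) {
    tis <- tissue_of[[st]]
    ref <- paste0("NORM_", tis, "_1")
    per_pat <- map_dfr(seq_len(cfg$n_patients_per_subtype), function(p) {
      pid <- paste0(st, p)
      k <- cfg$n_relapses_per_patient[[st]][p]
      tibble(
        sample_id = c(paste0(pid, "_P"), paste0(pid, "_R", seq_len(k))),
        patient_id = pid,
        subtype = st,
        role = c("primary", rep("relapse", k)),
        timepoint = 0:k,
        matched_normal_id = ref,
        pdox_of = NA_character_,
        recurred = TRUE
      )
    })
    if (cfg$include_nonrecurrent_primary) {
      pid <- paste0(st, cfg$n_patients_per_subtype + 1L)
      per_pat <- bind_rows(per_pat, tibble(
        sample_id = paste0(pid, "_P"), patient_id = pid, subtype = st,
        role = "primary", timepoint = 0L, matched_normal_id = ref,
        pdox_of = NA_character_, recurred = FALSE
      ))
    }
    per_pat
  })

  pdox <- tumors |>
    filter(.data$recurred) |>
    group_by(.data$patient_id) |>
    slice_max(.data$timepoint, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(
      pdox_of = .data$sample_id,
      sample_id = paste0("PDOX_", .data$sample_id),
      role = "pdox"
    )

  bind_rows(normals, tumors, pdox)
}

draw_baseline <- function(sites, cfg) {
  n <- nrow(sites)
  base <- numeric(n)
  bg <- which(sites$label == "baseline" & sites$context == "CpG")
  lows <- rbeta(length(bg), 1, 10)
  highs <- rbeta(length(bg), 10, 1)
  base[bg] <- ifelse(runif(length(bg)) < 0.55, lows, highs)
  cpa <- which(sites$context == "CpA")
  base[cpa] <- rbeta(length(cpa), 2, 30)
  hyper <- which(sites$direction %in% "hyper")
  if (length(hyper) > 0) {
    hi <- pbeta(1 - sites$delta[hyper], 1, 10)
    base[hyper] <- qbeta(runif(length(hyper), 0, hi), 1, 10)
  }
  hypo <- which(sites$direction %in% "hypo")
  if (length(hypo) > 0) {
    lo <- pbeta(sites$delta[hypo], 10, 1)
    base[hypo] <- qbeta(runif(length(hypo), lo, 1), 10, 1)
  }
  base
}

build_true_ratios <- function(sites, base, sheet, cfg) {
  n <- nrow(sites)
  M <- matrix(NA_real_, n, nrow(sheet),
              dimnames = list(sites$site_id, sheet$sample_id))
  is_bg <- sites$label == "baseline" & sites$context == "CpG"
  is_cpa <- sites$context == "CpA"
  n_bg <- sum(is_bg)
  n_cpa <- sum(is_cpa)
  sgn <- ifelse(sites$direction %in% "hyper", 1,
                ifelse(sites$direction %in% "hypo", -1, 0))
  planted_delta <- sgn * coalesce(sites$delta, 0)

  for (i in which(startsWith(sheet$role, "normal"))) {
    M[, i] <- base
  }

  tumor_sheet <- sheet |> filter(.data$role %in% c("primary", "relapse"))
  for (pid in unique(tumor_sheet$patient_id)) {
    rows <- tumor_sheet |>
      filter(.data$patient_id == pid) |>
      arrange(.data$timepoint)
    st <- rows$subtype[1]
    recurred <- isTRUE(rows$recurred[1])
    of_subtype <- sites$subtype %in% st
    idx_driver <- which(of_subtype & sites$kind %in% "driver")
    idx_booster <- which(of_subtype & sites$kind %in% "booster")
    idx_pred <- which(of_subtype & sites$kind %in% "predictor")
    idx_switch <- which(of_subtype & sites$kind %in% "switch")

    attractor <- numeric(n)
    attractor[is_bg] <- rnorm(n_bg, 0, cfg$drift_sd)
    u <- NULL
    for (j in seq_len(nrow(rows))) {
      tp <- rows$timepoint[j]
      if (is.null(u)) {
        u <- numeric(n)
        u[is_bg] <- rnorm(n_bg, 0, cfg$drift_sd)
      } else {
        u <- (1 - cfg$convergence_rate) * u + cfg$convergence_rate * attractor
      }
      dvec <- numeric(n)
      dvec[idx_driver] <- planted_delta[idx_driver]
      if (tp >= 1) dvec[idx_booster] <- planted_delta[idx_booster]
      if (recurred) dvec[idx_pred] <- planted_delta[idx_pred]
      if (length(idx_switch) > 0) {
        on <- runif(length(idx_switch)) < 0.5
        dvec[idx_switch[on]] <- planted_delta[idx_switch[on]]
      }
      ratio <- clamp01(base + dvec + u)
      if (n_cpa > 0) {
        ratio[is_cpa] <- clamp01(base[is_cpa] * cfg$cpa_tumor_factor +
                                   rnorm(n_cpa, 0, 0.02))
      }
      M[, rows$sample_id[j]] <- ratio
    }
  }

  pdox_sheet <- sheet |> filter(.data$role == "pdox")
  for (j in seq_len(nrow(pdox_sheet))) {
    src <- M[, pdox_sheet$pdox_of[j]]
    M[, pdox_sheet$sample_id[j]] <- clamp01(src + rnorm(n, 0, cfg$pdox_noise_sd))
  }
  M
}

draw_counts <- function(sites, true_ratios, cfg) {
  n <- nrow(sites)
  out <- lapply(colnames(true_ratios), function(s) {
    total <- rpois(n, cfg$mean_coverage)
    meth <- rbinom(n, total, true_ratios[, s])
    tibble(
      chrom = sites$chrom,
      start = sites$start,
      end = sites$end,
      context = sites$context,
      ratio = ifelse(total > 0, meth / total, 0),
      meth_reads = meth,
      total_reads = total
    )
  })
  setNames(out, colnames(true_ratios))
}

place_genes <- function(sites, clusters, cfg) {
  with_genes <- clusters |>
    filter(.data$kind %in% c("driver", "booster", "predictor")) |>
    mutate(
      tss = pmax(0L, .data$cluster_start +
                   as.integer(round(runif(dplyr::n(), -3000, 3000)))),
      coupled = runif(dplyr::n()) < cfg$frac_genes_methylation_coupled
    )
  if (nrow(with_genes) > cfg$n_genes) {
    abort("invalid cohort_config field `n_genes`: fewer genes than planted clusters",
          class = "methrelapse_config_error")
  }
  n_rest <- cfg$n_genes - nrow(with_genes)
  chrom_span <- sites |>
    group_by(.data$chrom) |>
    summarise(span = max(.data$end), .groups = "drop")
  rest_chrom <- chrom_span$chrom[
    sample.int(nrow(chrom_span), n_rest, replace = TRUE)]
  rest <- tibble(
    chrom = rest_chrom,
    tss = as.integer(round(runif(
      n_rest, 0, chrom_span$span[match(rest_chrom, chrom_span$chrom)]))),
    cluster_id = NA_character_, kind = NA_character_,
    subtype = NA_character_, direction = NA_character_,
    coupled = FALSE
  )
  genes <- bind_rows(
    with_genes |>
      select("chrom", "tss", "cluster_id", "kind", "subtype",
             "direction", "coupled"),
    rest
  )
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes <- genes |> arrange(chrom_rank(.data$chrom), .data$tss)
  genes$gene_id <- sprintf("GENE%04d", seq_len(nrow(genes)))
  genes |>
    select("gene_id", "chrom", "tss", "strand", "cluster_id", "kind",
           "subtype", "direction", "coupled")
}

draw_expression <- function(genes, sites, base, true_ratios, sheet, cfg) {
  n_genes <- nrow(genes)
  n_samples <- nrow(sheet)
  mu0 <- rlnorm(n_genes, cfg$expr_mean_log, cfg$expr_sd_log)
  shift <- matrix(0, n_genes, n_samples)
  coupled_idx <- which(genes$coupled)
  for (g in coupled_idx) {
    idx <- which(sites$cluster_id %in% genes$cluster_id[g])
    meth <- colMeans(true_ratios[idx, , drop = FALSE])
    shift[g, ] <- cfg$expr_slope * (meth - mean(base[idx]))
  }
  libf <- rlnorm(n_samples, 0, 0.15)
  mu <- (mu0 %o% libf) * exp(shift)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = cfg$nb_size),
                   nrow = n_genes)
  colnames(counts) <- sheet$sample_id
  bind_cols(tibble(gene_id = genes$gene_id), as_tibble(counts))
}
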