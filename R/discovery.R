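# Candidate discovery. All three procedures operate per subtype and return a
# common candidate-call tibble so they can share the PDOX filter and the
# downstream region/gene annotation:
#   kind, level, subtype, site_id, chrom, start, end, direction, mean_delta,
#   supporting_patients, present_in_all_relapses, rank_score, top

candidate_skeleton <- function() {
  tibble(
    kind = character(), level = character(), subtype = character(),
    site_id = character(), chrom = character(), start = integer(),
    end = integer(), direction = character(), mean_delta = numeric(),
    supporting_patients = character(), present_in_all_relapses = logical(),
    rank_score = numeric(), top = logical()
  )
}

site_coords <- function(dmc_calls, ids) {
  dmc_calls |>
    filter(.data$site_id %in% ids) |>
    distinct(.data$site_id, .data$chrom, .data$start, .data$end)
}

#' Find candidate methylation drivers of relapse
#'
#' A driver site carries the same abnormal methylation state (consistent
#' Hyper or consistent Hypo) from the primary through every relapse of every
#' patient of the subtype, and its mean absolute tumor-vs-normal ratio
#' difference across all tumor samples of the subtype strictly exceeds
#' `delta_min`.
#'
#' @param trajectories [build_state_sequences()] output.
#' @param dmc_calls Stacked [call_dmcs()] tibble with `sample_id`.
#' @param sample_sheet Sample sheet.
#' @param subtype `"RELA"` or `"PFA"`.
#' @param delta_min Strict mean-|delta| threshold (default 0.3).
#' @return Candidate tibble (kind = `"driver"`).
#' @export
find_drivers <- function(trajectories, dmc_calls, sample_sheet, subtype,
                         delta_min = 0.3) {
  traj <- trajectories |> filter(.data$subtype == !!subtype, .data$covered)
  pats <- sort(unique(traj$patient_id))
  if (length(pats) == 0) return(candidate_skeleton())
  if (length(pats) < 2) {
    warn(paste0("subtype ", subtype,
                " has a single patient with trajectories; ",
                "driver sharing cannot be established across patients"))
  }
  shared_dir <- function(cat) {
    sets <- lapply(pats, function(p)
      traj$site_id[traj$patient_id == p & traj$category == cat])
    names(sets) <- pats
    if (length(sets) == 1) sets[[1]] else intersect_patients(sets)$shared
  }
  shared <- c(shared_dir("ConsistentHyper"), shared_dir("ConsistentHypo"))
  if (length(shared) == 0) return(candidate_skeleton())
  # delta averaged over the supporting patients' tumor samples: sharing is
  # established across the patients with trajectories, so the consistency
  # filter uses those same patients' samples
  tumor_samples <- sample_sheet |>
    filter(.data$subtype == !!subtype, .data$patient_id %in% pats,
           .data$role %in% c("primary", "relapse")) |>
    pull("sample_id")
  kept <- apply_consistency_delta(shared, dmc_calls, tumor_samples,
                                  delta_min = delta_min)
  if (nrow(kept) == 0) return(candidate_skeleton())
  kept |>
    left_join(site_coords(dmc_calls, kept$site_id), by = "site_id") |>
    transmute(
      kind = "driver", level = "DMC", subtype = !!subtype,
      .data$site_id, .data$chrom, .data$start, .data$end,
      .data$direction, .data$mean_delta,
      supporting_patients = paste(pats, collapse = ","),
      present_in_all_relapses = TRUE,
      rank_score = abs(.data$mean_delta), top = NA
    ) |>
    arrange_sites()
}

#' Find candidate methylation boosters of relapse
#'
#' A booster site is newly acquired at relapse: NoChange in the primary and
#' the same polar state at every relapse, in every patient of the subtype.
#' Patients lacking a primary sample cannot certify "absent in primary" and
#' are excluded from the support with a warning.
#'
#' @inheritParams find_drivers
#' @return Candidate tibble (kind = `"booster"`); mean_delta is averaged over
#'   the subtype's relapse samples.
#' @export
find_boosters <- function(trajectories, dmc_calls, sample_sheet, subtype) {
  traj <- trajectories |> filter(.data$subtype == !!subtype, .data$covered)
  no_primary <- traj |>
    distinct(.data$patient_id, .data$has_primary) |>
    filter(!.data$has_primary)
  if (nrow(no_primary) > 0) {
    warn(paste0("excluding patient(s) without a primary sample from booster ",
                "support: ", paste(no_primary$patient_id, collapse = ", ")))
    traj <- traj |> filter(.data$has_primary)
  }
  pats <- sort(unique(traj$patient_id))
  if (length(pats) == 0) return(candidate_skeleton())
  shared_dir <- function(pattern) {
    sets <- lapply(pats, function(p)
      traj$site_id[traj$patient_id == p & grepl(pattern, traj$state_code)])
    names(sets) <- pats
    if (length(sets) == 1) sets[[1]] else intersect_patients(sets)$shared
  }
  hyper <- shared_dir("^NH+$")
  hypo <- shared_dir("^NL+$")
  ids <- c(hyper, hypo)
  if (length(ids) == 0) return(candidate_skeleton())
  relapse_samples <- sample_sheet |>
    filter(.data$subtype == !!subtype, .data$role == "relapse") |>
    pull("sample_id")
  deltas <- dmc_calls |>
    filter(.data$sample_id %in% relapse_samples, .data$site_id %in% ids) |>
    group_by(.data$site_id) |>
    summarise(mean_delta = mean(.data$delta), .groups = "drop")
  tibble(site_id = ids,
         direction = rep(c("Hyper", "Hypo"),
                         c(length(hyper), length(hypo)))) |>
    left_join(deltas, by = "site_id") |>
    left_join(site_coords(dmc_calls, ids), by = "site_id") |>
    transmute(
      kind = "booster", level = "DMC", subtype = !!subtype,
      .data$site_id, .data$chrom, .data$start, .data$end,
      .data$direction, .data$mean_delta,
      supporting_patients = paste(pats, collapse = ","),
      present_in_all_relapses = TRUE,
      rank_score = abs(.data$mean_delta), top = NA
    ) |>
    arrange_sites()
}

#' Find candidate relapse predictors in primary tumors
#'
#' A predictor site is a same-direction DMC in the primary tumor of every
#' patient who eventually recurred, is covered but \emph{not} a DMC in any
#' non-recurrent reference primary, and is a same-direction DMC in every
#' relapse sample of the subtype. Candidates are ranked by the mean absolute
#' ratio difference across the recurring primaries; those with
#' `rank_score >= delta_top` (inclusive) are flagged as top candidates.
#'
#' @param dmc_calls Stacked [call_dmcs()] tibble with `sample_id`.
#' @param sample_sheet Sample sheet; needs `recurred` flags and at least one
#'   non-recurrent primary of the subtype.
#' @param subtype `"RELA"` or `"PFA"`.
#' @param delta_top Inclusive threshold on the rank score (default 0.8).
#' @return Candidate tibble (kind = `"predictor"`), sorted by rank_score
#'   descending.
#' @export
find_predictors <- function(dmc_calls, sample_sheet, subtype,
                            delta_top = 0.8) {
  sheet <- sample_sheet |> filter(.data$subtype == !!subtype)
  rec_prim <- sheet |>
    filter(.data$role == "primary", .data$recurred) |> pull("sample_id")
  nonrec_prim <- sheet |>
    filter(.data$role == "primary", !.data$recurred) |> pull("sample_id")
  relapse <- sheet |> filter(.data$role == "relapse") |> pull("sample_id")
  if (length(nonrec_prim) == 0) {
    abort(paste0("no non-recurrent reference primary for subtype ", subtype,
                 "; predictor specificity cannot be established"),
          class = "methrelapse_missing_reference")
  }
  if (length(rec_prim) == 0 || length(relapse) == 0) {
    return(candidate_skeleton())
  }
  calls <- dmc_calls |>
    filter(.data$sample_id %in% c(rec_prim, nonrec_prim, relapse))

  dmc_in_all <- function(samples, dir) {
    hits <- calls |>
      filter(.data$sample_id %in% samples, .data$direction == dir) |>
      count(.data$site_id)
    hits$site_id[hits$n == length(samples)]
  }
  nochange_in_all_nonrec <- {
    hits <- calls |>
      filter(.data$sample_id %in% nonrec_prim,
             .data$direction == "NoChange") |>
      count(.data$site_id)
    hits$site_id[hits$n == length(nonrec_prim)]
  }
  per_dir <- function(dir) {
    Reduce(intersect, list(dmc_in_all(rec_prim, dir),
                           dmc_in_all(relapse, dir),
                           nochange_in_all_nonrec))
  }
  hyper <- per_dir("Hyper")
  hypo <- per_dir("Hypo")
  ids <- c(hyper, hypo)
  if (length(ids) == 0) return(candidate_skeleton())
  ranks <- calls |>
    filter(.data$sample_id %in% rec_prim, .data$site_id %in% ids) |>
    group_by(.data$site_id) |>
    summarise(rank_score = mean(abs(.data$delta)),
              mean_delta = mean(.data$delta), .groups = "drop")
  rec_pats <- sheet |>
    filter(.data$sample_id %in% rec_prim) |> pull("patient_id")
  tibble(site_id = ids,
         direction = rep(c("Hyper", "Hypo"),
                         c(length(hyper), length(hypo)))) |>
    left_join(ranks, by = "site_id") |>
    left_join(site_coords(calls, ids), by = "site_id") |>
    transmute(
      kind = "predictor", level = "DMC", subtype = !!subtype,
      .data$site_id, .data$chrom, .data$start, .data$end,
      .data$direction, .data$mean_delta,
      supporting_patients = paste(sort(rec_pats), collapse = ","),
      present_in_all_relapses = TRUE,
      rank_score = .data$rank_score,
      top = .data$rank_score >= delta_top
    ) |>
    arrange(desc(.data$rank_score))
}

#' Filter candidates by PDOX preservation
#'
#' A candidate is preserved when, in every available PDOX sample derived from
#' its supporting patients, the site is a same-direction DMC against the same
#' normal reference. Candidates with no matched PDOX sample are kept with
#' `pdox_preserved = NA` (not evaluated).
#'
#' @param candidates Candidate tibble from [find_drivers()],
#'   [find_boosters()] or [find_predictors()].
#' @param dmc_calls Stacked [call_dmcs()] tibble that includes the PDOX
#'   samples (each tested against its patient's matched normal).
#' @param sample_sheet Sample sheet with the pdox_of mapping.
#' @return `candidates` with a `pdox_preserved` logical column added.
#' @export
pdox_filter <- function(candidates, dmc_calls, sample_sheet) {
  if (nrow(candidates) == 0) {
    return(candidates |> mutate(pdox_preserved = logical(0)))
  }
  src_patient <- sample_sheet$patient_id[
    match(sample_sheet$pdox_of, sample_sheet$sample_id)]
  pdox_sheet <- sample_sheet |>
    mutate(source_patient = src_patient) |>
    filter(.data$role == "pdox")
  pdox_calls <- dmc_calls |>
    filter(.data$sample_id %in% pdox_sheet$sample_id) |>
    select("sample_id", "site_id", pdox_direction = "direction")

  expanded <- candidates |>
    mutate(.cand = dplyr::row_number(),
           patient_id = strsplit(.data$supporting_patients, ",")) |>
    tidyr::unnest("patient_id") |>
    inner_join(pdox_sheet |>
                 select(pdox_sample = "sample_id",
                        patient_id = "source_patient"),
               by = "patient_id", relationship = "many-to-many") |>
    left_join(pdox_calls,
              by = c(pdox_sample = "sample_id", "site_id"))
  verdict <- expanded |>
    group_by(.data$.cand) |>
    summarise(pdox_preserved = all(!is.na(.data$pdox_direction) &
                                     .data$pdox_direction == .data$direction),
              .groups = "drop")
  candidates |>
    mutate(.cand = dplyr::row_number()) |>
    left_join(verdict, by = ".cand") |>
    select(-".cand")
}

#' Preservation percentage, as printed in summaries
#'
#' @param preserved,total Counts of preserved and evaluated candidates.
#' @return `100 * preserved / total` rounded to one decimal place.
#' @export
#' @examples
#' preservation_percent(479, 529)
preservation_percent <- function(preserved, total) {
  round(100 * preserved / total, 1)
}

#' Summarize PDOX preservation by candidate kind and direction
#'
#' @param candidates Candidate tibble with a `pdox_preserved` column
#'   ([pdox_filter()] output); rows with `NA` (not evaluated) are excluded
#'   from the denominators.
#' @return Tibble: kind, subtype, direction, preserved, total, percent.
#' @export
preservation_summary <- function(candidates) {
  candidates |>
    filter(!is.na(.data$pdox_preserved)) |>
    group_by(.data$kind, .data$subtype, .data$direction) |>
    summarise(preserved = sum(.data$pdox_preserved),
              total = dplyr::n(), .groups = "drop") |>
    mutate(percent = preservation_percent(.data$preserved, .data$total))
}

#' Planted-signal recovery of the discovery procedures
#'
#' Compares recovered candidate sites against the generator's truth table.
#' Planted predictor sites instantiate the driver pattern among the recurring
#' patients by construction (consistent same-direction DMCs from primary
#' through every relapse), so driver recovery is scored against the union of
#' planted driver and predictor sites; predictor recovery is scored against
#' planted predictors only, and booster recovery against planted boosters.
#'
#' @param candidates Stacked candidate tibble (any mix of kinds/subtypes).
#' @param truth_sites The `truth$sites` tibble of a [simulate_cohort()]
#'   object.
#' @return Tibble: kind, subtype, n_recovered, n_truth, true_positive,
#'   precision, recall.
#' @export
planted_recovery <- function(candidates, truth_sites) {
  truth_for <- function(kind, st) {
    labs <- switch(kind,
      driver = c("driver_hyper", "driver_hypo",
                 "predictor_hyper", "predictor_hypo"),
      booster = c("booster_hyper", "booster_hypo"),
      predictor = c("predictor_hyper", "predictor_hypo")
    )
    truth_sites$site_id[truth_sites$label %in% labs &
                          truth_sites$subtype %in% st]
  }
  combos <- candidates |> distinct(.data$kind, .data$subtype)
  purrr::pmap_dfr(combos, function(kind, subtype) {
    rec <- unique(candidates$site_id[candidates$kind == kind &
                                       candidates$subtype == subtype])
    tr <- truth_for(kind, subtype)
    tp <- length(intersect(rec, tr))
    tibble(kind = kind, subtype = subtype,
           n_recovered = length(rec), n_truth = length(tr),
           true_positive = tp,
           precision = tp / length(rec), recall = tp / length(tr))
  })
}
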