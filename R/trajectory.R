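TRAJECTORY_CATEGORIES <- c(
  "ConsistentHyper", "ConsistentHypo", "GainHyper", "GainHypo",
  "LossHyper", "LossHypo", "Switch", "ExcludedPolaritySwitch"
)

#' Build per-site longitudinal state sequences for each patient
#'
#' Joins the per-timepoint DMC calls of each patient (every timepoint tested
#' against the same matched normal) into one ordered state sequence per site:
#' primary first (if present), then relapses in order. Sites not tested at
#' every timepoint (coverage failure at any stage) are marked `Uncovered`
#' and carry no category. Patients lacking a primary sample are kept — their
#' earliest available sample acts as timepoint 0 — and flagged via
#' `has_primary`.
#'
#' @param dmc_calls Tibble of [call_dmcs()] results for tumor samples,
#'   stacked, with a `sample_id` column.
#' @param sample_sheet Sample sheet covering those samples.
#' @return A tibble with one row per (patient, site): patient_id, subtype,
#'   site_id, chrom, start, n_timepoints, has_primary, covered, `state_code`
#'   (compact letters, H = Hyper, L = Hypo, N = NoChange), `states`
#'   (comma-separated full names) and `category` (see
#'   [classify_trajectory()]; `Uncovered` where coverage fails).
#' @export
build_state_sequences <- function(dmc_calls, sample_sheet) {
  stopifnot("sample_id" %in% names(dmc_calls))
  tumor_sheet <- sample_sheet |>
    filter(.data$role %in% c("primary", "relapse"),
           .data$sample_id %in% unique(dmc_calls$sample_id))
  counts <- tumor_sheet |> count(.data$patient_id)
  if (all(counts$n < 2)) {
    abort("classification impossible: no patient has >= 2 timepoints",
          class = "methrelapse_classification_error")
  }
  keep_pat <- counts$patient_id[counts$n >= 2]
  tumor_sheet <- tumor_sheet |>
    filter(.data$patient_id %in% keep_pat) |>
    arrange(.data$patient_id, .data$timepoint)

  calls <- dmc_calls |>
    inner_join(tumor_sheet |>
                 select("sample_id", "patient_id", "subtype", "timepoint"),
               by = "sample_id")

  map_dfr(unique(tumor_sheet$patient_id), function(pid) {
    pc <- calls |> filter(.data$patient_id == pid)
    tps <- sort(unique(pc$timepoint))
    letters <- c(Hyper = "H", Hypo = "L", NoChange = "N")
    wide <- pc |>
      mutate(letter = letters[.data$direction]) |>
      select("site_id", "chrom", "start", "timepoint", "letter") |>
      pivot_wider(names_from = "timepoint", values_from = "letter",
                  names_prefix = "t", values_fill = "?")
    code_cols <- paste0("t", tps)
    code <- do.call(paste0, wide[code_cols])
    covered <- !grepl("?", code, fixed = TRUE)
    category <- rep("Uncovered", nrow(wide))
    category[covered] <- classify_state_codes(code[covered])
    tibble(
      patient_id = pid,
      subtype = pc$subtype[1],
      site_id = wide$site_id,
      chrom = wide$chrom,
      start = wide$start,
      n_timepoints = length(tps),
      has_primary = 0L %in% tps,
      covered = covered,
      state_code = ifelse(covered, code, NA_character_),
      states = ifelse(
        covered,
        vapply(code, function(s)
          paste(decode_states(s), collapse = ","), character(1),
          USE.NAMES = FALSE),
        NA_character_),
      category = category
    )
  })
}

#' Classify one longitudinal state sequence
#'
#' Assigns a site's ordered tumor-vs-normal state sequence (over
#' Hyper / Hypo / NoChange, primary first then relapses) to one of the seven
#' dynamic categories, with two extra outcomes:
#' \itemize{
#'   \item `ExcludedPolaritySwitch` — any adjacent Hyper/Hypo (or Hypo/Hyper)
#'     pair; such sites are excluded from downstream tallies.
#'   \item `ConsistentHyper` / `ConsistentHypo` — the same polar state at
#'     every timepoint.
#'   \item `GainHyper` / `GainHypo` — a NoChange prefix followed by an
#'     all-polar suffix (one clean acquisition).
#'   \item `LossHyper` / `LossHypo` — a polar prefix followed by a NoChange
#'     suffix (one clean loss).
#'   \item `Switch` — any other pattern touching a polar state (more than one
#'     toggle between a polar state and NoChange, or compound gain-then-loss
#'     patterns).
#'   \item `NoChange` — never differentially methylated; not a DMC, excluded
#'     from category fractions.
#' }
#'
#' @param states Character vector of states (`"Hyper"`, `"Hypo"`,
#'   `"NoChange"`) for one site, length >= 2.
#' @return A single category string.
#' @export
#' @examples
#' classify_trajectory(c("NoChange", "Hyper", "Hyper"))
#' classify_trajectory(c("Hyper", "Hypo", "Hyper"))
classify_trajectory <- function(states) {
  if (length(states) < 2) {
    abort("classification impossible: need >= 2 timepoints",
          class = "methrelapse_classification_error")
  }
  classify_state_codes(encode_states(states))
}

# vectorized core over compact state codes (H/L/N strings)
classify_state_codes <- function(codes) {
  if (any(grepl("[^HLN]", codes))) {
    abort("invalid state symbol in state code")
  }
  dplyr::case_when(
    grepl("HL|LH", codes) ~ "ExcludedPolaritySwitch",
    grepl("^N+$", codes) ~ "NoChange",
    grepl("^H+$", codes) ~ "ConsistentHyper",
    grepl("^L+$", codes) ~ "ConsistentHypo",
    grepl("^N+H+$", codes) ~ "GainHyper",
    grepl("^N+L+$", codes) ~ "GainHypo",
    grepl("^H+N+$", codes) ~ "LossHyper",
    grepl("^L+N+$", codes) ~ "LossHypo",
    TRUE ~ "Switch"
  )
}

#' Per-patient fractions of trajectory categories
#'
#' Fractions of each dynamic category over the classified sites of each
#' patient: covered sites whose sequence touches a polar state (all-NoChange
#' sites are not DMCs and are excluded; `ExcludedPolaritySwitch` sites are
#' tallied so the exclusion rate is visible).
#'
#' @param trajectories Output of [build_state_sequences()].
#' @return A tibble of class `meth_categories`: patient_id, subtype,
#'   category, n, fraction (fractions sum to 1 per patient).
#' @export
category_fractions <- function(trajectories) {
  tallied <- trajectories |>
    filter(.data$covered, !.data$category %in% c("NoChange", "Uncovered")) |>
    count(.data$patient_id, .data$subtype, .data$category) |>
    group_by(.data$patient_id) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  class(tallied) <- c("meth_categories", class(tallied))
  tallied
}

#' Category flow counts between adjacent timepoints
#'
#' Tabulates, for every pair of adjacent timepoints of each patient, how many
#' sites moved from each state to each state — the tabular equivalent of an
#' alluvial diagram of DMC dynamics.
#'
#' @param trajectories Output of [build_state_sequences()].
#' @return Tibble: patient_id, from_timepoint, to_timepoint, state_from,
#'   state_to, n.
#' @export
state_flows <- function(trajectories) {
  lut <- setNames(names(STATE_LETTERS), STATE_LETTERS)
  trajectories |>
    filter(.data$covered) |>
    group_by(.data$patient_id) |>
    reframe({
      codes <- .data$state_code
      tlen <- nchar(codes[1])
      map_dfr(seq_len(tlen - 1), function(j) {
        tibble(
          from_timepoint = j - 1L,
          to_timepoint = j,
          state_from = unname(lut[substr(codes, j, j)]),
          state_to = unname(lut[substr(codes, j + 1, j + 1)])
        )
      })
    }) |>
    count(.data$patient_id, .data$from_timepoint, .data$to_timepoint,
          .data$state_from, .data$state_to)
}
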