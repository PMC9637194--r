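#' Intersect per-patient DMC sets (UpSet-style tallies)
#'
#' Given one site set per patient, computes the sites shared by all patients
#' and the exclusive-intersection tallies familiar from UpSet plots: each
#' nonempty patient combination is counted over the sites belonging to
#' exactly that combination, so the tallies sum to the size of the union.
#'
#' @param sets Named list (>= 2 elements) of character vectors of site keys,
#'   one per patient.
#' @return An object of class `dmc_intersection`: a list with `shared`
#'   (character vector of sites present in every set), `support` (tibble
#'   site_id, n_patients), `tally` (tibble patients, degree, count) and
#'   `membership` (site-by-patient logical tibble).
#' @export
#' @examples
#' ix <- intersect_patients(list(A = c("s1", "s2"), B = c("s2", "s3")))
#' ix$shared
#' ix$tally
intersect_patients <- function(sets) {
  if (length(sets) < 2) abort("need site sets for >= 2 patients")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("sets must be named by patient")
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    empty_membership <- as_tibble(matrix(logical(0), 0, length(sets),
                                         dimnames = list(NULL, names(sets))))
    return(structure(
      list(shared = character(0),
           support = tibble(site_id = character(0), n_patients = integer(0)),
           tally = tibble(patients = character(0), degree = integer(0),
                          count = integer(0)),
           membership = bind_cols(tibble(site_id = character(0)),
                                  empty_membership)),
      class = "dmc_intersection"))
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(sets)))
  support <- rowSums(membership)
  combo <- apply(membership, 1, function(r)
    paste(names(sets)[r], collapse = "+"))
  tally <- tibble(patients = combo, degree = support) |>
    count(.data$patients, .data$degree, name = "count") |>
    arrange(desc(.data$degree), .data$patients)
  structure(
    list(
      shared = universe[support == length(sets)],
      support = tibble(site_id = universe, n_patients = as.integer(support)),
      tally = tally,
      membership = bind_cols(tibble(site_id = universe),
                             as_tibble(membership))
    ),
    class = "dmc_intersection"
  )
}

#' @export
print.dmc_intersection <- function(x, ...) {
  cat("<dmc_intersection>\n")
  cat("  patients:", ncol(x$membership) - 1, " union:", nrow(x$support),
      " shared by all:", length(x$shared), "\n")
  invisible(x)
}

#' Consistency filter on shared DMC sets
#'
#' Retains sites whose mean absolute tumor-minus-normal ratio difference
#' across all requested tumor samples strictly exceeds `delta_min` (default
#' 0.3) and whose call direction is uniform across those samples. Sites with
#' a delta missing in any sample (untested there) are dropped; the number of
#' such drops is attached as the `n_dropped_missing` attribute.
#'
#' @param sites Character vector of candidate site keys (e.g. the `shared`
#'   element of [intersect_patients()]).
#' @param dmc_calls Stacked [call_dmcs()] tibble with a `sample_id` column.
#' @param sample_ids Tumor samples over which the deltas are averaged
#'   (all tumor samples of the subtype).
#' @param delta_min Strict lower bound on the mean |delta|.
#' @param per_sample If `TRUE`, require |delta| > `delta_min` in every
#'   sample instead of on average.
#' @return Tibble: site_id, direction, mean_delta, n_samples.
#' @export
apply_consistency_delta <- function(sites, dmc_calls, sample_ids,
                                    delta_min = 0.3, per_sample = FALSE) {
  relevant <- dmc_calls |>
    filter(.data$sample_id %in% sample_ids, .data$site_id %in% sites)
  per_site <- relevant |>
    group_by(.data$site_id) |>
    summarise(
      n_samples = dplyr::n(),
      mean_delta = mean(.data$delta),
      mean_abs_delta = mean(abs(.data$delta)),
      min_abs_delta = min(abs(.data$delta)),
      uniform = all(.data$delta > 0) || all(.data$delta < 0),
      .groups = "drop"
    )
  n_dropped <- sum(per_site$n_samples < length(sample_ids)) +
    length(setdiff(sites, per_site$site_id))
  if (n_dropped > 0) {
    warn(paste0(n_dropped,
                " site(s) dropped: delta missing in at least one sample"))
  }
  keep <- per_site |>
    filter(.data$n_samples == length(sample_ids), .data$uniform)
  keep <- if (per_sample) {
    keep |> filter(.data$min_abs_delta > delta_min)
  } else {
    keep |> filter(.data$mean_abs_delta > delta_min)
  }
  out <- keep |>
    transmute(.data$site_id,
              direction = ifelse(.data$mean_delta > 0, "Hyper", "Hypo"),
              mean_delta = .data$mean_delta,
              .data$n_samples)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}
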