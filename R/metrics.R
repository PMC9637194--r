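pearson_shared <- function(a, b, min_reads = 5L) {
  aa <- filter_coverage(a, min_reads)
  bb <- filter_coverage(b, min_reads)
  shared <- inner_join(
    aa |> transmute(.data$chrom, .data$start,
                    ra = .data$meth_reads / .data$total_reads),
    bb |> transmute(.data$chrom, .data$start,
                    rb = .data$meth_reads / .data$total_reads),
    by = c("chrom", "start")
  )
  list(r = if (nrow(shared) >= 2) cor(shared$ra, shared$rb) else NA_real_,
       n = nrow(shared))
}

#' Relapse-to-relapse convergence series for one patient
#'
#' For each tumor sample after the first (ordered by timepoint), computes the
#' Pearson correlation of methylation ratios with the immediately preceding
#' timepoint's sample; when that sample is missing, the nearest earlier
#' available sample is used instead and the pair is flagged
#' (`fallback_used`). Only sites covered by at least `min_reads` reads in
#' both members of a pair contribute.
#'
#' @param methylation Named list of per-sample site tibbles.
#' @param sample_sheet Sample sheet.
#' @param patient_id Patient whose series to compute.
#' @param min_reads Coverage filter (default 5).
#' @param min_sites Pairs with fewer shared covered sites are flagged
#'   (`low_sites`), not dropped.
#' @return A tibble of class `meth_convergence`: patient_id, from_sample,
#'   to_sample, from_timepoint, to_timepoint, pearson_r, n_shared_sites,
#'   fallback_used, low_sites.
#' @export
convergence_series <- function(methylation, sample_sheet, patient_id,
                               min_reads = 5L, min_sites = 100L) {
  rows <- sample_sheet |>
    filter(.data$patient_id == !!patient_id,
           .data$role %in% c("primary", "relapse"),
           .data$sample_id %in% names(methylation)) |>
    arrange(.data$timepoint)
  if (nrow(rows) < 2) {
    abort(paste0("patient ", patient_id,
                 " has fewer than 2 tumor samples with methylation data"))
  }
  out <- map_dfr(2:nrow(rows), function(j) {
    later <- rows[j, ]
    earlier <- rows[j - 1, ]
    ps <- pearson_shared(methylation[[earlier$sample_id]],
                         methylation[[later$sample_id]], min_reads)
    tibble(
      patient_id = patient_id,
      from_sample = earlier$sample_id,
      to_sample = later$sample_id,
      from_timepoint = earlier$timepoint,
      to_timepoint = later$timepoint,
      pearson_r = ps$r,
      n_shared_sites = ps$n,
      fallback_used = later$timepoint - earlier$timepoint > 1L,
      low_sites = ps$n < min_sites
    )
  })
  if (any(out$low_sites)) {
    warn(paste0("convergence pair(s) with fewer than ", min_sites,
                " shared covered sites for patient ", patient_id))
  }
  class(out) <- c("meth_convergence", class(out))
  out
}

#' Global methylome fidelity between a patient sample and its PDOX
#'
#' Pearson correlation of methylation ratios over all sites covered by at
#' least `min_reads` reads in both the patient tumor and the matched
#' patient-derived orthotopic xenograft sample.
#'
#' @param patient_tbl,pdox_tbl Site tibbles for the matched pair.
#' @param min_reads Coverage filter.
#' @return One-row tibble: pearson_r, n_shared_sites.
#' @export
global_fidelity <- function(patient_tbl, pdox_tbl, min_reads = 5L) {
  ps <- pearson_shared(patient_tbl, pdox_tbl, min_reads)
  if (ps$n == 0) {
    abort("no shared covered sites between patient and PDOX sample")
  }
  tibble(pearson_r = ps$r, n_shared_sites = ps$n)
}

#' Build a site-by-sample methylation ratio matrix
#'
#' Empirical ratios (meth/total) with NA where a site fails the coverage
#' filter in a sample.
#'
#' @param methylation Named list of per-sample site tibbles.
#' @param min_reads Coverage filter.
#' @return Wide tibble: site_id, chrom, start plus one column per sample.
#' @export
ratio_matrix <- function(methylation, min_reads = 5L) {
  long <- imap_dfr(methylation, function(tbl, s) {
    tibble(
      site_id = site_id(tbl$chrom, tbl$start),
      chrom = tbl$chrom,
      start = tbl$start,
      sample_id = s,
      ratio = ifelse(tbl$total_reads >= min_reads,
                     tbl$meth_reads / tbl$total_reads, NA_real_)
    )
  })
  long |>
    pivot_wider(names_from = "sample_id", values_from = "ratio") |>
    arrange_sites()
}

#' Select the most variable CpGs across samples
#'
#' Ranks sites covered in \emph{all} samples (complete cases) by their
#' across-sample ratio variance and returns the top `k`; ties are broken by
#' genome position (natural chromosome order, then start).
#'
#' @param ratios Wide ratio tibble from [ratio_matrix()].
#' @param k Number of sites to select; must not exceed the eligible
#'   (complete-case) count.
#' @return The selected rows of `ratios`, most variable first.
#' @export
top_variable_cpgs <- function(ratios, k) {
  m <- as.matrix(ratios[setdiff(names(ratios),
                                c("site_id", "chrom", "start"))])
  eligible <- which(stats::complete.cases(m))
  if (k > length(eligible)) {
    abort(paste0("k = ", k, " exceeds the ", length(eligible),
                 " sites covered in all samples"))
  }
  v <- apply(m[eligible, , drop = FALSE], 1, var)
  sub <- ratios[eligible, , drop = FALSE]
  ord <- order(-v, chrom_rank(sub$chrom), sub$start, method = "radix")
  sub[head(ord, k), , drop = FALSE]
}
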