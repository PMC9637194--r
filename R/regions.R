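#' Merge neighboring same-direction DMCs into regions
#'
#' Greedily merges maximal runs of same-direction DMCs on the same chromosome
#' whose consecutive start positions are at most `max_gap` apart; runs with
#' at least `min_dmcs` members become differentially methylated regions
#' (DMRs). The region envelope is 0-based half-open over the member sites.
#'
#' @param dmcs Tibble with columns chrom, start, end, direction, delta
#'   (one row per DMC), sorted by natural chromosome order and start.
#' @param max_gap Maximum start-to-start gap (bp) between consecutive member
#'   sites.
#' @param min_dmcs Minimum run length.
#' @return Tibble: dmr_id, chrom, start, end, direction, n_dmcs, mean_delta,
#'   site_ids (comma-separated member keys); disjoint and position-sorted.
#' @export
#' @examples
#' dmcs <- tibble::tibble(chrom = "chr1", start = c(100L, 200L, 350L),
#'                        end = c(102L, 202L, 352L),
#'                        direction = "Hyper", delta = 0.4)
#' merge_dmrs(dmcs)
merge_dmrs <- function(dmcs, max_gap = 300L, min_dmcs = 3L) {
  if (nrow(dmcs) == 0) {
    return(tibble(dmr_id = character(), chrom = character(),
                  start = integer(), end = integer(), direction = character(),
                  n_dmcs = integer(), mean_delta = numeric(),
                  site_ids = character()))
  }
  ord <- order(chrom_rank(dmcs$chrom), dmcs$start, method = "radix")
  if (!identical(ord, seq_len(nrow(dmcs)))) {
    abort("input must be sorted by (chrom, start)",
          class = "methrelapse_input_error")
  }
  new_chrom <- dmcs$chrom != dplyr::lag(dmcs$chrom, default = "")
  gap <- dmcs$start - dplyr::lag(dmcs$start, default = -1L)
  new_dir <- dmcs$direction != dplyr::lag(dmcs$direction, default = "")
  run <- cumsum(new_chrom | new_dir | gap > max_gap)
  dmcs |>
    mutate(.run = run) |>
    group_by(.data$.run) |>
    summarise(
      site_ids = paste(site_id(.data$chrom, .data$start), collapse = ","),
      n_dmcs = dplyr::n(),
      mean_delta = mean(.data$delta),
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      direction = .data$direction[1],
      .groups = "drop"
    ) |>
    filter(.data$n_dmcs >= min_dmcs) |>
    arrange(chrom_rank(.data$chrom), .data$start) |>
    mutate(dmr_id = paste(.data$chrom, .data$start, .data$end, sep = "-")) |>
    select("dmr_id", "chrom", "start", "end", "direction", "n_dmcs",
           "mean_delta", "site_ids")
}

#' Assign DMRs to genes via a TSS window
#'
#' Associates a region with a gene whenever the region interval overlaps the
#' window `[tss - window, tss + window]` around the gene's transcription
#' start site. The window is strand-agnostic ("up/downstream" covers both
#' sides); a region may hit several genes. The reported distance is the
#' signed offset from the TSS to the nearest region edge (0 when the region
#' covers the TSS; negative when the region lies upstream in coordinate
#' terms).
#'
#' @param dmrs [merge_dmrs()] output (needs dmr_id, chrom, start, end).
#' @param genes Gene annotation tibble (gene_id, chrom, tss, strand).
#' @param window Half-width of the TSS window in bp (default 5000).
#' @return Tibble: dmr_id, gene_id, chrom, distance plus the region's
#'   direction/mean_delta columns when present.
#' @export
assign_genes <- function(dmrs, genes, window = 5000L) {
  if (window < 0) abort("window must be >= 0")
  if (nrow(dmrs) == 0 || nrow(genes) == 0) {
    return(tibble(dmr_id = character(), gene_id = character(),
                  chrom = character(), distance = integer()))
  }
  hits <- inner_join(
    dmrs |> select(any_of(c("dmr_id", "chrom", "start", "end", "direction",
                            "mean_delta"))),
    genes |> select("gene_id", "chrom", "tss"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(.data$start <= .data$tss + window,
           .data$end > .data$tss - window) |>
    mutate(distance = case_when(
      .data$start <= .data$tss & .data$tss < .data$end ~ 0L,
      .data$start > .data$tss ~ .data$start - .data$tss,
      TRUE ~ .data$end - 1L - .data$tss
    ))
  hits |>
    select(any_of(c("dmr_id", "gene_id", "chrom", "distance", "direction",
                    "mean_delta"))) |>
    arrange(chrom_rank(.data$chrom), .data$dmr_id, .data$gene_id)
}
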