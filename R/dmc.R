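#' Filter sites by read coverage
#'
#' Retains only sites covered by at least `min_reads` reads; the canonical
#' threshold is five reads, applied before any differential testing.
#'
#' @param records Site tibble (see [read_methylation_table()]).
#' @param min_reads Minimum total reads (inclusive), >= 1.
#' @return The filtered tibble, original order preserved.
#' @export
#' @examples
#' tbl <- tibble::tibble(chrom = "chr1", start = c(0L, 10L), end = c(2L, 12L),
#'                       context = "CpG", ratio = c(0.5, 0.5),
#'                       meth_reads = c(2L, 3L), total_reads = c(4L, 6L))
#' filter_coverage(tbl, 5)
filter_coverage <- function(records, min_reads = 5L) {
  if (min_reads < 1) abort("min_reads must be >= 1")
  records[records$total_reads >= min_reads, , drop = FALSE]
}

#' Two-sided Fisher exact p-values for many 2x2 tables
#'
#' Computes, for each site, the two-sided Fisher exact test of the table
#' \verb{[(meth, unmeth) tumor vs normal]} by exact hypergeometric
#' enumeration: all tables with the observed margins whose probability does
#' not exceed that of the observed table (up to a relative error of 1e-7,
#' the convention used by [stats::fisher.test()]) contribute to the p-value.
#' Vectorized and chunked, so millions of sites are tested in seconds.
#'
#' @param meth1,total1 Methylated and total read counts in the first sample.
#' @param meth2,total2 Counts in the second sample.
#' @param chunk Number of tables per internal chunk.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_p_2x2 <- function(meth1, total1, meth2, total2, chunk = 20000L) {
  n_tab <- length(meth1)
  stopifnot(length(total1) == n_tab, length(meth2) == n_tab,
            length(total2) == n_tab)
  if (any(meth1 > total1 | meth2 > total2 | meth1 < 0 | meth2 < 0)) {
    abort("methylated counts must lie in [0, total]")
  }
  rel_err <- 1 + 1e-7
  p <- numeric(n_tab)
  starts <- seq(1L, n_tab, by = chunk)
  for (s in starts) {
    i <- s:min(s + chunk - 1L, n_tab)
    x <- meth1[i]; m <- total1[i]; y <- meth2[i]; n <- total2[i]
    K <- x + y
    N <- m + n
    lo <- pmax(0L, K - n)
    hi <- pmin(m, K)
    dobs <- dhyper(x, K, N - K, m)
    w <- max(hi - lo + 1L)
    kk <- outer(lo, 0:(w - 1L), `+`)
    dk <- dhyper(kk, K, N - K, m)  # K, N-K, m recycle down columns
    dk[kk > hi] <- 0
    p[i] <- pmin(1, rowSums(dk * (dk <= dobs * rel_err)))
  }
  p[total1 == 0 & total2 == 0] <- 1
  p
}

#' Call differentially methylated cytosines against a matched normal
#'
#' For every site shared between a tumor sample and its matched normal
#' (both assumed coverage-filtered; unmatched sites are dropped), tests the
#' 2x2 methylated/unmethylated read table with a two-sided Fisher exact test,
#' adjusts p-values with Benjamini-Hochberg across all tested sites of the
#' comparison, and assigns a direction: `Hyper` if delta >= `delta_min` and
#' q <= `q_max`, `Hypo` symmetrically, otherwise `NoChange`. Delta is the
#' tumor minus normal methylation ratio computed from the read counts.
#'
#' @param tumor,normal Coverage-filtered site tibbles for the tumor sample
#'   and its matched normal.
#' @param delta_min Minimum absolute ratio difference for a call (default
#'   0.2; the cross-patient consistency filter applies a stricter 0.3
#'   downstream).
#' @param q_max Maximum BH-adjusted q-value for a call.
#' @return A tibble with one row per shared site: chrom, start, end, site_id,
#'   context, tumor_ratio, normal_ratio, delta, direction, p_value, q_value,
#'   tumor_cov, normal_cov.
#' @export
call_dmcs <- function(tumor, normal, delta_min = 0.2, q_max = 0.05) {
  shared <- inner_join(
    tumor |> select("chrom", "start", "end", "context",
                    t_meth = "meth_reads", t_tot = "total_reads"),
    normal |> select("chrom", "start", "end",
                     n_meth = "meth_reads", n_tot = "total_reads"),
    by = c("chrom", "start", "end")
  )
  if (nrow(shared) == 0) {
    abort("no shared sites between tumor and normal (empty comparison)",
          class = "methrelapse_empty_comparison")
  }
  p <- fisher_p_2x2(shared$t_meth, shared$t_tot, shared$n_meth, shared$n_tot)
  q <- p.adjust(p, method = "BH")
  tumor_ratio <- shared$t_meth / shared$t_tot
  normal_ratio <- shared$n_meth / shared$n_tot
  delta <- tumor_ratio - normal_ratio
  shared |>
    transmute(
      .data$chrom, .data$start, .data$end,
      site_id = site_id(.data$chrom, .data$start),
      .data$context,
      tumor_ratio = tumor_ratio,
      normal_ratio = normal_ratio,
      delta = delta,
      direction = case_when(
        q <= q_max & delta >= delta_min ~ "Hyper",
        q <= q_max & delta <= -delta_min ~ "Hypo",
        TRUE ~ "NoChange"
      ),
      p_value = p,
      q_value = q,
      tumor_cov = .data$t_tot,
      normal_cov = .data$n_tot
    )
}

#' Mean methylation level of a sequence context
#'
#' Arithmetic mean of the per-site methylation ratios over coverage-filtered
#' sites of the requested context (CpG or CpA); used e.g. to summarize the
#' global CpA hypomethylation of tumors relative to normal brain tissue.
#'
#' @param records Site tibble with a `context` column.
#' @param context `"CpG"` or `"CpA"`.
#' @param min_reads Coverage filter applied before averaging.
#' @return Mean ratio (scalar); `NA` with a warning if no site of the
#'   requested context survives the filter.
#' @export
summarize_context <- function(records, context = c("CpG", "CpA"),
                              min_reads = 5L) {
  context <- match.arg(context)
  keep <- filter_coverage(records, min_reads)
  keep <- keep[keep$context == context, , drop = FALSE]
  if (nrow(keep) == 0) {
    warn(paste0("no covered sites of context ", context))
    return(NA_real_)
  }
  mean(keep$ratio)
}
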