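#' Counts-per-million normalization
#'
#' @param counts Tibble with gene_id plus integer sample columns.
#' @return Tibble of the same shape with CPM values.
#' @export
cpm_normalize <- function(counts) {
  m <- as.matrix(counts[-1])
  libsize <- colSums(m)
  if (any(libsize == 0)) abort("sample with zero total counts")
  cpm <- sweep(m, 2, libsize, "/") * 1e6
  bind_cols(counts[1], as_tibble(cpm))
}

#' Call differentially expressed genes (tumor vs normal)
#'
#' Normalizes to counts-per-million on library size, then per gene runs a
#' two-sided Welch (unequal-variance) t-test on log2(CPM + 1) between the
#' two groups, adjusts p-values with Benjamini-Hochberg across genes, and
#' flags DEGs at `q <= q_max` and `|log2 fold change| >= lfc_min` (both
#' inclusive; the defaults encode FDR <= 0.05 and fold change >= 2). The
#' fold change is the ratio of group-mean CPM. Genes with zero counts in
#' every sample are excluded from testing.
#'
#' @param counts Count tibble: gene_id plus one integer column per sample.
#' @param groups Named character vector or tibble (sample_id, group) mapping
#'   each count column to `"tumor"` or `"normal"`; each group needs >= 2
#'   samples.
#' @param q_max,lfc_min DEG thresholds.
#' @return Tibble: gene_id, log2_fold_change, p_value, q_value,
#'   mean_expr_tumor, mean_expr_normal (mean log2(CPM+1)), deg, direction
#'   (`up` / `down` / `none`).
#' @export
call_degs <- function(counts, groups, q_max = 0.05, lfc_min = 1) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$sample_id)
  }
  samples <- names(counts)[-1]
  groups <- groups[samples]
  if (any(is.na(groups)) || !all(groups %in% c("tumor", "normal"))) {
    abort("groups must map every count column to 'tumor' or 'normal'")
  }
  if (sum(groups == "tumor") < 2 || sum(groups == "normal") < 2) {
    abort("need >= 2 samples per group")
  }
  m <- as.matrix(counts[-1])
  if (any(m < 0)) abort("counts must be nonnegative")
  keep <- rowSums(m) > 0
  cpm <- as.matrix(cpm_normalize(counts)[-1])[keep, , drop = FALSE]
  lg <- log2(cpm + 1)
  ti <- which(groups == "tumor")
  ni <- which(groups == "normal")
  n1 <- length(ti); n2 <- length(ni)
  m1 <- rowMeans(lg[, ti, drop = FALSE])
  m2 <- rowMeans(lg[, ni, drop = FALSE])
  v1 <- apply(lg[, ti, drop = FALSE], 1, var)
  v2 <- apply(lg[, ni, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  q <- p.adjust(p, method = "BH")
  mean_cpm_t <- rowMeans(cpm[, ti, drop = FALSE])
  mean_cpm_n <- rowMeans(cpm[, ni, drop = FALSE])
  lfc <- log2(mean_cpm_t / mean_cpm_n)
  tibble(
    gene_id = counts$gene_id[keep],
    log2_fold_change = lfc,
    p_value = p,
    q_value = q,
    mean_expr_tumor = m1,
    mean_expr_normal = m2,
    deg = q <= q_max & abs(lfc) >= lfc_min,
    direction = case_when(
      q <= q_max & lfc >= lfc_min ~ "up",
      q <= q_max & lfc <= -lfc_min ~ "down",
      TRUE ~ "none"
    )
  )
}

#' Integrate candidate DMR genes with differential expression
#'
#' For each candidate gene, computes the Pearson correlation between its DMR
#' mean methylation and its normalized expression (log2(CPM+1)) across the
#' shared samples, and flags direction-concordant genes: a
#' hypermethylated-DMR gene that is a down-regulated DEG, or a
#' hypomethylated-DMR gene that is an up-regulated DEG, with strictly
#' negative correlation (optionally tightened via `max_r`).
#'
#' @param candidate_genes Tibble with gene_id, kind and direction (DMR
#'   direction, `Hyper`/`Hypo`), e.g. from [assign_genes()] joined to
#'   candidates.
#' @param degs [call_degs()] output.
#' @param meth Tibble gene_id plus sample columns: DMR mean methylation per
#'   sample (see [dmr_gene_methylation()]).
#' @param expr Tibble gene_id plus sample columns: log2(CPM+1) expression.
#'   Samples are matched to `meth` by column name.
#' @param max_r Upper bound on the correlation for concordance (default 0:
#'   any strictly negative correlation qualifies).
#' @return A tibble of class `meth_integration`, sorted by correlation
#'   ascending: gene_id, kind, direction, deg_direction, pearson_r,
#'   n_samples, evaluated, concordant.
#' @export
integrate_expression <- function(candidate_genes, degs, meth, expr,
                                 max_r = 0) {
  shared_samples <- intersect(names(meth)[-1], names(expr)[-1])
  if (length(shared_samples) == 0) {
    abort("no shared samples between methylation and expression matrices")
  }
  mm <- as.matrix(meth[shared_samples])
  rownames(mm) <- meth$gene_id
  em <- as.matrix(expr[shared_samples])
  rownames(em) <- expr$gene_id
  out <- candidate_genes |>
    distinct(.data$gene_id, .data$kind, .data$direction) |>
    left_join(degs |> select("gene_id", deg_direction = "direction", "deg"),
              by = "gene_id")
  rs <- map_dbl(out$gene_id, function(g) {
    if (!g %in% rownames(mm) || !g %in% rownames(em)) return(NA_real_)
    x <- mm[g, ]
    y <- em[g, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NA_real_)
    if (var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  })
  ns <- map_dbl(out$gene_id, function(g) {
    if (!g %in% rownames(mm) || !g %in% rownames(em)) return(0)
    sum(!is.na(mm[g, ]) & !is.na(em[g, ]))
  })
  res <- out |>
    mutate(
      pearson_r = rs,
      n_samples = as.integer(ns),
      evaluated = !is.na(rs),
      concordant = .data$evaluated &
        ((.data$direction == "Hyper" & .data$deg_direction %in% "down") |
           (.data$direction == "Hypo" & .data$deg_direction %in% "up")) &
        .data$pearson_r < max_r
    ) |>
    arrange(.data$pearson_r)
  class(res) <- c("meth_integration", class(res))
  res
}

#' DMR mean methylation per gene and sample
#'
#' Builds the gene-by-sample methylation matrix used by
#' [integrate_expression()]: for every gene with an assigned DMR, the mean
#' empirical methylation ratio over the DMR's member sites in each sample
#' (coverage-filtered; NA where no member site is covered).
#'
#' @param assignments [assign_genes()] output joined so that `site_ids`
#'   (comma-separated member keys) is present — e.g. join with the
#'   [merge_dmrs()] table.
#' @param methylation Named list of per-sample site tibbles.
#' @param min_reads Coverage filter.
#' @return Tibble: gene_id plus one column per sample.
#' @export
dmr_gene_methylation <- function(assignments, methylation, min_reads = 5L) {
  stopifnot("site_ids" %in% names(assignments))
  gene_sites <- assignments |>
    distinct(.data$gene_id, .data$site_ids) |>
    mutate(site_id = strsplit(.data$site_ids, ",")) |>
    tidyr::unnest("site_id") |>
    distinct(.data$gene_id, .data$site_id)
  per_sample <- imap(methylation, function(tbl, s) {
    covered <- filter_coverage(tbl, min_reads)
    ratios <- setNames(covered$meth_reads / covered$total_reads,
                       site_id(covered$chrom, covered$start))
    gene_sites |>
      mutate(ratio = unname(ratios[.data$site_id])) |>
      group_by(.data$gene_id) |>
      summarise(!!s := mean(.data$ratio, na.rm = TRUE), .groups = "drop")
  })
  Reduce(function(a, b) left_join(a, b, by = "gene_id"), per_sample)
}
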