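mk_counts <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat))),
                      samples = sprintf("S%d", seq_len(ncol(mat)))) {
  colnames(mat) <- samples
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(mat))
}

test_that("flat and exactly two-fold genes land on the DEG boundary", {
  # library sizes equal by construction; g2 is exactly 2x in tumors
  mat <- rbind(
    g1 = c(100, 100, 100, 100, 100, 100),
    g2 = c(200, 200, 200, 100, 100, 100),
    g3 = c(300, 300, 300, 400, 400, 400),
    g4 = c(0, 0, 0, 0, 0, 0)
  )
  counts <- mk_counts(mat, genes = rownames(mat))
  groups <- setNames(rep(c("tumor", "normal"), each = 3),
                     paste0("S", 1:6))
  degs <- call_degs(counts, groups)
  expect_false("g4" %in% degs$gene_id)  # all-zero gene excluded
  g1 <- degs[degs$gene_id == "g1", ]
  g2 <- degs[degs$gene_id == "g2", ]
  expect_equal(g1$log2_fold_change, 0)  # identical counts, equal libraries
  expect_false(g1$deg)
  expect_equal(g2$log2_fold_change, 1)  # exactly two-fold CPM
  expect_error(call_degs(counts, groups[1:3]), "groups")
  expect_error(call_degs(counts[, 1:3],
                         setNames(c("tumor", "normal"), c("S1", "S2"))),
               ">= 2 samples")
})

test_that("an exactly two-fold CPM gene with tiny variance is a DEG", {
  set.seed(5)
  # equal library sizes; one gene at exactly 2x CPM with zero within-group
  # variance -> degenerate-variance branch gives p = 0, |log2FC| = 1 exactly
  other <- matrix(50, nrow = 20, ncol = 10)
  sig <- c(rep(200, 5), rep(100, 5))
  pad <- c(rep(300, 5), rep(400, 5))  # keeps library sizes equal
  mat <- rbind(other, sig, pad)
  counts <- mk_counts(mat)
  groups <- setNames(rep(c("tumor", "normal"), each = 5), paste0("S", 1:10))
  degs <- call_degs(counts, groups)
  row <- degs[degs$gene_id == "g21", ]
  expect_equal(row$log2_fold_change, 1)
  expect_true(row$deg)  # boundary |log2FC| >= 1 is inclusive
  flat <- degs[degs$gene_id == "g01", ]
  expect_equal(flat$log2_fold_change, 0)
  expect_false(flat$deg)
})

test_that("null simulation keeps the BH-significant fraction under control", {
  set.seed(99)
  n_genes <- 2000
  mu <- rlnorm(n_genes, log(300), 1)
  mat <- matrix(rnbinom(n_genes * 10, mu = mu, size = 10), nrow = n_genes)
  counts <- mk_counts(mat)
  groups <- setNames(rep(c("tumor", "normal"), each = 5), paste0("S", 1:10))
  degs <- call_degs(counts, groups)
  expect_lt(mean(degs$q_value <= 0.05), 0.01)
})

test_that("planted methylation-coupled genes are recovered as DEGs", {
  co <- small_cohort()
  pipe <- small_pipeline()
  truth <- co$truth$genes
  hit <- agree <- logical(0)
  for (st in c("RELA", "PFA")) {
    degs <- pipe$degs[[st]]
    # booster-linked genes are diluted by their unshifted primaries; the
    # recall contract applies to genes shifted in every tumor sample
    coupled <- truth$gene_id[truth$coupled & truth$subtype %in% st &
                               truth$kind %in% c("driver", "predictor")]
    hit <- c(hit, coupled %in% degs$gene_id[degs$deg])
    # and their direction matches the planted sign
    lab <- truth$label[match(coupled, truth$gene_id)]
    dirs <- degs$direction[match(coupled, degs$gene_id)]
    agree <- c(agree, (lab == "hyper_down" & dirs == "down") |
                 (lab == "hypo_up" & dirs == "up"))
  }
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(agree, na.rm = TRUE), 0.9)
})

test_that("integration computes anticorrelation and concordance", {
  cand <- tibble::tibble(gene_id = c("gA", "gB"), kind = "driver",
                         direction = c("Hyper", "Hypo"))
  degs <- tibble::tibble(gene_id = c("gA", "gB"),
                         direction = c("down", "up"), deg = TRUE)
  meth <- mk_counts(rbind(gA = c(0.1, 0.5, 0.9), gB = c(0.5, 0.5, 0.5)),
                    genes = c("gA", "gB"))
  expr <- mk_counts(rbind(gA = c(9, 5, 1), gB = c(1, 5, 9)),
                    genes = c("gA", "gB"))
  out <- integrate_expression(cand, degs, meth, expr)
  a <- out[out$gene_id == "gA", ]
  expect_equal(a$pearson_r, -1)
  expect_true(a$concordant)
  b <- out[out$gene_id == "gB", ]  # constant methylation: not evaluated
  expect_false(b$evaluated)
  expect_false(b$concordant)
  expect_true(is.na(b$pearson_r))
})

test_that("reported correlations match the covariance formula exactly", {
  co <- small_cohort()
  pipe <- small_pipeline()
  intg <- pipe$integration[pipe$integration$evaluated, ]
  expect_gt(nrow(intg), 10)
  # recompute r for a handful of genes straight from the matrices
  st <- "RELA"
  sheet <- co$samples
  cols <- c(sheet$sample_id[sheet$subtype %in% st &
                              sheet$role %in% c("primary", "relapse")],
            sheet$sample_id[sheet$role == "normal_cerebrum"])
  hits <- pipe$gene_hits[pipe$gene_hits$subtype == st, ]
  meth <- dmr_gene_methylation(hits, co$methylation[cols])
  cpmv <- cpm_normalize(co$expression[c("gene_id", cols)])
  expr <- dplyr::bind_cols(cpmv[1],
                           tibble::as_tibble(log2(as.matrix(cpmv[-1]) + 1)))
  some <- head(intg$gene_id[intg$subtype == st], 5)
  for (g in some) {
    x <- as.numeric(meth[meth$gene_id == g, -1])
    y <- as.numeric(expr[expr$gene_id == g, -1])
    ok <- !is.na(x) & !is.na(y)
    r_manual <- sum((x[ok] - mean(x[ok])) * (y[ok] - mean(y[ok]))) /
      sqrt(sum((x[ok] - mean(x[ok]))^2) * sum((y[ok] - mean(y[ok]))^2))
    expect_equal(intg$pearson_r[intg$gene_id == g & intg$subtype == st][1],
                 r_manual, tolerance = 1e-12)
  }
  # concordant genes all have strictly negative correlation
  expect_true(all(intg$pearson_r[intg$concordant] < 0))
  # integration output only contains candidate genes
  expect_true(all(pipe$integration$gene_id %in% pipe$gene_hits$gene_id))
})
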