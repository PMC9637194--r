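# On-disk formats. Coordinates are 0-based half-open throughout: a CpG (or
# CpA) occupies [start, start + 2) covering the dinucleotide, so the printed
# identifier chr17-80943940-80943942 denotes the CpG starting at 80943940.
# Both strands of a CpG are assumed pooled upstream.

meth_cols <- c("chrom", "start", "end", "ratio", "meth_reads", "total_reads")

#' Read a per-sample methylation table
#'
#' Parses a bedGraph-like TSV with columns chrom, start, end, ratio,
#' meth_reads, total_reads and an optional seventh column giving the
#' sequence context (`CpG` or `CpA`; defaults to `CpG`). Lines starting with
#' `#` are ignored. Records are validated (end = start + 2, meth <= total,
#' ratio consistent with counts to 1e-6) and returned sorted by natural
#' chromosome order and start.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns chrom, start, end, context, ratio,
#'   meth_reads, total_reads.
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#") | lines == ""
  body <- lines[!is_comment]
  lineno <- which(!is_comment)
  if (length(body) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  context = character(), ratio = numeric(),
                  meth_reads = integer(), total_reads = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6 | nf > 7)) {
    abort(paste0("format error in ", path, ": expected 6 or 7 tab-separated ",
                 "columns at line(s) ", paste(head(lineno[nf < 6 | nf > 7], 5),
                                              collapse = ", ")),
          class = "methrelapse_format_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:7))
  tbl <- tibble(
    chrom = m[, 1],
    start = suppressWarnings(as.integer(m[, 2])),
    end = suppressWarnings(as.integer(m[, 3])),
    ratio = suppressWarnings(as.numeric(m[, 4])),
    meth_reads = suppressWarnings(as.integer(m[, 5])),
    total_reads = suppressWarnings(as.integer(m[, 6])),
    context = ifelse(is.na(m[, 7]), "CpG", m[, 7])
  )
  fail <- function(which_rows, why) {
    if (any(which_rows)) {
      abort(paste0("format error in ", path, ": ", why, " at line(s) ",
                   paste(head(lineno[which_rows], 5), collapse = ", ")),
            class = "methrelapse_format_error")
    }
  }
  fail(is.na(tbl$start) | is.na(tbl$end) | is.na(tbl$ratio) |
         is.na(tbl$meth_reads) | is.na(tbl$total_reads), "non-numeric field")
  fail(tbl$end != tbl$start + 2L, "end != start + 2")
  fail(tbl$meth_reads > tbl$total_reads | tbl$meth_reads < 0,
       "meth_reads outside [0, total_reads]")
  fail(tbl$total_reads > 0 &
         abs(tbl$ratio - tbl$meth_reads / tbl$total_reads) > 1e-6,
       "ratio inconsistent with counts")
  fail(!tbl$context %in% c("CpG", "CpA"), "unknown context")
  tbl |>
    select("chrom", "start", "end", "context", "ratio",
           "meth_reads", "total_reads") |>
    arrange_sites()
}

#' Write a per-sample methylation table
#'
#' Inverse of [read_methylation_table()]; emits a single `#`-prefixed header
#' line followed by 7 tab-separated columns.
#'
#' @param tbl Site tibble as returned by [read_methylation_table()] or found
#'   in a [simulate_cohort()] object's `methylation` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(tbl, path) {
  out <- tbl |>
    transmute(.data$chrom, .data$start, .data$end,
              ratio = sprintf("%.10g", .data$ratio),
              .data$meth_reads, .data$total_reads, .data$context)
  header <- paste0("#", paste(c(meth_cols, "context"), collapse = "\t"))
  writeLines(c(header, do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

sheet_cols <- c("sample_id", "patient_id", "subtype", "role", "timepoint",
                "matched_normal_id", "pdox_of", "recurred")

#' Read and validate a sample sheet
#'
#' The sheet is a CSV with columns sample_id, patient_id, subtype
#' (RELA/PFA, empty for normals), role (normal_cerebrum, normal_cerebellum,
#' primary, relapse, pdox), timepoint (0 = primary, k = k-th relapse),
#' matched_normal_id, pdox_of and recurred. Cross-references are validated:
#' matched normals and PDOX sources must exist, relapses must have
#' timepoint >= 1, and subtypes must pair with the correct normal tissue
#' (RELA with cerebrum, PFA with cerebellum).
#'
#' @param path Path to the CSV file.
#' @return A validated sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           sample_id = "c", patient_id = "c", subtype = "c",
                           role = "c", timepoint = "i",
                           matched_normal_id = "c", pdox_of = "c",
                           recurred = "l"
                         ))
  missing <- setdiff(sheet_cols, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("sample sheet missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "methrelapse_validation_error")
  }
  validate_sample_sheet(tbl[sheet_cols])
}

#' Validate a sample sheet tibble
#'
#' @param sheet Sample sheet tibble (see [read_sample_sheet()]).
#' @return The sheet, invisibly returned after validation; aborts with a
#'   validation error listing the offending sample_id otherwise.
#' @export
validate_sample_sheet <- function(sheet) {
  fail <- function(ids, why) {
    if (length(ids) > 0) {
      abort(paste0("sample sheet validation error: ", why, " for sample(s) ",
                   paste(head(ids, 5), collapse = ", ")),
            class = "methrelapse_validation_error")
    }
  }
  roles <- c("normal_cerebrum", "normal_cerebellum", "primary", "relapse",
             "pdox")
  fail(sheet$sample_id[!sheet$role %in% roles], "unknown role")
  fail(sheet$sample_id[duplicated(sheet$sample_id)], "duplicate sample_id")
  is_tumorish <- sheet$role %in% c("primary", "relapse", "pdox")
  fail(sheet$sample_id[is_tumorish & !sheet$subtype %in% c("RELA", "PFA")],
       "tumor/pdox sample without RELA/PFA subtype")
  fail(sheet$sample_id[sheet$role == "relapse" &
                         (is.na(sheet$timepoint) | sheet$timepoint < 1)],
       "relapse with timepoint < 1")
  fail(sheet$sample_id[sheet$role == "primary" &
                         (is.na(sheet$timepoint) | sheet$timepoint != 0)],
       "primary with timepoint != 0")
  ref <- match(sheet$matched_normal_id, sheet$sample_id)
  fail(sheet$sample_id[is_tumorish & is.na(ref)],
       "dangling or missing matched_normal_id")
  ref_role <- sheet$role[ref]
  fail(sheet$sample_id[is_tumorish & sheet$subtype %in% "RELA" &
                         ref_role != "normal_cerebrum"],
       "RELA sample not matched to normal_cerebrum")
  fail(sheet$sample_id[is_tumorish & sheet$subtype %in% "PFA" &
                         ref_role != "normal_cerebellum"],
       "PFA sample not matched to normal_cerebellum")
  src <- match(sheet$pdox_of, sheet$sample_id)
  fail(sheet$sample_id[sheet$role == "pdox" &
                         (is.na(sheet$pdox_of) | is.na(src))],
       "pdox sample with missing or dangling pdox_of")
  fail(sheet$sample_id[sheet$role == "pdox" &
                         !sheet$role[src] %in% c("primary", "relapse")],
       "pdox_of does not point at a tumor sample")
  invisible(sheet)
}

#' Write a sample sheet
#' @param sheet Sample sheet tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet[sheet_cols], path, na = "")
  invisible(path)
}

#' Read a gene annotation (BED6, 1-bp TSS features)
#'
#' Each gene is a single-base BED feature at its transcription start site:
#' columns chrom, start (0-based TSS), end (= start + 1), name (gene_id),
#' score (ignored), strand.
#'
#' @param path Path to the BED file.
#' @return Tibble with columns gene_id, chrom, tss, strand.
#' @export
read_gene_annotation <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_names = c("chrom", "start", "end", "gene_id",
                                       "score", "strand"),
                         col_types = "ciicdc")
  if (any(tbl$end != tbl$start + 1L)) {
    abort("gene annotation must contain 1-bp TSS features (end = start + 1)",
          class = "methrelapse_format_error")
  }
  if (any(duplicated(tbl$gene_id))) {
    abort("gene annotation contains duplicated gene_id",
          class = "methrelapse_format_error")
  }
  tbl |>
    transmute(.data$gene_id, .data$chrom, tss = .data$start, .data$strand) |>
    arrange(chrom_rank(.data$chrom), .data$tss)
}

#' Write a gene annotation as BED6
#' @param genes Tibble with gene_id, chrom, tss, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  out <- genes |>
    transmute(.data$chrom, start = .data$tss, end = .data$tss + 1L,
              .data$gene_id, score = 0L, .data$strand)
  writeLines(c("#chrom\tstart\tend\tgene_id\tscore\tstrand",
               do.call(paste, c(out, sep = "\t"))), path)
  invisible(path)
}

#' Read an expression count matrix (genes x samples TSV)
#' @param path Path to the TSV (first column gene_id, one column per sample).
#' @return Tibble with gene_id and one integer column per sample.
#' @export
read_expression_counts <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write an expression count matrix
#' @param counts Tibble with gene_id plus sample columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write a whole simulated cohort to a directory
#'
#' Emits one bedGraph-like methylation TSV per sample under
#' `dir/methylation/`, plus `samples.csv`, `genes.bed`, `expression.tsv`
#' and the truth tables (`truth_sites.tsv`, `truth_genes.tsv`).
#'
#' @param cohort A [simulate_cohort()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  meth_dir <- file.path(dir, "methylation")
  dir.create(meth_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$methylation)) {
    write_methylation_table(cohort$methylation[[s]],
                            file.path(meth_dir, paste0(s, ".bedgraph")))
  }
  write_sample_sheet(cohort$samples, file.path(dir, "samples.csv"))
  write_gene_annotation(cohort$genes, file.path(dir, "genes.bed"))
  write_expression_counts(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$truth$sites, file.path(dir, "truth_sites.tsv"))
  readr::write_tsv(cohort$truth$genes, file.path(dir, "truth_genes.tsv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `methylation/`, `samples.csv`,
#'   `genes.bed` and `expression.tsv`.
#' @return A list shaped like a [simulate_cohort()] object (without
#'   `true_ratios`; truth tables are read back if present).
#' @export
read_cohort <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  meth <- lapply(sheet$sample_id, function(s) {
    read_methylation_table(file.path(dir, "methylation",
                                     paste0(s, ".bedgraph")))
  })
  names(meth) <- sheet$sample_id
  truth <- NULL
  if (file.exists(file.path(dir, "truth_sites.tsv"))) {
    truth <- list(
      sites = readr::read_tsv(file.path(dir, "truth_sites.tsv"),
                              show_col_types = FALSE),
      genes = readr::read_tsv(file.path(dir, "truth_genes.tsv"),
                              show_col_types = FALSE)
    )
  }
  structure(
    list(
      methylation = meth,
      samples = sheet,
      genes = read_gene_annotation(file.path(dir, "genes.bed")),
      expression = read_expression_counts(file.path(dir, "expression.tsv")),
      truth = truth
    ),
    class = "meth_cohort"
  )
}
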