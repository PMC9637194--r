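# shared internal helpers

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Natural chromosome ordering
#'
#' Orders chromosome names so that numeric chromosomes sort numerically
#' (`chr2` before `chr10`) and non-numeric ones (`chrX`, `chrY`, `chrM`)
#' follow alphabetically. The sort is stable.
#'
#' @param chrom Character vector of chromosome names (with or without a
#'   `chr` prefix).
#' @return An integer rank usable inside `dplyr::arrange()` or `order()`.
#' @export
#' @examples
#' chrom_rank(c("chr10", "chr2", "chrX"))
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  lev <- unique(chrom[order(is.na(num), num, stripped, method = "radix")])
  as.integer(factor(chrom, levels = lev))
}

#' Compose a site identifier
#'
#' Site keys follow the `chrom-start-end` convention with 0-based half-open
#' coordinates, so a CpG at `chr17:80943940` is `chr17-80943940-80943942`.
#'
#' @param chrom,start,end Site coordinates (end defaults to `start + 2`).
#' @return Character vector of site identifiers.
#' @export
site_id <- function(chrom, start, end = start + 2L) {
  paste(chrom, start, end, sep = "-")
}

# stable arrange by genome position
arrange_sites <- function(tbl) {
  dplyr::arrange(tbl, chrom_rank(.data$chrom), .data$start)
}

# states are stored compactly: H = Hyper, L = Hypo, N = NoChange
STATE_LETTERS <- c(Hyper = "H", Hypo = "L", NoChange = "N")

encode_states <- function(states) {
  bad <- setdiff(unique(states), names(STATE_LETTERS))
  if (length(bad) > 0) {
    abort(paste0("invalid state symbol(s): ", paste(bad, collapse = ", ")))
  }
  paste(STATE_LETTERS[states], collapse = "")
}

decode_states <- function(code) {
  lut <- setNames(names(STATE_LETTERS), STATE_LETTERS)
  unname(lut[strsplit(code, "")[[1]]])
}
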