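# shared fixtures, built once per test session

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

small_cohort_config <- function(seed = 101, ...) {
  cohort_config(n_sites = 4000, n_genes = 300, n_chroms = 8,
                seed = seed, ...)
}

# minimal cohort with proportionally scaled planted signal
tiny_cohort_config <- function(seed, n_sites = 1500, ...) {
  cohort_config(n_sites = n_sites, n_chroms = 4, n_genes = 80,
                n_driver_sites = 60, n_booster_sites = 60,
                n_predictor_sites = 40, n_switch_sites = 40,
                seed = seed, ...)
}

small_cohort <- function() {
  memo("small_cohort", simulate_cohort(small_cohort_config()))
}

small_pipeline <- function() {
  memo("small_pipeline", suppressWarnings(run_pipeline(small_cohort())))
}

# high-coverage, noise-free cohort for fidelity checks
exact_cohort <- function() {
  memo("exact_cohort", simulate_cohort(small_cohort_config(
    seed = 202, mean_coverage = 100, pdox_noise_sd = 0)))
}

# default-scale cohort + pipeline used by the acceptance checks
acceptance_cohort <- function() {
  memo("acceptance_cohort", simulate_cohort(cohort_config(seed = 7)))
}

acceptance_pipeline <- function() {
  memo("acceptance_pipeline",
       suppressWarnings(run_pipeline(acceptance_cohort())))
}

# independent, procedural trajectory classifier (rule table over run-length
# segments; the implementation is regex-based)
oracle_classify <- function(states) {
  n <- length(states)
  for (i in seq_len(n - 1)) {
    pair <- states[c(i, i + 1)]
    if (all(pair %in% c("Hyper", "Hypo")) && pair[1] != pair[2]) {
      return("ExcludedPolaritySwitch")
    }
  }
  polar <- states[states != "NoChange"]
  if (length(polar) == 0) return("NoChange")
  if (length(unique(polar)) > 1) return("Switch")
  X <- polar[1]
  r <- rle(states)
  if (length(r$values) == 1) return(paste0("Consistent", X))
  if (length(r$values) == 2 && r$values[1] == "NoChange") {
    return(paste0("Gain", X))
  }
  if (length(r$values) == 2 && r$values[2] == "NoChange") {
    return(paste0("Loss", X))
  }
  "Switch"
}

all_state_sequences <- function(len) {
  grids <- rep(list(c("Hyper", "Hypo", "NoChange")), len)
  as.matrix(do.call(expand.grid, c(grids, stringsAsFactors = FALSE)))
}

# simple chain-walking DMR oracle
oracle_merge_dmrs <- function(df, max_gap = 300, min_dmcs = 3) {
  out <- list()
  i <- 1
  n <- nrow(df)
  while (i <= n) {
    j <- i
    while (j < n && df$chrom[j + 1] == df$chrom[j] &&
           df$direction[j + 1] == df$direction[j] &&
           df$start[j + 1] - df$start[j] <= max_gap) {
      j <- j + 1
    }
    if (j - i + 1 >= min_dmcs) {
      out[[length(out) + 1]] <- data.frame(
        chrom = df$chrom[i], start = df$start[i], end = df$end[j],
        direction = df$direction[i], n_dmcs = j - i + 1,
        mean_delta = mean(df$delta[i:j])
      )
    }
    i <- j + 1
  }
  dplyr::bind_rows(out)
}

# bedGraph-like lines -> temp file
write_meth_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bedgraph",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
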