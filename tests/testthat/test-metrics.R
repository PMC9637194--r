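mk_meth <- function(start, meth, total, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start) + 2L, context = "CpG",
                 ratio = ifelse(total > 0, meth / total, 0),
                 meth_reads = as.integer(meth), total_reads = as.integer(total))
}

mini_sheet <- function(samples, timepoints) {
  tibble::tibble(
    sample_id = samples, patient_id = "P1", subtype = "RELA",
    role = ifelse(timepoints == 0, "primary", "relapse"),
    timepoint = timepoints, matched_normal_id = samples[1],
    pdox_of = NA_character_, recurred = TRUE
  )
}

test_that("convergence handles identical profiles and missing samples", {
  set.seed(3)
  n <- 200
  meth <- rbinom(n, 30, 0.5)
  a <- mk_meth(seq_len(n) * 10, meth, 30)
  sheet <- mini_sheet(c("P", "R2", "R3"), c(0L, 2L, 3L))
  ml <- list(P = a, R2 = a, R3 = a)
  conv <- suppressWarnings(convergence_series(ml, sheet, "P1"))
  expect_equal(conv$pearson_r, c(1, 1))
  # R1 is missing: R2 pairs with the primary and is flagged as fallback
  expect_equal(conv$from_sample, c("P", "R2"))
  expect_equal(conv$fallback_used, c(TRUE, FALSE))
  expect_error(convergence_series(ml["P"], sheet[1, ], "P1"),
               "fewer than 2")
  # fewer than 100 shared covered sites warns and flags
  small <- lapply(ml, function(x) x[1:50, ])
  expect_warning(conv2 <- convergence_series(small, sheet, "P1"),
                 "shared covered sites")
  expect_true(all(conv2$low_sites))
})

test_that("convergence is invariant to site order", {
  set.seed(4)
  n <- 300
  a <- mk_meth(seq_len(n) * 10, rbinom(n, 30, runif(n)), 30)
  b <- mk_meth(seq_len(n) * 10, rbinom(n, 30, runif(n)), 30)
  sheet <- mini_sheet(c("P", "R1"), c(0L, 1L))
  r1 <- convergence_series(list(P = a, R1 = b), sheet, "P1")$pearson_r
  shuffle <- sample.int(n)
  r2 <- convergence_series(list(P = a[shuffle, ], R1 = b), sheet,
                           "P1")$pearson_r
  expect_equal(r1, r2)
})

test_that("global fidelity behaves at the extremes", {
  toy_a <- mk_meth(c(10, 20), c(0, 10), c(10, 10))
  toy_b <- mk_meth(c(10, 20), c(10, 0), c(10, 10))
  expect_equal(global_fidelity(toy_a, toy_b)$pearson_r, -1)

  # uncorrelated profiles over many sites stay near zero
  set.seed(6)
  n <- 20000
  p1 <- mk_meth(seq_len(n) * 10, rbinom(n, 30, runif(n)), 30)
  p2 <- mk_meth(seq_len(n) * 10, rbinom(n, 30, runif(n)), 30)
  expect_lt(abs(global_fidelity(p1, p2)$pearson_r), 0.1)

  expect_error(global_fidelity(toy_a, mk_meth(99, 1, 10)), "no shared")
})

test_that("noise-free PDOX methylomes correlate above 0.99 at high coverage", {
  co <- exact_cohort()  # coverage 100x, pdox_noise_sd = 0
  pd <- co$samples[co$samples$role == "pdox", ][1:2, ]
  for (i in 1:2) {
    fid <- global_fidelity(co$methylation[[pd$pdox_of[i]]],
                           co$methylation[[pd$sample_id[i]]])
    expect_gt(fid$pearson_r, 0.99)
  }
})

test_that("top-variable selection matches a full-sort oracle", {
  set.seed(12)
  n <- 300
  ratios <- ratio_matrix(list(
    S1 = mk_meth(seq_len(n) * 10, rbinom(n, 50, runif(n)), 50),
    S2 = mk_meth(seq_len(n) * 10, rbinom(n, 50, runif(n)), 50),
    S3 = mk_meth(seq_len(n) * 10, rbinom(n, 50, runif(n)), 50),
    S4 = mk_meth(seq_len(n) * 10, rbinom(n, 50, runif(n)), 50)
  ))
  got <- top_variable_cpgs(ratios, 40)
  v <- apply(as.matrix(ratios[, c("S1", "S2", "S3", "S4")]), 1, var)
  want <- ratios$site_id[order(-v, chrom_rank(ratios$chrom), ratios$start)]
  expect_equal(got$site_id, want[1:40])

  # k equal to the eligible count returns everything
  expect_equal(nrow(top_variable_cpgs(ratios, n)), n)
  expect_error(top_variable_cpgs(ratios, n + 1), "exceeds")

  # a constant site is never selected while any varying site exists
  const <- mk_meth(5L, 25, 50)
  ratios2 <- ratio_matrix(list(
    S1 = dplyr::bind_rows(const, mk_meth(10L, 0, 50)),
    S2 = dplyr::bind_rows(const, mk_meth(10L, 50, 50))
  ))
  expect_equal(top_variable_cpgs(ratios2, 1)$site_id, site_id("chr1", 10L))

  # sites uncovered anywhere are ineligible
  gap <- list(
    S1 = dplyr::bind_rows(mk_meth(5L, 25, 50), mk_meth(10L, 10, 50)),
    S2 = dplyr::bind_rows(mk_meth(5L, 20, 50), mk_meth(10L, 10, 3))
  )
  expect_error(top_variable_cpgs(ratio_matrix(gap), 2), "exceeds the 1")
})

test_that("the Pearson implementation matches the closed form", {
  set.seed(17)
  x <- runif(500)
  y <- 0.3 * x + rnorm(500, 0, 0.2)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  a <- mk_meth(seq_len(500) * 10, round(x * 1000), 1000)
  b <- mk_meth(seq_len(500) * 10, round(y * 500 + 500), 2000)
  got <- global_fidelity(a, b)$pearson_r
  xr <- round(x * 1000) / 1000
  yr <- (round(y * 500 + 500)) / 2000
  manual2 <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  expect_equal(got, manual2, tolerance = 1e-12)
})
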