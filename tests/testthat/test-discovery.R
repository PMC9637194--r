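# a tiny hand-built cohort: 2 recurring patients (P1 with P,R1,R2; P2 with
# P,R1), one non-recurrent primary (P9), one normal, one PDOX of P1_R2
toy_sheet <- function() {
  tibble::tibble(
    sample_id = c("N1", "P1_P", "P1_R1", "P1_R2", "P2_P", "P2_R1",
                  "P9_P", "PDOX_P1_R2"),
    patient_id = c("ND", "P1", "P1", "P1", "P2", "P2", "P9", "P1"),
    subtype = c(NA, rep("RELA", 7)),
    role = c("normal_cerebrum", "primary", "relapse", "relapse", "primary",
             "relapse", "primary", "pdox"),
    timepoint = c(NA, 0L, 1L, 2L, 0L, 1L, 0L, 2L),
    matched_normal_id = c(NA, rep("N1", 7)),
    pdox_of = c(rep(NA_character_, 7), "P1_R2"),
    recurred = c(NA, rep(TRUE, 5), FALSE, TRUE)
  )
}

toy_call <- function(s, start, dir, delta = 0.5) {
  if (dir == "NoChange") delta <- 0.01
  if (dir == "Hypo") delta <- -abs(delta)
  tibble::tibble(chrom = "chr1", start = start, end = start + 2L,
                 site_id = site_id("chr1", start), context = "CpG",
                 tumor_ratio = 0.1 + delta, normal_ratio = 0.1, delta = delta,
                 direction = dir, p_value = 1e-6, q_value = 1e-4,
                 tumor_cov = 50L, normal_cov = 50L, sample_id = s)
}

# site 100: driver pattern (consistent everywhere incl non-recurrent primary)
# site 200: booster pattern (NoChange in primaries, Hyper in all relapses)
# site 300: predictor pattern (DMC in recurring primaries + all relapses,
#           covered NoChange in the non-recurrent primary), delta 0.8
# site 400: booster-like in P1 but lost at R2 -> not a booster
# site 500: like predictor but also a DMC in the non-recurrent primary
toy_calls <- function() {
  rows <- list()
  spec <- list(
    `100` = c(P1_P = "Hyper", P1_R1 = "Hyper", P1_R2 = "Hyper",
              P2_P = "Hyper", P2_R1 = "Hyper", P9_P = "Hyper",
              PDOX_P1_R2 = "Hyper"),
    `200` = c(P1_P = "NoChange", P1_R1 = "Hyper", P1_R2 = "Hyper",
              P2_P = "NoChange", P2_R1 = "Hyper", P9_P = "NoChange",
              PDOX_P1_R2 = "NoChange"),
    `300` = c(P1_P = "Hyper", P1_R1 = "Hyper", P1_R2 = "Hyper",
              P2_P = "Hyper", P2_R1 = "Hyper", P9_P = "NoChange",
              PDOX_P1_R2 = "Hyper"),
    `400` = c(P1_P = "NoChange", P1_R1 = "Hyper", P1_R2 = "NoChange",
              P2_P = "NoChange", P2_R1 = "Hyper", P9_P = "NoChange",
              PDOX_P1_R2 = "NoChange"),
    `500` = c(P1_P = "Hyper", P1_R1 = "Hyper", P1_R2 = "Hyper",
              P2_P = "Hyper", P2_R1 = "Hyper", P9_P = "Hyper",
              PDOX_P1_R2 = "Hyper")
  )
  for (st in names(spec)) {
    delta <- if (st %in% c("300", "500")) 0.8 else 0.5
    for (s in names(spec[[st]])) {
      rows[[length(rows) + 1]] <-
        toy_call(s, as.integer(st), spec[[st]][[s]], delta)
    }
  }
  dplyr::bind_rows(rows)
}

toy_traj <- function() {
  calls <- toy_calls()
  tumor <- calls[calls$sample_id != "PDOX_P1_R2", ]
  build_state_sequences(tumor, toy_sheet())
}

test_that("driver discovery requires sharing by all patients", {
  traj <- toy_traj()
  calls <- toy_calls()
  drivers <- find_drivers(traj, calls, toy_sheet(), "RELA")
  # sites 100, 300 and 500 are consistent in both recurring patients (the
  # predictor-pattern site 300 necessarily satisfies the driver definition)
  expect_setequal(drivers$site_id, site_id("chr1", c(100L, 300L, 500L)))
  # consistent in one patient only is not enough: drop P2 support of site 100
  calls2 <- calls[!(calls$site_id == site_id("chr1", 100L) &
                      calls$sample_id == "P2_R1"), ]
  traj2 <- build_state_sequences(
    calls2[calls2$sample_id != "PDOX_P1_R2", ], toy_sheet())
  drivers2 <- find_drivers(traj2, calls2, toy_sheet(), "RELA")
  expect_false(site_id("chr1", 100L) %in% drivers2$site_id)
  # a delta threshold above the planted effect empties the set
  expect_equal(nrow(find_drivers(traj, calls, toy_sheet(), "RELA",
                                 delta_min = 0.9)), 0)
})

test_that("booster discovery enforces absence in primary and persistence", {
  traj <- toy_traj()
  boosters <- find_boosters(traj, toy_calls(), toy_sheet(), "RELA")
  expect_equal(boosters$site_id, site_id("chr1", 200L))
  # site 400 lost at R2 violates persistence
  expect_false(site_id("chr1", 400L) %in% boosters$site_id)
  # drivers and boosters are disjoint by definition
  drivers <- find_drivers(traj, toy_calls(), toy_sheet(), "RELA")
  expect_length(intersect(drivers$site_id, boosters$site_id), 0)
})

test_that("predictor discovery enforces specificity and inclusive ranking", {
  calls <- toy_calls()
  preds <- find_predictors(calls, toy_sheet(), "RELA")
  # site 300 qualifies; 500 is a DMC in the non-recurrent primary; 100 too
  expect_equal(preds$site_id, site_id("chr1", 300L))
  expect_equal(preds$rank_score, 0.8)
  expect_true(preds$top)  # >= 0.8 is inclusive

  # without a non-recurrent reference the procedure refuses
  sheet_norec <- toy_sheet()[toy_sheet()$sample_id != "P9_P", ]
  expect_error(
    find_predictors(calls[calls$sample_id != "P9_P", ], sheet_norec, "RELA"),
    class = "methrelapse_missing_reference")
})

test_that("PDOX filtering marks preservation per matched model", {
  traj <- toy_traj()
  calls <- toy_calls()
  sheet <- toy_sheet()
  cand <- dplyr::bind_rows(
    find_drivers(traj, calls, sheet, "RELA"),
    find_boosters(traj, calls, sheet, "RELA"),
    find_predictors(calls, sheet, "RELA")
  )
  flt <- pdox_filter(cand, calls, sheet)
  by_site <- setNames(flt$pdox_preserved, flt$site_id)
  expect_true(by_site[[site_id("chr1", 100L)]])
  expect_true(by_site[[site_id("chr1", 300L)]])
  # the PDOX model reverted site 200 to NoChange: not preserved
  expect_false(by_site[[site_id("chr1", 200L)]])
  summ <- preservation_summary(flt)
  expect_true(all(summ$total >= 1))
  expect_equal(summ$percent,
               preservation_percent(summ$preserved, summ$total))
})

test_that("planted candidates are recovered with high precision and recall", {
  co <- small_cohort()
  pipe <- small_pipeline()
  perf <- planted_recovery(pipe$candidates, co$truth$sites)
  expect_equal(nrow(perf), 6)  # 3 kinds x 2 subtypes
  expect_true(all(perf$precision >= 0.9))
  expect_true(all(perf$recall >= 0.9))
  # predictors are DMCs in every relapse sample by construction
  preds <- pipe$candidates[pipe$candidates$kind == "predictor", ]
  relapses <- co$samples$sample_id[co$samples$role == "relapse" &
                                     co$samples$subtype == "RELA"]
  calls <- pipe$dmc_calls
  for (sid in head(preds$site_id[preds$subtype == "RELA"], 5)) {
    dirs <- calls$direction[calls$site_id == sid &
                              calls$sample_id %in% relapses]
    expect_equal(length(dirs), length(relapses))
    expect_length(unique(dirs), 1)
    expect_true(unique(dirs) %in% c("Hyper", "Hypo"))
  }
})

test_that("exact PDOX copies are fully preserved and noise degrades them", {
  base_cfg <- function(noise, seed, coverage = 50) {
    cohort_config(n_sites = 1500, n_chroms = 4, n_genes = 60,
                  n_driver_sites = 100, n_booster_sites = 0,
                  n_predictor_sites = 0, n_switch_sites = 0,
                  mean_coverage = coverage,
                  pdox_noise_sd = noise, seed = seed)
  }
  exact <- suppressWarnings(
    run_pipeline(simulate_cohort(base_cfg(0, 71, coverage = 100))))
  expect_true(all(exact$candidates$pdox_preserved))

  tally <- function(noise, seeds) {
    res <- sapply(seeds, function(s) {
      p <- suppressWarnings(run_pipeline(simulate_cohort(base_cfg(noise, s))))
      c(sum(p$candidates$pdox_preserved, na.rm = TRUE),
        sum(!is.na(p$candidates$pdox_preserved)))
    })
    rowSums(res)
  }
  lo <- tally(0.05, 81:84)
  hi <- tally(0.30, 81:84)
  expect_gt(lo[1] / lo[2], hi[1] / hi[2])  # preservation drops with noise
})

test_that("preservation percentages print with one decimal", {
  expect_equal(preservation_percent(479, 529), 90.5)
  expect_equal(preservation_percent(1, 3), 33.3)
})
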