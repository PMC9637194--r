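test_that("canonical sequences classify as named", {
  expect_equal(classify_trajectory(rep("Hyper", 4)), "ConsistentHyper")
  expect_equal(classify_trajectory(c("NoChange", "Hyper", "Hyper")),
               "GainHyper")
  expect_equal(classify_trajectory(c("Hypo", "NoChange", "NoChange")),
               "LossHypo")
  expect_equal(classify_trajectory(c("NoChange", "Hyper", "NoChange")),
               "Switch")
  expect_equal(classify_trajectory(c("Hyper", "Hypo", "Hyper")),
               "ExcludedPolaritySwitch")
  expect_equal(classify_trajectory(c("NoChange", "NoChange")), "NoChange")
  expect_equal(classify_trajectory(c("Hyper", "NoChange", "Hypo")), "Switch")
  expect_error(classify_trajectory(c("Hyper", "banana")), "invalid state")
  expect_error(classify_trajectory("Hyper"),
               class = "methrelapse_classification_error")
})

test_that("classification agrees with the procedural oracle exhaustively", {
  for (len in 2:5) {
    seqs <- all_state_sequences(len)
    got <- apply(seqs, 1, classify_trajectory)
    want <- apply(seqs, 1, oracle_classify)
    expect_equal(got, want, info = paste("length", len))
  }
})

test_that("state sequences are built per patient with coverage handling", {
  sheet <- tibble::tibble(
    sample_id = c("N1", "P1_P", "P1_R1", "P1_R2"),
    patient_id = c("ND", "P1", "P1", "P1"),
    subtype = c(NA, "RELA", "RELA", "RELA"),
    role = c("normal_cerebrum", "primary", "relapse", "relapse"),
    timepoint = c(NA, 0L, 1L, 2L),
    matched_normal_id = c(NA, "N1", "N1", "N1"),
    pdox_of = NA_character_, recurred = c(NA, TRUE, TRUE, TRUE)
  )
  call_row <- function(s, start, dir) {
    tibble::tibble(chrom = "chr1", start = start, end = start + 2L,
                   site_id = site_id("chr1", start), context = "CpG",
                   tumor_ratio = 0.5, normal_ratio = 0.1, delta = 0.4,
                   direction = dir, p_value = 0.001, q_value = 0.01,
                   tumor_cov = 30L, normal_cov = 30L, sample_id = s)
  }
  calls <- dplyr::bind_rows(
    call_row("P1_P", 100L, "Hyper"),
    call_row("P1_R1", 100L, "Hyper"),
    call_row("P1_R2", 100L, "Hyper"),
    call_row("P1_P", 200L, "NoChange"),
    call_row("P1_R1", 200L, "Hyper"),
    call_row("P1_R2", 200L, "Hyper"),
    call_row("P1_P", 300L, "Hyper"),
    # site 300 untested at R1 (coverage failure)
    call_row("P1_R2", 300L, "Hyper")
  )
  traj <- build_state_sequences(calls, sheet)
  expect_equal(nrow(traj), 3)
  got <- traj[match(site_id("chr1", c(100L, 200L, 300L)), traj$site_id), ]
  expect_equal(got$category, c("ConsistentHyper", "GainHyper", "Uncovered"))
  expect_equal(got$states[1], "Hyper,Hyper,Hyper")
  expect_false(got$covered[3])
  expect_true(all(got$has_primary))

  # a single-timepoint cohort cannot be classified
  expect_error(
    build_state_sequences(calls[calls$sample_id == "P1_P", ], sheet),
    class = "methrelapse_classification_error")
})

test_that("planted drivers classify consistent and boosters gain", {
  co <- small_cohort()
  pipe <- small_pipeline()
  truth <- co$truth$sites
  traj <- pipe$trajectories
  for (st in c("RELA", "PFA")) {
    pats <- unique(traj$patient_id[traj$subtype == st])
    drv <- truth[truth$subtype %in% st &
                   truth$label %in% c("driver_hyper", "driver_hypo"), ]
    sub <- traj[traj$site_id %in% drv$site_id & traj$subtype == st &
                  traj$covered, ]
    want <- ifelse(drv$direction[match(sub$site_id, drv$site_id)] == "hyper",
                   "ConsistentHyper", "ConsistentHypo")
    expect_gt(mean(sub$category == want), 0.95)

    bst <- truth[truth$subtype %in% st &
                   truth$label %in% c("booster_hyper", "booster_hypo"), ]
    subb <- traj[traj$site_id %in% bst$site_id & traj$subtype == st &
                   traj$covered, ]
    wantb <- ifelse(bst$direction[match(subb$site_id, bst$site_id)] == "hyper",
                    "GainHyper", "GainHypo")
    expect_gt(mean(subb$category == wantb), 0.95)
  }
})

test_that("category fractions sum to one and track the planted mix", {
  toy <- tibble::tibble(
    patient_id = "P1", subtype = "RELA",
    site_id = paste0("s", 1:20), chrom = "chr1", start = 1:20,
    n_timepoints = 3L, has_primary = TRUE, covered = TRUE,
    state_code = rep(c("HHH", "NHN"), each = 10),
    states = NA_character_,
    category = rep(c("ConsistentHyper", "Switch"), each = 10)
  )
  fr <- category_fractions(toy)
  expect_equal(sort(fr$fraction), c(0.5, 0.5))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)

  empty <- category_fractions(toy[0, ])
  expect_equal(nrow(empty), 0)

  # polarity switches are rare when none are planted as such
  fr_all <- small_pipeline()$category_fractions
  excl <- fr_all[fr_all$category == "ExcludedPolaritySwitch", ]
  expect_true(all(excl$fraction < 0.02))

  # per-patient fractions always sum to 1
  sums <- tapply(fr_all$fraction, fr_all$patient_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("state flows tally adjacent-timepoint transitions", {
  toy <- tibble::tibble(
    patient_id = "P1", subtype = "RELA",
    site_id = c("a", "b"), chrom = "chr1", start = 1:2,
    n_timepoints = 3L, has_primary = TRUE, covered = TRUE,
    state_code = c("NHH", "HHN"), states = NA_character_,
    category = c("GainHyper", "LossHyper")
  )
  fl <- state_flows(toy)
  expect_equal(sum(fl$n), 4)  # 2 sites x 2 adjacent pairs
  got <- fl[fl$from_timepoint == 0 & fl$state_from == "NoChange", ]
  expect_equal(got$state_to, "Hyper")
})
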