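test_that("the bundled case tables read back exactly as transcribed", {
  tb <- read_case_tables()
  expect_equal(dim(tb$lesion_doses), c(4L, 7L))
  expect_equal(tb$lesion_doses$DLN1, c(25.57, 9.43, 8.3, 7.24))
  expect_equal(tb$lesion_doses$B1, c(5.55, 0.64, 0.48, NA))
  expect_equal(nrow(tb$lesion_suv), 24L)
  b1c1 <- tb$lesion_suv[tb$lesion_suv$lesion == "B1" &
                          tb$lesion_suv$cycle == 1, ]
  expect_equal(unlist(b1c1[, c("suvmax_4h", "suvmax_24h", "suvmax_48h")],
                      use.names = FALSE), c(9.5, 4.21, 2.61))
  expect_equal(tb$organ_doses$lacrimal_glands[tb$organ_doses$method ==
                                                "voxel"],
               c(0.80, 0.51, 0.37, 0.30))
})

test_that("trajectories carry six lesions over four cycles with bone N/A at cycle 4", {
  recs <- case_lesion_records()
  traj <- build_trajectories(recs)
  dose <- traj[traj$measure == "dose_Gy_per_GBq", ]
  expect_equal(nrow(dose), 6L * 4L)
  na4 <- dose[dose$cycle == 4 & is.na(dose$value), "lesion"]
  expect_setequal(na4, c("B1", "B2", "B3"))
  # read-back equality against the wide fixture
  tb <- read_case_tables()
  for (les in c("LLN", "DLN1", "DLN2", "B1", "B2", "B3"))
    expect_equal(dose$value[dose$lesion == les][order(dose$cycle[dose$lesion == les])],
                 tb$lesion_doses[[les]])
  # statuses: LLN resolved from cycle 3, bones not measurable at cycle 4
  expect_true(all(traj$status[traj$lesion == "LLN" & traj$cycle >= 3] ==
                    "resolved"))
  expect_true(all(traj$status[traj$lesion %in% c("B1", "B2", "B3") &
                                traj$cycle == 4] == "not_measurable"))
})

test_that("trajectory tables round-trip through records", {
  recs <- case_lesion_records()
  traj <- build_trajectories(recs)
  traj2 <- build_trajectories(trajectories_to_records(traj))
  o1 <- traj[order(traj$lesion, traj$measure, traj$cycle, traj$time_h), ]
  o2 <- traj2[order(traj2$lesion, traj2$measure, traj2$cycle, traj2$time_h), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
  expect_equal(nrow(build_trajectories(list())), 0L)
})

test_that("duplicate ids and duplicate measurements are rejected", {
  recs <- case_lesion_records()
  expect_error(build_trajectories(c(recs, recs["B1"])), "unique")
  r <- recs$B1
  r$suv <- rbind(r$suv, r$suv[1, ])
  expect_error(build_trajectories(list(r)), "duplicate")
})

test_that("bone group mean dose at cycle 1 matches the arithmetic oracle", {
  recs <- case_lesion_records()
  oracle <- mean(c(5.55, 6.25, 3.75)) * 7.395   # 38.33 Gy
  expect_equal(group_mean_dose(recs, "bone", 1, 7.395), oracle)
  # permutation invariance in lesion order
  expect_equal(group_mean_dose(rev(recs), "bone", 1, 7.395), oracle)
  # single-lesion group equals that lesion's dose
  expect_equal(group_mean_dose(recs, "local_LN", 1, 7.395), 6.89 * 7.395)
  # linear in injected activity
  expect_equal(group_mean_dose(recs, "bone", 1, 2 * 7.395), 2 * oracle)
  # all bone lesions unmeasurable at cycle 4
  expect_error(suppressMessages(group_mean_dose(recs, "bone", 4, 7.395)),
               "no active")
  expect_message(group_mean_dose(recs, "bone", 3, 7.395), NA)
})

test_that("fold changes use printed values and refuse missing entries", {
  recs <- case_lesion_records()
  fc <- fold_change(recs, "B1", "dose_Gy_per_GBq", 1, 3)
  expect_equal(fc, 5.55 / 0.48)     # 11.56, i.e. more than 10-fold
  expect_gt(fc, 10)
  expect_equal(fold_change(recs, "DLN2", "volume_ml", 2, 3), 0.4 / 0.26)
  expect_equal(fold_change(recs, "B1", "volume_ml", 1, 4), 1)
  expect_error(fold_change(recs, "LLN", "suvmax", 1, 3), "resolved")
  expect_error(fold_change(recs, "B2", "dose_Gy_per_GBq", 1, 4),
               "not available")
  expect_error(fold_change(recs, "XX", "volume_ml", 1, 2), "unknown")
})

test_that("washout slopes match a log-linear regression oracle and sort", {
  recs <- case_lesion_records()
  slopes <- suppressMessages(
    tac_slope_compare(recs, c("B1", "B2", "B3"), 1))
  oracle_b1 <- unname(coef(stats::lm(log(c(9.5, 4.21, 2.61)) ~
                                       c(4, 24, 48)))[2])
  expect_equal(unname(slopes["B1"]), oracle_b1, tolerance = 1e-12)
  expect_true(!is.unsorted(slopes))
  # lesions without two valid points are skipped with a message
  expect_message(tac_slope_compare(recs, c("B1", "B2"), 3), "skipping")
  # scale invariance: scaling a TAC leaves the slope unchanged
  r <- recs$B1
  r$suv$suvmax <- r$suv$suvmax * 7
  s2 <- tac_slope_compare(list(r), "B1", 1)
  expect_equal(unname(s2["B1"]), oracle_b1, tolerance = 1e-12)
})

test_that("a constant SUVmax trajectory has zero washout slope", {
  cycles <- data.frame(cycle = 1L, status = "active", volume_ml = 1,
                       dose_Gy_per_GBq = 2)
  suv <- data.frame(cycle = 1L, time_h = c(4, 24, 48), suvmax = 5)
  r <- lesion_record("flat", "bone", cycles, suv)
  expect_equal(unname(tac_slope_compare(list(r), "flat", 1)["flat"]), 0)
})

test_that("lesion records enforce the resolved-status contract", {
  cycles <- data.frame(cycle = 1:2, status = c("active", "resolved"),
                       volume_ml = c(1, 0.5), dose_Gy_per_GBq = c(2, NA))
  suv_bad <- data.frame(cycle = c(1L, 2L), time_h = 24, suvmax = c(3, 1))
  expect_error(lesion_record("x", "bone", cycles, suv_bad), "resolved")
  suv_ok <- data.frame(cycle = c(1L, 2L), time_h = 24, suvmax = c(3, NA))
  expect_silent(lesion_record("x", "bone", cycles, suv_ok))
})
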