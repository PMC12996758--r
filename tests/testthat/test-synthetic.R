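test_that("histories are reproducible under a fixed seed", {
  cfg <- synth_config(2000, seed = 11,
                      incidence = expand_schedule(norway_incidence_groups(),
                                                  50, 85))
  h1 <- generate_histories(cfg)
  h2 <- generate_histories(cfg)
  expect_identical(h1$screens, h2$screens)
  expect_identical(h1$cancers, h2$cancers)
  expect_identical(suppressWarnings(histories_to_inputs(h1)),
                   suppressWarnings(histories_to_inputs(h2)))
  h3 <- generate_histories(synth_config(2000, seed = 12,
                                        incidence = cfg$incidence))
  expect_false(identical(h1$screens, h3$screens))
})

test_that("zero attendance produces no false positives or screen detections", {
  cfg <- synth_config(3000, seed = 1,
                      program = screening_program(attendance = 0),
                      incidence = expand_schedule(norway_incidence_groups(),
                                                  50, 85))
  h <- generate_histories(cfg)
  expect_false(any(h$screens$attended))
  expect_false(any(h$screens$result == "false_positive", na.rm = TRUE))
  expect_false(any(h$cancers$mode == "screen_detected"))
  expect_equal(derive_fp_cumulative(h), 0)
})

test_that("forced attendance and certain recall give one FP per woman", {
  cfg <- synth_config(500, seed = 2,
                      program = screening_program(attendance = 1),
                      fp_rate_first = 1, fp_rate_subsequent = 0)
  h <- generate_histories(cfg)
  expect_equal(derive_fp_cumulative(h), 1.0)
})

test_that("mean false positives per invitee matches the per-round expectation", {
  cfg <- synth_config(50000, seed = 3)
  h <- generate_histories(cfg)
  expected <- 0.75 * (0.045 + 9 * 0.025)  # 0.2025
  # per-woman FP count has variance ~ sum of p_r (1 - p_r) ~ 0.198
  se <- sqrt(0.198) / sqrt(cfg$n_women)
  expect_lt(abs(derive_fp_cumulative(h) - expected), 3 * se)
})

test_that("a degenerate configuration yields only screen-detected DCIS", {
  cfg <- synth_config(2000, seed = 4,
                      program = screening_program(attendance = 1),
                      sd_sensitivity = 1,
                      incidence = flat_sched(2000, 36),
                      dcis_share_sd = 1)
  h <- generate_histories(cfg)
  mm <- derive_detection_mode_mix(h)
  win <- h$cancers$age <= 69
  expect_true(all(h$cancers$mode[win] == "screen_detected"))
  expect_equal(unname(mm$dcis_share_by_mode["screen_detected"]), 1)
})

test_that("configured DCIS share and treatment mixes are recovered", {
  cfg <- synth_config(100000, seed = 5,
                      incidence = expand_schedule(norway_incidence_groups(),
                                                  50, 85))
  h <- generate_histories(cfg)
  mm <- derive_detection_mode_mix(h)
  n_sd <- sum(h$cancers$mode == "screen_detected")
  se <- sqrt(0.19 * 0.81 / n_sd)
  expect_lt(abs(mm$dcis_share_by_mode["screen_detected"] - 0.19), 3 * se)
  # screen-detected share among in-window cancers: attendance x sensitivity
  inputs <- histories_to_inputs(h)
  n_win <- sum(h$cancers$age >= 50 & h$cancers$age <= 69)
  expect_lt(abs(inputs$sd_share - 0.75 * 0.85),
            3 * sqrt(0.6375 * 0.3625 / n_win))
  # regimen mix recovery in the largest stratum
  mix_in <- default_treatment_mixes()$screen_invasive
  mix_out <- inputs$mixes$screen_detected_invasive
  n_str <- sum(h$cancers$mode == "screen_detected" &
                 h$cancers$histology == "invasive")
  for (k in names(mix_in)) {
    p <- unclass(mix_in)[k]
    expect_lt(abs(unclass(mix_out)[k] - p),
              3 * sqrt(p * (1 - p) / n_str) + 1e-12)
  }
})

test_that("single-regimen generators are re-derived at proportion one", {
  mx <- default_treatment_mixes()
  for (nm in names(mx)) mx[[nm]] <- single_regimen_mix(
    "Surgery and hormonal therapy")
  cfg <- synth_config(5000, seed = 6, treatment_mixes = mx,
                      incidence = flat_sched(1000, 36))
  h <- generate_histories(cfg)
  mixes <- suppressWarnings(derive_treatment_mixes(h))
  for (m in mixes)
    expect_equal(unname(unclass(m)["Surgery and hormonal therapy"]), 1)
})

test_that("deriving from empty histories errors informatively", {
  cfg <- synth_config(100, seed = 7)  # no incidence -> no cancers
  h <- generate_histories(cfg)
  expect_error(derive_detection_mode_mix(h), "no cancer events")
  expect_error(derive_treatment_mixes(h), "no cancer events")
  bundle <- histories_to_inputs(h)
  expect_equal(bundle$sd_share, 0)
  expect_gt(bundle$fp_cumulative, 0)
})

test_that("micro-simulation survival matches the deterministic projection", {
  bcm <- expand_schedule(norway_bc_mortality_groups(), 50, 85)
  allc <- all_cause_mortality_synthetic()
  n <- 200000
  cfg <- synth_config(n, seed = 8,
                      program = screening_program(attendance = 0),
                      bc_mortality = bcm, all_cause_mortality = allc)
  h <- generate_histories(cfg)
  oc <- other_cause_schedule(age_schedule(50, schedule_rate(allc, 50:85)), bcm)
  det <- project_cohort(n, bcm, oc, flat_sched(0, 36), NULL, 85)
  p <- det$n_alive / n
  se <- sqrt(p * (1 - p) / n)
  emp <- h$alive_by_age$n_alive / n
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))
})

test_that("histories export to a typed long-format CSV", {
  cfg <- synth_config(300, seed = 9,
                      incidence = flat_sched(3000, 36),
                      bc_mortality = flat_sched(100, 36),
                      all_cause_mortality = flat_sched(2000, 36))
  h <- generate_histories(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histories(h, path)
  x <- read.csv(path)
  expect_setequal(unique(x$record_kind), c("screen", "cancer", "death"))
  expect_equal(sum(x$record_kind == "cancer"), nrow(h$cancers))
  expect_equal(sum(x$record_kind == "death"), nrow(h$deaths))
})
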