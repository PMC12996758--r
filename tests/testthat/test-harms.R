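test_that("biennial invitations 50-69 give ten rounds of 75,000 screens", {
  tr <- immortal_cohort()
  rd <- screening_rounds(screening_program(), tr)
  expect_equal(nrow(rd), 10)
  expect_equal(rd$age, seq(50, 68, by = 2))
  expect_true(all(rd$screened == 75000))
  rd0 <- screening_rounds(screening_program(attendance = 0), tr)
  expect_true(all(rd0$screened == 0))
})

test_that("round screens track survivors of the projected cohort", {
  n <- 36
  tr <- project_cohort(1e5, flat_sched(0, n), flat_sched(2000, n),
                       flat_sched(0, n), NULL, 85)
  rd <- screening_rounds(screening_program(), tr)
  expect_equal(rd$screened[10],
               0.75 * tr$n_alive[tr$age == 68])
  short <- project_cohort(1e5, flat_sched(0, 6), flat_sched(0, 6),
                          flat_sched(0, 6), NULL, 55)
  expect_error(screening_rounds(screening_program(), short),
               "invitation ages")
})

test_that("per-round false positives apply first/subsequent rates", {
  rd <- screening_rounds(screening_program(), immortal_cohort())
  fc <- fp_counts(fp_model("per_round"), rd)
  expect_equal(fc$total, 75000 * 0.045 + 9 * 75000 * 0.025)
  expect_equal(fc$total, 20250)
  rd0 <- screening_rounds(screening_program(attendance = 0), immortal_cohort())
  expect_equal(fp_counts(fp_model("per_round"), rd0)$total, 0)
})

test_that("cumulative method yields 0.147 false positives per invitee", {
  rd <- screening_rounds(screening_program(), immortal_cohort())
  fc <- fp_counts(fp_model("cumulative"), rd)
  expect_equal(fc$total, 14700)
  # allocation proportional to screened counts
  expect_true(all(abs(fc$per_round$fp - 1470) < 1e-9))
})

test_that("false-positive QALY loss is count times the profile integral", {
  rd <- screening_rounds(screening_program(), immortal_cohort())
  fc <- fp_counts(fp_model("cumulative"), rd)
  loss <- fp_qaly_loss(fc)
  expect_equal(loss$per_event_loss, 0.025 / 12 + 0.0125 * 35 / 12)
  expect_equal(loss$total, 14700 * loss$per_event_loss)
  # invariant to how the same total is distributed across rounds
  shuffled <- fc$per_round
  shuffled$fp <- rev(shuffled$fp) * c(2, rep(1, 8), 0)
  shuffled$fp <- shuffled$fp * sum(fc$per_round$fp) / sum(shuffled$fp)
  expect_equal(fp_qaly_loss(shuffled)$total, loss$total)
  empty <- huv_profile(numeric(0), numeric(0))
  expect_equal(fp_qaly_loss(fc, profile = empty)$total, 0)
})

test_that("screen-detected base counts follow the configured source", {
  n <- 36
  inc <- flat_sched(200, n)
  tr <- project_cohort(1e5, flat_sched(0, n), flat_sched(0, n), inc, NULL, 85)
  pr <- screening_program()
  s1 <- screen_detected_base(pr, tr, sd_share = 1, source = "incidence_share")
  win <- tr$age >= 50 & tr$age <= 69
  expect_equal(s1[win], tr$incident_cases[win])
  expect_true(all(s1[!win] == 0))
  expect_true(all(screen_detected_base(pr, tr, 0, "incidence_share") == 0))
  s2 <- screen_detected_base(pr, tr, source = "per_screen_rate")
  expect_equal(sum(s2 > 0), 10)
  expect_equal(unique(s2[s2 > 0]), 0.75 * 1e5 * 0.006)  # 450 per round
  expect_error(screen_detected_base(pr, tr, 1.5, "incidence_share"),
               "\\[0, 1\\]")
})

test_that("fixed-point overdiagnosis doubles screen detection at OdP 50%", {
  s <- c(rep(450, 10), rep(0, 5))
  o <- overdiagnosed_counts(od_model("sd_proportional", odp = 0.5), s)
  expect_equal(sum(o), 4500)
  expect_equal(sum(overdiagnosed_counts(
    od_model("sd_proportional", odp = 0), s)), 0)
  o15 <- overdiagnosed_counts(od_model("sd_proportional", odp = 0.15), s)
  expect_equal(sum(o15), 0.15 * 4500 / 0.85, tolerance = 1e-9)
  expect_error(od_model("sd_proportional", odp = 1), "divergent")
})

test_that("overdiagnosed counts grow convexly with OdP", {
  s <- rep(100, 10)
  odps <- seq(0, 0.8, by = 0.2)
  tot <- vapply(odps, function(p) sum(overdiagnosed_counts(
    od_model("sd_proportional", odp = p), s)), numeric(1))
  expect_true(all(diff(tot) > 0))
  expect_true(all(diff(diff(tot)) > 0))  # superlinear, matching the fixed point
})

test_that("alternative overdiagnosis methods behave as specified", {
  s <- rep(200, 5)
  base_inc <- rep(300, 5)
  o <- overdiagnosed_counts(od_model("pre_screening_incidence", odp = 0.2),
                            s, base_inc)
  expect_equal(o, rep(60, 5))
  # equal DCIS/invasive proportions collapse to the single-proportion model
  o_split <- overdiagnosed_counts(
    od_model("dcis_invasive_split", odp_dcis = 0.3, odp_invasive = 0.3), s)
  o_single <- overdiagnosed_counts(od_model("sd_proportional", odp = 0.3), s)
  expect_equal(o_split, o_single)
})

test_that("overdiagnosis QALY loss accrues the mix harm over follow-up", {
  out <- overdiagnosis_qaly_loss(1000, 55)
  expect_equal(out$total, 1000 * 0.4712)
  bct <- overdiagnosis_qaly_loss(1000, 55, mix = single_regimen_mix(
    "BCT with or without radiation therapy"))
  expect_equal(bct$total, 1000 * 0.325)
  expect_equal(overdiagnosis_qaly_loss(0, 55)$total, 0)
  expect_error(overdiagnosis_qaly_loss(10, 55, followup = 0), "positive")
})

test_that("overdiagnosis loss is monotone in OdP, follow-up and harm", {
  s <- rep(100, 10); ages <- seq(50, 68, 2)
  loss_at <- function(p) {
    o <- overdiagnosed_counts(od_model("sd_proportional", odp = p), s)
    overdiagnosis_qaly_loss(o, ages)$total
  }
  expect_true(all(diff(vapply(c(0, 0.2, 0.4, 0.6), loss_at,
                              numeric(1))) > 0))
  o <- overdiagnosed_counts(od_model("sd_proportional", odp = 0.3), s)
  by_fu <- vapply(c(2, 5, 10), function(fu)
    overdiagnosis_qaly_loss(o, ages, oc = flat_sched(1000, 40, 50),
                            followup = fu, horizon = 85)$total, numeric(1))
  expect_true(all(diff(by_fu) > 0))
})

test_that("horizon truncation and survival weighting reduce the loss", {
  full <- overdiagnosis_qaly_loss(100, 80)$total
  trunc <- overdiagnosis_qaly_loss(100, 80, horizon = 85)$total
  expect_equal(trunc, full / 2)  # 5 of 10 follow-up years remain
  weighted <- overdiagnosis_qaly_loss(100, 55, oc = flat_sched(5000, 40, 50))$total
  expect_lt(weighted, overdiagnosis_qaly_loss(100, 55)$total)
})
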