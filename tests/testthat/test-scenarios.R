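null_shift <- function() {
  mx <- default_treatment_mixes()
  mx$symptomatic_dcis <- mx$screen_dcis
  mx$symptomatic_invasive <- mx$screen_invasive
  stage_shift_model(dcis_share_screen = 0.19, dcis_share_interval = 0.19,
                    mixes = mx)
}

null_scenario <- function() {
  scenario("null",
           reduction = trapezium_curve(0),
           fp = fp_model("per_round", fp_rate_first = 0,
                         fp_rate_subsequent = 0, cumulative_per_invitee = 0),
           od = od_model("sd_proportional", odp = 0),
           shift = null_shift())
}

test_that("a scenario with no effects produces an all-zero ledger", {
  res <- run_scenario(null_scenario())
  for (col in c("lyg_raw", "lyg_transferred", "fp_loss", "od_loss",
                "treatment_gain", "net", "cumulative_net"))
    expect_true(all(res$ledger[[col]] == 0), info = col)
  expect_true(is.na(turning_age(res)) || turning_age(res) == 50)
})

test_that("the ledger identity holds exactly at every age", {
  for (res in list(run_scenario(model_a()), run_scenario(model_b()))) {
    l <- res$ledger
    expect_equal(l$net,
                 l$lyg_transferred - l$fp_loss - l$od_loss + l$treatment_gain,
                 tolerance = 0)
    expect_equal(l$cumulative_net, cumsum(l$net), tolerance = 0)
    expect_equal(res$totals$net, sum(l$net))
    expect_equal(res$totals$lyg_raw, sum(l$lyg_raw))
  }
})

test_that("scenario runs are deterministic and repeatable", {
  r1 <- run_scenario(model_a())
  r2 <- run_scenario(model_a())
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$totals, r2$totals)
})

test_that("turning age is the first age after which net stays non-negative", {
  led <- data.frame(age = 50:53, cumulative_net = c(-5, -1, 2, 3))
  expect_equal(turning_age(led), 52)
  expect_true(is.na(turning_age(data.frame(age = 50:53,
                                           cumulative_net = rep(-1, 4)))))
  # a dip below zero after an early crossing postpones the turning age
  led2 <- data.frame(age = 50:54, cumulative_net = c(-1, 2, -3, 1, 5))
  expect_equal(turning_age(led2), 53)
})

test_that("cumulative net QALYs start negative and cross zero once", {
  for (sc in list(model_a(), model_b(),
                  model_miscan())) {
    res <- run_scenario(sc, allow_placeholders = TRUE)
    cn <- res$ledger$cumulative_net
    expect_lt(cn[1], 0)
    sign_changes <- sum(diff(cn >= 0) != 0)
    expect_equal(sign_changes, 1)
    expect_gt(cn[length(cn)], 0)
  }
})

test_that("net QALYs move monotonically with the headline parameters", {
  run_at <- function(param, value)
    run_scenario(set_param(model_a(), param, value))$totals$net
  set_param <- screenqaly:::set_scenario_param
  by_transfer <- vapply(seq(0, 1, length.out = 5), function(v)
    run_at("transfer", v), numeric(1))
  expect_true(all(diff(by_transfer) > 0))
  by_max <- vapply(seq(0, 0.4, length.out = 5), function(v)
    run_at("reduction.max", v), numeric(1))
  expect_true(all(diff(by_max) > 0))
  by_odp <- vapply(seq(0, 0.8, length.out = 5), function(v)
    run_at("od.odp", v), numeric(1))
  expect_true(all(diff(by_odp) < 0))
  by_fp <- vapply(seq(0, 0.4, length.out = 5), function(v)
    run_at("fp.cumulative_per_invitee", v), numeric(1))
  expect_true(all(diff(by_fp) < 0))
})

test_that("tornado endpoints bracket re-runs and degenerate axes collapse", {
  axes <- data.frame(parameter = c("transfer", "od.odp"),
                     low = c(0.5, 0.15), high = c(1.0, 0.15))
  tw <- tornado_sweep(model_a(), axes)
  expect_lt(tw$net_at_low[1], tw$net_at_high[1])
  expect_equal(tw$net_at_low[2], tw$net_at_high[2])
  expect_equal(tw$net_at_low[2], tw$baseline_net[1])
  expect_error(tornado_sweep(model_a(),
                             data.frame(parameter = "no.such.path",
                                        low = 1, high = 2)),
               "cannot resolve")
})

test_that("horizon extension differs two runs and demands schedule coverage", {
  ext <- function(g) extend_schedule(expand_schedule(g, 50, 85), 100)
  sch <- list(incidence = ext(norway_incidence_groups()),
              bc_mortality = ext(norway_bc_mortality_groups()),
              all_cause = all_cause_mortality_synthetic())
  sc <- model_a(schedules = sch)
  same <- horizon_extension(sc, 85)
  expect_equal(same$delta_net, 0)
  he <- horizon_extension(sc, 95)
  expect_gt(he$delta_net, 0)
  expect_gt(he$delta_lyg_raw, 0)
  # bundled grouped tables stop at 85: extension without coverage errors
  expect_error(horizon_extension(model_a(), 95), "covers only up to")
})

test_that("placeholder scenarios refuse to run silently", {
  expect_error(run_scenario(model_miscan()), "placeholder")
  expect_s3_class(run_scenario(model_miscan(), allow_placeholders = TRUE),
                  "scenario_result")
})

test_that("scenario outputs round-trip to ledger.csv and summary.json", {
  dir <- withr::local_tempdir()
  res <- run_scenario(model_b())
  paths <- write_scenario_outputs(res, dir)
  led <- read.csv(paths[["ledger"]])
  expect_equal(names(led),
               c("age", "lyg_raw", "lyg_transferred", "fp_loss", "od_loss",
                 "treatment_gain", "net", "cumulative_net"))
  expect_equal(led$net, res$ledger$net, tolerance = 1e-9)
  sm <- jsonlite::read_json(paths[["summary"]])
  expect_equal(sm$totals$net, res$totals$net, tolerance = 1e-9)
  expect_equal(sm$turning_age, res$turning_age)
})

test_that("horizons outside the supported range are rejected", {
  expect_error(scenario("x", horizon = 79), "\\[80, 100\\]")
  expect_error(scenario("x", horizon = 101), "\\[80, 100\\]")
})
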