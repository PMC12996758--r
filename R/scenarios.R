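#' Assemble a screening scenario
#'
#' A scenario bundles everything needed for one model variant: cohort size and
#' horizon, the screening program, the breast-cancer mortality reduction curve
#' and mortality-transfer factor, the false-positive and overdiagnosis models,
#' the stage-shift (treatment) model, and the rate schedules. The
#' screen-detected share `sd_share` (proportion of incident cases during
#' screening ages that are screen-detected) defaults to the value implied by
#' the synthetic-history generator's defaults, attendance 0.75 times episode
#' sensitivity 0.85 = 0.6375; it can be overridden directly or with a value
#' derived from generated histories via [histories_to_inputs()].
#'
#' @param label scenario name.
#' @param n0 cohort size (default 100,000).
#' @param horizon last age of follow-up, in `[80, 100]` (default 85).
#' @param program a [screening_program].
#' @param reduction a `reduction_curve`.
#' @param transfer mortality transfer, proportion in `[0, 1]` (default 0.8).
#' @param fp an [fp_model].
#' @param od an [od_model].
#' @param shift a [stage_shift_model].
#' @param schedules list with `incidence`, `bc_mortality` (either
#'   `age_group_rates` or `age_schedule`) and `all_cause` (`age_schedule`);
#'   defaults to the bundled 1980-1985 tables plus the synthetic all-cause
#'   schedule.
#' @param sd_share screen-detected share of incident cases (scalar or
#'   per-age).
#' @param regimens regimen registry.
#' @param placeholder logical; marks a scenario whose curve/overdiagnosis
#'   inputs are non-authoritative placeholders (see [model_miscan()]).
#' @return An object of class `scenario`.
#' @export
scenario <- function(label, n0 = 1e5, horizon = 85,
                     program = screening_program(),
                     reduction = trapezium_curve(0.40),
                     transfer = 0.8,
                     fp = fp_model("cumulative"),
                     od = od_model("sd_proportional", odp = 0.15),
                     shift = stage_shift_model(),
                     schedules = NULL,
                     sd_share = 0.6375,
                     regimens = default_regimens(),
                     placeholder = FALSE) {
  stopifnot(n0 > 0)
  if (horizon < 80 || horizon > 100)
    stop("supported analyses use a horizon in [80, 100]")
  if (is.null(schedules))
    schedules <- list(incidence = norway_incidence_groups(),
                      bc_mortality = norway_bc_mortality_groups(),
                      all_cause = all_cause_mortality_synthetic())
  stopifnot(inherits(program, "screening_program"),
            inherits(reduction, "reduction_curve"),
            inherits(fp, "fp_model"), inherits(od, "od_model"),
            inherits(shift, "stage_shift_model"))
  transfer <- transfer_factor(transfer)
  structure(list(label = label, n0 = n0, horizon = horizon, program = program,
                 reduction = reduction, transfer = transfer, fp = fp, od = od,
                 shift = shift, schedules = schedules, sd_share = sd_share,
                 regimens = regimens, placeholder = isTRUE(placeholder)),
            class = "scenario")
}

#' Preset scenarios
#'
#' `model_a()`: trapezium reduction with a 40% plateau, overdiagnosis
#' proportion 15%, cumulative false-positive method. `model_b()`: trapezium
#' with a 20% plateau, overdiagnosis proportion 50%, per-round false-positive
#' method. `model_miscan()`: file-based reduction curve and age-specific
#' overdiagnosis proportions as exported from a microsimulation model; the
#' bundled curve and proportions are clearly invented placeholders (the
#' authoritative values exist only as figures), so the preset refuses to run
#' unless `allow_placeholders = TRUE` is passed to [run_scenario()]. All three
#' presets use an 80% mortality transfer and follow-up to age 85.
#'
#' The false-positive method defaults follow the reported per-scenario losses
#' (equal losses for the first two scenarios imply the cumulative method for
#' both, per-round for the third), which contradicts the scenario table's
#' grouping; pass a different [fp_model] to override.
#'
#' @param ... passed on to [scenario()] to override any component.
#' @return A `scenario`.
#' @export
model_a <- function(...) {
  args <- list(...)
  defaults <- list(label = "Model A",
                   reduction = trapezium_curve(0.40),
                   od = od_model("sd_proportional", odp = 0.15),
                   fp = fp_model("cumulative"))
  do.call(scenario, utils::modifyList(defaults, args))
}

#' @rdname model_a
#' @export
model_b <- function(...) {
  args <- list(...)
  defaults <- list(label = "Model B",
                   reduction = trapezium_curve(0.20),
                   od = od_model("sd_proportional", odp = 0.50),
                   fp = fp_model("per_round"))
  do.call(scenario, utils::modifyList(defaults, args))
}

#' @rdname model_a
#' @param curve_path,odp_path optional paths to an authoritative reduction
#'   curve (`age,reduction`) and age-specific overdiagnosis-proportion table
#'   (`age,reduction`-style CSV with header `age,odp`); defaults are bundled
#'   placeholders.
#' @export
model_miscan <- function(curve_path = NULL, odp_path = NULL, ...) {
  args <- list(...)
  placeholder <- is.null(curve_path) || is.null(odp_path)
  if (is.null(curve_path))
    curve_path <- system.file("extdata", "reduction_miscan_placeholder.csv",
                              package = "screenqaly", mustWork = TRUE)
  if (is.null(odp_path))
    odp_path <- system.file("extdata", "odp_miscan_placeholder.csv",
                            package = "screenqaly", mustWork = TRUE)
  odp_tab <- utils::read.csv(odp_path, stringsAsFactors = FALSE)
  if (!all(c("age", "odp") %in% names(odp_tab)))
    stop("age-specific OdP table must have header 'age,odp'")
  defaults <- list(label = "Model MISCAN",
                   reduction = read_reduction_curve(curve_path,
                                                    label = "tabulated curve"),
                   od = od_model("sd_proportional", odp = 0),
                   fp = fp_model("cumulative"),
                   placeholder = placeholder)
  sc <- do.call(scenario, utils::modifyList(defaults, args))
  sc$od_age_table <- odp_tab
  sc
}

resolve_schedule <- function(x, age_start, horizon, what) {
  if (inherits(x, "age_group_rates"))
    x <- expand_schedule(x, age_start, min(horizon, max(x$age_end)))
  if (!inherits(x, "age_schedule"))
    stop(what, " schedule must be age_group_rates or age_schedule")
  if (x$age_end < horizon)
    stop(what, " schedule covers only up to age ", x$age_end,
         " but the horizon is ", horizon,
         "; supply extended rates or use extend_schedule()")
  x
}

#' Run a scenario and produce its per-age QALY ledger
#'
#' Orchestrates the full pipeline: schedule expansion, projection of the
#' uninvited and invited cohorts, life-years gained with mortality transfer,
#' false-positive and overdiagnosis QALY losses, the less-aggressive-treatment
#' QALY gain, and the net-QALY ledger
#' `net(a) = lyg_transferred(a) - fp_loss(a) - od_loss(a) + treatment_gain(a)`.
#' The run is a pure function of the scenario: identical inputs give
#' identical outputs.
#'
#' @param sc a [scenario].
#' @param allow_placeholders logical; must be `TRUE` to run a scenario flagged
#'   as carrying placeholder inputs.
#' @return An object of class `scenario_result`: list with `ledger` (data
#'   frame with per-age columns `lyg_raw`, `lyg_transferred`, `fp_loss`,
#'   `od_loss`, `treatment_gain`, `net`, `cumulative_net`), `totals`,
#'   `turning_age`, `mortality_reduction`, the two trajectories, and the
#'   rounds/false-positive tables.
#' @export
run_scenario <- function(sc, allow_placeholders = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$placeholder && !allow_placeholders)
    stop("scenario '", sc$label, "' uses placeholder curve/overdiagnosis ",
         "inputs; supply authoritative tables or set allow_placeholders = TRUE")
  age_start <- 50L
  inc <- resolve_schedule(sc$schedules$incidence, age_start, sc$horizon,
                          "incidence")
  bcm <- resolve_schedule(sc$schedules$bc_mortality, age_start, sc$horizon,
                          "breast-cancer mortality")
  allc <- resolve_schedule(sc$schedules$all_cause, age_start, sc$horizon,
                           "all-cause mortality")
  win <- function(s) age_schedule(age_start,
                                  schedule_rate(s, age_start:sc$horizon))
  inc <- win(inc); bcm <- win(bcm); allc <- win(allc)
  oc <- other_cause_schedule(allc, bcm)

  baseline <- project_cohort(sc$n0, bcm, oc, inc, NULL, sc$horizon, age_start)
  screened <- project_cohort(sc$n0, bcm, oc, inc, sc$reduction, sc$horizon,
                             age_start)
  ages <- screened$age

  lyg <- life_years_gained(baseline, screened, sc$transfer)

  rounds <- screening_rounds(sc$program, screened)
  fpc <- fp_counts(sc$fp, rounds)
  fpl <- fp_qaly_loss(fpc,
                      oc = if (sc$fp$truncate) oc else NULL,
                      horizon = if (sc$fp$truncate) sc$horizon else Inf)
  fp_age <- numeric(length(ages))
  fp_age[match(fpl$per_age$age, ages)] <- fpl$per_age$qaly_loss

  s_base <- screen_detected_base(sc$program, screened, sd_share = sc$sd_share,
                                 source = sc$od$sd_base_source)
  odm <- sc$od
  if (!is.null(sc$od_age_table)) {
    odp_age <- numeric(length(ages))
    idx <- match(sc$od_age_table$age, ages)
    odp_age[idx[!is.na(idx)]] <- sc$od_age_table$odp[!is.na(idx)]
    odm$odp <- odp_age
  }
  base_inc <- baseline$incident_cases
  win_mask <- ages >= sc$program$first_invite_age &
    ages <= sc$program$last_invite_age
  base_inc[!win_mask] <- 0
  od_counts <- overdiagnosed_counts(odm, s_base, base_inc)
  odl <- overdiagnosis_qaly_loss(od_counts, ages, regimens = sc$regimens,
                                 oc = oc, horizon = sc$horizon)

  gain <- less_aggressive_benefit(sc$shift, s_base, ages,
                                  regimens = sc$regimens, oc = oc,
                                  horizon = sc$horizon)

  lyg_raw_age <- lyg$per_age$lyg
  ledger <- data.frame(
    age = ages,
    lyg_raw = lyg_raw_age,
    lyg_transferred = lyg_raw_age * unclass(sc$transfer),
    fp_loss = fp_age,
    od_loss = odl$per_age$qaly_loss,
    treatment_gain = gain$per_age$qaly_gain)
  ledger$net <- ledger$lyg_transferred - ledger$fp_loss - ledger$od_loss +
    ledger$treatment_gain
  ledger$cumulative_net <- cumsum(ledger$net)

  totals <- list(lyg_raw = lyg$total_raw,
                 lyg_transferred = lyg$total_transferred,
                 fp_count = fpc$total,
                 fp_loss = fpl$total,
                 od_count = sum(od_counts),
                 od_loss = odl$total,
                 treatment_gain = gain$total,
                 net = lyg$total_transferred - fpl$total - odl$total +
                   gain$total)

  res <- list(scenario = sc, ledger = ledger, totals = totals,
              turning_age = turning_age(ledger),
              mortality_reduction = total_mortality_reduction(baseline,
                                                              screened),
              baseline = baseline, screened = screened,
              rounds = fpc$per_round, od_counts = od_counts, s_base = s_base)
  class(res) <- "scenario_result"
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  t <- x$totals
  cat("<scenario_result>", x$scenario$label, "| n0 =",
      format(x$scenario$n0, big.mark = ","), "| horizon",
      x$scenario$horizon, "\n")
  cat(sprintf("  LYG (raw / transferred): %0.0f / %0.0f\n",
              t$lyg_raw, t$lyg_transferred))
  cat(sprintf("  FP loss: %0.0f (%0.0f false positives) | OD loss: %0.0f (%0.0f cases) | treatment gain: %0.0f\n",
              t$fp_loss, t$fp_count, t$od_loss, t$od_count, t$treatment_gain))
  cat(sprintf("  net QALYs: %0.0f | turning age: %s | total BC mortality reduction: %0.1f%%\n",
              t$net, ifelse(is.na(x$turning_age), "never", x$turning_age),
              100 * x$mortality_reduction))
  invisible(x)
}

#' Turning age of a QALY ledger
#'
#' Smallest age at which the cumulative net QALYs are non-negative and remain
#' non-negative through the horizon; `NA` if no such age exists. Using
#' "remains non-negative" rather than the first crossing alone makes the
#' definition robust to non-monotone toy inputs; the two coincide on
#' trajectories that are monotone after crossing.
#'
#' @param ledger a ledger data frame with `age` and `cumulative_net` columns
#'   (or a `scenario_result`).
#' @return Age in years, or `NA`.
#' @export
turning_age <- function(ledger) {
  if (inherits(ledger, "scenario_result")) ledger <- ledger$ledger
  ok <- rev(cumprod(rev(ledger$cumulative_net >= 0))) == 1
  if (!any(ok)) return(NA_integer_)
  ledger$age[which(ok)[1]]
}

# set a scalar field along a dotted path; understands the scenario's
# structured components (reduction.max rebuilds the trapezium)
set_scenario_param <- function(sc, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (identical(parts, c("reduction", "max"))) {
    k <- sc$reduction$ages
    sc$reduction <- trapezium_curve(value, k[1], k[2], k[3], k[4])
    return(sc)
  }
  if (identical(parts, "transfer")) {
    sc$transfer <- transfer_factor(value)
    return(sc)
  }
  node <- sc
  for (p in parts[-length(parts)]) {
    if (is.null(node[[p]])) stop("cannot resolve parameter path: ", path)
    node <- node[[p]]
  }
  if (is.null(node[[parts[length(parts)]]]))
    stop("cannot resolve parameter path: ", path)
  expr <- paste0("sc", paste0("[['", parts, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  sc
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs a scenario with one parameter moved to its low and high bound while
#' everything else stays fixed, recording total net QALYs at each endpoint.
#' Parameter paths address scenario fields with dots, e.g. `"transfer"`,
#' `"reduction.max"`, `"od.odp"`, `"horizon"`, `"fp.fp_rate_first"`.
#'
#' @param sc a [scenario].
#' @param axes data frame with columns `parameter`, `low`, `high`.
#' @param allow_placeholders passed to [run_scenario()].
#' @return A `tornado_result` data frame with columns `parameter`, `low`,
#'   `high`, `net_at_low`, `net_at_high`, `baseline_net`.
#' @export
tornado_sweep <- function(sc, axes, allow_placeholders = FALSE) {
  stopifnot(inherits(sc, "scenario"),
            all(c("parameter", "low", "high") %in% names(axes)))
  base <- run_scenario(sc, allow_placeholders)$totals$net
  run_at <- function(param, value) {
    run_scenario(set_scenario_param(sc, param, value),
                 allow_placeholders)$totals$net
  }
  out <- axes
  out$net_at_low <- mapply(run_at, axes$parameter, axes$low)
  out$net_at_high <- mapply(run_at, axes$parameter, axes$high)
  out$baseline_net <- base
  class(out) <- c("tornado_result", "data.frame")
  out
}

#' Effect of extending the follow-up horizon
#'
#' Difference in total net QALYs and in life-years gained between two runs of
#' the same scenario differing only in horizon. Rate schedules must cover the
#' new horizon (see [extend_schedule()]).
#'
#' @param sc a [scenario].
#' @param new_horizon later horizon (>= the scenario's horizon).
#' @param allow_placeholders passed to [run_scenario()].
#' @return List with `delta_net`, `delta_lyg_raw`, `delta_lyg_transferred`,
#'   and the two `scenario_result`s.
#' @export
horizon_extension <- function(sc, new_horizon, allow_placeholders = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (new_horizon < sc$horizon)
    stop("new_horizon must not precede the scenario horizon")
  r0 <- run_scenario(sc, allow_placeholders)
  sc2 <- sc
  sc2$horizon <- new_horizon
  r1 <- run_scenario(sc2, allow_placeholders)
  list(delta_net = r1$totals$net - r0$totals$net,
       delta_lyg_raw = r1$totals$lyg_raw - r0$totals$lyg_raw,
       delta_lyg_transferred = r1$totals$lyg_transferred -
         r0$totals$lyg_transferred,
       original = r0, extended = r1)
}

#' Write scenario outputs to a directory
#'
#' Writes `ledger.csv` (per-age ledger with header
#' `age,lyg_raw,lyg_transferred,fp_loss,od_loss,treatment_gain,net,cumulative_net`)
#' and `summary.json` (totals, turning age, total mortality reduction and a
#' scenario echo).
#'
#' @param result a `scenario_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario_outputs <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ledger_path <- file.path(dir, "ledger.csv")
  utils::write.csv(result$ledger, ledger_path, row.names = FALSE)
  sc <- result$scenario
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(label = sc$label,
         n0 = sc$n0, horizon = sc$horizon,
         transfer = unclass(sc$transfer),
         fp_method = sc$fp$method, od_method = sc$od$method,
         totals = result$totals,
         turning_age = result$turning_age,
         total_mortality_reduction = result$mortality_reduction),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(ledger = ledger_path, summary = summary_path))
}
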