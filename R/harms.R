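#' Screening-program parameters
#'
#' Organized biennial two-view mammographic screening: invitations from
#' `first_invite_age` to `last_invite_age` every `interval` years (rounds at
#' ages 50, 52, ..., 68 under the defaults), an attendance rate of 75% among
#' invited women, and a screen-detection rate of 0.6% of examinations.
#'
#' @param first_invite_age,last_invite_age invitation age window (years).
#' @param interval years between rounds (>= 1).
#' @param attendance proportion of invited women screened per round.
#' @param sd_rate_per_screen screen-detected cancers per examination.
#' @return An object of class `screening_program`.
#' @export
screening_program <- function(first_invite_age = 50, last_invite_age = 69,
                              interval = 2, attendance = 0.75,
                              sd_rate_per_screen = 0.006) {
  stopifnot(first_invite_age <= last_invite_age, interval >= 1,
            attendance >= 0, attendance <= 1,
            sd_rate_per_screen >= 0, sd_rate_per_screen <= 1)
  structure(list(first_invite_age = first_invite_age,
                 last_invite_age = last_invite_age,
                 interval = interval, attendance = attendance,
                 sd_rate_per_screen = sd_rate_per_screen),
            class = "screening_program")
}

#' Ages at which screening rounds take place
#'
#' @param program a [screening_program].
#' @return Integer vector of round ages.
#' @export
round_ages <- function(program) {
  seq(program$first_invite_age, program$last_invite_age,
      by = program$interval)
}

#' False-positive counting model
#'
#' Two methods are supported. `"per_round"` counts a fixed percentage of
#' first-round examinations (4.5%) and of consecutive-round examinations
#' (2.5%) as false positives. `"cumulative"` applies an observed cumulative
#' false-positive risk per woman invited at age 50 (0.147), allocated across
#' rounds in proportion to the number screened.
#'
#' @param method `"cumulative"` or `"per_round"`.
#' @param fp_rate_first,fp_rate_subsequent per-examination false-positive
#'   rates for the first and consecutive rounds.
#' @param cumulative_per_invitee cumulative false positives per woman invited
#'   at the first round.
#' @param truncate logical; survival-weight false-positive QALY losses on the
#'   other-cause schedule (off by default; the effect is below 1%).
#' @return An object of class `fp_model`.
#' @export
fp_model <- function(method = c("cumulative", "per_round"),
                     fp_rate_first = 0.045, fp_rate_subsequent = 0.025,
                     cumulative_per_invitee = 0.147, truncate = FALSE) {
  method <- match.arg(method)
  stopifnot(fp_rate_first >= 0, fp_rate_first <= 1,
            fp_rate_subsequent >= 0, fp_rate_subsequent <= 1,
            cumulative_per_invitee >= 0)
  structure(list(method = method, fp_rate_first = fp_rate_first,
                 fp_rate_subsequent = fp_rate_subsequent,
                 cumulative_per_invitee = cumulative_per_invitee,
                 truncate = isTRUE(truncate)),
            class = "fp_model")
}

#' Overdiagnosis model
#'
#' Three ways to attach overdiagnosed cases to the projected cohort:
#' \describe{
#'   \item{`sd_proportional`}{a fixed proportion `odp` of *all* screen-detected
#'     cancers (including the added overdiagnosed ones) is overdiagnosed,
#'     while the non-overdiagnosed incidence stays at its pre-screening level;
#'     solving the fixed point gives `O = odp * S_base / (1 - odp)` per age,
#'     which is convex and superlinear in `odp`.}
#'   \item{`pre_screening_incidence`}{overdiagnosed cases are `odp` times the
#'     baseline (pre-screening) incident cases during screening ages,
#'     ignoring screen-detected counts.}
#'   \item{`dcis_invasive_split`}{separate proportions of screen-detected DCIS
#'     and invasive cancers are overdiagnosed, each via the same fixed point.}
#' }
#'
#' @param method one of the three methods above.
#' @param odp overdiagnosis proportion in `[0, 1)`; either a scalar or a
#'   per-age vector aligned with the screen-detected base counts (age-specific
#'   proportions, e.g. exported from a microsimulation model).
#' @param odp_dcis,odp_invasive proportions for the split method.
#' @param dcis_share DCIS share of screen-detected cases, used by the split
#'   method (default 0.19).
#' @param sd_base_source how non-overdiagnosed screen-detected counts are
#'   formed: `"incidence_share"` (a share of baseline incident cases; default)
#'   or `"per_screen_rate"` (0.6% of examinations at round ages).
#' @return An object of class `od_model`.
#' @export
od_model <- function(method = c("sd_proportional", "pre_screening_incidence",
                                "dcis_invasive_split"),
                     odp = 0, odp_dcis = 0, odp_invasive = 0,
                     dcis_share = 0.19,
                     sd_base_source = c("incidence_share", "per_screen_rate")) {
  method <- match.arg(method)
  sd_base_source <- match.arg(sd_base_source)
  chk <- function(p, what) {
    if (any(p < 0) || any(p > 1)) stop(what, " must lie in [0, 1]")
    if (any(p == 1)) stop(what, " of 1 gives a divergent fixed point")
  }
  chk(odp, "odp"); chk(odp_dcis, "odp_dcis"); chk(odp_invasive, "odp_invasive")
  stopifnot(dcis_share >= 0, dcis_share <= 1)
  structure(list(method = method, odp = odp, odp_dcis = odp_dcis,
                 odp_invasive = odp_invasive, dcis_share = dcis_share,
                 sd_base_source = sd_base_source),
            class = "od_model")
}

#' Screening rounds applied to a projected cohort
#'
#' @param program a [screening_program].
#' @param trajectory a `cohort_trajectory` covering the invitation ages.
#' @return Data frame with one row per round: `round`, `age`, `invited`
#'   (women alive at the round age), `screened` (`invited * attendance`).
#' @export
screening_rounds <- function(program, trajectory) {
  stopifnot(inherits(program, "screening_program"),
            inherits(trajectory, "cohort_trajectory"))
  ra <- round_ages(program)
  if (!all(ra %in% trajectory$age))
    stop("trajectory does not cover invitation ages ",
         paste(setdiff(ra, trajectory$age), collapse = ", "))
  invited <- trajectory$n_alive[match(ra, trajectory$age)]
  data.frame(round = seq_along(ra), age = ra, invited = invited,
             screened = invited * program$attendance)
}

#' False-positive counts per round
#'
#' @param model an [fp_model].
#' @param rounds round table from [screening_rounds()].
#' @return List with `per_round` (the rounds table plus an `fp` column) and
#'   `total`.
#' @export
fp_counts <- function(model, rounds) {
  stopifnot(inherits(model, "fp_model"))
  if (nrow(rounds) == 0) stop("rounds table is empty")
  if (model$method == "per_round") {
    rate <- c(model$fp_rate_first,
              rep(model$fp_rate_subsequent, nrow(rounds) - 1L))
    fp <- rounds$screened * rate
  } else {
    total <- rounds$invited[1] * model$cumulative_per_invitee
    wt <- if (sum(rounds$screened) > 0) rounds$screened else rounds$invited
    fp <- total * wt / sum(wt)
  }
  rounds$fp <- fp
  list(per_round = rounds, total = sum(fp))
}

#' QALY loss from false-positive screening results
#'
#' Each false positive incurs the time integral of the HUV decrement profile
#' (0.0385417 QALYs under the default profile); losses are attributed to the
#' age of the round in which the false positive occurs. Optional survival
#' weighting multiplies each round's per-event loss by the expected fraction
#' of the profile lived under the other-cause schedule.
#'
#' @param fp result of [fp_counts()], or any data frame with `age` and `fp`
#'   columns.
#' @param profile an [huv_profile]; default [fp_huv_profile()].
#' @param oc optional other-cause `age_schedule` for survival weighting.
#' @param horizon follow-up horizon for truncation (default `Inf`).
#' @return List with `total` QALYs lost, `per_age` data frame, and
#'   `per_event_loss`.
#' @export
fp_qaly_loss <- function(fp, profile = fp_huv_profile(), oc = NULL,
                         horizon = Inf) {
  stopifnot(inherits(profile, "huv_profile"))
  dur <- sum(profile$duration)
  if (dur > 40) stop("profile duration exceeds 40 years")
  tab <- if (is.data.frame(fp)) fp else fp$per_round
  per_event <- profile_integral(profile)
  wt <- if (is.null(oc) && is.infinite(horizon)) rep(1, nrow(tab))
        else accrual_weight(tab$age, oc = oc, horizon = horizon, years = dur)
  loss <- tab$fp * per_event * wt
  list(total = sum(loss),
       per_age = data.frame(age = tab$age, qaly_loss = loss),
       per_event_loss = per_event)
}

#' Non-overdiagnosed screen-detected case counts per age
#'
#' @param program a [screening_program].
#' @param trajectory a `cohort_trajectory` with incident cases.
#' @param sd_share proportion of incident cases that are screen-detected,
#'   either a scalar or a per-age vector aligned with the trajectory; used by
#'   the `"incidence_share"` source.
#' @param source `"incidence_share"` (share of baseline incident cases within
#'   the invitation window) or `"per_screen_rate"` (`screened *
#'   sd_rate_per_screen` at round ages).
#' @return Numeric vector aligned with `trajectory$age`; zero outside
#'   screening ages.
#' @export
screen_detected_base <- function(program, trajectory, sd_share = NULL,
                                 source = c("incidence_share",
                                            "per_screen_rate")) {
  source <- match.arg(source)
  stopifnot(inherits(program, "screening_program"),
            inherits(trajectory, "cohort_trajectory"))
  ages <- trajectory$age
  out <- numeric(length(ages))
  if (source == "incidence_share") {
    if (is.null(sd_share)) stop("sd_share is required for incidence_share")
    if (any(sd_share < 0) || any(sd_share > 1))
      stop("sd_share must lie in [0, 1]")
    share <- rep_len(sd_share, length(ages))
    win <- ages >= program$first_invite_age & ages <= program$last_invite_age
    out[win] <- trajectory$incident_cases[win] * share[win]
  } else {
    rounds <- screening_rounds(program, trajectory)
    out[match(rounds$age, ages)] <- rounds$screened * program$sd_rate_per_screen
  }
  out
}

#' Overdiagnosed case counts per age
#'
#' @param model an [od_model].
#' @param s_base per-age non-overdiagnosed screen-detected counts.
#' @param baseline_incidence_cases per-age baseline incident cases (required
#'   for the `pre_screening_incidence` method); entries outside screening ages
#'   should already be zeroed by the caller.
#' @return Per-age overdiagnosed counts, aligned with `s_base`.
#' @export
overdiagnosed_counts <- function(model, s_base,
                                 baseline_incidence_cases = NULL) {
  stopifnot(inherits(model, "od_model"))
  switch(model$method,
    sd_proportional = {
      odp <- rep_len(model$odp, length(s_base))
      odp * s_base / (1 - odp)
    },
    pre_screening_incidence = {
      if (is.null(baseline_incidence_cases))
        stop("baseline incident cases required for pre_screening_incidence")
      stopifnot(length(baseline_incidence_cases) == length(s_base))
      rep_len(model$odp, length(s_base)) * baseline_incidence_cases
    },
    dcis_invasive_split = {
      s_dcis <- s_base * model$dcis_share
      s_inv <- s_base - s_dcis
      model$odp_dcis * s_dcis / (1 - model$odp_dcis) +
        model$odp_invasive * s_inv / (1 - model$odp_invasive)
    })
}

#' QALY loss from treating overdiagnosed women
#'
#' Each overdiagnosed woman accrues the expected treatment harm of the
#' overdiagnosed-treatment mix over a 10-year follow-up, survival-weighted on
#' the other-cause mortality schedule and truncated at the horizon.
#'
#' @param od_counts per-age overdiagnosed counts aligned with `ages`.
#' @param ages ages (years).
#' @param mix [treatment_mix] for overdiagnosed women; default
#'   [overdiagnosed_mix()].
#' @param regimens regimen registry.
#' @param oc other-cause `age_schedule`, or `NULL` for no survival weighting.
#' @param followup follow-up years of treatment harm (> 0, default 10).
#' @param horizon truncation horizon (default `Inf`).
#' @param shape yearly harm shape passed to [regimen_yearly_profile()].
#' @return List with `total` QALYs lost, `per_age` data frame, and
#'   `per_case_harm` (untruncated expected harm per woman).
#' @export
overdiagnosis_qaly_loss <- function(od_counts, ages,
                                    mix = NULL,
                                    regimens = default_regimens(),
                                    oc = NULL, followup = 10, horizon = Inf,
                                    shape = "uniform") {
  if (followup <= 0) stop("followup must be positive")
  stopifnot(length(od_counts) == length(ages))
  if (is.null(mix)) mix <- overdiagnosed_mix(regimens)
  per_case <- mix_expected_harm(mix, regimens)
  # the regimen harm profile spans 10 years; `followup` and the horizon
  # truncate it (they never rescale the yearly rate)
  profile_years <- 10
  cap <- pmin(horizon, ages + followup)
  if (shape == "uniform") {
    wt <- accrual_weight(ages, oc = oc, horizon = cap, years = profile_years)
    harm <- per_case * wt
  } else {
    prof <- regimen_yearly_profile(per_case, shape = shape,
                                   years = profile_years)
    harm <- vapply(seq_along(ages), function(j) {
      a <- ages[j]
      k <- max(0, min(profile_years, cap[j] - a))
      if (k == 0) return(0)
      surv <- 1
      tot <- 0
      for (t in seq_len(ceiling(k))) {
        frac <- min(1, k - (t - 1))
        tot <- tot + prof$decrement[t] * surv * frac
        if (!is.null(oc))
          surv <- surv * (1 - annual_probability(schedule_rate(oc, a + t - 1)))
      }
      tot
    }, numeric(1))
  }
  loss <- od_counts * harm
  list(total = sum(loss),
       per_age = data.frame(age = ages, qaly_loss = loss),
       per_case_harm = per_case)
}
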