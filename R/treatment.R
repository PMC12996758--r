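#' Health-utility decrement profile
#'
#' A piecewise-constant decrement in health utility value (HUV) over time:
#' ordered segments of (duration in years, decrement in HUV units). The QALY
#' loss implied by the profile is its time integral,
#' `sum(duration * decrement)`.
#'
#' @param duration segment durations in years, all > 0.
#' @param decrement HUV decrements per segment, all >= 0.
#' @return An object of class `huv_profile`.
#' @examples
#' # false-positive profile: -0.025 for one month, then -0.0125 for the
#' # remainder of three years
#' p <- huv_profile(c(1/12, 35/12), c(0.025, 0.0125))
#' profile_integral(p)  # 0.0385417 QALYs per event
#' @export
huv_profile <- function(duration, decrement) {
  stopifnot(length(duration) == length(decrement))
  if (any(duration <= 0)) stop("segment durations must be positive")
  if (any(decrement < 0)) stop("HUV decrements must be non-negative")
  structure(list(duration = as.numeric(duration),
                 decrement = as.numeric(decrement)),
            class = "huv_profile")
}

#' @rdname huv_profile
#' @param profile an `huv_profile`.
#' @export
profile_integral <- function(profile) {
  stopifnot(inherits(profile, "huv_profile"))
  sum(profile$duration * profile$decrement)
}

#' Default false-positive HUV-loss profile
#'
#' A recalled woman without cancer loses 0.025 HUV during the first month and
#' 0.0125 HUV thereafter. Under the default `"36mo"` reading the depressed
#' period totals three years (month 1 at 0.025, months 2-36 at 0.0125), giving
#' 0.0385417 QALYs per false positive; `"37mo"` reads "for 3 years after" as
#' 36 further months (0.0395833 per false positive).
#'
#' @param reading `"36mo"` (default) or `"37mo"`.
#' @return An `huv_profile`.
#' @export
fp_huv_profile <- function(reading = c("36mo", "37mo")) {
  reading <- match.arg(reading)
  months <- if (reading == "36mo") 35 else 36
  huv_profile(c(1 / 12, months / 12), c(0.025, 0.0125))
}

#' Treatment-regimen registry
#'
#' The five regimens modelled for breast-cancer treatment, their cumulative
#' HUV loss over a 10-year follow-up, and the share of overdiagnosed women
#' assumed to receive each (the mid points of the sensitivity ranges). The
#' bundled registry can be replaced by any CSV with header
#' `regimen,cumulative_harm_10y,proportion_overdiagnosed`.
#'
#' @param path optional CSV path; default is the bundled registry.
#' @return A data frame of class `regimen_registry` with columns `regimen`,
#'   `cumulative_harm_10y`, `proportion_overdiagnosed`.
#' @export
default_regimens <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "regimens.csv", package = "screenqaly",
                        mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("regimen", "cumulative_harm_10y", "proportion_overdiagnosed")
  if (!all(need %in% names(x)))
    stop("regimen registry must have columns: ", paste(need, collapse = ", "))
  if (any(x$cumulative_harm_10y < 0)) stop("regimen harms must be >= 0")
  class(x) <- c("regimen_registry", "data.frame")
  x
}

#' Yearly HUV-loss profile for a treatment regimen
#'
#' Distributes a 10-year cumulative harm over yearly values. `"uniform"`
#' spreads it evenly; `"front_loaded"` uses a geometric decay with ratio 0.7
#' normalized to the cumulative total, reflecting that acute treatment effects
#' dominate the first years. Either way the profile integrates back to the
#' cumulative harm.
#'
#' @param cumulative total HUV loss over `years` of follow-up (>= 0).
#' @param shape `"uniform"` or `"front_loaded"`.
#' @param years follow-up length, default 10.
#' @return An `huv_profile` with `years` one-year segments.
#' @export
regimen_yearly_profile <- function(cumulative,
                                   shape = c("uniform", "front_loaded"),
                                   years = 10) {
  shape <- match.arg(shape)
  if (cumulative < 0) stop("cumulative harm must be >= 0")
  stopifnot(years >= 1)
  w <- switch(shape,
              uniform = rep(1, years),
              front_loaded = 0.7^(seq_len(years) - 1))
  huv_profile(rep(1, years), cumulative * w / sum(w))
}

#' Treatment mix
#'
#' Proportions of cases receiving each treatment regimen; must be non-negative
#' and sum to 1.
#'
#' @param proportions named numeric vector, names matching the regimen
#'   registry.
#' @return An object of class `treatment_mix`.
#' @export
treatment_mix <- function(proportions) {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    stop("treatment mix proportions must be named by regimen")
  if (any(proportions < 0)) stop("mix proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("mix proportions must sum to 1 (got ", sum(proportions), ")")
  structure(as.numeric(proportions), names = names(proportions),
            class = "treatment_mix")
}

#' Expected 10-year treatment harm under a mix
#'
#' The mix-weighted mean of the regimens' cumulative 10-year HUV losses,
#' `sum(p_k * h_k)`.
#'
#' @param mix a [treatment_mix].
#' @param regimens a regimen registry (see [default_regimens()]).
#' @return Expected HUV loss per treated case over 10 years.
#' @export
mix_expected_harm <- function(mix, regimens = default_regimens()) {
  stopifnot(inherits(mix, "treatment_mix"))
  missing <- setdiff(names(mix), regimens$regimen)
  if (length(missing))
    stop("regimen(s) not in registry: ", paste(missing, collapse = ", "))
  h <- regimens$cumulative_harm_10y[match(names(mix), regimens$regimen)]
  sum(unclass(mix) * h)
}

#' Mix of treatments assumed for overdiagnosed women
#'
#' @param regimens a regimen registry with a `proportion_overdiagnosed` column.
#' @return A [treatment_mix] built from that column.
#' @export
overdiagnosed_mix <- function(regimens = default_regimens()) {
  treatment_mix(stats::setNames(regimens$proportion_overdiagnosed,
                                regimens$regimen))
}

#' Default treatment mixes by detection mode and histology
#'
#' Synthetic stand-ins for registry treatment distributions (which are not
#' publicly printed): screen-detected cancers receive systemic therapy less
#' often than symptomatic ones, and DCIS is treated almost exclusively
#' surgically. These defaults double as the generator parameters of
#' [synth_config()] and can be overridden with any set of [treatment_mix]
#' objects.
#'
#' @return Named list of [treatment_mix] objects: `screen_dcis`,
#'   `screen_invasive`, `symptomatic_dcis`, `symptomatic_invasive`.
#' @export
default_treatment_mixes <- function() {
  rg <- c("BCT with or without radiation therapy",
          "Mastectomy with or without radiation therapy",
          "Surgery and hormonal therapy",
          "Surgery and chemotherapy",
          "Surgery, hormonal therapy and chemotherapy")
  mk <- function(p) treatment_mix(stats::setNames(p, rg))
  list(
    screen_dcis          = mk(c(0.70, 0.28, 0.02, 0.00, 0.00)),
    screen_invasive      = mk(c(0.40, 0.15, 0.25, 0.12, 0.08)),
    symptomatic_dcis     = mk(c(0.52, 0.44, 0.04, 0.00, 0.00)),
    symptomatic_invasive = mk(c(0.18, 0.22, 0.25, 0.17, 0.18))
  )
}

#' Stage-shift model for less aggressive treatment
#'
#' Screen-detected, non-overdiagnosed cancers fall into three groups with a
#' treatment benefit: (a) DCIS that would also have been diagnosed as DCIS
#' without screening, (b) DCIS that would have presented as invasive cancer,
#' and (d) invasive cancers that would have been diagnosed later. Group sizes
#' derive from the DCIS share among screen-detected cancers
#' (`dcis_share_screen`) and, for group (a), the DCIS share among interval
#' cancers as a proxy for symptomatic presentation (`dcis_share_interval`,
#' published range 5-7%, default at the midpoint 6%).
#'
#' @param dcis_share_screen DCIS share among screen-detected cancers (default
#'   0.19).
#' @param dcis_share_interval DCIS share among interval cancers (default 0.06);
#'   must not exceed `dcis_share_screen`.
#' @param mixes named list of four [treatment_mix] objects as returned by
#'   [default_treatment_mixes()].
#' @return An object of class `stage_shift_model`.
#' @export
stage_shift_model <- function(dcis_share_screen = 0.19,
                              dcis_share_interval = 0.06,
                              mixes = default_treatment_mixes()) {
  stopifnot(dcis_share_screen >= 0, dcis_share_screen <= 1,
            dcis_share_interval >= 0, dcis_share_interval <= 1)
  if (dcis_share_interval > dcis_share_screen)
    stop("interval-cancer DCIS share cannot exceed the screen-detected share")
  need <- c("screen_dcis", "screen_invasive", "symptomatic_dcis",
            "symptomatic_invasive")
  if (!all(need %in% names(mixes)))
    stop("mixes must contain: ", paste(need, collapse = ", "))
  for (m in need) stopifnot(inherits(mixes[[m]], "treatment_mix"))
  structure(list(dcis_share_screen = dcis_share_screen,
                 dcis_share_interval = dcis_share_interval,
                 mixes = mixes),
            class = "stage_shift_model")
}

# Survival-weighted accrual factor: expected fraction of a `years`-long,
# uniform-in-time exposure starting at each of `ages` that is actually lived,
# given the other-cause mortality schedule and the follow-up horizon.
# oc = NULL disables survival weighting; horizon = Inf disables truncation.
accrual_weight <- function(ages, oc = NULL, horizon = Inf, years = 10) {
  horizon <- rep_len(horizon, length(ages))
  vapply(seq_along(ages), function(j) {
    a <- ages[j]
    k <- max(0, min(years, horizon[j] - a))
    if (k == 0) return(0)
    full <- floor(k)
    frac <- k - full
    surv <- 1
    w <- 0
    t <- 0
    while (t < full) {
      w <- w + surv
      if (!is.null(oc))
        surv <- surv * (1 - annual_probability(schedule_rate(oc, a + t)))
      t <- t + 1
    }
    if (frac > 0) w <- w + surv * frac
    w / years
  }, numeric(1))
}

#' QALY gain from less aggressive treatment of screen-detected cancers
#'
#' For each non-overdiagnosed screen-detected case, the gain is the expected
#' 10-year treatment harm under the counterfactual (symptomatic-detection)
#' mix minus the harm under the screen-detection mix, weighted over groups
#' (a), (b) and (d) of the stage-shift model, survival-weighted on the
#' other-cause mortality schedule and truncated at the horizon. A negative
#' per-case gain (counterfactual milder than actual) is allowed and reported
#' with a message.
#'
#' @param shift a [stage_shift_model].
#' @param non_od_sd_counts per-age counts of non-overdiagnosed screen-detected
#'   cases, aligned with `ages`.
#' @param ages ages (years) corresponding to `non_od_sd_counts`.
#' @param regimens regimen registry.
#' @param oc other-cause mortality `age_schedule`, or `NULL` for no survival
#'   weighting.
#' @param horizon follow-up horizon for truncation (default `Inf`).
#' @return List with `total` QALYs gained, `per_age` data frame, and
#'   `per_case_gain` (the unweighted 10-year gain per case).
#' @export
less_aggressive_benefit <- function(shift, non_od_sd_counts, ages,
                                    regimens = default_regimens(),
                                    oc = NULL, horizon = Inf) {
  stopifnot(inherits(shift, "stage_shift_model"),
            length(non_od_sd_counts) == length(ages))
  if (any(non_od_sd_counts < 0)) stop("case counts must be non-negative")
  m <- shift$mixes
  h <- function(mix) mix_expected_harm(mix, regimens)
  w_a <- shift$dcis_share_interval
  w_b <- shift$dcis_share_screen - shift$dcis_share_interval
  w_d <- 1 - shift$dcis_share_screen
  gain_per_case <-
    w_a * (h(m$symptomatic_dcis) - h(m$screen_dcis)) +
    w_b * (h(m$symptomatic_invasive) - h(m$screen_dcis)) +
    w_d * (h(m$symptomatic_invasive) - h(m$screen_invasive))
  if (gain_per_case < 0)
    message("counterfactual treatment is milder than screen-detected ",
            "treatment: per-case gain is negative (",
            signif(gain_per_case, 4), ")")
  wt <- accrual_weight(ages, oc = oc, horizon = horizon)
  per_age <- non_od_sd_counts * gain_per_case * wt
  list(total = sum(per_age),
       per_age = data.frame(age = ages, qaly_gain = per_age),
       per_case_gain = gain_per_case)
}
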