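#' Configuration for the synthetic screening-history generator
#'
#' Generates BreastScreen-Norway-like individual histories: biennial
#' invitations with Bernoulli attendance, false-positive results (4.5% of
#' first-round and 2.5% of consecutive-round examinations), breast-cancer
#' onset drawn from an incidence schedule, detection-mode assignment
#' (screen-detected with probability attendance x episode sensitivity while
#' covered by the program, otherwise interval or symptomatic), histology
#' (DCIS vs invasive) by mode, treatment-regimen assignment from per-stratum
#' mixes, and optional competing mortality. Cancer onset is driven by the
#' incidence schedule rather than by a per-examination detection rate so that
#' total incidence among invitees matches the pre-screening baseline (the
#' generator adds no overdiagnosis); the per-screen detection rate remains a
#' deterministic-model parameter.
#'
#' Women exit screening after a breast-cancer diagnosis. All draws derive from
#' a single seed; runs with the same configuration are exactly reproducible.
#'
#' @param n_women number of women (> 0).
#' @param seed integer RNG seed.
#' @param program a [screening_program].
#' @param fp_rate_first,fp_rate_subsequent per-examination false-positive
#'   probabilities.
#' @param sd_sensitivity probability that a cancer arising in a program
#'   attender is screen-detected (episode sensitivity, default 0.85).
#' @param incidence optional `age_schedule` of breast-cancer incidence; `NULL`
#'   disables cancers.
#' @param dcis_share_sd,dcis_share_interval,dcis_share_symptomatic DCIS
#'   shares by detection mode (defaults 0.19, 0.06, 0.06).
#' @param treatment_mixes named list as from [default_treatment_mixes()];
#'   interval cancers use the symptomatic mixes.
#' @param bc_mortality,all_cause_mortality optional `age_schedule`s enabling
#'   competing mortality (other-cause = all-cause minus breast-cancer).
#' @param horizon last age simulated (default 85).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_women, seed = 1L,
                         program = screening_program(),
                         fp_rate_first = 0.045, fp_rate_subsequent = 0.025,
                         sd_sensitivity = 0.85,
                         incidence = NULL,
                         dcis_share_sd = 0.19, dcis_share_interval = 0.06,
                         dcis_share_symptomatic = 0.06,
                         treatment_mixes = default_treatment_mixes(),
                         bc_mortality = NULL, all_cause_mortality = NULL,
                         horizon = 85) {
  stopifnot(n_women > 0, inherits(program, "screening_program"))
  for (p in c(fp_rate_first, fp_rate_subsequent, sd_sensitivity,
              dcis_share_sd, dcis_share_interval, dcis_share_symptomatic))
    stopifnot(p >= 0, p <= 1)
  structure(list(n_women = as.integer(n_women), seed = as.integer(seed),
                 program = program, fp_rate_first = fp_rate_first,
                 fp_rate_subsequent = fp_rate_subsequent,
                 sd_sensitivity = sd_sensitivity, incidence = incidence,
                 dcis_share_sd = dcis_share_sd,
                 dcis_share_interval = dcis_share_interval,
                 dcis_share_symptomatic = dcis_share_symptomatic,
                 treatment_mixes = treatment_mixes,
                 bc_mortality = bc_mortality,
                 all_cause_mortality = all_cause_mortality,
                 horizon = horizon),
            class = "synth_config")
}

sample_mix <- function(mix, n) {
  if (n == 0) return(character(0))
  sample(names(mix), n, replace = TRUE, prob = unclass(mix))
}

#' Generate synthetic individual screening histories
#'
#' @param config a [synth_config].
#' @return An object of class `synth_histories`: a list with data frames
#'   `screens` (`id`, `round`, `age`, `attended`, `result`), `cancers` (`id`,
#'   `age`, `mode`, `histology`, `regimen`), `deaths` (`id`, `age`, `cause`),
#'   `alive_by_age` (per-age count alive at the start of the age-year), and
#'   the generating `config`.
#' @export
generate_histories <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_women
  pr <- config$program
  ra <- round_ages(pr)
  age0 <- 50L
  ages <- seq.int(age0, config$horizon)

  q_bc <- q_oc <- rep(0, length(ages))
  if (!is.null(config$all_cause_mortality)) {
    q_all <- annual_probability(schedule_rate(config$all_cause_mortality, ages))
    if (!is.null(config$bc_mortality)) {
      q_bc <- annual_probability(schedule_rate(config$bc_mortality, ages))
      q_oc <- pmax(q_all - q_bc, 0)
    } else q_oc <- q_all
  }
  q_inc <- if (is.null(config$incidence)) rep(0, length(ages)) else
    annual_probability(schedule_rate(config$incidence, ages))

  alive <- rep(TRUE, n)
  diagnosed <- rep(FALSE, n)
  alive_by_age <- integer(length(ages))
  screens <- vector("list", length(ra))
  cancer_id <- integer(0); cancer_age <- integer(0); cancer_mode <- character(0)
  death_id <- integer(0); death_age <- integer(0); death_cause <- character(0)

  covered_until <- ra[length(ra)] + pr$interval - 1L

  for (i in seq_along(ages)) {
    a <- ages[i]
    alive_by_age[i] <- sum(alive)
    if (i == length(ages)) break

    # deaths first within the cycle
    if (q_bc[i] + q_oc[i] > 0) {
      idx <- which(alive)
      u <- stats::runif(length(idx))
      d_bc <- u < q_bc[i]
      d_oc <- !d_bc & u < q_bc[i] + q_oc[i]
      died <- idx[d_bc | d_oc]
      if (length(died)) {
        death_id <- c(death_id, died)
        death_age <- c(death_age, rep(a, length(died)))
        death_cause <- c(death_cause,
                         ifelse(d_bc[d_bc | d_oc], "breast_cancer", "other"))
        alive[died] <- FALSE
      }
    }

    # screening round
    if (a %in% ra) {
      rnd <- match(a, ra)
      idx <- which(alive & !diagnosed)
      att <- stats::runif(length(idx)) < pr$attendance
      fp_rate <- if (rnd == 1L) config$fp_rate_first else
        config$fp_rate_subsequent
      is_fp <- att & stats::runif(length(idx)) < fp_rate
      screens[[rnd]] <- data.frame(
        id = idx, round = rnd, age = a, attended = att,
        result = ifelse(is_fp, "false_positive",
                        ifelse(att, "negative", NA_character_)))
    }

    # cancer onset, survivors of the year only
    if (q_inc[i] > 0) {
      idx <- which(alive & !diagnosed)
      onset <- idx[stats::runif(length(idx)) < q_inc[i]]
      if (length(onset)) {
        covered <- a >= pr$first_invite_age & a <= covered_until
        u <- stats::runif(length(onset))
        p_sd <- if (covered) pr$attendance * config$sd_sensitivity else 0
        p_iv <- if (covered) pr$attendance * (1 - config$sd_sensitivity) else 0
        mode <- ifelse(u < p_sd, "screen_detected",
                       ifelse(u < p_sd + p_iv, "interval", "symptomatic"))
        cancer_id <- c(cancer_id, onset)
        cancer_age <- c(cancer_age, rep(a, length(onset)))
        cancer_mode <- c(cancer_mode, mode)
        diagnosed[onset] <- TRUE
      }
    }
  }

  cancers <- data.frame(id = cancer_id, age = cancer_age, mode = cancer_mode,
                        stringsAsFactors = FALSE)
  if (nrow(cancers)) {
    dcis_p <- c(screen_detected = config$dcis_share_sd,
                interval = config$dcis_share_interval,
                symptomatic = config$dcis_share_symptomatic)
    cancers$histology <- ifelse(
      stats::runif(nrow(cancers)) < dcis_p[cancers$mode], "DCIS", "invasive")
    mx <- config$treatment_mixes
    pick <- function(mode, hist) {
      key <- if (mode == "screen_detected") {
        if (hist == "DCIS") "screen_dcis" else "screen_invasive"
      } else {
        if (hist == "DCIS") "symptomatic_dcis" else "symptomatic_invasive"
      }
      mx[[key]]
    }
    cancers$regimen <- NA_character_
    for (mode in unique(cancers$mode)) for (hist in c("DCIS", "invasive")) {
      sel <- cancers$mode == mode & cancers$histology == hist
      cancers$regimen[sel] <- sample_mix(pick(mode, hist), sum(sel))
    }
  } else {
    cancers$histology <- character(0)
    cancers$regimen <- character(0)
  }

  structure(list(
    screens = do.call(rbind, screens[!vapply(screens, is.null, logical(1))]),
    cancers = cancers,
    deaths = data.frame(id = death_id, age = death_age, cause = death_cause,
                        stringsAsFactors = FALSE),
    alive_by_age = data.frame(age = ages, n_alive = alive_by_age),
    config = config), class = "synth_histories")
}

#' @export
print.synth_histories <- function(x, ...) {
  cat("<synth_histories>", x$config$n_women, "women, seed", x$config$seed, "\n")
  cat("  screens:", if (is.null(x$screens)) 0 else nrow(x$screens),
      "| cancers:", nrow(x$cancers), "| deaths:", nrow(x$deaths), "\n")
  invisible(x)
}

#' Cumulative false positives per woman invited at the first round
#'
#' Total false-positive events at ages within the invitation window divided
#' by the number of women who started screening at the first invitation age
#' (all women alive at that age).
#'
#' @param histories a `synth_histories`.
#' @return False positives per invitee.
#' @export
derive_fp_cumulative <- function(histories) {
  stopifnot(inherits(histories, "synth_histories"))
  pr <- histories$config$program
  n50 <- histories$alive_by_age$n_alive[
    histories$alive_by_age$age == pr$first_invite_age]
  if (length(n50) == 0 || n50 == 0) stop("no women invited at the first round")
  s <- histories$screens
  if (is.null(s)) return(0)
  fp <- sum(s$result == "false_positive" & s$age >= pr$first_invite_age &
              s$age <= pr$last_invite_age, na.rm = TRUE)
  fp / n50
}

#' Detection-mode mix and DCIS shares from synthetic histories
#'
#' @param histories a `synth_histories`.
#' @return List with `mode_shares` (named proportions of screen-detected,
#'   interval and symptomatic cancers), `dcis_share_by_mode`, and
#'   `sd_share_by_age` (per-age probability that a cancer is screen-detected,
#'   ages with at least one cancer).
#' @export
derive_detection_mode_mix <- function(histories) {
  stopifnot(inherits(histories, "synth_histories"))
  cc <- histories$cancers
  if (nrow(cc) == 0) stop("no cancer events in histories")
  mode_shares <- prop.table(table(cc$mode))
  dcis <- tapply(cc$histology == "DCIS", cc$mode, mean)
  sd_age <- tapply(cc$mode == "screen_detected", cc$age, mean)
  list(mode_shares = c(mode_shares),
       dcis_share_by_mode = c(dcis),
       sd_share_by_age = data.frame(age = as.integer(names(sd_age)),
                                    sd_share = as.numeric(sd_age)))
}

#' Empirical treatment mixes per detection mode and histology
#'
#' @param histories a `synth_histories`.
#' @param regimens regimen registry naming the admissible regimens.
#' @return Named list of [treatment_mix] objects keyed `<mode>_<histology>`;
#'   empty strata are omitted with a warning.
#' @export
derive_treatment_mixes <- function(histories, regimens = default_regimens()) {
  stopifnot(inherits(histories, "synth_histories"))
  cc <- histories$cancers
  if (nrow(cc) == 0) stop("no cancer events in histories")
  out <- list()
  for (mode in c("screen_detected", "interval", "symptomatic")) {
    for (hist in c("DCIS", "invasive")) {
      sel <- cc$mode == mode & cc$histology == hist
      key <- paste(mode, tolower(hist), sep = "_")
      if (!any(sel)) {
        warning("empty stratum omitted: ", key)
        next
      }
      counts <- table(factor(cc$regimen[sel], levels = regimens$regimen))
      out[[key]] <- treatment_mix(stats::setNames(as.numeric(counts) /
                                                    sum(counts),
                                                  regimens$regimen))
    }
  }
  out
}

#' Derive the full model-input bundle from synthetic histories
#'
#' Bridges the generator to scenario construction: cumulative false-positive
#' risk, overall and per-age screen-detected shares, DCIS shares by mode, and
#' treatment mixes, all re-derived empirically from the histories. Generating
#' histories from a bundle and re-deriving recovers the bundle within
#' Monte-Carlo error.
#'
#' @param histories a `synth_histories`.
#' @param regimens regimen registry.
#' @return List with `fp_cumulative`, `sd_share`, `sd_share_by_age`,
#'   `dcis_share_sd`, `dcis_share_interval`, `mode_shares`, and `mixes`.
#' @export
histories_to_inputs <- function(histories, regimens = default_regimens()) {
  stopifnot(inherits(histories, "synth_histories"))
  fp_cum <- derive_fp_cumulative(histories)
  if (nrow(histories$cancers) == 0)
    return(list(fp_cumulative = fp_cum, sd_share = 0,
                sd_share_by_age = NULL, dcis_share_sd = NA_real_,
                dcis_share_interval = NA_real_, mode_shares = NULL,
                mixes = NULL))
  mm <- derive_detection_mode_mix(histories)
  pr <- histories$config$program
  cc <- histories$cancers
  win <- cc$age >= pr$first_invite_age & cc$age <= pr$last_invite_age
  sd_share <- if (any(win)) mean(cc$mode[win] == "screen_detected") else 0
  list(fp_cumulative = fp_cum,
       sd_share = sd_share,
       sd_share_by_age = mm$sd_share_by_age,
       dcis_share_sd = unname(mm$dcis_share_by_mode["screen_detected"]),
       dcis_share_interval = unname(mm$dcis_share_by_mode["interval"]),
       mode_shares = mm$mode_shares,
       mixes = derive_treatment_mixes(histories, regimens))
}

#' Write histories as a long-format CSV
#'
#' One row per woman-round and per event, typed by a `record_kind` column
#' (`screen`, `cancer`, `death`).
#'
#' @param histories a `synth_histories`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_histories <- function(histories, path) {
  stopifnot(inherits(histories, "synth_histories"))
  blank <- function(n) rep(NA_character_, n)
  s <- histories$screens
  rows <- list()
  if (!is.null(s) && nrow(s))
    rows$screen <- data.frame(record_kind = "screen", id = s$id, age = s$age,
                              round = s$round, attended = s$attended,
                              result = s$result, mode = blank(nrow(s)),
                              histology = blank(nrow(s)),
                              regimen = blank(nrow(s)), cause = blank(nrow(s)))
  cc <- histories$cancers
  if (nrow(cc))
    rows$cancer <- data.frame(record_kind = "cancer", id = cc$id, age = cc$age,
                              round = NA_integer_, attended = NA,
                              result = blank(nrow(cc)), mode = cc$mode,
                              histology = cc$histology, regimen = cc$regimen,
                              cause = blank(nrow(cc)))
  d <- histories$deaths
  if (nrow(d))
    rows$death <- data.frame(record_kind = "death", id = d$id, age = d$age,
                             round = NA_integer_, attended = NA,
                             result = blank(nrow(d)), mode = blank(nrow(d)),
                             histology = blank(nrow(d)),
                             regimen = blank(nrow(d)), cause = d$cause)
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$age), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
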