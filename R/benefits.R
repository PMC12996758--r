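#' Life-years gained from screening
#'
#' Per-age difference in person-years between the invited (screened) and
#' uninvited (baseline) cohort projections. The raw total is multiplied by the
#' mortality-transfer factor to give the life-years gained in terms of reduced
#' all-cause mortality; the transfer acts as a scalar on the total (and
#' per-age) life-years, not as a modification of mortality rates.
#'
#' @param baseline,screened `cohort_trajectory` objects with identical age
#'   ranges and starting size.
#' @param transfer a [transfer_factor] or a plain proportion in `[0, 1]`.
#' @return A list with `per_age` (data frame: `age`, `lyg`), `total_raw`, and
#'   `total_transferred`.
#' @export
life_years_gained <- function(baseline, screened, transfer) {
  stopifnot(inherits(baseline, "cohort_trajectory"),
            inherits(screened, "cohort_trajectory"))
  if (!identical(baseline$age, screened$age))
    stop("trajectories must cover identical age ranges")
  if (!isTRUE(all.equal(attr(baseline, "n0"), attr(screened, "n0"))))
    stop("trajectories must start from the same cohort size")
  if (!inherits(transfer, "transfer_factor")) transfer <- transfer_factor(transfer)
  lyg <- screened$person_years - baseline$person_years
  total <- sum(lyg)
  list(per_age = data.frame(age = baseline$age, lyg = lyg),
       total_raw = total,
       total_transferred = total * unclass(transfer))
}

#' Total breast-cancer mortality reduction over follow-up
#'
#' Total breast-cancer deaths prevented by invitation to screening divided by
#' total breast-cancer deaths in the absence of screening. Distinct from the
#' peak of the age-specific reduction curve: a trapezium with a 40% plateau
#' over the screening ages yields a substantially smaller total reduction over
#' ages 50-85 because deaths at older ages are unaffected.
#'
#' @inheritParams life_years_gained
#' @return Proportion of breast-cancer deaths prevented.
#' @export
total_mortality_reduction <- function(baseline, screened) {
  stopifnot(inherits(baseline, "cohort_trajectory"),
            inherits(screened, "cohort_trajectory"))
  if (!identical(baseline$age, screened$age))
    stop("trajectories must cover identical age ranges")
  d0 <- sum(baseline$bc_deaths)
  if (d0 <= 0) stop("baseline cohort has no breast-cancer deaths")
  (d0 - sum(screened$bc_deaths)) / d0
}
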