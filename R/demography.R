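#' Project a cohort under competing breast-cancer and other-cause mortality
#'
#' Deterministic expectation model on discrete annual cycles. Women alive at
#' the start of each age-year die of breast cancer with probability
#' `q_BC(a) * (1 - r(a))` (where `r` is an optional proportional mortality
#' reduction) and of other causes with probability `q_OC(a)`; counts are
#' real-valued expectations, not integers. A "never diagnosed" pool is tracked
#' for incidence: within each cycle deaths are applied first, then new cases
#' arise from the surviving never-diagnosed pool at the incidence probability.
#'
#' Person-years for age-year `a` use the trapezoidal (half-cycle) convention
#' `(n_alive(a) + n_alive(a+1)) / 2` by default; the alternative credits a
#' full year to everyone alive at the start of the age-year. The final row
#' (the horizon age) records survivors only: follow-up ends there, so its
#' transition columns are zero.
#'
#' @param n0 cohort size at age `age_start` (> 0).
#' @param bc,oc,incidence `age_schedule`s of breast-cancer mortality,
#'   other-cause mortality and breast-cancer incidence rates per 100,000
#'   women-years, covering `[age_start, horizon]`.
#' @param reduction optional [reduction_curve] applied to breast-cancer
#'   mortality, or `NULL` for the uninvited cohort.
#' @param horizon last age of follow-up (>= 50).
#' @param age_start first age, default 50.
#' @param person_years_convention `"trapezoid"` (default) or `"start_of_year"`.
#' @return A `cohort_trajectory`: a data frame with one row per age
#'   `age_start..horizon` and columns `age`, `n_alive`, `bc_deaths`,
#'   `oc_deaths`, `person_years`, `n_never_diagnosed`, `incident_cases`.
#' @examples
#' flat <- function(r) age_schedule(50, rep(r, 3))
#' tr <- project_cohort(1000, flat(10000), flat(10000), flat(0), NULL, 52)
#' tr$n_alive  # 1000, 800, 640
#' @export
project_cohort <- function(n0, bc, oc, incidence, reduction = NULL,
                           horizon, age_start = 50L,
                           person_years_convention = c("trapezoid",
                                                       "start_of_year")) {
  person_years_convention <- match.arg(person_years_convention)
  stopifnot(n0 > 0)
  if (horizon < 50) stop("horizon must be at least age 50")
  if (horizon < age_start) stop("horizon must not precede age_start")
  ages <- seq.int(age_start, horizon)
  n_age <- length(ages)
  q_bc  <- annual_probability(schedule_rate(bc, ages))
  q_oc  <- annual_probability(schedule_rate(oc, ages))
  q_inc <- annual_probability(schedule_rate(incidence, ages))
  r <- if (is.null(reduction)) rep(0, n_age) else reduction_at(reduction, ages)

  n_alive <- numeric(n_age); n_alive[1] <- n0
  pool    <- numeric(n_age); pool[1]    <- n0
  bc_d <- oc_d <- py <- inc <- numeric(n_age)

  for (i in seq_len(n_age - 1L)) {
    q_bc_eff <- q_bc[i] * (1 - r[i])
    if (q_bc_eff + q_oc[i] > 1)
      stop("combined annual death probability exceeds 1 at age ", ages[i])
    bc_d[i] <- n_alive[i] * q_bc_eff
    oc_d[i] <- n_alive[i] * q_oc[i]
    n_alive[i + 1L] <- n_alive[i] - bc_d[i] - oc_d[i]
    pool_surv <- pool[i] * (1 - q_bc_eff - q_oc[i])
    inc[i] <- pool_surv * q_inc[i]
    pool[i + 1L] <- pool_surv - inc[i]
    py[i] <- if (person_years_convention == "trapezoid")
      (n_alive[i] + n_alive[i + 1L]) / 2 else n_alive[i]
  }

  out <- data.frame(age = ages, n_alive = n_alive, bc_deaths = bc_d,
                    oc_deaths = oc_d, person_years = py,
                    n_never_diagnosed = pool, incident_cases = inc)
  attr(out, "n0") <- n0
  attr(out, "person_years_convention") <- person_years_convention
  class(out) <- c("cohort_trajectory", "data.frame")
  out
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat("<cohort_trajectory> n0 =", format(attr(x, "n0"), big.mark = ","),
      "ages", min(x$age), "-", max(x$age), "\n")
  cat("  total person-years:", round(sum(x$person_years), 1),
      "| BC deaths:", round(sum(x$bc_deaths), 1),
      "| other-cause deaths:", round(sum(x$oc_deaths), 1), "\n")
  invisible(x)
}
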