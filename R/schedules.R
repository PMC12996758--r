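#' Grouped age-specific rate table
#'
#' Represents event rates per 100,000 women-years given for age groups,
#' the form in which population breast-cancer incidence and mortality are
#' published (e.g. 120/100,000 wy for ages 50-54). Groups must be
#' non-overlapping; both bounds are inclusive, so a printed label such as
#' "80-85 years" covers the six single ages 80..85.
#'
#' @param age_start,age_end integer vectors of inclusive group bounds (years).
#' @param rate_per_100000 non-negative event rates per 100,000 women-years.
#' @return An object of class `age_group_rates` (a data frame).
#' @examples
#' age_group_rates(c(50, 55), c(54, 59), c(120, 133))
#' @export
age_group_rates <- function(age_start, age_end, rate_per_100000) {
  stopifnot(length(age_start) == length(age_end),
            length(age_start) == length(rate_per_100000))
  if (any(age_start > age_end))
    stop("each group must satisfy age_start <= age_end")
  if (any(rate_per_100000 < 0))
    stop("rates must be non-negative")
  o <- order(age_start)
  g <- data.frame(age_start = as.integer(age_start[o]),
                  age_end   = as.integer(age_end[o]),
                  rate_per_100000 = rate_per_100000[o])
  if (nrow(g) > 1 && any(g$age_start[-1] <= g$age_end[-nrow(g)]))
    stop("age groups overlap")
  class(g) <- c("age_group_rates", "data.frame")
  g
}

#' Read a grouped rate table from CSV
#'
#' Expected header: `age_start,age_end,rate_per_100000`, one row per group;
#' single-age rows (`age_start == age_end`) are allowed, so the same format
#' carries all-cause mortality schedules given per single year of age.
#'
#' @param path path to a UTF-8 CSV file.
#' @return An `age_group_rates` object.
#' @export
read_rate_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "age_end", "rate_per_100000")
  if (!all(need %in% names(x)))
    stop("rate table must have columns: ", paste(need, collapse = ", "))
  age_group_rates(x$age_start, x$age_end, x$rate_per_100000)
}

#' Single-year-of-age rate schedule
#'
#' @param age_start first age covered (years).
#' @param values per-age rates (events per 100,000 women-years), one value per
#'   single year of age starting at `age_start`.
#' @return An object of class `age_schedule`.
#' @export
age_schedule <- function(age_start, values) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("schedule must contain at least one age")
  if (any(values < 0) || anyNA(values)) stop("rates must be non-negative")
  structure(list(age_start = as.integer(age_start),
                 age_end = as.integer(age_start) + length(values) - 1L,
                 rate = values),
            class = "age_schedule")
}

#' @export
print.age_schedule <- function(x, ...) {
  cat("<age_schedule> ages ", x$age_start, "-", x$age_end,
      ", rates per 100,000 wy in [", min(x$rate), ", ", max(x$rate), "]\n",
      sep = "")
  invisible(x)
}

#' Look up per-age rates in a schedule
#'
#' @param schedule an `age_schedule`.
#' @param ages ages (years) to query; must all be covered.
#' @return Numeric vector of rates per 100,000 women-years.
#' @export
schedule_rate <- function(schedule, ages) {
  stopifnot(inherits(schedule, "age_schedule"))
  i <- ages - schedule$age_start + 1L
  if (any(i < 1L | i > length(schedule$rate)))
    stop("age(s) ", paste(ages[i < 1L | i > length(schedule$rate)], collapse = ", "),
         " not covered by schedule [", schedule$age_start, ", ",
         schedule$age_end, "]")
  schedule$rate[i]
}

#' Expand grouped rates to a single-year-of-age schedule
#'
#' Each single age receives the rate of its containing group (piecewise
#' constant interpolation). The groups must cover `[age_start, age_end]`
#' without gaps.
#'
#' @param groups an `age_group_rates` table.
#' @param age_start,age_end inclusive range of single ages to cover.
#' @return An `age_schedule`.
#' @examples
#' g <- age_group_rates(c(50, 55), c(54, 59), c(120, 133))
#' schedule_rate(expand_schedule(g, 50, 59), 52)  # 120
#' @export
expand_schedule <- function(groups, age_start, age_end) {
  stopifnot(inherits(groups, "age_group_rates"), age_start <= age_end)
  ages <- seq.int(age_start, age_end)
  idx <- vapply(ages, function(a) {
    j <- which(groups$age_start <= a & a <= groups$age_end)
    if (length(j) == 0L) stop("age ", a, " not covered by any group")
    if (length(j) > 1L) stop("age ", a, " covered by overlapping groups")
    j
  }, integer(1))
  age_schedule(age_start, groups$rate_per_100000[idx])
}

#' Convert a rate per 100,000 women-years to an annual probability
#'
#' Direct division by 100,000; no exponential transform is applied because the
#' model's input rates are small and population-rate arithmetic is used
#' throughout.
#'
#' @param rate events per 100,000 women-years; must lie in `[0, 100000]`.
#' @return Annual event probability.
#' @export
annual_probability <- function(rate) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(rate > 100000)) stop("rate exceeds 100,000 per 100,000 women-years")
  rate / 100000
}

#' Other-cause mortality as all-cause minus breast-cancer mortality
#'
#' Computes the per-age difference between an all-cause and a breast-cancer
#' mortality schedule. Negative differences (possible with noisy inputs) are
#' clamped to zero with a warning.
#'
#' @param all_cause,bc `age_schedule` objects with identical age coverage.
#' @return An `age_schedule` of other-cause mortality rates.
#' @export
other_cause_schedule <- function(all_cause, bc) {
  stopifnot(inherits(all_cause, "age_schedule"), inherits(bc, "age_schedule"))
  if (all_cause$age_start != bc$age_start ||
      length(all_cause$rate) != length(bc$rate))
    stop("all-cause and breast-cancer schedules must cover identical ages")
  d <- all_cause$rate - bc$rate
  if (any(d < 0)) {
    warning("all-cause mortality below breast-cancer mortality at age(s) ",
            paste(seq_along(d)[d < 0] + all_cause$age_start - 1L, collapse = ", "),
            "; clamping other-cause rate to 0")
    d[d < 0] <- 0
  }
  age_schedule(all_cause$age_start, d)
}

#' Restrict or extend a schedule's age range
#'
#' `extend_schedule()` lengthens a schedule by holding its final rate constant,
#' for supplementary analyses whose horizon exceeds the published rate tables;
#' results beyond the original coverage inherit this assumption and should be
#' read accordingly.
#'
#' @param schedule an `age_schedule`.
#' @param to last age (years) the extended schedule must cover.
#' @return An `age_schedule` covering `[age_start, to]`.
#' @export
extend_schedule <- function(schedule, to) {
  stopifnot(inherits(schedule, "age_schedule"))
  if (to <= schedule$age_end) return(schedule)
  extra <- rep(schedule$rate[length(schedule$rate)], to - schedule$age_end)
  age_schedule(schedule$age_start, c(schedule$rate, extra))
}

#' Bundled default rate tables
#'
#' `norway_incidence_groups()` and `norway_bc_mortality_groups()` return the
#' pre-screening (1980-1985) Norwegian invasive breast-cancer incidence and
#' breast-cancer mortality rates by five-year age group, ages 50-85.
#' `all_cause_mortality_synthetic()` returns a *synthetic* stand-in for the
#' all-cause mortality of a 1940 Norwegian female birth cohort: a Gompertz
#' schedule, rate(a) = 100,000 x 0.0026 exp(0.088 (a - 50)) for ages 50-100,
#' calibrated to generic Norwegian female life-table facts (remaining life
#' expectancy at 50 of about 34 years). It is NOT the registry table used in
#' published analyses; supply the authoritative schedule via
#' [read_rate_table()] for exact reproduction.
#'
#' @return `age_group_rates` for the two grouped tables; an `age_schedule`
#'   (ages 50-100) for the synthetic all-cause schedule.
#' @name default_rates
NULL

#' @rdname default_rates
#' @export
norway_incidence_groups <- function() {
  read_rate_table(system.file("extdata", "incidence_invasive_1980_1985.csv",
                              package = "screenqaly", mustWork = TRUE))
}

#' @rdname default_rates
#' @export
norway_bc_mortality_groups <- function() {
  read_rate_table(system.file("extdata", "bc_mortality_1980_1985.csv",
                              package = "screenqaly", mustWork = TRUE))
}

#' @rdname default_rates
#' @export
all_cause_mortality_synthetic <- function() {
  g <- read_rate_table(system.file(
    "extdata", "all_cause_mortality_female_1940_synthetic.csv",
    package = "screenqaly", mustWork = TRUE))
  expand_schedule(g, min(g$age_start), max(g$age_end))
}
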