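#' Age-shaped breast-cancer mortality reduction curves
#'
#' A reduction curve gives the proportional reduction `r(a)` in breast-cancer
#' mortality at each age, in `[0, 1]`, and is 0 outside its support.
#' `trapezium_curve()` builds the piecewise-linear shape used for screening
#' ages 50-69: zero at `rise_start`, rising linearly to `max_reduction` at
#' `plateau_start`, flat through `plateau_end`, declining linearly to zero at
#' `fall_end`. `read_reduction_curve()` loads a tabulated curve (for instance
#' one exported from a microsimulation model) from a CSV with header
#' `age,reduction`; between tabulated ages the curve is linearly interpolated,
#' outside the tabulated range it is 0.
#'
#' @param max_reduction peak proportional reduction, in `[0, 1]`.
#' @param rise_start,plateau_start,plateau_end,fall_end knot ages (years),
#'   strictly increasing.
#' @param label curve label used in printing.
#' @return An object of class `reduction_curve`.
#' @examples
#' tz <- trapezium_curve(0.40)
#' reduction_at(tz, c(50, 53, 56, 71, 75))  # 0, 0.2, 0.4, 0.4, 0
#' @export
trapezium_curve <- function(max_reduction, rise_start = 50, plateau_start = 56,
                            plateau_end = 71, fall_end = 75,
                            label = sprintf("trapezium max %.0f%%",
                                            100 * max_reduction)) {
  if (max_reduction < 0 || max_reduction > 1)
    stop("max_reduction must lie in [0, 1]")
  knots <- c(rise_start, plateau_start, plateau_end, fall_end)
  if (any(diff(knots) <= 0)) stop("knot ages must be strictly increasing")
  structure(list(ages = knots, r = c(0, max_reduction, max_reduction, 0),
                 label = label),
            class = "reduction_curve")
}

#' @rdname trapezium_curve
#' @param path CSV file with header `age,reduction`, reductions in `[0, 1]`.
#' @export
read_reduction_curve <- function(path, label = basename(path)) {
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("cannot read reduction curve: ",
                                         conditionMessage(e)))
  if (!all(c("age", "reduction") %in% names(x)))
    stop("reduction curve file must have header 'age,reduction'")
  if (nrow(x) == 0) stop("reduction curve file is empty")
  if (anyNA(x$age) || anyNA(x$reduction))
    stop("malformed row(s) in reduction curve: ",
         paste(which(is.na(x$age) | is.na(x$reduction)), collapse = ", "))
  if (anyDuplicated(x$age))
    stop("duplicate age(s) in reduction curve: ",
         paste(unique(x$age[duplicated(x$age)]), collapse = ", "))
  bad <- which(x$reduction < 0 | x$reduction > 1)
  if (length(bad))
    stop("reduction outside [0, 1] at row(s) ", paste(bad, collapse = ", "))
  o <- order(x$age)
  structure(list(ages = x$age[o], r = x$reduction[o], label = label),
            class = "reduction_curve")
}

#' Evaluate a reduction curve at given ages
#'
#' @param curve a `reduction_curve`.
#' @param ages ages (years).
#' @return Proportional reductions in `[0, 1]`; 0 outside the curve's support.
#' @export
reduction_at <- function(curve, ages) {
  stopifnot(inherits(curve, "reduction_curve"))
  if (length(curve$ages) == 1L)
    return(ifelse(ages == curve$ages, curve$r, 0))
  out <- stats::approx(curve$ages, curve$r, xout = ages,
                       yleft = 0, yright = 0, ties = "ordered")$y
  out
}

#' @export
print.reduction_curve <- function(x, ...) {
  cat("<reduction_curve>", x$label, "\n")
  cat("  support ages", min(x$ages), "-", max(x$ages),
      "| peak reduction", max(x$r), "\n")
  invisible(x)
}

#' Mortality-transfer factor
#'
#' The proportion by which a reduction in breast-cancer mortality translates
#' into a reduction in all-cause mortality; applied as a scalar multiplier on
#' total life-years gained. Values below 1 reflect, e.g., excess cardiac and
#' lung-cancer deaths after radiation therapy of early-stage disease.
#'
#' @param value proportion in `[0, 1]`.
#' @return The validated numeric value, classed `transfer_factor`.
#' @export
transfer_factor <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    stop("mortality transfer must be a single proportion in [0, 1]")
  structure(value, class = "transfer_factor")
}
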