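#' Piecewise-linear forcing function
#'
#' Builds the piecewise-linear interpolant through observed plasma
#' concentrations, used as the glucose and insulin inputs FFG(t) and I(t)
#' of the kinetic models.  Between knots the interpolant is linear; outside
#' the knot range it holds the nearest endpoint value constant, so a forcing
#' that includes basal (negative-time) samples stays at basal before the
#' bolus.
#'
#' @param times numeric vector of knot times (minutes), strictly increasing,
#'   length >= 2.
#' @param values numeric vector of the same length.
#' @return A function of class `pl_forcing` mapping time (vectorised) to the
#'   interpolated value, with attributes `knots` and `values`.
#' @examples
#' f <- pl_forcing(c(0, 10), c(5, 7))
#' f(5)    # 6
#' f(200)  # 7 (endpoint hold)
#' @export
pl_forcing <- function(times, values) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2)
    stop("a forcing needs at least two points", call. = FALSE)
  if (length(values) != length(times))
    stop("times and values must have equal length", call. = FALSE)
  if (anyNA(times) || anyNA(values) || any(!is.finite(c(times, values))))
    stop("forcing knots and values must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("forcing times must be strictly increasing", call. = FALSE)
  f <- stats::approxfun(times, values, method = "linear", rule = 2)
  attr(f, "knots") <- times
  attr(f, "values") <- values
  class(f) <- c("pl_forcing", "function")
  f
}

#' @export
print.pl_forcing <- function(x, ...) {
  k <- attr(x, "knots")
  cat("Piecewise-linear forcing: ", length(k), " knots on [",
      min(k), ", ", max(k), "] min; range [",
      signif(min(attr(x, "values")), 4), ", ",
      signif(max(attr(x, "values")), 4), "]\n", sep = "")
  invisible(x)
}

# forcings for a subject's observed series: include basal knots so the
# pre-bolus forcing sits at the measured basal level
series_forcings <- function(series) {
  list(glucose = pl_forcing(series$time_min, series$glucose_mmol_l),
       insulin = pl_forcing(series$time_min, series$insulin_pmol_l))
}
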