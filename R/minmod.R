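#' Parameters of the Bergman glucose minimal model
#'
#' @param s_g glucose effectiveness, 1/min.
#' @param p2 fractional removal rate of insulin action, 1/min.
#' @param p3 transfer rate of the insulin increment into insulin action,
#'   1/min^2 per mU/l (the classical minimal-model insulin unit; insulin
#'   data in pmol/l are converted internally by the factor 6.0).
#' @param g0 modelled glucose concentration at t = 0, mmol/l (the
#'   post-mixing value implied by the bolus, estimated in fits).
#' @param g_b,i_b basal glucose (mmol/l) and insulin (pmol/l).
#' @return An object of class `minmod_params`.
#' @export
minmod_params <- function(s_g = 0.02, p2 = 0.05, p3 = 1.8e-5, g0 = 15,
                          g_b = 5.25, i_b = 45) {
  p <- list(s_g = s_g, p2 = p2, p3 = p3, g0 = g0, g_b = g_b, i_b = i_b)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("minmod_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  class(p) <- "minmod_params"
  p
}

#' @export
print.minmod_params <- function(x, ...) {
  cat("Minimal model parameters:\n")
  cat(sprintf("  s_g = %.4g 1/min, p2 = %.4g 1/min, p3 = %.4g 1/min^2 per mU/l\n",
              x$s_g, x$p2, x$p3))
  cat(sprintf("  g0 = %.4g mmol/l, g_b = %.4g mmol/l, i_b = %.4g pmol/l\n",
              x$g0, x$g_b, x$i_b))
  cat(sprintf("  S_I = p3/p2 = %.4g (mU/l)^-1 min^-1\n", x$p3 / x$p2))
  invisible(x)
}

.minmod_rhs <- function(t, y, parms) {
  p <- parms$params
  ins <- parms$insulin(t)
  list(c(-(p$s_g + y[2]) * y[1] + p$s_g * p$g_b,
         -p$p2 * y[2] + p$p3 * (ins - p$i_b) / .PMOL_PER_MU))
}

#' Simulate the glucose minimal model
#'
#' Integrates dG/dt = -(s_g + X) G + s_g g_b with G(0) = g0 and
#' dX/dt = -p2 X + p3 (I(t) - i_b) with X(0) = 0, driven by an insulin
#' forcing.
#'
#' @param params a [minmod_params()].
#' @param insulin insulin forcing (see [pl_forcing()]), pmol/l.
#' @param t_grid output times, minutes, starting at 0.
#' @param method,h as in [simulate_ffa()].
#' @return A `glucose_trajectory` data frame with columns `time_min`,
#'   `glucose_mmol_l`, `x_per_min`.
#' @export
simulate_minmod <- function(params, insulin, t_grid,
                            method = c("lsoda", "rk4"), h = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(params, "minmod_params"))
  t_grid <- as.numeric(t_grid)
  if (t_grid[1] != 0) stop("t_grid must start at 0", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  y0 <- c(glucose = params$g0, x = 0)
  parms <- list(params = params, insulin = insulin)
  sol <- .integrate(.minmod_rhs, y0, t_grid, parms, method, h)
  out <- data.frame(time_min = sol[, 1], glucose_mmol_l = sol[, 2],
                    x_per_min = sol[, 3])
  class(out) <- c("glucose_trajectory", "data.frame")
  out
}

#' Acute insulin response to glucose (AIRg)
#'
#' Trapezoid-rule area of the insulin increment above basal over the first
#' ten minutes after the glucose bolus, using the observed samples and the
#' basal insulin from [basal_state()].
#'
#' @param series an [fsigt_series()].
#' @param window integration window in minutes, default `c(0, 10)`.
#' @return AIRg in pmol/l * min.
#' @export
airg <- function(series, window = c(0, 10)) {
  b <- basal_state(series)
  keep <- series$time_min >= window[1] & series$time_min <= window[2]
  if (sum(keep) < 2)
    stop("need at least two insulin samples in [", window[1], ", ",
         window[2], "] min", call. = FALSE)
  t <- series$time_min[keep]
  inc <- series$insulin_pmol_l[keep] - b$i_b
  sum(diff(t) * (utils::head(inc, -1) + utils::tail(inc, -1)) / 2)
}

#' Disposition index
#'
#' The product of insulin sensitivity and the acute insulin response,
#' DI = S_I x AIRg: a measure of beta-cell compensation for insulin
#' resistance.
#'
#' @param s_i insulin sensitivity, (mU/l)^-1 min^-1.
#' @param airg acute insulin response, pmol/l * min.
#' @return DI (dimensionless).
#' @export
disposition_index <- function(s_i, airg) {
  if (!all(is.finite(s_i)) || !all(is.finite(airg)))
    stop("s_i and airg must be finite", call. = FALSE)
  s_i * airg
}

#' Peak of an insulin-action trajectory
#'
#' Maximum of a simulated action time course and the time at which it
#' occurs; ties are broken by the earliest time.  Peaks are taken from the
#' dense simulated trajectory, not from the sampling grid.
#'
#' @param times time grid, minutes.
#' @param x action values on the grid, 1/min.
#' @return A list with elements `t_peak` (min) and `x_max` (1/min).
#' @export
peak_action <- function(times, x) {
  if (length(times) < 2 || length(x) != length(times))
    stop("need matching time/action vectors of length >= 2", call. = FALSE)
  i <- which.max(x) # which.max returns the first (earliest) maximum
  list(t_peak = times[i], x_max = x[i])
}
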