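#' @export
coef.fsigt_fit <- function(object, ...) object$coefficients

#' @export
vcov.fsigt_fit <- function(object, ...) object$vcov

#' @export
fitted.fsigt_fit <- function(object, ...) object$fitted

#' Residuals of a fitted FSIGT model
#'
#' @param object an `ffa_fit` or `minmod_fit`.
#' @param type `"standardized"` (per assay SD, the default) or `"response"`
#'   (observed - fitted in concentration units).
#' @param ... unused.
#' @export
residuals.fsigt_fit <- function(object, type = c("standardized", "response"),
                                ...) {
  type <- match.arg(type)
  if (type == "standardized") object$std_residuals
  else object$observed - object$fitted
}

#' @export
print.fsigt_fit <- function(x, ...) {
  model <- if (inherits(x, "ffa_fit")) "FFA kinetics model" else
    "glucose minimal model"
  cat("Weighted NLS fit of the ", model, "\n", sep = "")
  cat("Subject: ", attr(x$series, "subject_id"), "; ",
      length(x$observed), " fitted samples; WRSS = ",
      format(x$wrss, digits = 5), "\n", sep = "")
  print(signif(x$coefficients, 4))
  if (inherits(x, "ffa_fit"))
    cat(sprintf("S_I(FFA) = %.4g (mU/l)^-1 min^-1\n", x$si_ffa))
  else
    cat(sprintf("S_I = %.4g (mU/l)^-1 min^-1\n", x$s_i))
  invisible(x)
}

#' Summarise a fitted FSIGT model
#'
#' @param object an `ffa_fit` or `minmod_fit`.
#' @param ... unused.
#' @return A `summary.fsigt_fit` object: coefficient table (estimate, SE,
#'   FSD), derived sensitivity index, WRSS, convergence and acceptance
#'   verdict.
#' @export
summary.fsigt_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               FSD = object$fsd)
  verdict <- tryCatch(acceptance_check(object), error = function(e) NULL)
  structure(list(coefficients = tab, wrss = object$wrss,
                 n = length(object$observed), n_iter = object$n_iter,
                 converged = object$converged, flags = object$flags,
                 verdict = verdict,
                 si = if (inherits(object, "ffa_fit")) object$si_ffa else object$s_i,
                 si_se = if (inherits(object, "ffa_fit")) object$si_ffa_se else object$s_i_se,
                 si_label = if (inherits(object, "ffa_fit")) "S_I(FFA)" else "S_I",
                 model = class(object)[1]),
            class = "summary.fsigt_fit")
}

#' @export
print.summary.fsigt_fit <- function(x, ...) {
  cat("Model:", if (x$model == "ffa_fit") "FFA kinetics" else "glucose minimal model",
      "\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("%s = %.4g +/- %.2g (mU/l)^-1 min^-1\n",
              x$si_label, x$si, x$si_se))
  cat(sprintf("WRSS = %.5g on %d samples; converged in %d iterations\n",
              x$wrss, x$n, x$n_iter))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  if (!is.null(x$verdict))
    cat("Acceptance:", if (x$verdict$pass) "PASS" else
      paste("FAIL -", paste(x$verdict$reasons, collapse = "; ")), "\n")
  invisible(x)
}

#' Predict model trajectories from a fit
#'
#' @param object an `ffa_fit` or `minmod_fit`.
#' @param times prediction times in minutes (>= 0); defaults to a dense
#'   0.5-min grid over the fitted range.
#' @param ... unused.
#' @return The model trajectory data frame at `times` (including the state
#'   of the remote insulin-action compartment).
#' @export
predict.fsigt_fit <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(0, max(object$times), by = 0.5)
  times <- sort(unique(c(0, times[times >= 0])))
  if (inherits(object, "ffa_fit"))
    simulate_ffa(object$params, object$forcings$glucose,
                 object$forcings$insulin, times)
  else
    simulate_minmod(object$params, object$forcings$insulin, times)
}

#' Simulate new noisy observations from a fitted model
#'
#' Draws replicate measurement vectors at the fitted sampling times by
#' applying multiplicative Gaussian assay noise (the fit's `assay_fsd`) to
#' the fitted trajectory.
#'
#' @param object an `ffa_fit` or `minmod_fit`.
#' @param nsim number of replicate series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A matrix with one column per replicate and one row per fitted
#'   sampling time.
#' @export
simulate.fsigt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  fsd <- object$options$assay_fsd
  mu <- object$fitted
  draw <- function() mu * (1 + fsd * stats::rnorm(length(mu)))
  sims <- if (is.null(seed)) replicate(nsim, draw()) else
    withr_seed(seed, replicate(nsim, draw()))
  sims <- matrix(sims, nrow = length(mu))
  rownames(sims) <- object$times
  sims
}

#' Plot a fitted FSIGT model
#'
#' Two base-graphics panels: observed data with the fitted dense trajectory,
#' and standardized residuals with the +/- 2 SD acceptance band.
#'
#' @param x an `ffa_fit` or `minmod_fit`.
#' @param ... passed to `plot.default` for the data panel.
#' @export
plot.fsigt_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  dense <- predict(x)
  ycol <- if (inherits(x, "ffa_fit")) "ffa_umol_l" else "glucose_mmol_l"
  ylab <- if (inherits(x, "ffa_fit")) "FFA (umol/l)" else "Glucose (mmol/l)"
  graphics::plot(x$times, x$observed, xlab = "Time (min)", ylab = ylab,
                 main = paste("Subject", attr(x$series, "subject_id")), ...)
  graphics::lines(dense$time_min, dense[[ycol]], col = "steelblue", lwd = 2)
  graphics::plot(x$times, x$std_residuals, xlab = "Time (min)",
                 ylab = "Standardized residual",
                 ylim = range(c(-2.5, 2.5, x$std_residuals)))
  graphics::abline(h = c(-2, 0, 2), lty = c(2, 1, 2), col = "grey40")
}
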