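#' Options controlling the weighted nonlinear least-squares fit
#'
#' @param initial_values named numeric vector of starting values for the
#'   fitted parameters; `NULL` uses the model's documented defaults.
#' @param assay_fsd fractional standard deviation of the assay, used as the
#'   residual weight 1/(assay_fsd * observation); default 0.05, the standard
#'   FFA assay precision.  Minimal-model glucose fits default to 0.02.
#' @param max_iterations maximum optimizer iterations.
#' @param convergence_tol relative convergence tolerance passed to the
#'   Levenberg--Marquardt optimizer.
#' @param n_starts number of optimizer starts; starts beyond the first
#'   jitter the initial values lognormally (sd 0.5 on the log scale) and the
#'   fit with the lowest weighted residual sum of squares is kept.
#' @param seed integer seed for the multi-start jitter.
#' @param fit_start earliest observation time (minutes) entering the
#'   objective; `0` for FFA fits, `2` (the first post-bolus sample) for
#'   minimal-model glucose fits.
#' @param propagate_basal propagate the assay uncertainty of the fixed
#'   basal constants (estimated as means of the few pre-bolus samples)
#'   into the parameter covariance by the delta method.  Without this the
#'   Wald intervals condition on the plugged-in basal values and
#'   undercover.
#' @param insulin_assay_fsd fractional SD of the insulin assay, used only
#'   for the basal-uncertainty propagation (the insulin samples themselves
#'   enter as forcings, not as fitted observations).
#' @return A `fit_options` list.
#' @export
fit_options <- function(initial_values = NULL, assay_fsd = 0.05,
                        max_iterations = 200, convergence_tol = 1e-10,
                        n_starts = 1, seed = 1, fit_start = NULL,
                        propagate_basal = TRUE, insulin_assay_fsd = 0.05) {
  if (!is.numeric(assay_fsd) || assay_fsd <= 0 || assay_fsd >= 1)
    stop("assay_fsd must be in (0, 1)", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(initial_values = initial_values, assay_fsd = assay_fsd,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 n_starts = n_starts, seed = seed, fit_start = fit_start,
                 propagate_basal = propagate_basal,
                 insulin_assay_fsd = insulin_assay_fsd),
            class = "fit_options")
}

# Levenberg-Marquardt weighted least squares in log-parameter space.
# resid_fn takes the natural-scale parameter vector and returns weighted
# residuals; positivity is enforced by optimizing over log(theta).
.wnls_optim <- function(resid_fn, start, options) {
  stopifnot(all(start > 0))
  run_one <- function(lpar) {
    minpack.lm::nls.lm(
      par = lpar,
      fn = function(lp) resid_fn(exp(lp)),
      # epsfcn sets the forward-difference step well above the ODE
      # solver's error floor (rtol 1e-8), so Jacobians are not swamped
      # by integration noise
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iterations, epsfcn = 1e-6,
        ftol = options$convergence_tol, ptol = options$convergence_tol))
  }
  fits <- list(run_one(log(start)))
  if (options$n_starts > 1) {
    jit <- withr_seed(options$seed, {
      lapply(seq_len(options$n_starts - 1), function(i)
        log(start) + stats::rnorm(length(start), sd = 0.5))
    })
    fits <- c(fits, lapply(jit, run_one))
  }
  dev <- vapply(fits, stats::deviance, 0)
  best <- fits[[which.min(dev)]]
  theta <- exp(best$par)
  names(theta) <- names(start)
  # nls.lm info codes 1-4 indicate a convergence criterion was met
  list(estimates = theta, wrss = stats::deviance(best),
       converged = best$info %in% 1:4, n_iter = best$niter,
       message = best$message)
}

# evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# central-difference Jacobian of the weighted residuals at the optimum
# (natural scale), and the known-weights generalized-least-squares
# covariance (J'WJ)^-1: the assay variance model (fractional SD of the
# observation) is declared, not estimated, so no residual scale factor
# multiplies the covariance.  WRSS/(n-p) is returned as a variance-scale
# diagnostic (≈1 when the declared noise model explains the residuals).
# Near-singular information matrices fall back to the Moore-Penrose
# pseudoinverse with the null directions flagged as unidentifiable.
.wnls_covariance <- function(resid_fn, theta, wrss) {
  p <- length(theta)
  r0 <- resid_fn(theta)
  n <- length(r0)
  J <- matrix(0, n, p, dimnames = list(NULL, names(theta)))
  for (j in seq_len(p)) {
    hj <- 1e-5 * abs(theta[j])
    up <- dn <- theta
    up[j] <- theta[j] + hj
    dn[j] <- theta[j] - hj
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * hj)
  }
  jtj <- crossprod(J)
  sigma2 <- 1
  flags <- character(0)
  col_norm <- sqrt(diag(jtj))
  dead <- col_norm < 1e-12 * max(col_norm, 1)
  rc <- tryCatch(rcond(jtj), error = function(e) 0)
  if (any(dead) || rc < 1e-14) {
    bad <- names(theta)[dead]
    if (!length(bad)) bad <- "(joint direction)"
    flags <- c(flags, paste0("unidentifiable: ", paste(bad, collapse = ", ")))
    cov <- sigma2 * MASS::ginv(jtj)
    dimnames(cov) <- list(names(theta), names(theta))
    se <- sqrt(pmax(diag(cov), 0))
    se[dead] <- Inf
  } else {
    cov <- sigma2 * solve(jtj)
    se <- sqrt(pmax(diag(cov), 0))
  }
  list(cov = cov, se = se, fsd = se / abs(theta), flags = flags,
       jacobian = J, jtj = jtj, variance_scale = wrss / max(n - p, 1))
}

# Delta-method propagation of the uncertainty of a fixed basal constant b
# into the parameter covariance.  The WNLS estimator solves
# J'r(theta, b) = 0, so dtheta/db = -(J'J)^{-1} J' dr/db; the added
# covariance is Var(b) * (dtheta/db)(dtheta/db)'.  dr/db comes from a
# central difference of the weighted residuals at the optimum.
.basal_delta_cov <- function(resid_b, theta, cv, b, var_b) {
  if (var_b <= 0) return(0)
  h <- 1e-3 * b
  drdb <- (resid_b(b + h) - resid_b(b - h)) / (2 * h)
  s <- tryCatch(-solve(cv$jtj, crossprod(cv$jacobian, drdb)),
                error = function(e) NULL)
  if (is.null(s)) return(0)
  var_b * tcrossprod(s)
}

#' Fit the FFA kinetics model to one subject's FSIGT data
#'
#' Estimates the four kinetic parameters (alpha, s_ffa, p_xfcr, p_xa) by
#' weighted nonlinear least squares against the post-bolus FFA samples,
#' with weights 1/(assay_fsd * FFA_obs)^2 (inverse assay variance).  The
#' basal constants ffa_b and i_b are fixed from the pre-bolus samples, not
#' fitted.  Optimization runs in log-parameter space (enforcing positivity)
#' with a Levenberg--Marquardt damped Gauss--Newton core; the covariance is
#' the known-weights generalized-least-squares expression (J'WJ)^-1
#' evaluated on the natural scale (the assay variance model is declared,
#' not estimated), from which per-parameter fractional standard deviations
#' (FSD = SE/|estimate|) are reported as the identifiability diagnostic.
#' The ratio WRSS/(n-p) is recorded as `variance_scale`; values near 1
#' indicate the declared noise model accounts for the residuals.
#'
#' @param series an [fsigt_series()].
#' @param options a [fit_options()]; `assay_fsd` defaults to 0.05.
#' @param glucose,insulin optional forcing functions; by default the
#'   observed samples are interpolated piecewise-linearly (including the
#'   basal knots).
#' @return An object of class `c("ffa_fit", "fsigt_fit")` with components
#'   `coefficients`, `se`, `fsd`, `vcov`, `wrss`, `std_residuals`,
#'   `fitted`, `converged`, `n_iter`, `flags`, `basal`, `si_ffa`,
#'   `si_ffa_se` (delta method), plus the data and forcings used.
#' @examples
#' cfg <- cohort_config(n_subjects = 1, param_cv = 0, noise_fsd = c(
#'   ffa = 0.02, glucose = 0.01, insulin = 0.02), basal_cv = c(0, 0, 0))
#' subj <- generate_subject(cfg, 1)
#' fit <- fit_ffa(subj$series)
#' coef(fit)
#' @export
fit_ffa <- function(series, options = fit_options(),
                    glucose = NULL, insulin = NULL) {
  stopifnot(inherits(series, "fsigt_series"))
  basal <- basal_state(series)
  if (is.null(glucose) || is.null(insulin)) {
    fc <- series_forcings(series)
    if (is.null(glucose)) glucose <- fc$glucose
    if (is.null(insulin)) insulin <- fc$insulin
  }
  fit_start <- if (is.null(options$fit_start)) 0 else options$fit_start
  keep <- series$time_min >= fit_start
  t_obs <- series$time_min[keep]
  y_obs <- series$ffa_umol_l[keep]
  w_den <- options$assay_fsd * y_obs
  t_sim <- if (t_obs[1] == 0) t_obs else c(0, t_obs)
  pick <- if (t_obs[1] == 0) seq_along(t_obs) else seq_along(t_obs) + 1L

  # integration failures in wild parameter regions are reported to the
  # optimizer as uniformly huge residuals so the damped step backs off
  resid_full <- function(theta, ffa_b = basal$ffa_b, i_b = basal$i_b) {
    tryCatch({
      p <- ffa_params(alpha = theta[[1]], s_ffa = theta[[2]],
                      p_xfcr = theta[[3]], p_xa = theta[[4]],
                      ffa_b = ffa_b, i_b = i_b)
      traj <- simulate_ffa(p, glucose, insulin, t_sim)
      r <- (y_obs - traj$ffa_umol_l[pick]) / w_den
      if (any(!is.finite(r))) rep(1e6, length(y_obs)) else r
    }, error = function(e) rep(1e6, length(y_obs)))
  }
  resid_fn <- function(theta) resid_full(theta)

  start <- options$initial_values
  if (is.null(start))
    start <- c(alpha = 1 / basal$g_b, s_ffa = 0.01, p_xfcr = 0.1, p_xa = 1e-5)
  start <- start[c("alpha", "s_ffa", "p_xfcr", "p_xa")]

  opt <- .wnls_optim(resid_fn, start, options)
  if (!opt$converged)
    stop("FFA model fit did not converge in ", opt$n_iter, " iterations: ",
         opt$message, call. = FALSE)
  cv <- .wnls_covariance(resid_fn, opt$estimates, opt$wrss)
  if (length(cv$flags))
    stop("FFA model fit is unidentifiable (singular information matrix); ",
         paste(cv$flags, collapse = "; "), call. = FALSE)
  if (isTRUE(options$propagate_basal)) {
    n_b <- sum(series$time_min < 0)
    cv$cov <- cv$cov +
      .basal_delta_cov(function(b) resid_full(opt$estimates, ffa_b = b),
                       opt$estimates, cv, basal$ffa_b,
                       (options$assay_fsd * basal$ffa_b)^2 / n_b) +
      .basal_delta_cov(function(b) resid_full(opt$estimates, i_b = b),
                       opt$estimates, cv, basal$i_b,
                       (options$insulin_assay_fsd * basal$i_b)^2 / n_b)
    cv$se <- sqrt(pmax(diag(cv$cov), 0))
    cv$fsd <- cv$se / abs(opt$estimates)
  }

  pars <- ffa_params(alpha = opt$estimates[["alpha"]],
                     s_ffa = opt$estimates[["s_ffa"]],
                     p_xfcr = opt$estimates[["p_xfcr"]],
                     p_xa = opt$estimates[["p_xa"]],
                     ffa_b = basal$ffa_b, i_b = basal$i_b)
  traj <- simulate_ffa(pars, glucose, insulin, t_sim)
  pred <- traj$ffa_umol_l[pick]
  flags <- character(0)
  if (attr(traj, "negative_lipolysis"))
    flags <- c(flags, "negative_lipolysis: X_FFA exceeded s_ffa")

  # delta method for S_I(FFA) = p_xa / p_xfcr
  g <- c(alpha = 0, s_ffa = 0,
         p_xfcr = -opt$estimates[["p_xa"]] / opt$estimates[["p_xfcr"]]^2,
         p_xa = 1 / opt$estimates[["p_xfcr"]])
  si_se <- sqrt(max(0, drop(t(g) %*% cv$cov %*% g)))

  structure(list(
    coefficients = opt$estimates, se = cv$se, fsd = cv$fsd, vcov = cv$cov,
    wrss = opt$wrss, variance_scale = cv$variance_scale,
    std_residuals = standardized_residuals(y_obs, pred, options$assay_fsd),
    fitted = pred, observed = y_obs, times = t_obs,
    converged = opt$converged, n_iter = opt$n_iter, flags = flags,
    basal = basal, params = pars,
    si_ffa = si_ffa(pars), si_ffa_se = si_se,
    series = series, forcings = list(glucose = glucose, insulin = insulin),
    options = options, response = "ffa", call = match.call()),
    class = c("ffa_fit", "fsigt_fit"))
}

#' Fit the glucose minimal model to one subject's FSIGT data
#'
#' Estimates (s_g, p2, p3, g0) by weighted nonlinear least squares against
#' the glucose samples from `fit_start` (default 2 min, the first
#' post-bolus sample) onward, with fractional weights (default assay FSD
#' 2%).  Basal glucose and insulin are fixed from the pre-bolus samples.
#' Insulin sensitivity S_I = p3/p2 is reported with a delta-method standard
#' error.  A near-singular information matrix (e.g. insulin never leaving
#' basal, so p2 and p3 carry no signal) does not abort the fit: the
#' affected parameters get infinite FSDs and an `unidentifiable` flag.
#'
#' @param series an [fsigt_series()] with at least 10 post-bolus glucose
#'   samples.
#' @param options a [fit_options()]; `assay_fsd` defaults to 0.02 and
#'   `fit_start` to 2 for this model.
#' @param insulin optional insulin forcing; defaults to interpolated
#'   observed samples.
#' @return An object of class `c("minmod_fit", "fsigt_fit")`; components as
#'   in [fit_ffa()] plus `s_i` and `s_i_se`.
#' @export
fit_minmod <- function(series, options = fit_options(assay_fsd = 0.02),
                       insulin = NULL) {
  stopifnot(inherits(series, "fsigt_series"))
  if (sum(series$time_min > 0) < 10)
    stop("need at least 10 post-bolus glucose samples", call. = FALSE)
  basal <- basal_state(series)
  if (is.null(insulin)) insulin <- series_forcings(series)$insulin
  fit_start <- if (is.null(options$fit_start)) 2 else options$fit_start
  keep <- series$time_min >= fit_start
  t_obs <- series$time_min[keep]
  y_obs <- series$glucose_mmol_l[keep]
  w_den <- options$assay_fsd * y_obs
  t_sim <- if (t_obs[1] == 0) t_obs else c(0, t_obs)
  pick <- if (t_obs[1] == 0) seq_along(t_obs) else seq_along(t_obs) + 1L

  resid_full <- function(theta, g_b = basal$g_b, i_b = basal$i_b) {
    tryCatch({
      p <- minmod_params(s_g = theta[[1]], p2 = theta[[2]], p3 = theta[[3]],
                         g0 = theta[[4]], g_b = g_b, i_b = i_b)
      traj <- simulate_minmod(p, insulin, t_sim)
      r <- (y_obs - traj$glucose_mmol_l[pick]) / w_den
      if (any(!is.finite(r))) rep(1e6, length(y_obs)) else r
    }, error = function(e) rep(1e6, length(y_obs)))
  }
  resid_fn <- function(theta) resid_full(theta)

  start <- options$initial_values
  if (is.null(start))
    start <- c(s_g = 0.02, p2 = 0.05, p3 = 5e-6, g0 = max(y_obs))
  start <- start[c("s_g", "p2", "p3", "g0")]

  opt <- .wnls_optim(resid_fn, start, options)
  if (!opt$converged)
    stop("minimal model fit did not converge in ", opt$n_iter,
         " iterations: ", opt$message, call. = FALSE)
  cv <- .wnls_covariance(resid_fn, opt$estimates, opt$wrss)
  if (isTRUE(options$propagate_basal) && !length(cv$flags)) {
    n_b <- sum(series$time_min < 0)
    cv$cov <- cv$cov +
      .basal_delta_cov(function(b) resid_full(opt$estimates, g_b = b),
                       opt$estimates, cv, basal$g_b,
                       (options$assay_fsd * basal$g_b)^2 / n_b) +
      .basal_delta_cov(function(b) resid_full(opt$estimates, i_b = b),
                       opt$estimates, cv, basal$i_b,
                       (options$insulin_assay_fsd * basal$i_b)^2 / n_b)
    cv$se <- sqrt(pmax(diag(cv$cov), 0))
    cv$fsd <- cv$se / abs(opt$estimates)
  }

  pars <- minmod_params(s_g = opt$estimates[["s_g"]], p2 = opt$estimates[["p2"]],
                        p3 = opt$estimates[["p3"]], g0 = opt$estimates[["g0"]],
                        g_b = basal$g_b, i_b = basal$i_b)
  traj <- simulate_minmod(pars, insulin, t_sim)
  pred <- traj$glucose_mmol_l[pick]
  g <- c(s_g = 0, p2 = -opt$estimates[["p3"]] / opt$estimates[["p2"]]^2,
         p3 = 1 / opt$estimates[["p2"]], g0 = 0)
  s_i_se <- if (any(!is.finite(cv$se[c("p2", "p3")]))) Inf else
    sqrt(max(0, drop(t(g) %*% cv$cov %*% g)))

  structure(list(
    coefficients = opt$estimates, se = cv$se, fsd = cv$fsd, vcov = cv$cov,
    wrss = opt$wrss, variance_scale = cv$variance_scale,
    std_residuals = standardized_residuals(y_obs, pred, options$assay_fsd),
    fitted = pred, observed = y_obs, times = t_obs,
    converged = opt$converged, n_iter = opt$n_iter, flags = cv$flags,
    basal = basal, params = pars,
    s_i = pars$p3 / pars$p2, s_i_se = s_i_se,
    series = series, forcings = list(insulin = insulin),
    options = options, response = "glucose", call = match.call()),
    class = c("minmod_fit", "fsigt_fit"))
}

#' Standardized residuals under fractional assay weighting
#'
#' r_i = (obs_i - pred_i) / (assay_fsd * obs_i): the residual in units of
#' the assay standard deviation of that observation.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param assay_fsd fractional assay standard deviation.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(observed, predicted, assay_fsd = 0.05) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (any(observed == 0))
    stop("zero observation: standardized residual undefined", call. = FALSE)
  (observed - predicted) / (assay_fsd * observed)
}

# Wald-Wolfowitz runs test on residual signs (normal approximation).
# Zeros are dropped.  Returns the two-sided p-value; degenerate sequences
# (all one sign) return p = NA and are treated as systematic deviation.
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = as.integer(n > 0), p_value = NA_real_))
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  list(runs = runs, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Model acceptance check for a fitted subject
#'
#' A fit is accepted when (i) every parameter's fractional standard
#' deviation is below 0.5 (unique identifiability), (ii) at most 5% of
#' standardized residuals fall outside +/- 2 assay standard deviations, and
#' (iii) a Wald--Wolfowitz runs test on the residual signs does not reject
#' randomness at alpha = 0.05 (no systematic deviation).
#'
#' @param fit an `ffa_fit` or `minmod_fit`.
#' @param fsd_limit identifiability bound on the FSDs (default 0.5).
#' @param outlier_fraction maximum tolerated fraction of |r| > 2 residuals.
#' @param runs_alpha significance level of the runs test.
#' @return An `acceptance_verdict` list with elements `pass` (logical),
#'   `criteria` (named logicals: `fsd`, `residual_band`, `runs`), `reasons`
#'   (character, empty when passing), `max_fsd`, `outlier_fraction`,
#'   `runs_p`.
#' @export
acceptance_check <- function(fit, fsd_limit = 0.5, outlier_fraction = 0.05,
                             runs_alpha = 0.05) {
  if (!isTRUE(fit$converged))
    stop("acceptance_check requires a converged fit", call. = FALSE)
  fsd_ok <- all(fit$fsd < fsd_limit)
  out_frac <- mean(abs(fit$std_residuals) > 2)
  band_ok <- out_frac <= outlier_fraction
  rt <- runs_test(fit$std_residuals)
  runs_ok <- !is.na(rt$p_value) && rt$p_value >= runs_alpha
  reasons <- character(0)
  if (!fsd_ok)
    reasons <- c(reasons, paste0("FSD >= ", fsd_limit, " for: ",
                                 paste(names(fit$fsd)[fit$fsd >= fsd_limit],
                                       collapse = ", ")))
  if (!band_ok)
    reasons <- c(reasons, sprintf(
      "%.0f%% of standardized residuals outside +/-2 SD (limit %.0f%%)",
      100 * out_frac, 100 * outlier_fraction))
  if (!runs_ok)
    reasons <- c(reasons, sprintf(
      "runs test signals systematic residual deviation (p = %.3g)",
      rt$p_value))
  structure(list(pass = fsd_ok && band_ok && runs_ok,
                 criteria = c(fsd = fsd_ok, residual_band = band_ok,
                              runs = runs_ok),
                 reasons = reasons, max_fsd = max(fit$fsd),
                 outlier_fraction = out_frac, runs_p = rt$p_value),
            class = "acceptance_verdict")
}

#' @export
print.acceptance_verdict <- function(x, ...) {
  cat("Model acceptance:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  max FSD = %.3g; %.1f%% residuals outside +/-2 SD; runs p = %.3g\n",
              x$max_fsd, 100 * x$outlier_fraction, x$runs_p))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Write a per-subject fit report
#'
#' Serialises estimates, standard errors, FSDs, WRSS, flags and the
#' acceptance verdict as JSON, and the residuals as CSV, under `dir`.
#'
#' @param fit an `ffa_fit` or `minmod_fit`.
#' @param dir output directory (created if needed).
#' @return The JSON path, invisibly.
#' @export
write_fit_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- attr(fit$series, "subject_id")
  v <- acceptance_check(fit)
  rep <- list(subject_id = id, estimates = as.list(fit$coefficients),
              se = as.list(fit$se), fsd = as.list(fit$fsd),
              wrss = fit$wrss, converged = fit$converged,
              n_iter = fit$n_iter, flags = fit$flags,
              acceptance = list(pass = v$pass, reasons = v$reasons))
  jpath <- file.path(dir, paste0(id, "_fit.json"))
  jsonlite::write_json(rep, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(
    data.frame(time_min = fit$times, observed = fit$observed,
               fitted = fit$fitted, std_residual = fit$std_residuals),
    file.path(dir, paste0(id, "_residuals.csv")), row.names = FALSE)
  invisible(jpath)
}
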