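#' Parameters of the FFA kinetics model
#'
#' The one-compartment non-linear model of plasma FFA during an FSIGT has
#' four free parameters plus two basal constants fixed from the fasting
#' samples:
#' \describe{
#'   \item{alpha}{scaling of the proportional glucose control over FFA
#'     disposal, l/mmol.}
#'   \item{s_ffa}{fractional FFA disposal rate, 1/min.}
#'   \item{p_xfcr}{fractional removal rate of insulin action from the remote
#'     compartment, 1/min (analogue of the minimal model's p2).}
#'   \item{p_xa}{transfer rate of the plasma insulin increment into remote
#'     insulin action, 1/min^2 per mU/l (analogue of p3).  Insulin-action
#'     parameters follow the classical minimal-model convention of insulin
#'     in mU/l (= uU/ml); plasma insulin data are stored canonically in
#'     pmol/l and converted internally by the standard factor 6.0.}
#'   \item{ffa_b}{basal (fasting) plasma FFA, umol/l.}
#'   \item{i_b}{basal plasma insulin, pmol/l.}
#' }
#' Defaults for the four kinetic parameters are representative healthy-adult
#' cohort means.
#'
#' @param alpha,s_ffa,p_xfcr,p_xa,ffa_b,i_b see Description; all must be
#'   strictly positive.
#' @return An object of class `ffa_params` (named list).
#' @export
ffa_params <- function(alpha = 0.1, s_ffa = 0.02, p_xfcr = 0.06,
                       p_xa = 3.4e-5, ffa_b = 326, i_b = 45) {
  p <- list(alpha = alpha, s_ffa = s_ffa, p_xfcr = p_xfcr, p_xa = p_xa,
            ffa_b = ffa_b, i_b = i_b)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("ffa_params: '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  class(p) <- "ffa_params"
  p
}

#' @export
print.ffa_params <- function(x, ...) {
  cat("FFA model parameters:\n")
  cat(sprintf("  alpha  = %.4g l/mmol\n", x$alpha))
  cat(sprintf("  s_ffa  = %.4g 1/min\n", x$s_ffa))
  cat(sprintf("  p_xfcr = %.4g 1/min\n", x$p_xfcr))
  cat(sprintf("  p_xa   = %.4g 1/min^2 per mU/l\n", x$p_xa))
  cat(sprintf("  ffa_b  = %.4g umol/l, i_b = %.4g pmol/l\n", x$ffa_b, x$i_b))
  cat(sprintf("  S_I(FFA) = p_xa/p_xfcr = %.4g (mU/l)^-1 min^-1\n",
              si_ffa(x)))
  invisible(x)
}

#' Right-hand side of the FFA kinetics ODEs
#'
#' Evaluates the model derivatives literally, with no clamping:
#' \deqn{dFFA/dt = -(S_{FFA} \alpha FFG(t)) FFA + (S_{FFA} - X_{FFA}) FFA_b}
#' \deqn{dX_{FFA}/dt = -p_{XFCR} X_{FFA} + p_{X\alpha} (I(t) - I_b)}
#' where the insulin increment \eqn{I(t) - I_b} enters in mU/l (forcings
#' supply pmol/l; the conversion by 6.0 is internal).  The lipolysis term
#' \eqn{(S_{FFA} - X_{FFA}) FFA_b} is allowed to go negative when insulin
#' action exceeds the basal fractional disposal rate; simulations record
#' this as a diagnostic rather than clamping.
#'
#' @param state numeric vector `c(ffa, x_ffa)` (umol/l, 1/min).
#' @param t time, minutes.
#' @param params an [ffa_params()].
#' @param glucose,insulin forcing functions of time (see [pl_forcing()])
#'   returning mmol/l and pmol/l.
#' @return Numeric vector `c(dffa_dt, dx_ffa_dt)`.
#' @export
ffa_derivatives <- function(state, t, params, glucose, insulin) {
  if (any(!is.finite(state)))
    stop("non-finite state in ffa_derivatives", call. = FALSE)
  ffa <- state[[1]]
  x <- state[[2]]
  dffa <- -(params$s_ffa * params$alpha * glucose(t)) * ffa +
    (params$s_ffa - x) * params$ffa_b
  dx <- -params$p_xfcr * x +
    params$p_xa * (insulin(t) - params$i_b) / .PMOL_PER_MU
  c(dffa, dx)
}

# deSolve-form RHS shared by the adaptive and fixed-step integrators
.ffa_rhs <- function(t, y, parms) {
  p <- parms$params
  g <- parms$glucose(t)
  ins <- parms$insulin(t)
  list(c(-(p$s_ffa * p$alpha * g) * y[1] + (p$s_ffa - y[2]) * p$ffa_b,
         -p$p_xfcr * y[2] + p$p_xa * (ins - p$i_b) / .PMOL_PER_MU))
}

#' Simulate the FFA kinetics model
#'
#' Integrates the FFA model from the basal initial condition
#' (FFA(0) = FFA_b, X_FFA(0) = 0) over the requested time grid, driven by
#' observed (or synthetic) glucose and insulin forcings.
#'
#' @param params an [ffa_params()].
#' @param glucose,insulin forcing functions (see [pl_forcing()]).
#' @param t_grid output times in minutes, starting at 0, strictly increasing.
#' @param method integration method: `"lsoda"` (adaptive, rtol 1e-8,
#'   atol 1e-10; the default) or `"rk4"` (fixed-step 4th-order
#'   Runge--Kutta on a step of `h` minutes, used as a cross-check).
#' @param h fixed step size in minutes for `method = "rk4"`.
#' @return An `ffa_trajectory` data frame with columns `time_min`,
#'   `ffa_umol_l`, `x_ffa_per_min`; attribute `negative_lipolysis` flags
#'   whether X_FFA ever exceeded s_ffa (net re-esterification).
#' @export
simulate_ffa <- function(params, glucose, insulin, t_grid,
                         method = c("lsoda", "rk4"), h = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(params, "ffa_params"))
  t_grid <- as.numeric(t_grid)
  if (t_grid[1] != 0) stop("t_grid must start at 0", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing", call. = FALSE)
  y0 <- c(ffa = params$ffa_b, x_ffa = 0)
  parms <- list(params = params, glucose = glucose, insulin = insulin)
  sol <- .integrate(.ffa_rhs, y0, t_grid, parms, method, h)
  out <- data.frame(time_min = sol[, 1], ffa_umol_l = sol[, 2],
                    x_ffa_per_min = sol[, 3])
  attr(out, "negative_lipolysis") <- any(out$x_ffa_per_min > params$s_ffa)
  class(out) <- c("ffa_trajectory", "data.frame")
  out
}

# shared integrator front-end; rk4 solves on a fine fixed grid and linearly
# interpolates back onto the requested output times
.integrate <- function(rhs, y0, t_grid, parms, method, h) {
  if (method == "lsoda") {
    sol <- deSolve::lsoda(y = y0, times = t_grid, func = rhs, parms = parms,
                          rtol = 1e-8, atol = 1e-10)
    if (nrow(sol) < length(t_grid))
      stop("ODE integration failed at t = ", max(sol[, 1]), " min",
           call. = FALSE)
    sol
  } else {
    tf <- sort(unique(c(seq(min(t_grid), max(t_grid), by = h), t_grid)))
    sol <- deSolve::rk4(y = y0, times = tf, func = rhs, parms = parms)
    idx <- match(t_grid, sol[, 1])
    if (anyNA(idx)) { # guard against floating-point grid mismatch
      keep <- vapply(t_grid, function(tt) which.min(abs(sol[, 1] - tt)), 0L)
      idx <- keep
    }
    sol[idx, , drop = FALSE]
  }
}

#' Equilibrium FFA concentration under constant glucose
#'
#' With insulin at basal (so X_FFA = 0) and glucose held at `g_const`, the
#' FFA equation has the unique steady state FFA_b / (alpha * g_const).  When
#' alpha * g_const < 1 this exceeds basal FFA — the late-FSIGT rebound
#' equilibrium.
#'
#' @param params an [ffa_params()].
#' @param g_const constant glucose, mmol/l (> 0).
#' @return Steady-state FFA, umol/l.
#' @export
steady_state_ffa <- function(params, g_const) {
  stopifnot(inherits(params, "ffa_params"))
  if (!is.numeric(g_const) || any(g_const <= 0))
    stop("g_const must be positive", call. = FALSE)
  params$ffa_b / (params$alpha * g_const)
}

#' Adipose-tissue insulin sensitivity index
#'
#' The sensitivity of FFA kinetics to insulin is summarised as the ratio of
#' the remote-compartment transfer and removal parameters,
#' S_I(FFA) = p_xa / p_xfcr, in (mU/l)^-1 min^-1 — the direct analogue of
#' the minimal model's S_I = p3/p2.
#'
#' @param params an [ffa_params()], or a list/vector with elements `p_xa`
#'   and `p_xfcr`.
#' @return S_I(FFA), (mU/l)^-1 min^-1.
#' @export
si_ffa <- function(params) {
  p_xa <- params[["p_xa"]]
  p_xfcr <- params[["p_xfcr"]]
  if (!is.numeric(p_xfcr) || p_xfcr <= 0)
    stop("p_xfcr must be positive", call. = FALSE)
  p_xa / p_xfcr
}

#' Lipolysis and disposal rate series implied by a trajectory
#'
#' Decomposes the FFA balance into its two fluxes, expressed per kg body
#' weight through an assumed FFA distribution volume:
#' lipolysis(t) = (s_ffa - X_FFA(t)) * ffa_b * vd, and
#' disposal(t) = s_ffa * alpha * FFG(t) * FFA(t) * vd, both in umol/kg/min.
#'
#' @param params an [ffa_params()].
#' @param traj an `ffa_trajectory` from [simulate_ffa()].
#' @param glucose the glucose forcing used for the simulation.
#' @param vd_per_kg FFA distribution volume, l/kg (default 0.19,
#'   approximately the plasma space).
#' @return A data frame with columns `time_min`, `lipolysis`, `disposal`
#'   (umol/kg/min).
#' @seealso [mean_rates()]
#' @export
rate_series <- function(params, traj, glucose, vd_per_kg = 0.19) {
  stopifnot(inherits(params, "ffa_params"))
  if (!is.numeric(vd_per_kg) || vd_per_kg <= 0)
    stop("vd_per_kg must be positive", call. = FALSE)
  t <- traj$time_min
  lip <- (params$s_ffa - traj$x_ffa_per_min) * params$ffa_b * vd_per_kg
  disp <- params$s_ffa * params$alpha * glucose(t) * traj$ffa_umol_l * vd_per_kg
  data.frame(time_min = t, lipolysis = lip, disposal = disp)
}

#' Time-averaged lipolysis and disposal rates
#'
#' Trapezoid-rule averages of the flux series over a time window
#' (default the 0--180 min FSIGT).
#'
#' @param rates output of [rate_series()].
#' @param window numeric length-2 vector, minutes.
#' @return Named numeric vector `c(lipolysis, disposal)`, umol/kg/min.
#' @export
mean_rates <- function(rates, window = c(0, 180)) {
  keep <- rates$time_min >= window[1] & rates$time_min <= window[2]
  t <- rates$time_min[keep]
  if (length(t) < 2) stop("need at least two samples in window", call. = FALSE)
  span <- diff(range(t))
  trap <- function(v) sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2) / span
  c(lipolysis = trap(rates$lipolysis[keep]),
    disposal = trap(rates$disposal[keep]))
}

#' Export a simulated trajectory with its flux decomposition
#'
#' @param params an [ffa_params()].
#' @param traj an `ffa_trajectory`.
#' @param glucose glucose forcing used in the simulation.
#' @param path output CSV path.
#' @param vd_per_kg FFA distribution volume, l/kg.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(params, traj, glucose, path,
                                 vd_per_kg = 0.19) {
  r <- rate_series(params, traj, glucose, vd_per_kg)
  d <- data.frame(time_min = traj$time_min, ffa_umol_l = traj$ffa_umol_l,
                  x_ffa_per_min = traj$x_ffa_per_min,
                  lipolysis = r$lipolysis, disposal = r$disposal)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
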