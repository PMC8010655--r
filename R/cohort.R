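#' Configuration for the synthetic FSIGT cohort generator
#'
#' Defines the study conditions emulated by the generator: an
#' insulin-modified FSIGT in healthy adults (glucose bolus 0.3 g/kg at
#' t = 0, insulin bolus 0.03 U/kg at t = 20 min, dense sampling to
#' 180 min), fasting glucose about 5.25 mmol/l, insulin about 45 pmol/l and
#' FFA about 326 umol/l, with 5% fractional FFA assay noise.  Between-
#' subject variation of the kinetic parameters is lognormal with a 30%
#' coefficient of variation around the healthy-cohort means.
#'
#' @param n_subjects number of subjects.
#' @param seed integer master seed; every subject draws from a
#'   deterministic substream of it.
#' @param ffa_means named list/vector of mean FFA-model kinetic parameters
#'   (`alpha`, `s_ffa`, `p_xfcr`, `p_xa`).
#' @param minmod_means named list/vector of mean minimal-model parameters
#'   (`s_g`, `p2`, `p3`) — conventional healthy-subject magnitudes.
#' @param param_cv between-subject lognormal CV of the kinetic parameters.
#' @param noise_fsd named vector of fractional assay SDs for `ffa`,
#'   `glucose`, `insulin` (multiplicative Gaussian measurement noise).
#' @param basal_means named vector of mean basal `glucose` (mmol/l),
#'   `insulin` (pmol/l) and `ffa` (umol/l).
#' @param basal_cv named vector of between-subject lognormal CVs of the
#'   basal values (cohort-scale spread of fasting levels).
#' @param schedule a [sample_schedule()].
#' @param insulin_curve list describing the synthetic plasma-insulin
#'   response: endogenous first-phase amplitude `a1` (pmol/l) and time
#'   constant `tau1` (min), exogenous-bolus amplitude `a2` and time
#'   constant `tau2`, bolus `delay` (min) and per-subject lognormal
#'   amplitude CV `amp_cv`.  The default `a2` = 1200 pmol/l is the peak
#'   increment implied by the 0.03 U/kg bolus distributed over about
#'   0.15 l/kg (200 mU/l).
#' @param glucose_dose glucose bolus, g/kg.
#' @param vg_dl_per_kg glucose distribution volume, dl/kg (sets the
#'   post-mixing glucose G0 implied by the bolus).
#' @param body_weight_mean,body_weight_cv body-weight distribution, kg.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 25, seed = 1,
                          ffa_means = c(alpha = 0.1, s_ffa = 0.02,
                                        p_xfcr = 0.06, p_xa = 3.4e-5),
                          minmod_means = c(s_g = 0.02, p2 = 0.05, p3 = 1.8e-5),
                          param_cv = 0.30,
                          noise_fsd = c(ffa = 0.05, glucose = 0.02,
                                        insulin = 0.05),
                          basal_means = c(glucose = 5.25, insulin = 45,
                                          ffa = 326),
                          basal_cv = c(glucose = 0.07, insulin = 0.30,
                                       ffa = 0.35),
                          schedule = sample_schedule(),
                          insulin_curve = list(a1 = 300, tau1 = 4, a2 = 1200,
                                               tau2 = 3, delay = 20,
                                               amp_cv = 0.2),
                          glucose_dose = 0.3, vg_dl_per_kg = 1.6,
                          body_weight_mean = 70, body_weight_cv = 0.12) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  noise_fsd <- .named_defaults(noise_fsd, c(ffa = 0.05, glucose = 0.02,
                                            insulin = 0.05))
  basal_cv <- .named_defaults(basal_cv, c(glucose = 0.07, insulin = 0.30,
                                          ffa = 0.35))
  basal_means <- .named_defaults(basal_means, c(glucose = 5.25, insulin = 45,
                                                ffa = 326))
  if (any(noise_fsd < 0) || any(noise_fsd >= 1))
    stop("noise_fsd values must be in [0, 1)", call. = FALSE)
  if (param_cv < 0 || param_cv >= 1)
    stop("param_cv must be in [0, 1)", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 ffa_means = ffa_means, minmod_means = minmod_means,
                 param_cv = param_cv, noise_fsd = noise_fsd,
                 basal_means = basal_means, basal_cv = basal_cv,
                 schedule = schedule, insulin_curve = insulin_curve,
                 glucose_dose = glucose_dose, vg_dl_per_kg = vg_dl_per_kg,
                 body_weight_mean = body_weight_mean,
                 body_weight_cv = body_weight_cv),
            class = "cohort_config")
}

# fill unnamed/partial named vectors against defaults
.named_defaults <- function(x, defaults) {
  if (is.null(names(x)) && length(x) == length(defaults)) names(x) <- names(defaults)
  out <- defaults
  out[names(x)] <- x
  out
}

# lognormal draw with arithmetic mean m and coefficient of variation cv;
# cv = 0 returns the mean exactly
.rlnorm_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# deterministic per-subject seed below 2^31
.subject_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + 7919 * as.numeric(index)) %% 2147483647
}

#' Synthetic plasma-insulin profile for one FSIGT subject
#'
#' Two gamma-shaped pulses on a basal level: an endogenous first-phase
#' response `a1 * (t/tau1) * exp(1 - t/tau1)` starting at the glucose bolus
#' (peak a1 at t = tau1), and an exogenous pulse of the same form delayed
#' to the insulin bolus at `delay` minutes (peak a2 at delay + tau2).
#' Before t = 0 the profile is basal.
#'
#' @param config a [cohort_config()] (supplies the curve constants).
#' @param i_b basal insulin, pmol/l.
#' @param a1,a2 pulse amplitudes, pmol/l; default to the config values
#'   (per-subject draws are passed in by [generate_subject()]).
#' @param grid_by spacing of the interpolation knots, minutes.
#' @return A [pl_forcing()] over [-15, 180] min.
#' @export
synthetic_insulin_profile <- function(config, i_b = config$basal_means[["insulin"]],
                                      a1 = config$insulin_curve$a1,
                                      a2 = config$insulin_curve$a2,
                                      grid_by = 0.25) {
  ic <- config$insulin_curve
  f <- function(t) {
    v <- rep(i_b, length(t))
    pos <- t >= 0
    v[pos] <- v[pos] + a1 * (t[pos] / ic$tau1) * exp(1 - t[pos] / ic$tau1)
    late <- t > ic$delay
    td <- t[late] - ic$delay
    v[late] <- v[late] + a2 * (td / ic$tau2) * exp(1 - td / ic$tau2)
    v
  }
  knots <- sort(unique(c(min(config$schedule$basal_times), -1,
                         seq(0, max(config$schedule$post_times), by = grid_by))))
  pl_forcing(knots, f(knots))
}

#' Generate one synthetic FSIGT subject with known ground truth
#'
#' Draws subject-level kinetic parameters and basal values lognormally
#' around the configured means, builds the latent (noise-free) insulin and
#' glucose curves — glucose by simulating the minimal model with
#' G0 = g_b + bolus/(distribution volume) — drives the FFA model with those
#' latent curves, samples all three analytes on the FSIGT schedule, and
#' applies independent multiplicative Gaussian assay noise.  Basal samples
#' are the subject's basal level plus assay noise.  Parameter vectors whose
#' noise-free FFA trajectory would be non-positive (physically unrealizable
#' subjects) are rejected and redrawn within the subject's RNG substream.
#' The same `(seed, index)` pair always reproduces the same subject
#' bit-for-bit.
#'
#' @param config a [cohort_config()].
#' @param index subject index in `1:n_subjects`.
#' @return An `fsigt_subject` list: `subject_id`, `series` (an
#'   [fsigt_series()]), `true_ffa_params`, `true_minmod_params`, and
#'   `latent` (the noise-free glucose/insulin forcings used to generate the
#'   data).
#' @export
generate_subject <- function(config, index) {
  stopifnot(inherits(config, "cohort_config"))
  if (index < 1 || index > config$n_subjects)
    stop("index must be in 1..n_subjects", call. = FALSE)
  withr_seed(.subject_seed(config$seed, index), {
    fm <- config$ffa_means
    mm <- config$minmod_means
    cv <- config$param_cv
    # post-mixing glucose implied by the 0.3 g/kg bolus and distribution volume
    g_inc <- convert_units(config$glucose_dose * 1000 / config$vg_dl_per_kg,
                           "glucose", "mg/dl", "mmol/l")
    post <- config$schedule$post_times
    knots <- c(config$schedule$basal_times, post)

    # draw until the noise-free FFA trajectory is positive: independent
    # lognormal draws can combine low s_ffa with high insulin action into
    # physically unrealizable (negative-FFA) subjects, which an observed
    # cohort cannot contain
    for (try in 1:50) {
      alpha <- .rlnorm_cv(1, fm[["alpha"]], cv)
      s_ffa <- .rlnorm_cv(1, fm[["s_ffa"]], cv)
      p_xfcr <- .rlnorm_cv(1, fm[["p_xfcr"]], cv)
      p_xa <- .rlnorm_cv(1, fm[["p_xa"]], cv)
      s_g <- .rlnorm_cv(1, mm[["s_g"]], cv)
      p2 <- .rlnorm_cv(1, mm[["p2"]], cv)
      p3 <- .rlnorm_cv(1, mm[["p3"]], cv)
      g_b <- .rlnorm_cv(1, config$basal_means[["glucose"]],
                        config$basal_cv[["glucose"]])
      i_b <- .rlnorm_cv(1, config$basal_means[["insulin"]],
                        config$basal_cv[["insulin"]])
      ffa_b <- .rlnorm_cv(1, config$basal_means[["ffa"]],
                          config$basal_cv[["ffa"]])
      weight <- .rlnorm_cv(1, config$body_weight_mean, config$body_weight_cv)
      a1 <- .rlnorm_cv(1, config$insulin_curve$a1, config$insulin_curve$amp_cv)
      a2 <- .rlnorm_cv(1, config$insulin_curve$a2, config$insulin_curve$amp_cv)

      # latent forcings are represented piecewise-linearly at the sampling
      # resolution: what drives the kinetics is exactly what a fit of the
      # sampled (noise-free) data would reconstruct, so the only generative
      # distortions are the declared measurement noises
      ins_smooth <- synthetic_insulin_profile(config, i_b = i_b,
                                              a1 = a1, a2 = a2)
      insulin_curve <- pl_forcing(knots, ins_smooth(knots))
      true_mm <- minmod_params(s_g = s_g, p2 = p2, p3 = p3, g0 = g_b + g_inc,
                               g_b = g_b, i_b = i_b)
      gtraj <- simulate_minmod(true_mm, insulin_curve, c(0, post))
      glucose_curve <- pl_forcing(
        knots, c(rep(g_b, length(config$schedule$basal_times)),
                 gtraj$glucose_mmol_l[-1]))

      true_ffa <- ffa_params(alpha = alpha, s_ffa = s_ffa, p_xfcr = p_xfcr,
                             p_xa = p_xa, ffa_b = ffa_b, i_b = i_b)
      ftraj <- tryCatch(
        simulate_ffa(true_ffa, glucose_curve, insulin_curve, c(0, post)),
        error = function(e) NULL)
      if (!is.null(ftraj) && all(ftraj$ffa_umol_l > 0)) break
      ftraj <- NULL
    }
    if (is.null(ftraj))
      stop("could not draw a physiologically realizable subject in 50 tries",
           call. = FALSE)

    nf <- config$noise_fsd
    noisy <- function(v, fsd) v * (1 + fsd * stats::rnorm(length(v)))
    nb <- length(config$schedule$basal_times)
    times <- c(config$schedule$basal_times, post)
    glucose <- c(noisy(rep(g_b, nb), nf[["glucose"]]),
                 noisy(glucose_curve(post), nf[["glucose"]]))
    insulin <- c(noisy(rep(i_b, nb), nf[["insulin"]]),
                 noisy(insulin_curve(post), nf[["insulin"]]))
    ffa <- c(noisy(rep(ffa_b, nb), nf[["ffa"]]),
             noisy(ftraj$ffa_umol_l[-1], nf[["ffa"]]))
    id <- sprintf("S%03d", index)
    series <- fsigt_series(id, times, glucose, insulin, ffa,
                           body_weight = weight)
    structure(list(subject_id = id, series = series,
                   true_ffa_params = true_ffa, true_minmod_params = true_mm,
                   latent = list(glucose = glucose_curve,
                                 insulin = insulin_curve)),
              class = "fsigt_subject")
  })
}

#' @export
print.fsigt_subject <- function(x, ...) {
  cat("Synthetic FSIGT subject", x$subject_id, "\n")
  print(x$series)
  invisible(x)
}

#' Generate a synthetic FSIGT cohort
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory: writes one CSV per subject (the
#'   canonical dialect of [write_fsigt_csv()]), `manifest.csv`,
#'   `truth.csv` with the generating parameters, and a `config.json` echo.
#' @return An `fsigt_cohort`: list of [generate_subject()] results with the
#'   config attached.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) generate_subject(config, i))
  names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  cohort <- structure(subjects, class = "fsigt_cohort", config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- paste0(names(subjects), ".csv")
    for (i in seq_along(subjects))
      write_fsigt_csv(subjects[[i]]$series, file.path(dir, files[i]))
    utils::write.csv(
      data.frame(subject_id = names(subjects), file = files,
                 body_weight_kg = vapply(subjects, function(s)
                   attr(s$series, "body_weight"), 0)),
      file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(cohort_truth(cohort), file.path(dir, "truth.csv"),
                     row.names = FALSE, quote = FALSE)
    cfg <- config
    cfg$schedule <- unclass(cfg$schedule)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cohort
}

#' @export
print.fsigt_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic FSIGT cohort:", length(x), "subjects (seed ", cfg$seed,
      ", parameter CV ", cfg$param_cv, ")\n")
  invisible(x)
}

#' Ground-truth parameter table of a synthetic cohort
#'
#' @param cohort an `fsigt_cohort`.
#' @return A data frame, one row per subject, with the generating FFA-model
#'   and minimal-model parameters, basal values and the implied true
#'   S_I(FFA) and S_I.
#' @export
cohort_truth <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    fp <- s$true_ffa_params
    mp <- s$true_minmod_params
    data.frame(subject_id = s$subject_id, alpha = fp$alpha, s_ffa = fp$s_ffa,
               p_xfcr = fp$p_xfcr, p_xa = fp$p_xa, ffa_b = fp$ffa_b,
               i_b = fp$i_b, si_ffa = si_ffa(fp), s_g = mp$s_g, p2 = mp$p2,
               p3 = mp$p3, g0 = mp$g0, g_b = mp$g_b, s_i = mp$p3 / mp$p2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
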