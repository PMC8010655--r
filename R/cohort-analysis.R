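#' Cohort summary of fitted FFA-model parameters
#'
#' Arithmetic mean and standard error of the mean (SD/sqrt(n)) of each
#' kinetic parameter and of its fractional standard deviation, over the
#' subjects whose fits pass [acceptance_check()] (all subjects when
#' `accepted_only = FALSE`).  The adipose sensitivity index S_I(FFA) is
#' summarised as the mean of the per-subject ratios p_xa/p_xfcr, which in
#' general differs from the ratio of the parameter means (Jensen gap); the
#' ratio of means is also reported for comparison.
#'
#' @param fits list of `ffa_fit` objects.
#' @param accepted_only drop fits failing the acceptance check?
#' @return A `cohort_summary`: data frame (rows alpha, s_ffa, p_xfcr, p_xa,
#'   si_ffa; columns mean, se, mean_fsd, se_fsd) with attributes
#'   `n_subjects`, `n_accepted` and `si_ffa_ratio_of_means`.
#' @export
summarize_parameters <- function(fits, accepted_only = TRUE) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "ffa_fit")))
  if (accepted_only) {
    ok <- vapply(fits, function(f) acceptance_check(f)$pass, TRUE)
    kept <- fits[ok]
  } else kept <- fits
  if (length(kept) < 2)
    stop("need at least 2 accepted fits to summarise (", length(kept),
         " available)", call. = FALSE)
  pnames <- c("alpha", "s_ffa", "p_xfcr", "p_xa")
  est <- t(vapply(kept, function(f) f$coefficients[pnames], numeric(4)))
  fsd <- t(vapply(kept, function(f) f$fsd[pnames], numeric(4)))
  si <- vapply(kept, function(f) f$si_ffa, 0)
  si_fsd <- vapply(kept, function(f) f$si_ffa_se / f$si_ffa, 0)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  tab <- data.frame(
    parameter = c(pnames, "si_ffa"),
    mean = c(colMeans(est), mean(si)),
    se = c(apply(est, 2, sem), sem(si)),
    mean_fsd = c(colMeans(fsd), mean(si_fsd)),
    se_fsd = c(apply(fsd, 2, sem), sem(si_fsd)))
  rownames(tab) <- tab$parameter
  attr(tab, "n_subjects") <- length(fits)
  attr(tab, "n_accepted") <- length(kept)
  attr(tab, "si_ffa_ratio_of_means") <-
    mean(est[, "p_xa"]) / mean(est[, "p_xfcr"])
  class(tab) <- c("cohort_summary", "data.frame")
  tab
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort parameter summary (", attr(x, "n_accepted"), " accepted of ",
      attr(x, "n_subjects"), " subjects; mean +/- SE)\n", sep = "")
  units <- c(alpha = "l/mmol", s_ffa = "1/min", p_xfcr = "1/min",
             p_xa = "1/min^2 per mU/l", si_ffa = "(mU/l)^-1 min^-1")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-7s %.3g +/- %.2g %-22s FSD %.2f +/- %.2f\n",
                x$parameter[i], x$mean[i], x$se[i], units[[x$parameter[i]]],
                x$mean_fsd[i], x$se_fsd[i]))
  cat(sprintf("  S_I(FFA) ratio-of-means = %.3g (vs mean-of-ratios %.3g)\n",
              attr(x, "si_ffa_ratio_of_means"), x["si_ffa", "mean"]))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard large-sample approximation t = rho * sqrt((n-2)/(1-rho^2)) on
#' n - 2 degrees of freedom (two-sided).  |rho| = 1 gives p = 0.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return A list with elements `rho`, `p_value` and `n`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  rho <- sum(dx * dy) / den
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Rank-correlation table between minimal-model indices and FFA parameters
#'
#' Spearman correlation of every pair of columns, with a significance flag
#' at `alpha`.  Rows are aligned by a `subject_id` column when both tables
#' have one, otherwise by position.
#'
#' @param minmod_indices data frame of per-subject minimal-model indices
#'   (e.g. s_i, s_g, airg, di, g0, p2, p3).
#' @param ffa_params data frame of per-subject FFA-model estimates
#'   (e.g. alpha, s_ffa, p_xfcr, p_xa, si_ffa).
#' @param alpha significance level for the flags.
#' @return A `correlation_table`: list of matrices `rho`, `p` and
#'   `significant` (minmod indices in rows, FFA parameters in columns).
#' @export
correlation_table <- function(minmod_indices, ffa_params, alpha = 0.05) {
  if ("subject_id" %in% names(minmod_indices) &&
      "subject_id" %in% names(ffa_params)) {
    if (!setequal(minmod_indices$subject_id, ffa_params$subject_id))
      stop("subject_id mismatch between the two tables", call. = FALSE)
    ffa_params <- ffa_params[match(minmod_indices$subject_id,
                                   ffa_params$subject_id), , drop = FALSE]
    minmod_indices$subject_id <- NULL
    ffa_params$subject_id <- NULL
  } else if (nrow(minmod_indices) != nrow(ffa_params))
    stop("tables must describe the same subjects", call. = FALSE)
  rho <- p <- matrix(NA_real_, ncol(minmod_indices), ncol(ffa_params),
                     dimnames = list(names(minmod_indices), names(ffa_params)))
  for (i in seq_len(ncol(minmod_indices)))
    for (j in seq_len(ncol(ffa_params))) {
      s <- spearman_cor(minmod_indices[[i]], ffa_params[[j]])
      rho[i, j] <- s$rho
      p[i, j] <- s$p_value
    }
  structure(list(rho = rho, p = p, significant = p < alpha, alpha = alpha),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  cat("Spearman rank correlations (", nrow(x$rho), " indices x ",
      ncol(x$rho), " parameters)\n", sep = "")
  m <- matrix(sprintf(paste0("%.", digits, "f%s"), x$rho,
                      ifelse(x$significant, "*", " ")),
              nrow(x$rho), dimnames = dimnames(x$rho))
  print(m, quote = FALSE)
  cat("* P <", x$alpha, "\n")
  invisible(x)
}

#' Paired comparison of peak insulin-action magnitudes
#'
#' Tests whether the peak insulin action on glucose (X_max, from the
#' minimal model) and the peak insulin action on FFA (X_max,FFA) differ, by
#' a two-sided paired t-test on the per-subject differences (or a Welch
#' two-sample t-test with `paired = FALSE`).
#'
#' @param x_max,x_max_ffa per-subject peak action values, 1/min.
#' @param paired paired test (default) or two-sample.
#' @return A list with `t_statistic`, `p_value`, `df` and `mean_difference`.
#' @export
paired_peak_test <- function(x_max, x_max_ffa, paired = TRUE) {
  if (length(x_max) != length(x_max_ffa) && paired)
    stop("paired test needs matched subjects", call. = FALSE)
  if (length(x_max) < 2 || length(x_max_ffa) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  d <- x_max - x_max_ffa
  if (paired && stats::var(d) <= max(1e-12 * mean(d)^2, 1e-300))
    stop("zero variance of paired differences: test degenerate",
         call. = FALSE)
  ht <- stats::t.test(x_max, x_max_ffa, paired = paired)
  list(t_statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter),
       mean_difference = mean(x_max) - mean(x_max_ffa))
}

#' Per-subject minimal-model index row
#'
#' Convenience extractor combining a minimal-model fit with the observed
#' series: S_I, S_G, AIRg, DI, G0, p2, p3 and the peak insulin action from
#' the dense simulated trajectory.
#'
#' @param fit a `minmod_fit`.
#' @return A one-row data frame.
#' @export
minmod_indices <- function(fit) {
  stopifnot(inherits(fit, "minmod_fit"))
  a <- airg(fit$series)
  dense <- predict(fit)
  pk <- peak_action(dense$time_min, dense$x_per_min)
  data.frame(subject_id = attr(fit$series, "subject_id"),
             s_i = fit$s_i, s_g = fit$coefficients[["s_g"]], airg = a,
             di = disposition_index(fit$s_i, a),
             g0 = fit$coefficients[["g0"]], p2 = fit$coefficients[["p2"]],
             p3 = fit$coefficients[["p3"]],
             x_max = pk$x_max, t_peak = pk$t_peak)
}

#' Per-subject FFA-model estimate row
#'
#' @param fit an `ffa_fit`.
#' @return A one-row data frame with alpha, s_ffa, p_xfcr, p_xa, si_ffa and
#'   the peak FFA insulin action from the dense simulated trajectory.
#' @export
ffa_indices <- function(fit) {
  stopifnot(inherits(fit, "ffa_fit"))
  dense <- predict(fit)
  pk <- peak_action(dense$time_min, dense$x_ffa_per_min)
  data.frame(subject_id = attr(fit$series, "subject_id"),
             alpha = fit$coefficients[["alpha"]],
             s_ffa = fit$coefficients[["s_ffa"]],
             p_xfcr = fit$coefficients[["p_xfcr"]],
             p_xa = fit$coefficients[["p_xa"]],
             si_ffa = fit$si_ffa,
             x_max_ffa = pk$x_max, t_peak_ffa = pk$t_peak)
}
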