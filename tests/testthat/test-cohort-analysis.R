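# minimal fitted-subject stand-in carrying what the cohort summaries read
fake_ffa_fit <- function(coefs, fsd = rep(0.1, 4), resid = NULL, id = "f") {
  # mixed-sign pattern whose run count sits near its null expectation
  if (is.null(resid)) resid <- rep(c(0.4, 0.4, -0.4, -0.4), length.out = 27)
  coefs <- stats::setNames(coefs, c("alpha", "s_ffa", "p_xfcr", "p_xa"))
  si <- coefs[["p_xa"]] / coefs[["p_xfcr"]]
  structure(list(coefficients = coefs,
                 fsd = stats::setNames(fsd, names(coefs)),
                 si_ffa = si, si_ffa_se = 0.1 * si,
                 converged = TRUE, std_residuals = resid),
            class = c("ffa_fit", "fsigt_fit"))
}

test_that("spearman matches the base-R rank correlation on a seeded battery", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE) + stats::runif(n, 0, 0.01)
    y <- if (i %% 3 == 0) sample(1:3, n, replace = TRUE)  # heavy ties
         else stats::rnorm(n)
    if (length(unique(y)) < 2) y <- y + seq_len(n) * 0.1
    s <- spearman_cor(x, y)
    expect_equal(s$rho, stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  # monotone vectors and a hand-ranked case
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(1:10, (1:10)^3)$p_value, 0)
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "at least 4")
})

test_that("spearman p-values agree with the t-approximation oracle", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(c(8, 15, 25), 1)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n) + 0.3 * x
    s <- spearman_cor(x, y)
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(s$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("cohort summary reports means, SEMs, FSD summaries and the Jensen gap", {
  f1 <- fake_ffa_fit(c(0.1, 0.01, 0.05, 3e-5), fsd = rep(0.10, 4))
  f2 <- fake_ffa_fit(c(0.1, 0.03, 0.08, 4e-5), fsd = rep(0.20, 4))
  sm <- summarize_parameters(list(f1, f2))
  expect_equal(sm["s_ffa", "mean"], 0.02)
  expect_equal(sm["s_ffa", "se"], 0.01)
  expect_equal(sm["alpha", "se"], 0)
  expect_equal(sm["s_ffa", "mean_fsd"], 0.15)
  expect_equal(attr(sm, "n_accepted"), 2)

  # S_I(FFA): mean of ratios differs from the ratio of means
  mor <- mean(c(3e-5 / 0.05, 4e-5 / 0.08))
  rom <- mean(c(3e-5, 4e-5)) / mean(c(0.05, 0.08))
  expect_equal(sm["si_ffa", "mean"], mor)
  expect_equal(attr(sm, "si_ffa_ratio_of_means"), rom)
  expect_false(isTRUE(all.equal(mor, rom)))

  # permutation invariance over subjects
  expect_equal(as.data.frame(summarize_parameters(list(f2, f1))),
               as.data.frame(sm))

  # non-accepted fits are dropped (and too few accepted is an error)
  f3 <- fake_ffa_fit(c(9, 9, 9, 9), fsd = c(0.9, 0.1, 0.1, 0.1))
  sm2 <- summarize_parameters(list(f1, f2, f3))
  expect_equal(attr(sm2, "n_accepted"), 2)
  expect_equal(attr(sm2, "n_subjects"), 3)
  expect_error(summarize_parameters(list(f1, f3)), "at least 2 accepted")
})

test_that("correlation table flags perfect, derived and mismatched columns", {
  set.seed(3)
  n <- 25
  shared <- stats::rnorm(n)
  mm <- data.frame(subject_id = paste0("S", 1:n),
                   s_i = shared, airg = stats::rnorm(n))
  p_xfcr <- rep(0.06, n)
  p_xa <- stats::rlnorm(n, log(3e-5), 0.3)
  ff <- data.frame(subject_id = paste0("S", 1:n),
                   alpha = shared, p_xa = p_xa,
                   si_ffa = p_xa / p_xfcr)
  ct <- correlation_table(mm, ff)
  expect_equal(ct$rho["s_i", "alpha"], 1)
  expect_true(ct$significant["s_i", "alpha"])
  # with constant p_xfcr the index is monotone in p_xa
  expect_equal(ct$rho["airg", "si_ffa"], ct$rho["airg", "p_xa"])
  expect_equal(dim(ct$rho), c(2, 3))

  # row alignment follows subject_id, not position
  ff_shuffled <- ff[sample(n), ]
  ct2 <- correlation_table(mm, ff_shuffled)
  expect_equal(ct2$rho, ct$rho)

  ff_bad <- ff
  ff_bad$subject_id[1] <- "zzz"
  expect_error(correlation_table(mm, ff_bad), "mismatch")
})

test_that("paired peak test behaves under null, offset and sign flip", {
  set.seed(8)
  x <- stats::rlnorm(25, log(0.0086), 0.3)
  jitter <- c(rep(c(1e-7, -1e-7), 12), 0)  # differences sum exactly to zero
  null_res <- paired_peak_test(x, x + jitter)
  expect_gt(null_res$p_value, 0.99)   # symmetric differences: t ~ 0

  y <- x + stats::rnorm(25, 0, 5e-4)
  shifted <- paired_peak_test(x + 0.01, y)
  expect_lt(shifted$p_value, 0.001)

  flipped <- paired_peak_test(y, x + 0.01)
  expect_equal(flipped$p_value, shifted$p_value, tolerance = 1e-9)
  expect_equal(flipped$t_statistic, -shifted$t_statistic, tolerance = 1e-9)

  expect_error(paired_peak_test(x, x + 0.01), "zero variance")
  expect_error(paired_peak_test(1, 1), "at least 2")
})

test_that("index extractors combine fit, secretion and peak-action summaries", {
  fmm <- fit_minmod(nf_subject$series)
  row <- minmod_indices(fmm)
  expect_equal(row$di, row$s_i * row$airg)
  expect_equal(row$s_i, row$p3 / row$p2)
  expect_gt(row$x_max, 0)

  fff <- fit_ffa(nf_subject$series)
  frow <- ffa_indices(fff)
  expect_equal(frow$si_ffa, frow$p_xa / frow$p_xfcr)
  expect_gt(frow$x_max_ffa, 0)
})
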