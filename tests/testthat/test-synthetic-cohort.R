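test_that("subject generation is deterministic per (seed, index) and seed-sensitive", {
  cfg <- cohort_config(n_subjects = 2, seed = 9)
  a <- generate_subject(cfg, 1)
  b <- generate_subject(cfg, 1)
  expect_identical(a$series$ffa_umol_l, b$series$ffa_umol_l)
  expect_identical(a$true_ffa_params, b$true_ffa_params)

  c2 <- generate_subject(cfg, 2)
  expect_false(identical(a$series$ffa_umol_l, c2$series$ffa_umol_l))

  other <- generate_subject(cohort_config(n_subjects = 2, seed = 10), 1)
  expect_false(identical(a$series$ffa_umol_l, other$series$ffa_umol_l))
  expect_identical(a$series$time_min, other$series$time_min)  # same schedule

  co <- generate_cohort(cohort_config(n_subjects = 1, seed = 9))
  expect_identical(co[[1]]$series,
                   generate_subject(cohort_config(n_subjects = 1, seed = 9), 1)$series)
})

test_that("zero-noise samples lie exactly on the model solutions", {
  s <- nf_subject
  post <- s$series$time_min[s$series$time_min > 0]
  tr <- simulate_ffa(s$true_ffa_params, s$latent$glucose, s$latent$insulin,
                     c(0, post))
  expect_equal(s$series$ffa_umol_l[s$series$time_min > 0],
               tr$ffa_umol_l[-1], tolerance = 1e-10)
  expect_equal(s$series$glucose_mmol_l[s$series$time_min > 0],
               s$latent$glucose(post), tolerance = 1e-10)
  expect_equal(s$series$insulin_pmol_l[s$series$time_min > 0],
               s$latent$insulin(post), tolerance = 1e-10)
  # basal rows are the basal constants themselves
  expect_equal(unique(s$series$ffa_umol_l[s$series$time_min < 0]),
               s$true_ffa_params$ffa_b)
})

test_that("the sampling schedule matches the insulin-modified FSIGT protocol", {
  s <- generate_subject(cohort_config(n_subjects = 1, seed = 3), 1)
  expect_equal(s$series$time_min,
               c(-15, -10, -5, -1,
                 2, 3, 4, 5, 6, 8, 10, 12, 14, 16, 19, 22, 24, 25, 27, 30,
                 40, 50, 60, 70, 80, 90, 100, 120, 140, 160, 180))
  expect_true(all(s$series$glucose_mmol_l > 0))
  expect_true(all(s$series$insulin_pmol_l > 0))
  expect_true(all(s$series$ffa_umol_l > 0))
})

test_that("synthetic insulin profile is basal at the boundaries with peaks near 4 and 23 min", {
  cfg <- cohort_config()
  f <- synthetic_insulin_profile(cfg, i_b = 45)
  expect_equal(f(0), 45, tolerance = 1e-8)
  expect_equal(f(-10), 45)
  expect_lt(abs(f(180) - 45) / 45, 0.02)   # pulses have decayed

  tt <- seq(0, 60, 0.25)
  v <- f(tt)
  locmax <- tt[which(diff(sign(diff(v))) == -2) + 1]
  expect_equal(length(locmax), 2)
  expect_lt(abs(locmax[1] - 4), 1)
  expect_lt(abs(locmax[2] - 23), 1.5)

  # no exogenous bolus: a single peak near tau1
  f1 <- synthetic_insulin_profile(cfg, i_b = 45, a2 = 0)
  v1 <- f1(tt)
  locmax1 <- tt[which(diff(sign(diff(v1))) == -2) + 1]
  expect_equal(length(locmax1), 1)
  expect_lt(abs(locmax1 - 4), 0.5)
})

test_that("generated FFA is positive and multiphasic: plateau, nadir, rebound", {
  s <- nf_subject$series
  ffa <- s$ffa_umol_l
  t <- s$time_min
  ffa_b <- mean(ffa[t < 0])
  nadir <- min(ffa[t > 0])
  expect_gt(nadir, 0)
  # early plateau: first post-bolus samples stay near basal
  expect_gt(mean(ffa[t >= 2 & t <= 6]) / ffa_b, 0.85)
  # suppression: the nadir sits well below basal
  expect_lt(nadir / ffa_b, 0.6)
  # late rebound: the final phase rises clear of the nadir
  expect_gt(mean(ffa[t >= 140]) / nadir, 1.5)
  expect_gt(which.min(ffa[t > 0]), 5)  # nadir after the early plateau
})

test_that("cohort parameter draws average to the configured means", {
  cfg <- cohort_config(n_subjects = 120, seed = 5)
  truth <- cohort_truth(generate_cohort(cfg))
  for (nm in c("alpha", "s_ffa", "p_xfcr", "p_xa")) {
    m <- cfg$ffa_means[[nm]]
    sem <- stats::sd(truth[[nm]]) / sqrt(nrow(truth))
    expect_lt(abs(mean(truth[[nm]]) - m), 3.5 * sem)
  }
})

test_that("zero-noise cohort subjects are recovered end-to-end below 1% error", {
  cfg <- nf_config(n = 3, seed = 21, param_cv = 0.3)
  co <- generate_cohort(cfg)
  truth <- cohort_truth(co)
  for (i in seq_along(co)) {
    f <- fit_ffa(co[[i]]$series)
    tr <- unlist(truth[i, c("alpha", "s_ffa", "p_xfcr", "p_xa")])
    expect_lt(max(abs(coef(f) - tr) / tr), 0.01)
  }
})
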