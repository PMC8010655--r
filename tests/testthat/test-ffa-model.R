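const_forcing <- function(v) pl_forcing(c(-20, 200), c(v, v))

test_that("derivatives vanish at basal equilibrium and follow the model's signs", {
  p <- ffa_params()               # healthy-cohort mean parameters
  gl <- const_forcing(1 / p$alpha) # alpha * G = 1
  ins <- const_forcing(p$i_b)
  expect_equal(ffa_derivatives(c(p$ffa_b, 0), 0, p, gl, ins), c(0, 0))

  # a 100 mU/l (600 pmol/l) insulin increment feeds the remote compartment
  # at p_xa * dI = 3.4e-3 min^-2
  ins_step <- const_forcing(p$i_b + 600)
  d <- ffa_derivatives(c(p$ffa_b, 0), 0, p, gl, ins_step)
  expect_equal(d[2], 3.4e-3)

  # insulin action above s_ffa makes the lipolysis contribution negative
  d2 <- ffa_derivatives(c(p$ffa_b, 2 * p$s_ffa), 0, p, gl, ins)
  expect_lt(d2[1], 0)
  expect_error(ffa_derivatives(c(NaN, 0), 0, p, gl, ins), "non-finite")
})

test_that("equilibria: preservation, closed form, inverse proportionality", {
  p <- ffa_params()
  expect_equal(steady_state_ffa(ffa_params(alpha = 0.1), 10), 326)
  expect_equal(steady_state_ffa(p, 5.25), 326 / 0.525, tolerance = 1e-12)
  expect_equal(round(steady_state_ffa(p, 5.25), 1), 621.0)
  expect_equal(steady_state_ffa(p, 10), 2 * steady_state_ffa(p, 20))

  # basal equilibrium is preserved by the solver
  gl <- const_forcing(1 / p$alpha)
  tr <- simulate_ffa(p, gl, const_forcing(p$i_b), seq(0, 300, 10))
  expect_equal(tr$ffa_umol_l, rep(p$ffa_b, nrow(tr)), tolerance = 1e-7)
  expect_equal(tr$x_ffa_per_min, rep(0, nrow(tr)), tolerance = 1e-10)
})

test_that("FFA rises monotonically to the rebound equilibrium under basal forcings", {
  p <- ffa_params()  # alpha * 5.25 = 0.525 < 1: supra-basal equilibrium
  tr <- simulate_ffa(p, const_forcing(5.25), const_forcing(p$i_b),
                     seq(0, 2000, 5))
  expect_true(all(diff(tr$ffa_umol_l) > -1e-8))
  expect_equal(tr$ffa_umol_l[nrow(tr)] / p$ffa_b, 1.905, tolerance = 1e-3)
})

test_that("remote insulin action follows its linear-ODE closed form", {
  p <- ffa_params(p_xfcr = 0.11, p_xa = 2e-5)
  dI_pmol <- 480   # 80 mU/l step
  tr <- simulate_ffa(p, const_forcing(1 / p$alpha),
                     const_forcing(p$i_b + dI_pmol), seq(0, 180, 1))
  analytic <- (p$p_xa * 80 / p$p_xfcr) * (1 - exp(-p$p_xfcr * tr$time_min))
  expect_lt(max(abs(tr$x_ffa_per_min - analytic)), 1e-8)
})

test_that("si_ffa is the transfer/removal ratio with its invariances", {
  expect_equal(si_ffa(ffa_params()), 3.4e-5 / 6.0e-2)
  expect_equal(si_ffa(list(p_xa = 0, p_xfcr = 0.06)), 0)
  p <- ffa_params()
  expect_equal(si_ffa(ffa_params(p_xa = 10 * p$p_xa, p_xfcr = 10 * p$p_xfcr)),
               si_ffa(p))
  expect_error(si_ffa(list(p_xa = 1e-5, p_xfcr = 0)), "positive")
})

test_that("flux decomposition reproduces basal lipolysis and disposal rates", {
  p <- ffa_params()
  basal_traj <- data.frame(time_min = c(0, 180), ffa_umol_l = c(326, 326),
                           x_ffa_per_min = c(0, 0))
  r <- rate_series(p, basal_traj, const_forcing(5.25), vd_per_kg = 0.19)
  expect_equal(round(r$lipolysis[1], 2), 1.24)   # 0.02 * 326 * 0.19
  expect_equal(round(r$disposal[1], 3), 0.650)   # 0.02*0.1*5.25*326*0.19
  expect_equal(mean_rates(r), c(lipolysis = r$lipolysis[1],
                                disposal = r$disposal[1]))

  # at equilibrium (alpha*G = 1, X = 0, FFA = ffa_b) the fluxes balance
  re <- rate_series(p, basal_traj, const_forcing(1 / p$alpha))
  expect_equal(re$lipolysis, re$disposal)
})

test_that("simulated FFA stays positive and flags negative lipolysis", {
  s <- nf_subject
  tr <- simulate_ffa(s$true_ffa_params, s$latent$glucose, s$latent$insulin,
                     seq(0, 180, 1))
  expect_true(all(tr$ffa_umol_l > 0))
  # at the default mean parameters the bolus drives X_FFA above s_ffa
  expect_true(attr(tr, "negative_lipolysis"))
  expect_error(simulate_ffa(s$true_ffa_params, s$latent$glucose,
                            s$latent$insulin, c(5, 10)), "start at 0")
})
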