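# shared fixtures: a noise-free configuration at the default (healthy-cohort
# mean) parameters, and one noise-free subject generated from it

nf_config <- function(n = 1, seed = 1, param_cv = 0, ...) {
  cohort_config(n_subjects = n, seed = seed, param_cv = param_cv,
                noise_fsd = c(ffa = 0, glucose = 0, insulin = 0),
                basal_cv = c(glucose = 0, insulin = 0, ffa = 0), ...)
}

# generated once per test run; every kinetic parameter equals the
# configured mean and samples sit exactly on the model solution
nf_subject <- generate_subject(nf_config(), 1)

mean_truth <- unlist(nf_subject$true_ffa_params[
  c("alpha", "s_ffa", "p_xfcr", "p_xa")])

# small valid series builder for hand-constructed cases
toy_series <- function(times = c(-15, -10, -5, -1, 0, 5, 10, 20, 30, 60),
                       glucose = rep(5.25, length(times)),
                       insulin = rep(45, length(times)),
                       ffa = rep(326, length(times)),
                       id = "toy") {
  fsigt_series(id, times, glucose, insulin, ffa)
}
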