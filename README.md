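# ffakin

Modelling plasma free fatty acid (FFA) kinetics during an
insulin-modified frequently sampled intravenous glucose tolerance test
(FSIGT), for investigators who want an adipose-tissue insulin sensitivity
index from the same experiment that yields the classical glucose
minimal-model indices.

During an FSIGT (glucose bolus 0.3 g/kg at t = 0, insulin bolus
0.03 U/kg at t = 20 min, sampling to 180 min), plasma FFA shows an early
plateau, deep suppression, and a late rebound that can overshoot the
fasting level. `ffakin` fits a one-compartment non-linear model of that
profile in which insulin suppresses lipolysis through a remote
insulin-action compartment and plasma glucose proportionally controls FFA
disposal:

    dFFA/dt   = -(S_FFA * alpha * G(t)) * FFA + (S_FFA - X_FFA) * FFA_b,   FFA(0) = FFA_b
    dX_FFA/dt = -p_XFCR * X_FFA + p_Xa * (I(t) - I_b),                     X_FFA(0) = 0

G(t) and I(t) are piecewise-linear interpolants of the measured glucose
and insulin; `FFA_b`, `I_b` are fixed from the fasting samples. The four
kinetic parameters (alpha, S_FFA, p_XFCR, p_Xa) are estimated per subject
by weighted nonlinear least squares (fractional assay SD 5%,
Levenberg-Marquardt in log-parameter space), with identifiability
reported as fractional standard deviations (FSD = SE/|estimate|) from the
known-weights GLS covariance. The adipose insulin sensitivity index is

    S_I(FFA) = p_Xa / p_XFCR        [per mU/l per min]

the analogue of the minimal model's S_I = p3/p2. The package also
provides the Bergman glucose minimal model (S_I, S_G, AIRg, DI, and the
insulin-action trajectory X(t)) for comparison, a seeded synthetic FSIGT
cohort generator with known ground truth, and cohort summaries with
Spearman rank-correlation tables.

## Worked example

Generate one synthetic subject at the default (healthy-cohort mean)
parameters with realistic assay noise, fit the FFA model, and read off
the estimates and diagnostics:

```r
library(ffakin)

cfg  <- cohort_config(n_subjects = 1, seed = 42)
subj <- generate_subject(cfg, 1)
fit  <- fit_ffa(subj$series)
summary(fit)
#> Model: FFA kinetics 
#>         Estimate Std. Error     FSD
#> alpha  1.555e-01  6.325e-03 0.04067
#> s_ffa  1.160e-02  7.998e-04 0.06894
#> p_xfcr 7.865e-02  9.109e-03 0.11580
#> p_xa   2.748e-05  2.523e-06 0.09180
#> S_I(FFA) = 0.0003494 +/- 1.4e-05 (mU/l)^-1 min^-1
#> WRSS = 26.178 on 27 samples; converged in 10 iterations
#> Flags: negative_lipolysis: X_FFA exceeded s_ffa 
#> Acceptance: PASS
```

The estimates sit close to the generating truth
(`subj$true_ffa_params`: alpha 0.147, s_ffa 0.0116, p_xfcr 0.0776,
p_xa 2.88e-05); every FSD is below the 0.5 identifiability bound, no
more than 5% of standardized residuals leave the ±2 band, and the runs
test finds no systematic deviation, so `acceptance_check()` passes the
fit. The `negative_lipolysis` flag records that this subject's fitted
insulin action transiently exceeded S_FFA — net re-esterification, which
the model permits and reports rather than clamping. `S_I(FFA)` ≈ 3.5e-4
per mU/l per min says a sustained 1 mU/l insulin increment ultimately
raises the fractional suppression of lipolysis by about 3.5e-4 per
minute.

The same object supports the usual modelling verbs: `coef()`, `vcov()`,
`predict()` (dense model trajectory including X_FFA), `residuals()`
(standardized by default), `plot()` (fit + residual band), and
`simulate()` (new noisy replicates). `fit_minmod()` returns the matching
glucose minimal-model fit, `minmod_indices()`/`ffa_indices()` assemble
per-subject index tables, and `correlation_table()` crosses them with
Spearman rho and significance flags.

A thin command-line wrapper covers the batch workflows:

```sh
exec/ffakin cohort --n 25 --seed 1 --out cohort/
exec/ffakin fit --input cohort/S001.csv --out report/
exec/ffakin correlate --cohort cohort/ --out table.csv
```

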