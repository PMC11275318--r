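# dynosurv

Dynamic prediction of overall survival (OS) by landmarking, built for
high-grade resectable osteosarcoma cohorts — patients followed from surgery,
with local recurrence (LR) and new metastatic disease (NM) arising during
follow-up.

Static survival models predict once, from surgery, and ignore everything
learned afterwards. `dynosurv` fits a **proportional landmark supermodel**:
for each landmark time `s` on a grid (default 0–5 years, 3-month steps) the
patients still alive at `s` form a data set with delayed entry at `s`,
administrative censoring at `s + w` (window `w = 5` years), and LR/NM status
frozen at `s`; the stacked union is fitted as one Cox-type model with a
shared Breslow baseline:

```
h(t | x, s) = h0(t) · exp( x'β + γ1·s + γ2·s²
                           + poor·(δ0 + δ1·s + δ2·s²)
                           + βLR·LR(s) + βNM·NM(s) )
```

so the poor-vs-good histological-response hazard ratio at prediction time
`tp` is `HR(tp) = HRcon · HRlin^tp · HRquad^(tp²)`, and the probability of
dying within `w` years, predicted at `tp`, is
`1 − exp(−[H0(tp+w) − H0(tp)]·exp(lp))`. Estimation is by pseudo partial
likelihood (Breslow ties, Newton with step halving, compiled risk-set
sweep), with a cluster-robust sandwich covariance by patient — each patient
contributes up to 21 stacked rows. Validation tools: heuristic shrinkage
`(χ² − p)/χ²`, a sliding-window leave-one-out cross-validated C-index, and
reverse Kaplan–Meier median follow-up. Missing tumor volume / histology are
handled by multiple imputation with exact Rubin's-rules pooling.

Because the motivating trial data are not public, the package ships a
synthetic multistate cohort generator with known ground truth (baseline
covariate marginals, LR/NM onset processes, death hazard driven by
published-scale effect sizes). See the methods vignette
(`vignettes/landmark-dynamic-prediction.Rmd`) for the model, the generator's
stated world, and its limits — including why landmark estimates of
mid-window events (NM above all) are attenuated relative to instantaneous
hazard ratios.

## Worked example

```r
library(dynosurv)

cohort <- simulate_cohort(n = 1000, seed = 2026)      # synthetic trial-like cohort
elig   <- apply_eligibility_filters(cohort)
stack  <- build_landmark_stack(elig$cohort, landmark_grid())
fit    <- fit_supermodel(stack)

tab <- hazard_ratio_table(fit)   # HRs with cluster-robust 95% CIs
print(tab[tab$group %in% c("Histological response", "Local recurrence (LR)",
                           "New metastatic disease (NM)"),
          c("label", "HR", "lower", "upper", "p_value")],
      digits = 3, row.names = FALSE)
#                          label    HR lower upper  p_value
#                     Good (ref) 1.000    NA    NA       NA
#                Poor - constant 3.176 2.411  4.19 2.17e-16
#     Poor - linear time-varying 0.855 0.690  1.06 1.53e-01
#  Poor - quadratic time-varying 1.020 0.974  1.07 4.01e-01
#                       No (ref) 1.000    NA    NA       NA
#                            Yes 2.050 1.241  3.39 5.05e-03   # LR
#                       No (ref) 1.000    NA    NA       NA
#                            Yes 4.701 3.604  6.13 3.58e-30   # NM

eff <- tv_effect_from_fit(fit)
time_varying_hr(eff, 0:5)    # HR(tp) with pointwise CIs
#   tp    hr lower upper
#    0 3.176 2.411 4.186
#    1 2.770 2.117 3.624
#    ...
hr_crossing_time(eff)        # first tp whose CI contains 1 (NA here)

# 5-year death probability at tp = 1 for a poor responder, by disease status
sapply(c("none", "LR", "NM", "LR+NM"), function(s)
  predict_window_death_probability(
    fit, patient_profile(histology = "poor", status = s), tp = 1))
#  none    LR    NM LR+NM
# 0.379 0.624 0.894 0.990

heuristic_shrinkage(fit)                          # 0.9917
dynamic_cindex(elig$cohort, t = 0, w = 5)$cindex  # 0.687
reverse_km_median_followup(elig$cohort)$median    # 4.83 years
```

Read: NM multiplies the death hazard ~4.7-fold in this simulated fit (the
landmark estimand; the instantaneous generative HR is larger), a poor
responder who develops both LR and NM at 1 year has a ~99% chance of dying
within 5 years, the model shows essentially no overfitting (shrinkage ≈ 1),
and discrimination at surgery is C ≈ 0.69.

A command-line interface covers the same pipeline
(`inst/cli/dynosurv simulate | stack | fit | predict | validate | impute |
pool`), e.g.

```sh
Rscript inst/cli/dynosurv simulate --n 500 --seed 7 --out cohort.csv
Rscript inst/cli/dynosurv stack --cohort cohort.csv --out stack.csv
Rscript inst/cli/dynosurv fit --stack stack.csv --out-fit fit.json
```

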