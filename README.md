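# ctmon: longitudinal ctDNA monitoring in advanced pancreatic cancer

Patients with advanced pancreatic ductal adenocarcinoma on palliative
chemotherapy are followed with 8-weekly CT and serum CA19-9, both of which
have known blind spots. Circulating tumour DNA (ctDNA), measured as the
*KRAS*-mutant fraction of plasma cell-free DNA by PNA-clamp qPCR, offers a
monthly blood-based alternative. `ctmon` implements the full analysis chain
for such a monitoring study, for biostatisticians and translational
researchers working with serial biomarker data:

- **qPCR quantification.** Duplicate Cq values with and without the PNA
  clamp are averaged and converted to ΔCq = Cq(+PNA) − Cq(−PNA) and
  ΔΔCq = ΔCq_wt,min − ΔCq, where ΔCq_wt,min is the minimum ΔCq of a
  non-cancer control panel. ΔΔCq > 0 calls ctDNA detected; negative values
  are floored at 0. One ΔΔCq unit is one qPCR cycle ≈ a 2-fold change in
  relative mutant abundance.
- **Exact baseline statistics.** Fisher's exact test (own hypergeometric
  enumeration for 2×2, Freeman–Halton enumeration for r×c) comparing
  baseline characteristics by ctDNA status.
- **Survival analysis.** Kaplan–Meier with log-log CIs, log-rank tests, Cox
  regression (Breslow ties) with likelihood-ratio backward elimination
  (removal threshold p > 0.1), landmarking to avoid immortal-time bias, and
  Schoenfeld-residual proportional-hazards diagnostics, built on the
  `survival` package.
- **Joint model (the core).** A Bayesian joint model of the longitudinal
  ΔΔCq trajectory and time to first progression:
  y_ij ~ N(m_i(t_ij) + δ_cat(ij), σ²), with m_i(t) = x(t)ᵀβ + z(t)ᵀb_i on
  natural cubic spline bases (fixed df 3, random intercept + df-2 time
  effect), infusion-timing offsets δ, and hazard
  h_i(t) = h₀(t) exp(γᵀw_i + α·f_i(t)) with piecewise-constant h₀ and
  f_i(t) the current value, slope, or scaled area of m_i. Estimated by an
  adaptive Metropolis-within-Gibbs sampler written in C++ (RcppArmadillo),
  with Gauss–Legendre quadrature of the cumulative hazard and conjugate
  Gibbs updates for the hazard levels. Subject-specific dynamic predictions
  π(u|t) = 1 − E[S_i(u)/S_i(t)] follow from the posterior.
- **Monitoring classifier.** Serial samples are classified
  increase/persistence/decrease/negative from consecutive ΔΔCq pairs
  (doubling/halving = ±1 cycle rules); patient-level success and the lead
  time of ctDNA-indicated progression over radiological imaging are
  summarised with a continuity-corrected Wilcoxon signed-rank test, plus an
  analogous CA19-9 (>50% over nadir) comparison and marker concordance.
- **Synthetic cohorts.** A seeded generator emulating the study design
  (81 patients, Table-1-like covariate frequencies, monthly bloods,
  8-weekly CT, spline trajectories with random effects, hazard linked to
  the current ctDNA level) so that every stage is testable without patient
  data.

## Worked example

```r
library(ctmon)

cohort <- generate_cohort(sim_config(), seed = 42)   # 81 patients
report <- run_pipeline(cohort, seed = 9)
s <- report_summary(report)

s$baseline$n_detected / s$baseline$n_baseline  # 0.444  baseline ctDNA detection
days_to_months(s$survival$pfs$median_by_status[["1"]]$median_days)  # 3.41 months
days_to_months(s$survival$pfs$median_by_status[["0"]]$median_days)  # 6.52 months
s$joint$hr                                     # 1.25   HR per ddCq unit
s$monitoring$n_eligible                        # 15     monitoring cohort
s$monitoring$median_lead_days                  # 16     ctDNA lead over CT
s$monitoring$union_fraction                    # 0.80   either marker detects
```

On this seed, ctDNA is detected at baseline in 44% of patients; detected
patients progress earlier (median PFS 3.4 vs 6.5 months); the joint model
estimates a hazard ratio of 1.25 per ΔΔCq unit of the current trajectory
value (generating value 1.21); and among the 15 monitoring-eligible
patients the serial classifier flags progression a median of 16 days before
the radiological date, with either ctDNA or CA19-9 flagging 80%.

Dynamic prediction for one patient:

```r
fit <- report$joint
dynamic_predict(fit, "P001", t = 84, horizon = c(84, 112, 140, 196))
#>     u  risk lower upper      (cumulative progression risk from day 84)
#> 1  84 0.000 0.000 0.000
#> 2 112 0.312 0.145 0.552
#> 3 140 0.464 0.215 0.719
#> 4 196 0.674 0.350 0.907
```

A thin command-line front-end over the same functions ships in
`inst/cli/ctmon.R` (subcommands `simulate`, `quantify`, `baseline-stats`,
`monitor`, `report`).

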