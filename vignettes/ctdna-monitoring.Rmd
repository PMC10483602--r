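---
title: "Methods: joint modelling and serial monitoring of plasma ctDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint modelling and serial monitoring of plasma ctDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctmon)
```

# The measurement and its scale

PNA-clamp qPCR suppresses amplification of wild-type *KRAS*, so the cycle
difference ΔCq = Cq(+PNA) − Cq(−PNA) measures the mutant fraction of plasma
cell-free DNA: the smaller the ΔCq, the more mutant template. A panel of
non-cancer controls defines the assay floor; its minimum ΔCq (default
11.27 cycles) is the cutoff, and

ΔΔCq = ΔCq_wt,min − ΔCq_sample

is the working ctDNA level: positive values mean more mutant-specific
signal than any control ever showed, one unit is one qPCR cycle (a 2-fold
change in relative abundance), and values below 0 are floored to 0.
Duplicates are averaged; when only one +PNA replicate amplifies that
replicate is used, and when neither amplifies the sample is not detected.
Replicates disagreeing by more than 2 cycles trigger a warning but are
still averaged — plates do occasionally produce such pairs and silently
dropping them would bias levels downward. Cq values outside (0, 50) are
rejected at parse time as instrument-range violations.

# Exact baseline comparisons

Baseline characteristics are compared between patients with and without
baseline ctDNA by Fisher's exact test: hypergeometric enumeration for 2×2
tables and the Freeman–Halton generalization for r×c tables (depth-first
enumeration over all tables with the observed margins, pruned by remaining
margins). The two-sided p-value is the total probability of tables whose
probability does not exceed the observed one, with a relative tolerance of
1e-7 so that floating-point ties are included. Enumeration is guarded to
table totals of 200; larger tables would need a Monte-Carlo approximation
that this package deliberately does not provide.

Whether "unknown" categories (unstaged tumours, unknown grade) belong in
the test is a genuine design choice: they carry information about
ascertainment but not about the characteristic itself. `build_table()`
keeps them by default — the published group counts only add up when they
are counted — but for grade and T/N stage the published p-values are
reproduced only when the unknown rows are excluded, so the tests of record
for those variables drop them (`include_unknown = FALSE`).

# Survival analysis

Kaplan–Meier curves use Greenwood variance and log(−log) confidence
intervals; the median CI inverts the pointwise band (Brookmeyer–Crowley
style), a choice the analysis plan leaves open and which we fix for
determinism. Cox models use the Breslow tie approximation by default
(Efron behind a flag) to match the convention of the clinical software
this analysis mirrors. Backward elimination removes, at each step, the
candidate with the largest likelihood-ratio p-value above 0.1, testing
categorical variables as whole blocks. Landmarking at a sampling day
excludes patients whose event precedes the landmark and restarts the
clock, avoiding immortal-time bias in the "1-month ctDNA status"
analyses. Proportional hazards are checked with the Grambsch–Therneau
score test on scaled Schoenfeld residuals against event-time rank, plus
log(−log S) curves; with a single event the test is degenerate and is
reported as `NA` rather than an error. Times are days internally; months
are days/30.4375.

# The joint model

Serial ctDNA is an endogenous, measured-with-error covariate: Cox models
with time-varying covariates would carry the measurement error and the
informative observation times straight into the hazard. The joint model
instead couples

- a longitudinal submodel
  y_ij ~ Normal(m_i(t_ij) + δ_cat(ij), σ²), with
  m_i(t) = x(t)ᵀβ + z(t)ᵀb_i, b_i ~ MVN(0, D),
- and a survival submodel
  h_i(t) = h₀(t) exp(γᵀw_i + α·f_i(m_i, t)),

where f is the current value m_i(t) (primary), its slope dm_i/dt, or the
scaled area (1/t)∫₀ᵗ m_i. The slope hazard ratio is reported per 0.01
units, the others per unit. The hazard uses the underlying trajectory
*excluding* the infusion offsets δ: a transient post-infusion rise in
cell-free DNA reflects treatment-induced release, not tumour burden.

**Spline bases.** Fixed effect of time: natural cubic spline with 3
degrees of freedom; random effects: intercept plus a 2-df natural spline
of time. "Three knots" in the source analysis plan is ambiguous between
df = 3 and three interior knots; we read it as df = 3 (two interior knots
plus the natural boundary behaviour), the default convention of the
joint-modelling software that plan names, and both are available through
`jm_spec()`. Interior knots sit at quantiles of the observed measurement
times; boundary knots at 0 and the largest observed time. The basis is
built from the truncated-power natural-spline construction rather than a
packaged basis because the slope and area association forms need analytic
derivatives and antiderivatives, and extrapolation beyond the boundary
must be exactly linear (dynamic prediction integrates the hazard past the
last observation). Time is internally rescaled to the unit interval so
all columns are O(1).

**Baseline hazard.** Piecewise constant on 7 intervals split at event-time
quantiles — the standard default in joint-modelling software; flexible
enough to absorb the shape of the progression hazard while keeping a
conjugate update.

**Priors and estimation.** Normal(0, 10²) on β, δ, γ and α; half-Cauchy(2.5)
on σ and the random-effect sds; uniform (LKJ η = 1) on the random-effect
correlation matrix; Gamma(0.1, 0.1) on the hazard levels. Sampling is
Metropolis-within-Gibbs in C++: componentwise adaptive random-walk updates
(Robbins–Monro step adaptation toward 0.44 acceptance, 0.25 for the
3-dimensional b_i blocks, frozen after burn-in) for all regression and
variance parameters, and conjugate Gibbs draws for the hazard levels. The
cumulative hazard is integrated by 15-node Gauss–Legendre quadrature
*per hazard-interval segment* of each patient's risk interval, so the
integrand seen by each rule is smooth; doubling the nodes changes patient
log-likelihoods by less than 1e-6. Defaults are 3 chains × 6000 iterations
(1000 burn-in, thin 5); convergence is flagged by split-R̂ on α with a 1.1
threshold, reported, and warned about rather than silently accepted.

**Left-censoring.** ΔΔCq values of 0 are "below assay floor", not true
zeros. The primary analysis treats the floored values as Gaussian — the
convention of the source analysis — and a Tobit (left-censored) likelihood
is available via `jm_spec(tobit = TRUE)` for sensitivity analyses.

**Dynamic prediction.** π(u|t) = 1 − E[S_i(u)/S_i(t)] is computed by
drawing the patient's random effects from their conditional posterior
given the history up to t and survival to t (a short Metropolis chain per
retained posterior draw, warm-started across draws) and averaging the
survival ratio; interval bounds are Monte-Carlo percentiles. π(t|t) = 0 by
construction and each draw's curve is non-decreasing. Note the implied
hazard is proper only while the extrapolated trajectory keeps the hazard
bounded away from zero: for a patient whose fitted trajectory declines,
the linearly extrapolated m_i(u) → −∞ makes exp(α m_i(u)) vanish and
π(∞|t) can plateau below 1. That is a faithful property of the model, not
a numerical artifact.

**CA19-9 variant.** The same machinery fits log2 CA19-9 (heavily skewed,
hence the transform) without infusion adjustment.

# Serial monitoring and lead time

Monitoring eligibility: baseline ctDNA detected, at least two samples, and
at least one sample within 31 days of radiologically confirmed
progression. "One month" is fixed at 31 days everywhere, and the
eligibility window is strict (< 31), matching the "less than 1 month"
wording. Post-baseline samples up to 31 days after radiology are
classified against their immediate predecessor on the ΔΔCq scale:
negative (level 0), increase (≥ 1 cycle rise, i.e. at least a doubling, or
any rise from a negative sample), decrease (> 1 cycle fall, or any fall
below ΔΔCq = 1), else persistence. A patient's monitoring succeeds when
any sample is an increase (call day = first such sample) or — under the
primary rule — when every post-baseline sample shows persistence
(persistently high ctDNA). The call day for persistently-high patients is
not defined by the source analysis; we anchor it at the first
post-baseline sample, the earliest day the pattern is observable, and
expose it as a config choice. The stricter `increase_only` rule is also
provided.

CA19-9 progression is called at the first value more than 50% above the
running on-treatment nadir. The 50% rule's comparison baseline is not
stated in the source; the running nadir is the convention in
CA19-9-response criteria and is less noise-sensitive than the immediately
preceding value. CA19-9 succeeds only at or before radiology (no grace
window), per the "at or before" wording.

Lead time = radiology day − call day, summarised by the median over
successes and a two-sided Wilcoxon signed-rank test against zero (zeros
dropped; exact enumeration when n ≤ 25 without ties, otherwise the normal
approximation with 0.5 continuity correction).

# The synthetic cohort generator

`generate_cohort()` emulates the study design: 81 patients with the
published covariate frequencies (sites 63/18, 40% female, ECOG 18/48/15,
treatments 36/38/7, metastases 12/16/53, age ~ N(67, 8²)); bloods at
baseline and 4-weekly (with 1–14-day scheduling jitter so the
infusion-timing factor has within-category variation — without jitter
every draw would land a fixed lag after an infusion and the δ offsets
would be confounded with time); CT at baseline and 8-weekly; latent
trajectories on the same spline family as the model, with a
decline-then-regrowth mean shape (anchor values in ΔΔCq cycles, free
parameters of the generator, not claims about any cohort); random effects
with sds (2.5, 1.2, 1.2) and an intercept–slope correlation of −0.3;
residual sd 0.8 cycles; post-infusion offsets (0.8, 0.3, 0) cycles for
1–2 / 3–7 / > 7 days since infusion; association α = log(1.21) per unit;
covariate log-hazards set to the published joint-model hazard ratios;
constant baseline hazard 0.001/day; progression drawn by inversion on a
0.25-day grid; radiological detection at the first scheduled CT on or
after latent progression (this scan lag is precisely what creates ctDNA
lead time); death after an Exp(mean 60 days) gap; administrative
censoring at day 730. The fixed-effect intercept is solved from the
configured 56% baseline detection probability given the noise scales.
Observed levels are floored at 0 after noise and re-encoded as duplicate
Cq values (no +PNA amplification once the implied Cq exceeds the
instrument range), so the qPCR module round-trips the generated levels.

What the generator does *not* emulate: second-line treatment effects,
unscheduled CT scans triggered by clinical suspicion, assay batch effects,
missing visits, competing causes of death, or CHIP artifacts. Passing
tests therefore demonstrate correctness of the statistical machinery under
the assumed data-generating process, not clinical performance on real
cohorts.

**Parameter-recovery conditions.** The recovery and coverage experiments
for the joint model generate emissions *without* the zero floor
(`floor_emissions = FALSE`): they validate the estimator under the model
it assumes. With the default 56% baseline detection, flooring censors
almost half of all baseline values, which makes the Gaussian joint model
deliberately misspecified — that misspecification is a property of the
primary analysis convention, and conflating it with sampler validation
would make the recovery experiment uninterpretable. All other stages
(pipeline, monitoring, baseline statistics) use the floored default.

# Problem sizes and numerical conventions

The test-suite and acceptance experiments use sizes chosen to give stable
Monte-Carlo verdicts at interactive run times: recovery at n = 300
patients × 10 replicates with single chains of 1800 iterations (600
burn-in), factorization and prediction checks at n = 80–100, Cox
parameter recovery at n = 800 × 20 replicates on the latent (exactly
proportional-hazards) progression times, and Schoenfeld size checks at 60
small replicates. Full-length MCMC defaults (3 × 6000) are recommended for
actual analyses. Degenerate inputs are handled explicitly: empty control
panels, constant covariates, collinear designs, monotone partial
likelihoods, single-event PH tests, patients without observations before a
prediction time, and zero-margin contingency tables all raise informative
errors or defined fallbacks (p = 1, `NA`) as documented.

# Known limitations

- The Gaussian treatment of floored ΔΔCq biases trajectory estimates for
  low-shedding patients; the Tobit flag exists but is not the default.
- The piecewise-constant hazard limits extrapolation of dynamic
  predictions far beyond the last event time (the last level is carried
  forward).
- The Freeman–Halton enumeration is exact but exponential in table size;
  it is guarded rather than approximated.
- Lead-time magnitudes in synthetic cohorts depend strongly on the
  regrowth shape and the CT interval; they validate the machinery, not
  the clinical lead time.
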