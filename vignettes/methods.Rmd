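---
title: "Models and methods behind mndaccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mndaccel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mndaccel` evaluates wrist-worn accelerometer outcomes as longitudinal
endpoints in motor neuron disease (MND). It covers four connected pieces of
methodology — raw-signal feature extraction, joint longitudinal–survival
modelling, simulation-based trial sizing, and descriptive association
analyses — plus a synthetic-data generator that reproduces the statistical
structure those analyses assume, so every stage can be exercised and tested
without patient data.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the design decisions that were genuinely open.
No empirical numbers are claimed here beyond what the package's own tests
and `scripts/acceptance.R` compute.

# The synthetic cohort generator

`simulate_cohort()` is the generative mirror of the analysis models, not a
model of real wear data. Per participant and outcome, observations follow

y_ij = (mu + b0_i) + (beta + b1_i) t_ij + e_ij,

with (b0_i, b1_i) bivariate normal and e_ij Gaussian. Death times come from
a Weibull baseline hazard multiplied by `exp(gamma_age agec_i + gamma_sex
fem_i + alpha m_i(t))`, where m_i(t) is the participant's current *latent*
(unclipped) value of the association outcome — the same current-value
linkage the fitted joint model assumes. Event times are drawn by
inverse-transform sampling of the cumulative hazard on a 0.1-month grid with
linear interpolation inside a grid cell.

Defaults are the study conditions the package is tested under:

* 95 participants, visits every 3.4 months (SD 0.8, gaps floored at 1
  month), first visit at 0, administrative censoring at 36 months;
* age 60 ± 9.3 years, 23% female;
* outcome means/SDs and per-month slopes from published MND cohort values
  (ALSFRS-R total 37.4 ± 5.5 declining 0.62 points/month, motor domain
  16.4 ± 4.6 declining 0.38, and accelerometer features whose pooled SDs
  are consistent with their standardised slopes — e.g. peak 6-min activity
  at −0.07 SD/month vs −0.03 for mean ENMO);
* association `alpha = log(0.959)` per ALSFRS-R point; Weibull shape 1.3
  (a mildly increasing hazard, typical of MND cohorts) and scale 16.3
  months, the one calibrated quantity: it is set so the default cohort's
  event fraction is ~64%, matching the cohort the defaults describe. The
  calibration was done once, at n = 4000, and not revisited.

Slope heterogeneity (`slope_sd`, e.g. 0.45 points/month for ALSFRS-R total)
and residual SDs are not printed in the sources the means come from; they
were chosen once as values a clinician would call realistic for an MND
cohort (pre-study progression rates with an IQR of about one point/month
imply substantial slope variance) and are deliberately generous, which makes
the trial-size machinery conservative rather than optimistic.

ALSFRS-R-type outcomes are simulated as continuous values, then rounded and
clipped to their range; accelerometer features are clipped at zero. The
hazard uses the latent linear predictor, not the clipped observation — the
clipping is measurement, the hazard is physiology. Random effects are
independent across outcomes; tests that need cross-outcome dependence inject
it explicitly (shared visit-level shocks), which keeps each mechanism
visible.

A caution that matters when validating the generator: conditional on dying,
fast decliners do *not* necessarily die earlier than slow decliners — their
hazard grows over time, so their deaths concentrate late, a classic
selection artefact. The generator's association property is therefore
tested on the unconditional follow-up distribution (rank correlation of
slope with observed time, and death rates by slope tertile).

`simulate_raw_recording()` produces gravity plus a bout-gated sinusoidal
arm-swing component along the gravity axis (so the swing modulates the
vector norm) plus white noise. Bouts arrive as a Poisson process; one dial,
`activity_level`, scales both bout rate and swing amplitude, emulating
functional level. Defaults: 30 Hz, 8 days, 2 Hz swing, 0.8 g peak amplitude
at level 1, 10 bouts/hour at level 1, 10 mg sensor noise. What it does *not*
emulate — circadian structure, sleep, non-wear, posture changes, device
artefacts — bounds what passing tests show about real recordings: they
validate the arithmetic of the feature extractors and the statistical
machinery downstream, not robustness to messy wear patterns.

# Feature extraction

**ENMO** (`compute_enmo`): per sample `max(0, ||a|| − 1)` in g, averaged in
5-s epochs, reported in milli-g. The truncation-then-average order matters
and is tested against direct per-epoch recomputation. ENMO is rotation
invariant by construction.

**Activity counts** (`compute_activity_counts`): an open implementation of
the documented device pipeline — per axis, band-pass 0.29–1.63 Hz at 30 Hz,
decimate to 10 Hz, clip at 2.13 g, rectify, 0.068 g dead band, 8-bit
quantisation (1 LSB = 2.13/128 g), accumulate per 10-s epoch, then the
vector magnitude across axes rounded to an integer. The band-pass stage is a
3rd-order Butterworth designed to the published passband; the proprietary
coefficient set is not reproduced, so absolute count magnitudes are not
interchangeable with device exports, but the properties the analyses rely on
(zero under static gravity, monotone in movement amplitude, axis-permutation
invariant) are exact and tested. The signal mean is removed before
filtering so the filter's zero initial state cannot turn a constant gravity
component into a startup transient. The device's "low frequency extension"
variant is not supported.

**MVPA** (`mvpa_from_enmo`): minutes per day in 5-s epochs with ENMO
strictly above 100 mg.

**Peak 5-h ENMO / M5** (`rolling_peak_enmo`) and **peak 6-min activity**
(`peak_window_percentile`): sliding windows step one epoch and never cross
day boundaries; M5 is the maximum 5-h window mean; peak activity is the
95th percentile of 6-min window values. The window aggregate is the *mean*
(units stay counts/epoch); a sum option exists. Percentiles interpolate
linearly between order statistics (R type 7) — stated because percentile
conventions differ. Both operators are tested against exhaustive window
enumeration.

**Steps** (`estimate_steps`): peak detection on the vector magnitude at
15 Hz with four published-style rule families — magnitude (> 1.2 g),
periodicity (inter-peak gap 0.33–1 s), similarity of alternating peak
heights (≤ 0.5 g), and continuity (runs of ≥ 4 valid peaks). The continuity
rule is what rejects aperiodic noise peaks; a 2 Hz synthetic gait bout of
60 s yields ~120 steps.

**Weekly protocol** (`summarize_recording`): recordings start around midday
and span 8 days; trimming 12 h from each end leaves exactly 7 × 24 h. Days
are consecutive 24-h blocks aligned to the trimmed start. (Aligning to
calendar midnight instead would leave only six complete days given the
midday start — that is why the recording-aligned convention was chosen; it
always yields exactly seven full days, each covering a full circadian
cycle.) Weekly features are unweighted means of the seven daily values.
Non-wear detection is not implemented; real-data users must handle non-wear
upstream.

**Epoch variants** (`select_epoch_variant`): where a feature family exists
at several epoch lengths, the variant with the most negative standardised
slope is kept; ties break to the shortest epoch, deterministically.

# Longitudinal and joint models

`fit_lmm()` fits `value ~ time + (time | participant)` via lme4 (REML by
default), with Wald 95% CIs. Slopes are reported in base units and, after
`standardize_outcome()` (pooled over all observations, sample SD with n−1),
in SD/month; the pooled rather than baseline SD is used because whole
trajectories are standardised, and baseline-only SDs can be supplied where
wanted.

`fit_joint_model()` couples that longitudinal sub-model with a Weibull
proportional-hazards sub-model through the current value of the
subject-specific linear predictor:

h_i(t) = (k/λ)(t/λ)^{k−1} exp(γ_a agec_i + γ_s fem_i + α m_i(t)).

Age is centred at the cohort mean (numerics only; HRs unaffected); sex is
coded female = 1. Administrative censoring at 36 months is applied before
fitting. Two estimation routes:

* **Two-stage** (default): empirical-Bayes trajectories from the REML mixed
  model are plugged into the survival likelihood, whose five parameters are
  maximised by BFGS with the cumulative hazard integrated by 15-node
  Gauss–Legendre quadrature per subject. Fast and stable; the SE of α
  ignores plug-in uncertainty and is approximate — adequate at null and
  moderate associations, optimistic for strong ones.
* **Full likelihood**: the joint marginal likelihood integrates the two
  random effects by 9-point-per-dimension Gauss–Hermite quadrature centred
  on the empirical-Bayes modes and scaled by the EB posterior covariance
  (one fixed adaptation), with log-sum-exp accumulation; optimisation by
  `nlminb` over an 11-parameter vector with a log-Cholesky parameterisation
  of the random-effect covariance; SEs from the numerical Hessian. With α
  fixed at 0 this reproduces, to well under 0.1 log-likelihood units, the
  sum of the independent lme4 fit and a Weibull PH regression — that
  decoupling is the implementation's main correctness oracle, checked in
  the tests against flexsurv.

`hazard_ratios()` reports exp(α) per base unit, per 100 units, and per
pooled SD, with identically transformed Wald CIs; the scaling identities
are exact by construction.

`residual_matrix()` summarises, per participant and outcome, the
observation-level residuals after removing fixed *and* random time trends
(default: their mean), or alternatively the random-slope deviations. The
observation-level default was chosen because it is the only reading under
which residuals are defined for every participant with any data; both
notions are offered because the distinction is genuinely ambiguous in
descriptions of such analyses.

# Trial power and sample size

`events_for_power()` / `power_given_events()` implement the Schoenfeld
events formula for a continuous covariate,
d = (z_{1−α/2} + z_pow)² / (σ ln HR)², and its inversion. The worked design
assumption — HR 0.88 per ALSFRS-R point, baseline SD 5 — gives 28 events for
92% power and 20 for 80%. `simulate_survival_power()` checks the formula by
simulation: exponential survival, Normal covariate, follow-up stopped at the
target event count, Cox score test (the continuous-covariate log-rank). Its
default cohort size of 95 mirrors the motivating cohort, where 30 events is
roughly a one-third event fraction; the formula is a local (small-effect)
approximation, and with nearly-saturated event fractions the simulated power
genuinely falls a few points below it — a property of the formula, not a
bug.

`bootstrap_trial_power()` estimates the power of a two-arm,
`duration`-month trial with ~3-monthly assessments by resampling
participants with replacement, truncating their observed visit histories at
the trial duration (so attrition is mirrored, with no imputation), applying
the treatment as a `fraction` reduction of the decline — by default
subtracting `fraction × (population slope) × t` from treated values, which
keeps within-subject noise real and works on observed data; regeneration
from latent per-subject slopes is available for simulated cohorts — and
fitting `value ~ time * arm + (time | id)`, testing the interaction
two-sided. The design schedule is realised through the cohort's own
~3-monthly visits rather than an idealised exact grid. The default test is
a Satterthwaite-df t test (lmerTest); `find_sample_size()` defaults to the
large-sample Wald z instead because its search fits thousands of models and
the candidate arm sizes of interest give hundreds of denominator degrees of
freedom, where the two are indistinguishable; the type-I calibration test
runs against this machinery at its defaults. A likelihood-ratio option
exists. Replicate fit failures are counted, never silently dropped; more
than 5% triggers a warning.

`find_sample_size()` exploits monotonicity of power in N: bisection over a
coarse grid (20–400 by 20), then refinement to a step of 2. Each candidate N
uses a seed derived from the master seed and N, so the curve is reproducible
and independent of evaluation order. Bootstrap replicates default to 1000
per N (binomial SE ≈ 1.3% at power 0.8); the package's own end-to-end tests
use 200–500 replicates and cohorts of 95–200 participants to keep the suite
fast, which is also the problem size the acceptance script uses.

# Association analyses

`score_alsfrs()` and `delta_frs()` are the scale arithmetic (domains:
bulbar 1–3, upper-limb 4–5, lower-limb 8–9, motor 4–9, respiratory 10–12;
ΔFRS = (total − 48)/months since onset).

`correlation_analysis()` offers the two procedures that are both defensible
for repeated measures: one randomly selected collection per participant
(seeded), or Pearson correlations between columns of the residual matrix
(time partialled out). The two answer different questions — the single-visit
mode deliberately retains cross-sectional level differences, and on
declining outcomes it will show correlation induced purely by the shared
sampling time, which is exactly the confounding the residual mode removes;
the null-calibration test therefore uses flat trajectories. Holm correction
(via `stats::p.adjust`) treats all tested pairs as one family; zero-variance
outcomes are excluded from the family with a warning. The longitudinal
residuals of a two-stage joint fit are its mixed-model residuals, so the
residual mode fits plain mixed models.

`pca_residuals()` works on the correlation matrix (outcomes have
incommensurate units): columns centred and scaled, `prcomp`, contributions
100·loading²/Σloading² per component. Missing cells: complete-case by
default, mean imputation as an option. `km_logrank()` wraps survival's
product-limit estimator (Greenwood SEs, log-scale CIs), the two-group
log-rank test, and a univariate Cox HR; grouping helpers implement the
median split (ties at the median go low) and the ΔFRS −0.5/month threshold
(values exactly at the threshold count as faster-progressing). Medians
unattained because a subgroup had too few deaths are reported as missing,
not invented.

# Degenerate inputs and numerical choices

* Perfectly linear (noise-free) data: lme4 fits are singular but exact;
  tolerated and flagged, not errors.
* All-censored survival data, single-visit-only cohorts, zero-variance
  outcomes, hazard ratio 1, zero events: explicit errors.
* Quadrature orders (15 Gauss–Legendre, 9² Gauss–Hermite) were chosen so
  that halving or doubling them moves the decoupling oracle by less than
  the test tolerance; log-sum-exp is used everywhere densities are
  combined.
* Seeds: every stochastic routine takes one; child seeds are derived with a
  fixed integer recurrence kept below 2³¹.

# Known limitations

* The counts and step algorithms reproduce the published pipeline
  *structure* with documented parameters, not proprietary coefficient sets;
  compare trends, not absolute magnitudes, against device software.
* The two-stage joint SEs understate uncertainty for strong associations.
* The generator's slope heterogeneity and residual SDs are plausible
  choices, not fitted values; absolute sample-size outputs on synthetic
  cohorts characterise the machinery, and real cohorts should be run
  through the same functions for design decisions.
* No non-wear handling, no multivariate joint models, no competing risks.
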