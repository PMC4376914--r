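---
title: "Models and methods in riskimagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in riskimagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`riskimagery` implements the statistical pipeline for a three-part research
design linking affect-laden mental imagery to risk taking: trial-level
rating studies analysed with serial mixed-model mediation, a cuff
blood-pressure protocol for psychophysiological stress reactivity, and an
EEG protocol quantifying imagery intensity through alpha-band attenuation,
finished by Johnson–Neyman moderation probing. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

```{r setup, message = FALSE}
library(riskimagery)
```

## Serial two-mediator mediation with crossed random intercepts

Trial-level ratings are non-independent: each subject rates many scenarios
and each scenario is rated by many subjects. All regressions therefore carry
additive random intercepts for subjects and items (scenarios or risk
domains). The serial chain X → M₁ → M₂ → Y is estimated with three models:

1. `m1 ~ x` — path *a₁*;
2. `m2 ~ x + m1` — paths *a₂* and *d₂₁*;
3. `y ~ x + m1 + m2 (+ covariates)` — paths *c′*, *b₁*, *b₂*.

Subject-level covariates (trait anxiety, risk propensity) enter only the
outcome model: they are constant within subject, so in the mediator models
their influence is absorbed by the subject intercepts, while for the outcome
we want path coefficients adjusted for stable individual differences.
Coefficients are unstandardized.

**REML versus ML.** Reported coefficients and SEs come from REML fits, the
standard low-bias choice for variance components. The likelihood-ratio test
comparing `y ~ x (+ covariates)` against `y ~ x + m1 + m2 (+ covariates)`
refits both models by maximum likelihood, because REML likelihoods are not
comparable across fixed-effect structures. The statistic is
χ² = 2(ℓ_full − ℓ_base) on 2 df; a negative value beyond numerical
tolerance raises an error rather than being reported silently.

**Monte-Carlo CI for the indirect effect.** The sampling distribution of
*a₁d₂₁b₂* is approximated by k independent draws of each coefficient from
N(estimate, SE²); the 95% interval is the 2.5th/97.5th percentile of the k
products (type-7 quantiles, i.e. linear interpolation between order
statistics). Draws are independent across the three paths; a joint-normal
variant would need cross-model covariances, which the three separate fits do
not supply — within each model the relevant coefficients (e.g. *d₂₁* and
*b₂*) come from different fits, so the independence assumption is the
natural default. The seed is mandatory and recorded in the result, making
the interval bit-reproducible. Defaults: k = 100 000; k < 1000 is refused.

**Degenerate fits.** With exactly noiseless data the residual variance
collapses and the mixed-model covariance factorization fails; `fit_lmm()`
then falls back to the OLS covariance σ̂²(XᵀX)⁻¹, which correctly tends to
zero with the noise, so point estimates remain exact and SEs go to 0. If a
crossed fit fails outright (e.g. too few items), the model falls back to a
subject-only random intercept with a message.

## Blood-pressure reduction

Cuff readings are converted to Mean Arterial Pressure,
MAP = ⅔·diastolic + ⅓·systolic (mmHg), which weights the two pressures by
the approximate fraction of the cardiac cycle spent in each phase. The
canonical session is 20 readings: 8 pre-baseline, 1 training, 5 scenario
(one per risk domain), 6 post-baseline. The reduction drops the first three
pre-baseline readings (novel-laboratory stress), the training reading, and
the first post-baseline reading (post-stress recovery), then z-scores the
remaining 15 within subject. Averaging the five retained readings of each
baseline and keeping the five visualization z-scores yields three phase
summaries per subject.

Numerical choices: z-scores use the sample SD (n−1 denominator), the
psychophysiology convention; a zero-variance retained set raises a
degenerate-variance error; duplicated scenario domains within a subject are
a layout error (each of the five domains must appear exactly once). Note
that the three phase summaries sum to zero by construction, so their
contrast covariance is singular; sphericity corrections are then undefined
and the phase ANOVA reports ε = 1 with the uncorrected p. Pairwise phase
follow-ups are uncorrected paired t-tests.

## EEG alpha power and the Imagery Alpha Index

The preprocessing chain per channel: zero-phase band-pass 0.1–35 Hz,
2-second epoching per event segment (partial trailing windows discarded),
artifact rejection, periodogram alpha power, IAI.

**Filter design.** The default is a Butterworth cascade — order-2 high-pass
at 0.1 Hz followed by order-4 low-pass at 35 Hz, each applied
forward-backward (`signal::filtfilt`) for zero phase. A windowed-sinc FIR
band-pass is available via `design = "fir"`, but a 0.1 Hz transition edge at
200 Hz sampling demands kernels thousands of taps long, so the IIR cascade
is the practical default; the tests verify its measured response against the
analytic digital transfer function (about 98% amplitude rejection at 50 Hz
after the forward-backward pass, <1% ripple at 10 Hz).

**Artifact criterion.** An epoch is rejected when |amplitude| exceeds 70 µV
anywhere in the epoch; a peak-to-peak criterion is available via
`criterion = "peak_to_peak"`. The rejection fraction is reported; a segment
whose epochs are all rejected raises an error carrying the counts.

**Alpha power.** Each 2-s epoch (400 samples at 200 Hz) is transformed with
a rectangular-window FFT, giving 0.5 Hz bins; the one-sided power spectral
density is scaled so that the density integrated over frequency equals the
mean squared amplitude (Parseval). Alpha power is the mean density over the
bins in [8, 13] Hz inclusive (11 bins), averaged over kept epochs. No taper
is applied: the synthetic signals and the index consumed downstream are
narrowband, and the ratio statistic cancels leakage effects common to
numerator and denominator.

**IAI.** IAI = mean(baseline₁, baseline₂ power) / mean(domain scenario
power), per subject × electrode × domain × phase. The two baselines are
weighted equally regardless of epoch counts. Both baseline segments
contribute their full duration (a configurable choice; the alternative of
restricting baselines to listening-phase epochs is not the default because
the baseline scenario has no task/listening split in the session layout).
IAI is scale-invariant — multiplying the whole recording by a constant
cancels — and monotone decreasing in task power. The moderation analysis
averages the visualization-phase IAI over O1, O2, P3, P4, the
parieto-occipital sites where imagery-related alpha attenuation is expected;
frontal channels act as control sites.

## Repeated-measures ANOVA, reliability, and change scores

`rm_anova()` handles fully within-subject designs via the multivariate
linear-model route (`car::Anova` with an `idesign`), reporting per effect
the F statistic, uncorrected dfs, Greenhouse–Geisser
ε = (tr Σ)²/((k−1)·tr Σ²) computed from the double-centered covariance of
the contrast variables, the ε-corrected p, and partial
η² = SS_effect/(SS_effect + SS_error). One-df effects satisfy sphericity
trivially (ε = 1). A two-level factor reproduces the paired t-test exactly
(F = t²), which the tests exploit as an oracle.

The valence analysis compares per-scenario mean thought valence against a
neutral point of 0. Modelling neutrality as an explicit constant reference
level of the within-subject factor gives an 11-level factor for 10
scenarios, hence F(10, 10(n−1)) — with 60 subjects, F(10, 590). This
reconstruction is the only design consistent with both the df convention
and a "difference from neutral" reading, and it is the package's default
(`valence_anova()`). Per-scenario follow-ups are one-sample t-tests on
subject means, Holm-adjusted across scenarios; zero-variance scenarios are
flagged as degenerate rather than producing NaN.

Reliability uses ICC(3,k) — two-way mixed, consistency, average measures:
(MS_rows − MS_error)/MS_rows. The consistency variant is the right match for
ratings whose anchoring may differ between subjects while their scenario
profile is what matters; absolute-agreement variants ICC(2,k) and ICC(2,1)
are available via `type`. Note the estimator is negatively biased under the
null at small n (E[1 − MS_E/MS_R] < 0), which the tests account for.

PANAS change analysis reports ΔPA and ΔNA with 95% t-intervals plus the
scale-by-time interaction, computed as a one-sample F on the contrast
(ΔNA − ΔPA), equivalent to the 2×2 within-subject interaction; F(1, n−1).

## Moderation and Johnson–Neyman regions

`fit_interaction()` fits `y ~ x + w` and `y ~ x + w + x:w` with crossed
random intercepts; the interaction is tested by a 1-df ML likelihood-ratio
test while coefficients come from the REML step-2 fit. Predictors are not
mean-centered: with a moderator like the IAI (values near 1), raw-scale
coefficients keep the large negative moderator main effect interpretable and
match how such models are conventionally tabled.

The conditional effect is θ(w) = b₁ + b₃w with
SE(θ(w)) = √(v₁₁ + 2w·v₁₃ + w²·v₃₃). Simple slopes are probed at the
moderator mean and ±1 SD, with the SD computed across analysis rows
(subject × domain), matching the row-level modelling unit. Johnson–Neyman
boundaries solve |θ(w)|/SE(w) = t* exactly via the quadratic
(b₃² − t*²v₃₃)w² + 2(b₁b₃ − t*²v₁₃)w + (b₁² − t*²v₁₁) = 0; only real roots
inside the observed moderator range are reported, and complex roots yield an
empty boundary list with a uniform significance status. The critical value
uses Student t with df = n_obs − p (number of fixed effects) by default —
mixed models have no exact residual df, and this choice is conservative
relative to the normal approximation, which remains available via
`df_method = "normal"`. A dense grid of θ(w) with pointwise bands is
returned for plotting (`autoplot()`), and the tests verify the analytic
roots against a 10⁻⁴-step grid scan.

## What the synthetic generators emulate

Each study design has its own generator with the study's published scale as
the default: `gen_study1()` (60 subjects × 10 scenarios, two per domain),
`gen_study2()` (22 subjects, canonical 20-reading cuff layout, PANAS
pre/post, five-domain rating chain), and `gen_study3()` (16 analyzable
subjects, six-channel 200 Hz recordings, 30 s risky-scenario phases with
baselines four times as long).

Key generator defaults and their rationale:

- Study-1 paths (a₁, a₂, d₂₁, b₁, b₂, c′) = (1.0, 0.3, 0.5, 0.05, −0.6,
  −0.15) and Study-2 paths (0.64, 0.3, 0.52, 0.05, −0.64, 0.10): the
  published point estimates where available, with moderate noise SDs
  (subject 0.5, item 0.3, residual 1.0 rating points) typical of 10-point
  single-item scales. Valence is truncated normal on [−2, 2] with mean 0.83
  and SD 0.98 (the published recoded-valence moments).
- Ratings are generated on a continuous latent scale; `discretize = TRUE`
  rounds and clips to the printed 1–10/1–5 scales. Discretization is off by
  default because parameter-recovery checks need the uncoarsened model.
- Blood pressure: between-subject resting MAP N(93, 8) mmHg, reading noise
  3 mmHg (the monitor's stated error), pulse pressure N(40, 5) mmHg, and a
  visualization elevation of δ = 4.5 mmHg scaled by relative vividness —
  calibrated once so the reduced visualization z-score averages ≈ +0.8, the
  published phase elevation. Systolic/diastolic pairs are reconstructed as
  SY = MAP + ⅔PP, DY = MAP − ⅓PP, an exact algebraic inverse of the MAP
  formula.
- PANAS shifts default to −2.5 (PA) and +2.67 (NA) with 4-point change
  noise; the PA change is coupled to the subject's realized visualization
  blood-pressure z (7 PANAS points per z unit), reproducing the published
  negative PA-change/blood-pressure correlation of about −0.35.
- EEG: 10 Hz alpha carrier of 10 µV on all channels plus white noise
  (SD 1 µV); during risky-scenario visualization the parieto-occipital
  amplitude is divided by √g, where g is the subject's imagery-ability
  factor (truncated normal, mean 1.06, SD 0.06, range [0.95, 1.25],
  spanning the published IAI range of roughly 0.97–1.19). Since power scales
  with amplitude squared, the noiseless IAI equals g exactly — the ground
  truth for recovery tests. Frontal channels are unmodulated (IAI ≈ 1).
  Artifacts are 150 µV square pulses injected on the 2-s epoch grid at rate
  0.05, the published rejection fraction. Noise is white rather than 1/f:
  the only statistic consumed downstream is a narrowband power ratio, which
  is insensitive to the broadband noise colour at these SNRs.
- Moderation truth: (b₀, b₁, b₂, b₃) = (31.5, −3.5, −25, 3.0), giving
  conditional slopes near −0.5/−0.35/−0.2 across the observed g range and a
  Johnson–Neyman boundary inside it.

Everything is driven by a single integer seed through a temporary RNG state,
so identical (configuration, seed) pairs give byte-identical outputs and
generation never disturbs the caller's random stream.

**What the generators do not emulate.** Real EEG morphology (eye blinks,
1/f background, spindles, line noise), non-normal rating distributions,
missing-data patterns, serial dependence between consecutive cuff readings,
and any relation between the questionnaire covariates and the EEG signal.
Passing recovery tests on these generators therefore demonstrates that the
estimators are correct under the stated models, not that the models are
adequate for any particular real dataset.

## Problem sizes used by the test suite

The statistical acceptance checks run at the study scale: 200 simulated
datasets (60 × 10) for path-recovery bias, 500 replicates for the
Monte-Carlo CI coverage (93–97% band) with k = 10 000 draws per interval,
500 replicates each for the type-I error of the mediation LRT and the
interaction LRT (3–7% band at α = .05), and 100 random coefficient/vcov
draws for the Johnson–Neyman grid-scan agreement. These sizes keep the
Monte-Carlo error of each rate small relative to its acceptance band while
completing in a few minutes on a single CPU.

## Known limitations

- The likelihood-ratio χ² reference for mixed models is asymptotic;
  at very small subject counts the test can be mildly conservative.
- `rm_anova()` requires complete balanced within-subject data; no
  mixed between/within designs and no multivariate tests are exposed.
- The Monte-Carlo CI treats the three path estimates as independent
  normals; finite-sample skew of the product distribution is captured, but
  cross-model estimation covariance is ignored (it is unavailable from
  separate fits by construction).
- Epoching is non-overlapping and rectangular-windowed; Welch-style
  overlap or tapers would trade bias for variance differently but would not
  change the baseline/task ratio materially for narrowband signals.
- No EDF/BDF/BrainVision parsing: EEG enters as a delimited matrix with a
  JSON event sidecar. No beat-to-beat blood-pressure processing.
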