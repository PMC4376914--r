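# riskimagery

Analysis toolkit for studying how **affect-laden mental imagery** shapes risk
perception and risk taking. When people face a risky prospect ("should I
postpone this medical exam?"), they spontaneously imagine its consequences;
the emotional stress those images evoke feeds into how risky the situation
feels and, ultimately, into whether they act. `riskimagery` implements the
statistical machinery for testing that chain on trial-level rating data,
cuff blood-pressure series, and multichannel EEG — together with
deterministic synthetic-data generators so that every stage is testable with
known ground truth.

The package is written for behavioural and psychophysiology researchers:
tibbles in, tibbles out, `tidy()`/`glance()` accessors on fitted objects,
and `autoplot()` methods for the main result types.

## What it computes

**Serial two-mediator mixed-model mediation.** For trial-level data
(subjects crossed with scenarios/risk domains), the chain
X → M₁ → M₂ → Y is estimated by three linear mixed models with crossed
random intercepts for subjects and items:

- M₁ ~ X  →  *a₁*
- M₂ ~ X + M₁  →  *a₂*, *d₂₁*
- Y ~ X + M₁ + M₂ (+ covariates)  →  *c′*, *b₁*, *b₂*

The three-path indirect effect *a₁d₂₁b₂* gets a Monte-Carlo percentile CI:
each coefficient is drawn independently from N(estimate, SE²), and the 2.5th
and 97.5th percentiles of the k products delimit the interval. A 2-df
likelihood-ratio test (ML refits) compares the mediated outcome model with
the X-only baseline.

**Blood-pressure stress reactivity.** Raw cuff readings are converted to
Mean Arterial Pressure (MAP = ⅔·DBP + ⅓·SBP); the canonical 20-reading
session (8 pre-baseline, 1 training, 5 scenario, 6 post-baseline) is reduced
by dropping the first three pre-baseline readings, the training reading and
the first post-baseline reading; the 15 remaining MAPs are z-scored within
subject; baseline phases are averaged and the five visualization z-scores
serve as the stress indicator. A repeated-measures ANOVA contrasts the three
phases.

**EEG Imagery Alpha Index (IAI).** Signals (200 Hz; Fp1, Fp2, P3, P4, O1,
O2) are band-passed 0.1–35 Hz (zero-phase), cut into 2-s epochs, epochs
exceeding 70 µV rejected, and alpha-band (8–13 Hz) power density computed by
periodogram. The IAI is baseline alpha power divided by task alpha power,
per electrode × risk domain × phase; values above 1 mean task-related alpha
attenuation, i.e. stronger imagery-related activation. The moderation
analysis uses the IAI averaged over the parieto-occipital sites (O1, O2,
P3, P4).

**Johnson–Neyman moderation probing.** A crossed random-intercept model
Y ~ X + W + X·W yields the conditional effect θ(w) = b₁ + b₃w with
SE(θ) = √(v₁₁ + 2w·v₁₃ + w²·v₃₃). Simple slopes are probed at the moderator
mean ±1 SD, and the Johnson–Neyman boundaries — the moderator values where
the pointwise CI for θ touches zero — are obtained analytically from the
quadratic (b₃² − t²v₃₃)w² + 2(b₁b₃ − t²v₁₃)w + (b₁² − t²v₁₁) = 0.

**Classical within-subject statistics.** Repeated-measures ANOVA with
Greenhouse–Geisser ε, Holm step-down post-hocs against a neutral reference,
ICC(3,k) rating reliability, PANAS pre/post change analysis, and
subject-level Pearson correlations.

## Worked example

```r
library(riskimagery)

trials <- gen_study1(seed = 11)   # 60 subjects x 10 scenarios, known truth
med <- serial_mediation(trials, x = "x", m1 = "stress",
                        m2 = "risk_perception", y = "risk_taking",
                        covariates_on_y = c("stai", "siri"),
                        k = 100000, seed = 12)
med
#> Serial mediation: x -> stress -> risk_perception -> risk_taking
#> # A tibble: 6 x 3
#>   path    estimate     se
#>   <chr>      <dbl>  <dbl>
#> 1 a1        0.968  0.0518
#> 2 a2        0.273  0.0639
#> 3 d21       0.538  0.0403
#> 4 c_prime  -0.0949 0.0648
#> 5 b1        0.0483 0.0457
#> 6 b2       -0.657  0.0406
#> indirect a1*d21*b2 = -0.3419, 95% MC CI [-0.4197, -0.2711] (k = 100000)
#> LRT vs baseline: chi^2(2) = 257.315, p = 1.333e-56
```

The generator's true paths are a₁ = 1.0, d₂₁ = 0.5, b₂ = −0.6,
c′ = −0.15: more negative imagery raises stress (*a₁* ≈ 0.97), stress raises
perceived risk (*d₂₁* ≈ 0.54), and higher perceived risk lowers the
willingness to take the risk (*b₂* ≈ −0.66). The Monte-Carlo CI for the
serial indirect effect excludes zero, and the likelihood-ratio test shows
that adding the two mediators improves the outcome model.

End-to-end study pipelines are one call each:

```r
s2 <- gen_study2(seed = 1)
run_study2(s2$trials, s2$bp, s2$panas, seed = 2)   # PANAS, MAP reduction, mediation

s3 <- gen_study3(seed = 3)
res <- run_study3(s3$recordings, s3$trials, seed = 4)  # EEG -> IAI -> J-N
autoplot(res$jn)                                    # conditional-effect plot
```

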