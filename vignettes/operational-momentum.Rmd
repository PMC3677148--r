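---
title: "Operational momentum in non-symbolic arithmetic: design, simulation and Bayesian analysis"
author: "opmom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Operational momentum: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmom)
```

## The scientific problem

When people estimate the outcome of approximate, non-symbolic arithmetic —
"how many dots are in the box after 14 went in and 5 more followed?" — their
answers are biased by the operation itself. Adults tend to overestimate
addition outcomes and underestimate subtraction outcomes, a phenomenon
known as *operational momentum* (OM). Young children can show the opposite
("inverse") pattern. The effect is usually quantified on a logarithmic
scale, consistent with the view that the approximate number system (ANS)
represents magnitude on a compressed mental number line obeying Weber's
law: the standard deviation of magnitude estimates grows in proportion to
their mean, so the coefficient of variation (CV = SD/mean) is constant
across numerosities.

`opmom` packages the full computational side of a choice-based OM
paradigm:

1. **Stimulus design** — deterministic reconstruction of the problem set,
   response alternatives and trial schedules.
2. **Cohort simulation** — a generative model of child and adult subjects
   whose trial-level behaviour carries the statistical structure the
   analyses assume.
3. **Descriptive metrics** — OM bias, CV profiles, choice-rank
   distributions, memory regressions, and Posner-cueing orienting and
   reorienting effects.
4. **A heteroscedastic Bayesian repeated-measures model** — the package's
   core — fit by a purpose-built Gibbs sampler.

## Stimulus design

Each problem (e.g. 6 + 2 = 8) is paired with nine candidate outcomes
spanning half to double the correct result, geometrically spaced:

\[ v_i = \mathrm{round}\!\left(c \cdot 2^{i/4}\right), \quad i = -4, \dots, 4. \]

Rounding is *half away from zero*. That convention reproduces the printed
design tables this paradigm uses (the 25-outcome series rounds 12.5 up to
13); the one known exception is the 19-outcome series, whose smallest
candidate is the half-integer 9.5, printed as 9 in the original tables —
irreconcilable with the 25-series under any single tie rule. We implement
the 25-series convention and treat that cell as a documented deviation.

For the memorization outcome 6 the rounded series contains duplicates
(`3 4 4 5 7 8 10 12`). Following the design, `resolve_duplicates()`
repeatedly subtracts one from a single occurrence of the smallest
duplicated value until all values are distinct, giving `2 3 4 5 7 8 10 12`.

Only six of the nine candidates are shown per trial. The *low range*
displays the lower six (correct outcome = fifth smallest); the *high
range* displays the upper six (correct outcome = second smallest). The two
ranges therefore share the three middle values.

The session design states only totals: 44 test trials — 12 memorization,
16 addition, 16 subtraction — which forces 4 repetitions of each of the 11
problems. We cross the two response ranges with the two dot-area control
modes factorially (2 × 2 = 4), the natural balanced choice; the original
totals are equally consistent with a non-factorial assignment, so this is
an explicit assumption of the reconstruction. Training re-uses 8 randomly
drawn test configurations, untimed; test trials carry the 20 s response
limit. The cueing session has 60 test trials (40 valid / 10 invalid / 10
neutral), target side balanced within validity, the two stimulus-onset
asynchronies (200, 800 ms) balanced within validity, preceded by 8
training trials.

Dot arrays exist as coordinate lists, not rendered images. Dots are placed
by uniform rejection sampling in a 400 × 400 abstract-pixel field with a
2-pixel minimum gap. In `fixed_total_area` mode every array has summed dot
area \(A\) (default \(A = 50 \cdot \pi \cdot 7^2\)), so the radius is
\(\sqrt{A / (n\pi)}\); in `fixed_dot_size` mode the radius is constant
(default 7). Across trials neither total area nor dot size predicts
numerosity.

## The synthetic cohort

No subject-level generative model is given by the paradigm itself, so the
generator is an explicit construct whose parameters must never be read as
estimates of any real cohort. Its purpose is to produce data with the
structure every downstream stage assumes, with known ground truth for
recovery testing.

**Choice model.** A subject's internal estimate of the correct outcome
\(c\) is log-normal:
\(\ln X = \ln c + \beta_{\mathrm{op}} \ln 10 + w Z\), with \(Z\) standard
normal. The subject picks the displayed alternative nearest \(X\) on the
log scale (ties to the smaller value); with probability `lapse` the choice
is uniform instead. The nearest-alternative rule (rather than a softmax)
is parameter-free beyond \(w\), and makes the zero-noise case exactly
verifiable: with \(w = 0\) and \(\beta = 0\) the subject always picks the
correct outcome. The Weber fraction \(w\) (natural-log SD) fixes the CV of
unconstrained estimates at \(\sqrt{e^{w^2} - 1}\); operation biases
\(\beta\) are expressed in log10 units because the bias statistic is
log10-based.

**Defaults.** Group-level means (log10 units): adults
\(\beta_{add} = +0.02\), \(\beta_{sub} = -0.05\) (regular OM); children
\(\beta_{add} = 0\), \(\beta_{sub} = +0.03\) (inverse OM). Weber fractions
0.15 (adults) and 0.25 (children). These are calibration choices that
reproduce the qualitative standardized effect pattern of the paradigm —
they are not measured population values. Between-subject bias SDs (0.05
adults, 0.09 children) make children the more variable group, the
heteroscedasticity that motivates the Bayesian model; within-subject
add/sub bias correlations are −0.34 (adults) and +0.42 (children). Lapse
rates default to 0.01 (adults) and 0.05 (children), producing
non-degenerate rank distributions.

**Cueing.** Reaction times are log-normal with additive condition effects
after exponentiation (a shifted normal could go negative): valid trials
subtract the orienting benefit (child mean 30 ms), invalid trials add the
reorienting cost (child mean 60 ms, SD 40 ms — reorienting costs vary
widely across children of this age). Wrong-side responses occur at 2 %,
the error level this paradigm reports for children. Across children the
OM difference \(\beta_{add} - \beta_{sub}\) and the reorienting *cost*
parameter are drawn with correlation `rho_om_reorient` = −0.6: children
with smaller costs show more regular OM, which on the analysis side
(reorienting effect = neutral − invalid, i.e. the *negative* of the cost
in z units) appears as a *positive* OM-by-reorienting correlation. Note
the measured correlation in a 16-child sample is strongly attenuated by
trial noise (10 invalid trials per child) and is reported descriptively,
not tested against a fixed value.

**What the generator does not emulate.** Strategy use and heuristics,
learning or fatigue across the session, age substructure within groups,
heavy-tailed RT contamination, and spatial response biases. Passing tests
therefore show that the *pipeline* is correct under the stated model, not
that the model captures every feature of real behaviour.

## Descriptive metrics

All bias statistics use base-10 logarithms; results are base-invariant up
to a constant factor. The OM bias of subject \(s\) in operation *op* is
the mean of \(\log_{10}(\mathrm{chosen}) - \log_{10}(\mathrm{correct})\);
the OM difference is addition bias minus subtraction bias.

The CV profile pools all trials of all subjects within each
operation-by-outcome cell before taking SD/mean: with only 2–4 trials per
subject per cell, per-subject CVs are dominated by sampling noise (a
per-subject variant is available behind `by_subject = TRUE`). Choice-rank
proportions are accompanied by the arcsine-square-root transform used for
proportion-scale ANOVAs. Memory regressions fit `chosen ~ shown` per
subject by OLS with group-level one-sample t tests on intercepts and
slopes (slope null value selectable: 0 for "any dependence", 1 for
"identity").

Cueing analyses use correct trials only. Each subject's correct-trial RTs
are z-standardized within subject *at the trial level* before condition
averaging; the alternative reading — z-scoring the three condition means
themselves, which forces mean 0 and SD 1 across three numbers and destroys
effect-size information — is noted but not implemented. A subject with
zero RT spread is assigned all-zero scores rather than NaN. Classical
repeated-measures ANOVA with sphericity corrections is deliberately not
reimplemented; the package exposes the cell means and SDs needed to run
one elsewhere.

## The Bayesian heteroscedastic repeated-measures model

Per-subject score pairs \(y_{ik} = (y_{i1k}, y_{i2k})'\) (addition,
subtraction) in group \(k\) (1 = adults, 2 = children) are modelled as

\[ y_{ik} \sim N(\mu_k, \Sigma_k), \qquad
   \mu_{jk} \sim N(0, 10^5), \qquad
   \Sigma_k \sim \mathrm{inv\text{-}Wishart}(I, 2). \]

Group-specific \(\Sigma_k\) frees the model from the homoscedasticity a
classical repeated-measures ANOVA assumes — exactly the assumption the
child/adult comparison violates. The inverse-Wishart convention is pinned
(libraries differ): density \(\propto |\Sigma|^{-(\nu + p + 1)/2}
\exp(-\mathrm{tr}(S\Sigma^{-1})/2)\) with \(p = 2\), scale \(S = I\) and
\(\nu = 2\) degrees of freedom, proper for \(\nu > p - 1\). The prior on
\(\mu\) is independent per component (a scalar normal per \(\mu_{jk}\)),
not a conjugate matrix-normal; the full conditional of \(\mu_k\) is still
Gaussian:

\[ \mu_k \mid \Sigma_k, y \sim N\!\big(\Lambda_k^{-1} n_k \Sigma_k^{-1}
   \bar y_k,\; \Lambda_k^{-1}\big), \qquad
   \Lambda_k = n_k \Sigma_k^{-1} + 10^{-5} I, \]

and \(\Sigma_k \mid \mu_k, y \sim \mathrm{inv\text{-}Wishart}(I + S_k,\,
2 + n_k)\) with \(S_k\) the centred scatter matrix. The two groups are
conditionally independent, so each runs its own chain. Before fitting,
scores are standardized by the pooled grand mean and SD over all
\(2(n_1 + n_2)\) values; per-group or per-measurement standardization
would change the scale of the reported effects but not their signs, and
pooled is the only variant that leaves between-group variance differences
intact — which is the point of the model.

Operation effects are derived per iteration: \(\mu_{11} - \mu_{21}\)
(adults), \(\mu_{12} - \mu_{22}\) (children) and their difference (the
interaction). Each monitored quantity is summarized by its posterior
mean, a 95 % highest-density interval (the mass level is a package
default; `hdi_mass` changes it) and the posterior sign probability
\(P(\theta > 0)\), the fraction of retained draws above zero.

### Numerical choices

* The default run is 600,000 iterations with 100,000 burn-in; tests and
  examples use 60,000/10,000, where summaries already agree with a
  tenfold longer chain to two decimals (this fast-mixing conjugate
  sampler has near-iid draws).
* The HDI is the shortest contiguous window containing
  \(\lceil mass \cdot N \rceil\) sorted draws — exact for unimodal
  posteriors.
* Convergence is monitored with split-chain potential scale reduction
  (warning above 1.01) and an autocorrelation-based effective sample size
  (warning below 400).
* 2 × 2 inversions keep the off-diagonal exactly symmetric, and Cholesky
  factorizations symmetrize and, if needed, ridge their argument, so
  nearly singular scatter matrices from degenerate data cannot poison a
  chain. A rank-deficient sample covariance (e.g. two subjects per group)
  falls back to the prior scale matrix for initialization.
* The sampler refuses to run without a seed; draws are reproducible
  through R's RNG.

### What the recovery suite shows — and what it cannot

The raw cohort data behind this paradigm's headline analysis were never
deposited, so its exact posterior values are not reproducible. The
package's substitute is a parameter-recovery suite: 32 + 32 subjects are
simulated with standardized group means set to the reference effect
pattern (0.226, −0.513 adults; −0.034, 0.321 children) and identity
covariances, and the fitted model must reproduce the qualitative pattern —
\(P(\text{adult effect} > 0) > 0.9\),
\(P(\text{interaction} > 0) > 0.9\),
\(P(\text{child effect} < 0) > 0.7\) — in at least 15 of 20 seeds. At
\(n = 32\) the child effect (−0.355 standardized, posterior SD ≈ 0.25) is
genuinely marginal, which is why its threshold is looser and why a few
seeds legitimately miss it.

## Problem sizes used in the tests

Monte-Carlo checks use 4,000–10,000 simulated choices per cell, chains of
22,000–60,000 iterations (510,000 for the chain-length stability check),
\(10^6\) draws for the HDI/sign-probability analytics, and 20-seed suites
for the recovery and sign-pattern properties. The acceptance script runs
the full pipeline at the default 600,000/100,000 chain length.

## Known limitations

* The generator's choice rule is deterministic given the internal
  estimate; real subjects may mix strategies.
* Pooled-SD CV profiles conflate within- and between-subject variability
  by design (matching how such profiles are usually plotted).
* The Bayesian module is specialized to two groups × two repeated
  measures; group count is structurally extensible but not exposed.
* The observed OM-by-reorienting correlation at 16 children is noisy and
  attenuated; only the parameter-level correlation is testable.
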