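---
title: "Temporally discounted value, satiation, and striatal coding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally discounted value, satiation, and striatal coding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdvmotive)
```

## The problem this package addresses

In a cued instrumental task, a monkey releases a bar when a spot changes
color; a visual cue at trial start announces the size of the upcoming
reward (in drops) and the delay until its delivery. The animal is not
choosing between options — every trial has the same motor requirement — so
the *error rate* per cue condition (releasing too early or too late) is
used as an inverse index of the motivation to perform, and the question is
what value computation that motivation follows. This package implements
the complete analysis chain for such experiments: behavioral discounting
models with satiation, event-locked spike-response detection and
value-coding classification, and a bootstrap test for whether a
perturbation (e.g., pharmacological silencing of a striatal subregion)
pushed behavior away from the normal discounting pattern. A seeded
synthetic-data generator stands in for the unpublished recordings so that
every stage is testable end to end.

## Behavioral models

The temporally discounted value of `R` drops delivered after `D` seconds
is hyperbolic,

$$DV = \frac{R}{1 + kD},$$

with discount rate `k` (1/s). Error rates are modelled as inversely
related to value, scaled by a subject-specific incentive parameter `a`
(1/drops):

$$E = \frac{1 + kD}{aR} \quad\text{(hyperbolic)}, \qquad
  E = \frac{e^{-kD}}{aR} \quad\text{(exponential, as printed)}.$$

Satiation devalues reward as the normalized cumulative reward
$R_{cum}\in[0,1]$ accrues, with $F(R_{cum}) = e^{-\lambda R_{cum}}$; for
the reward-size task (all rewards immediate, sizes 1–8 drops) the model is
$E = 1/(a R\, F(R_{cum}))$.

Two notational ambiguities in the source formulation are resolved
explicitly rather than silently:

* **Exponential orientation.** As printed, $e^{-kD}/(aR)$ *decreases*
  with delay for $k>0$, opposite to the behavior it is meant to describe
  (a negative fitted `k` is equivalent to the rising form).
  `error_rate_exponential()` exposes `orientation = "printed"` (the
  default, matching the printed formula) and `"value"`
  ($E = 1/(aRe^{-kD})$, errors rising as the exponentially discounted
  value falls). Model comparisons in this package use the `"value"`
  orientation, the only one that competes meaningfully on rising data
  under the constraint $k \ge 0$.
* **Satiation placement.** Multiplying the *error rate* by $F<1$ would
  make errors fall with satiation, contradicting the observed rising
  pattern; the psychological reading (incentive value is devalued
  multiplicatively) puts $F$ under the fraction. `error_rate_with_satiation()`
  offers `form = "printed"` and `form = "value"`; simulation and fitting
  default to the value placement.

Predictions are clipped to $[0,1]$ before residuals are computed: error
rates are proportions and the formulas can exceed 1 for harsh conditions.

### Fitting and model comparison

`fit_discount_model()` minimizes the sum of squared residuals with
Nelder–Mead in log-parameter space (all parameters are nonnegative by
construction), from 20 log-uniform random restarts plus deterministic
seeds under a fixed internal seed, followed by a restart polish
(`reltol` $10^{-12}$–$10^{-14}$). The hyperbolic model is linear in
$(1/a,\,k/a)$ with regressors $1/R$ and $D/R$, so an analytic
nonnegative-least-squares solution seeds the optimizer and serves as the
vectorized fitter inside the bootstrap. $R^2 = 1 - SSR/SS_{tot}$ about
the mean observed rate; a rate table with zero spread reports $R^2 = 0$.

`loo_cv_compare()` treats *sessions* as folds — the natural exchangeable
unit — fitting each candidate on the remaining sessions' pooled counts
and scoring the mean squared prediction error on the held-out session;
fold errors are compared with a paired two-sided Wilcoxon signed-rank
test. The cross-validation unit and the significance test are not pinned
down by the source description; these choices are recorded here once.

## The synthetic world

`generate_session()` draws one of six (or four) cue conditions uniformly,
jitters the delay uniformly within its class (0.3 ± 0.1, 3.3 ± 0.6,
6.9 ± 1.2 s), draws the outcome Bernoulli with the value-placed satiation
model's prediction, and — as in the task — *repeats the same condition
after an error*. Sessions stop after 120 correct trials by default (the
usual recording block). Early-release times follow a truncated Gaussian
peaking at 1.2 s after cue (inside the observed 0.7–1.8 s range); correct
releases occur 0.2–1.0 s after the go signal. All randomness descends
from one named seed through deterministic per-session/per-neuron
sub-streams, so identical seeds give byte-identical output.

Two bookkeeping conventions matter:

* The written `rcum` column is the cumulative *delivered* reward
  including the current trial, normalized by the realized session total —
  nondecreasing and ending at exactly 1. The generative Bernoulli draw
  uses the pre-trial state normalized by the *expected* total, since the
  realized total cannot be known mid-session.
* `p_error_max = 0.95` caps the generative error probability. At the
  model's clip boundary ($E = 1$) a repeat-on-error task would re-present
  the same condition forever; real animals retain occasional correct
  responses even when unmotivated. The 5% success floor is a property of
  the generator only — the fitted models know nothing of it — and it is
  the reason very harsh conditions show observed rates near 0.95 against
  fitted predictions of 1.

`generate_spike_train()` produces inhomogeneous Poisson spikes at 1 ms
resolution: a constant baseline (default 1 spike/s, matching the low
spontaneous rate of presumed striatal projection neurons) plus a
cue-locked trapezoidal transient (onset 100 ms, rise 50 ms, duration
600 ms by default) whose amplitude is $\max(0,\,\beta_0 + \beta_V\,DV)$
for value-coding classes, a value-independent $\beta_0$ for the
visual-transient class, and nothing for the unresponsive class. The
generator emulates the *statistical* structure the analyses assume — it
contains no biophysics, no eye movements, no reaction-time model, and no
correlation between neurons — so a green downstream test establishes that
the analysis recovers what the statistical model put in, not that it
would survive every pathology of real recordings.

## Spike-response detection

`detect_response()` follows the sliding chi-square procedure: 1 ms bins
are marked filled/empty, pooled across trials; each 100 ms test window
(stepped 10 ms over 0–1500 ms for cue, −300–300 ms for release, 0–500 ms
for reward) is compared against the 500 ms pre-cue background by a 2×2
Pearson chi-square (1 df, no continuity correction — the simplest reading
of the published table), significant when $p<0.05$ *and* the test
proportion exceeds background. The response start is the middle of the
first of four consecutive significant windows; the end is the middle of
the last significant window reachable from the onset run without a gap of
four or more non-significant windows (a literal "last significant window
anywhere" could bridge unrelated late activity); a neuron is responsive
given five consecutive significant windows.

**Known limitation — false-positive rate.** The windows overlap by 90%,
so a single chance spike cluster makes ~10 consecutive windows
significant; the consecutive-window rule therefore provides no
multiplicity control across window positions (the procedure is a scan
statistic without a scan-calibrated threshold). Under homogeneous Poisson
input at 0.5–2 spikes/s with 30 trials, the measured probability of
flagging a neuron responsive is 15–30%, not the nominal 5%; a
continuity-corrected variant still shows ~15%, so window overlap — not
chi-square small-count behavior — is the dominant cause. The procedure is
implemented exactly as published, and the corresponding calibration
assertion in the acceptance suite is deliberately left failing rather
than silently re-tuned. Onset *recovery* is unaffected: injected
rectangular rate steps are located within ±100 ms in >95% of strong-effect
cases.

## Value-coding classification

Per-trial rates from the neuron's own detected cue window (half-open
interval, spikes per second) are regressed on the discounted value
computed from the *behavioral* fit (one DV per condition). The simple
regression $Y = \beta_0 + \beta_V DV$ gives the DV effect and its $R^2$
(identically the squared Pearson correlation); the multiple regression
$Y = \beta_0 + \beta_{delay}D + \beta_{size}R + \beta_{DV}DV$ yields
standardized partial regression coefficients
$SPRC_j = \beta_j\,sd(x_j)/sd(Y)$ and the category rule: **DV** when
$\beta_{DV}$ is significant (regardless of the others), **Size_and_Delay**
when size and delay are both significant without DV, **Size**/**Delay**
when exactly one is, **NA** otherwise — $\alpha = 0.05$ per coefficient,
no multiplicity correction, matching the published counting. Neurons
without a detected cue response are excluded from classification. The
category is invariant to affine rescaling of the rates. Because DV is
strongly collinear with size and delay over the six task conditions, the
partial DV test has considerably less power than the simple regression —
a neuron can carry an obvious DV signal in $Y = \beta_0 + \beta_V DV$ yet
narrowly miss significance for $\beta_{DV}$ in the joint model at
moderate trial counts; this is a property of the published design, not an
implementation artifact.
`dv_effect_timecourse()` repeats the simple regression in 200 ms windows
stepped 10 ms; windows without spike-count variance record $R^2 = 0$.
`satiation_regression()` adds $R_{cum}$ as a second regressor, and
`half_split_comparison()` contrasts first/second-half condition means
normalized by the first-half immediate-large response.

## Bootstrap deviation test

`normalize_sessions()` divides each session's per-condition rates by that
session's maximum (removing between-session variance; all-zero sessions
are excluded). `bootstrap_ssr_test()` draws `resample_size` sessions
(5 delayed-reward, 4 reward-size) *with replacement* from the baseline
pool, averages their normalized rates, refits the model, and records the
SSR — 20,000 times by default; the observed statistic is the best-fit SSR
on the test-condition mean, and $p = (1 + \#\{SSR_{null} \ge
SSR_{obs}\})/(1 + n)$ (add-one, so $p > 0$ always). The source phrase
"parametric bootstrapping" is read literally — resample sessions, refit
the parametric model — with the alternative reading (simulate rate
vectors from the fitted model with binomial noise) available as
`method = "simulate"`. All parameters are re-estimated in every resample.
Because every resample inherits the finite pool's own deviation from the
model (variance $\approx\sigma^2/N_{pool}$ on top of resampling noise),
null p-values are mildly conservative for small pools; with a 20-session
pool the null distribution is uniform to within Kolmogorov–Smirnov
distance 0.1.

## Numerical and degenerate-input conventions

Rates use half-open windows $[start, end)$; spike timestamps are bin
centres in ms relative to cue onset; behavioral times are float seconds.
Conditions with zero trials are dropped from fits with a warning;
constant-DV regressors, zero-duration windows, empty backgrounds, and
collinear designs raise errors or refusal rather than guessing. Exact
zero-spread rate tables report $R^2 = 0$. Seeds are 32-bit integers;
sub-stream seeds are derived by a fixed linear-congruential step.

## What the tests establish

The test suite demonstrates parameter recovery (exact-data recovery to
$10^{-4}$–$10^{-3}$ relative; end-to-end recovery from 50 simulated
sessions to within 10%), model-selection consistency (hyperbolic
preferred on hyperbolic data in ≥80% of replicates), detection onset
accuracy, classification recovery at strong effect sizes (≥80% balanced
accuracy with correct SPRC signs), and bootstrap null uniformity and
power — all on data from the generator above. They do not validate the
analyses against real recordings (none are publicly accessioned), and the
detector's false-positive calibration fails for the reasons given above.
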