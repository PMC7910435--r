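---
title: "Modelling posting latencies as average-reward reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling posting latencies as average-reward reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbarl)
```

## The model

`rbarl` treats posting on a social platform as free-operant behavior: the
user chooses *when* to respond, and the only decision variable is the
latency $\tau_t$ between successive posts. Each latency is a draw from an
exponential distribution whose mean is set by the current response policy
and the subjective average net reward rate $\bar R$:

$$\tau_t \sim \mathrm{Exp}\!\left(\mu_t\right), \qquad
  \mu_t = e^{\mathrm{Policy}_t - \alpha \bar R_t}.$$

After a post earns $R_t$ likes, the agent computes a net reward prediction
error that charges the effort of responding (amortized over the latency)
and the opportunity cost of the time spent waiting:

$$\delta_t = R_t - \frac{C}{\tau_t} - \bar R_t \, \tau_t.$$

Both learned quantities are then updated with the same step size $\alpha$:
the policy moves along a stochastic gradient estimate, the product of the
latency "exploration" step with the net outcome, and the average reward
rate integrates the prediction error:

$$\mathrm{Policy}_{t+1} = \mathrm{Policy}_t
    + \alpha\,(\tau_t - \tau_{t-1})\,\delta_t, \qquad
  \bar R_{t+1} = \bar R_t + \alpha\,\delta_t.$$

Because both updates use the same pre-update $\delta_t$, their order within
a step is immaterial; the package applies them jointly. For a fixed reward
the net reward is maximized at $\tau^\* = \sqrt{C/\bar R}$
(`optimal_latency()`), so a higher average reward rate pulls the optimum
toward faster responding — the core vigor prediction. With Poisson likes of
rate $\lambda$ the stochastic fixed point of the full recursion is
$\tau^\* = 2C/\lambda$ and $\bar R^\* = \lambda^2/(4C)$, identities used
throughout to reason about realistic regimes.

Free parameters per user: the learning rate $\alpha \in (0, 1]$, the
initial policy $P \ge 0$ (log-hours; the latency mean before any learning),
and the effort cost sensitivity $C > 0$. The no-learning null model keeps a
constant latency mean $e^P$ (one parameter). Reconstructed alternative
variants modify the effort term (absent, constant, or increasing in
$\tau$) or freeze the policy so that only the momentary $-\alpha \bar R$
("Pavlovian") term varies; they are comparison baselines, not validated
accounts.

## Likelihood and estimation conventions

The likelihood replays the recursion over a user's observed latencies and
likes and scores every inter-post interval under its model-implied
exponential mean, $\mathrm{NLL} = \sum_t (\log \mu_t + \tau_t/\mu_t)$.
Every interval contributes a likelihood term; the policy update needs a
latency *difference* and therefore begins at the second interval, while the
first interval's prediction error already updates $\bar R$. This convention
keeps the null-model maximum likelihood exactly at the sample mean latency
($e^{\hat P} = \bar\tau$), which doubles as an estimator self-test. Likes
attached to a user's very first post precede any interval and never enter
the likelihood. $\bar R$ starts at 0 (a neutral prior on *net* reward) and
is exposed as `rbar0` for sensitivity analysis.

`rrl_fit()` maximizes the likelihood by multi-start Nelder–Mead on an
unconstrained scale (logistic-transformed $\alpha$, log-transformed $P$
with a 0.01 offset so the $P = 0$ boundary stays reachable, log $C$), with
two deterministic starts — a weak learner at the exponential MLE and a
near-zero learning rate, which guarantees the nested null likelihood is
always attainable — 20 random starts by default, and a final simplex
restart from the incumbent. Parameter points with non-finite likelihood are
treated as $+\infty$ and counted; a convergence tolerance of $10^{-8}$
(relative) is used. The latency-mean exponent is clamped to $\pm 50$ with a
warning so the likelihood is always finite.

## The synthetic cohorts, and why their parameters look the way they do

The cohort generator is the package's study-condition definition, not a
convenience. Likes are i.i.d. Poisson draws with the same rate for all
users (default $\lambda = 5$ per post) — deliberately the weakest possible
assumption about the like process. Timelines are produced by the generative
model itself, with ground truth stored for recovery studies and every
cohort byte-reproducible from its serialized spec.

Two numerical properties of the update rule shape the admissible parameter
ranges, and both are worth understanding before changing any default:

* **Heavy-tailed update steps.** The policy step is
  $\alpha\,\Delta\tau\,\delta$. Under exponential draws the effort term
  $C/\tau$ has infinite expectation, so a single very short latency paired
  with a long preceding one produces a jump of order $\alpha C / q$ for
  small quantiles $q$. Products $\alpha C$ much above $\sim 10^{-2}$
  (relative to the latency scale) drive the policy into the exponent clamp
  and chaotic ping-pong.
* **Pavlovian saturation.** At the stochastic fixed point
  $\alpha \bar R^\* = \alpha \lambda^2 / (4C)$; if this product is large
  the $-\alpha\bar R$ exponent term dominates and pins the latency at its
  floor.

Two guards keep simulation outputs usable everywhere: a minimum producible
latency (one minute on the hour scale — composing and uploading a post
takes time; it also bounds the $C/\tau$ spike), and a re-seeding rule that
re-simulates the rare run whose policy passes $|\log \mu| > 20$ (counted in
`truth$n_reseeds`, and an error if a parameter point diverges under 50
seeds).

Four documented populations serve different studies:

* `default_param_ranges()` — $\alpha \in [7\times10^{-4}, 3\times10^{-3}]$
  (log-uniform), $P \in [\log 1, \log 4]$ log-hours, $C \in [0.1, 1]$
  (log-uniform). This is the headline-simulation population: agents operate
  near their steady state with genuine reward-rate fluctuation, and a
  1000-user, 250-post cohort yields a low-vs-high $\bar R$ contrast of
  about +0.18 on log latency — the magnitude the generative analysis is
  designed to reproduce. Because the ranges control that coefficient
  directly, they were fixed once against this target and are documented
  here rather than left tunable in silence.
* `strong_learning_ranges()` — $\alpha \in [3\times10^{-3}, 10^{-2}]$,
  $C \in [0.1, 0.3]$: clearly detectable learning within a few hundred
  posts; the condition for model-recovery classification.
* `recovery_study_ranges()` — every parameter spans its full stable
  plausible region ($C$ over 1.3 decades); the condition for
  parameter-identifiability (recovery-correlation) studies, which should
  measure identifiability across the range, not within a narrow slice.
* `granger_power_ranges()` (paired with $\lambda = 1$) — the linear
  likes-to-latency footprint scales with $\alpha^2\,\mathrm{sd}(R)$, so a
  detectable panel Granger signal requires high learning rates, small
  effort costs and sparse likes; this is the only stable corner where the
  coupling is visible to a linear test.

What the generator does *not* emulate: like-accrual dynamics (final counts
are treated as observed before the next latency choice), content and action
selection, follower effects, circadian and weekday structure, or any
heterogeneity in the like process beyond the optional per-user rate. A
green test suite therefore certifies the machinery and its behavior under
the model's own assumptions — not that real platform data satisfy them.

## Behavioral statistics

**Dichotomized reward-rate regression.** Per user, the $\bar R$ series is
rank-transformed, standardized, and thresholded at 0 (ties at exactly 0 go
to Low, so an odd-length monotone series has $\lfloor n/2 \rfloor$ High
values). Because $\bar R$ entering interval $t$ is determined by rewards
through post $t-1$, the indicator is already the lag-1 predictor of
$\tau_t$. `mixed_model_latency()` fits a log-linear random-intercept model;
by default it adjusts for the previous post's likes, the post number and
the weekday of the preceding post, all standardized within user (centering
within cluster); the headline-simulation computation uses the bare
indicator-plus-intercept form. Inference is by large-sample normal
approximation, and $e^\beta - 1$ is reported alongside each focal
coefficient. Low is coded as the exposure, so the dichotomized coefficient
is positive while the continuous standardized-$\bar R$ variant has the
opposite sign.

**Panel Granger causality.** Per user, a Wald F statistic tests whether
lags of the like counts improve the prediction of the first-differenced
latency beyond its own lags; the statistics are aggregated by exact-F-moment
standardization into a panel z statistic (large-N normal under the null,
robust to unbalanced series). The latency is differenced (its level carries
the drifting policy); the like series enters *in levels*: it is already
stationary, and differencing it creates a non-invertible MA(1) that no
finite-lag regression can whiten, which biases the panel statistic upward
under the null — measured as false-positive rates of 15–22% at small panels
and essentially 1 at large ones. A `diff_likes = TRUE` option retains the
both-differenced form for comparison. Users shorter than $5L + 1$ usable
differenced observations (or with residual df $\le 4$, where the F moments
are infinite) are dropped and counted. One residual caveat: with lagged
dependent variables the F moments are exact only as the series length
grows, so a small per-user bias of order $1/T$ remains; at panels of a few
hundred users and 250 posts it is negligible, but aggregating thousands of
short series will eventually surface it — use longer series as panels grow.

`calibrate_granger_lags()` selects the lag order on simulated ground truth:
power is estimated on large panels resampled from a learning cohort (the
per-user coupling is weak relative to the exponential latency noise, so
detection is an aggregation phenomenon), the false-positive rate on many
small panels from a no-learning cohort; the chosen lag maximizes power
subject to the FPR staying within a margin of the nominal level.

**Quantitative law of effect.** `law_of_effect()` compares the saturating
(hyperbolic, `k*r/(r + r0)`) and linear response-rate functions by $R^2$;
fits use Levenberg–Marquardt with a double-reciprocal fallback start. The
schedule-battery study (`law_of_effect_schedule_study()`) runs each subject
through variable-interval schedules spanning rich to lean (18 seconds to 8
hours of mean arming time), and computes rates from post-burn-in responses
only: the saturating relation is a *steady-state* property — during
acquisition the response rate is still policy-limited and the rate-reward
relation degenerates to proportionality (every collected reward is
proportional to responding), which is exactly what the burn-in removes.

## Phenotyping

`cluster_parameters()` log-transforms and standardizes the per-user
$(\alpha, P, C)$ estimates and runs k-means (50 restarts per candidate k,
k from 2 to 10) with the cluster count chosen by majority vote over mean
silhouette width, Calinski–Harabasz, Davies–Bouldin and the gap statistic
(first-SE-max rule), ties broken by silhouette. Centroids are sorted on
their first coordinate so labels are stable across runs and user
permutations. On unstructured (single-blob) data the four criteria
disagree and silhouettes stay uniformly low rather than pointing to the
smallest k — absolute criterion values, not just the argmax, are the
meaningful readout there. Bootstrap stability is summarized as the
adjusted Rand agreement between re-clustered resamples and the original
assignment.

## The experiment module

`generate_experiment()` simulates two-block sessions in minutes (the one
unit conversion is the exported `MINUTES_PER_HOUR`): 25-minute sessions,
uniform likes 0–9 (low) vs 10–19 (high), block order counterbalanced
exactly. Learning participants need $\alpha \in [0.05, 0.15]$ — an order of
magnitude above the platform-cohort defaults — because a session offers
only a dozen posts; minute-scale latencies keep those rates stable. A
scripted (non-learning) participant type with a known multiplicative block
effect provides the estimator's ground truth. The analysis lags the block
label by one post: a latency unfolds under the reward condition in force
when it started. Participants with fewer than 5 posts are excluded with a
logged reason, and a single-participant input falls back to a fixed-effects
model with a warning.

## Study sizes

The packaged studies use: 1000 users × 250 posts for the headline
simulation; 200 + 200 agents at 50/200/500 posts for model recovery; 200
agents × 500 posts for parameter recovery; 1500-user panels (power) and
600 × 20-user panels (false-positive rate) for Granger calibration; 12–20
subjects × 7 schedules × 1200 responses for the law-of-effect battery; and
176-participant session batches for the experiment analyses. These sizes
make every study rerunnable on a laptop in minutes while keeping
Monte-Carlo error well inside each check's tolerance.

## Known limitations

* The policy-gradient recursion is numerically fragile outside the
  documented parameter regions; the generator refuses (rather than hides)
  chronically divergent parameter points.
* $C$ is weakly identified when $\alpha C$ is small — its likelihood
  footprint passes entirely through the state dynamics. Recovery
  correlations for $C$ are honest but materially lower than for $P$.
* The linear Granger test cannot see the quadratic-order like-to-latency
  coupling of slow learners; model comparison (likelihood-based) is the
  sensitive instrument in that regime, which is the methodological point
  the pipeline makes.
* Large-sample z inference replaces finite-sample df corrections in the
  mixed models; at the packaged study sizes the difference is immaterial.
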