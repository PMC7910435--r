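# rbarl

Average-reward reinforcement learning models of social media posting.

## What problem this package addresses

When people can post whenever they like and are paid in likes, is the
*timing* of their posts shaped by reward learning? Learning theory makes a
sharp prediction for such free-operant settings: response latencies should
shorten when the average rate of accrued reward is high, because waiting
then forgoes more reward. `rbarl` implements a complete modelling pipeline
for this question, for researchers in computational cognitive science and
computational social science who work with per-user posting records
(timestamps and like counts).

## The model

Each inter-post latency is an exponential draw whose mean is set by a
learned response policy and the subjective average net reward rate R̄:

    tau_t ~ Exp(mu_t),   mu_t = exp(Policy_t − alpha * Rbar_t)

After a post earns R_t likes, a net reward prediction error charges the
effort cost of responding and the opportunity cost of waiting,

    delta_t = R_t − C / tau_t − Rbar_t * tau_t

and both learned quantities update with the same step size:

    Policy_{t+1} = Policy_t + alpha * (tau_t − tau_{t−1}) * delta_t
    Rbar_{t+1}   = Rbar_t + alpha * delta_t

Three free parameters per user — the learning rate `alpha`, the initial
policy `P` (log-hours) and the effort cost sensitivity `C` — form a
computational phenotype. A one-parameter null model (constant mean latency,
no learning) and a family of reconstructed alternative variants serve as
comparison baselines. For fixed reward the net reward peaks at
`tau* = sqrt(C / Rbar)`: higher average reward rates demand faster
responding.

Around this core the package provides per-user maximum-likelihood fitting
and AIC / random-effects Bayesian model comparison, parameter- and
model-recovery harnesses, model-independent reward-sensitivity diagnostics
(the quantitative law of effect on interval schedules; panel Granger
causality with simulation-calibrated lags), dichotomized reward-rate mixed
models, k-means computational phenotyping, synthetic cohort / experiment /
reinforcement-schedule generators, and an end-to-end analysis pipeline.

## A worked example

Simulate one reward-learning user, then fit and compare the learning model
against the no-learning null:

```r
library(rbarl)
truth <- agent_params(alpha = 0.005, P = log(3), C = 0.25)
tl <- trace_to_timeline(
  simulate_agent(truth, reward_process = 5, n_posts = 400, seed = 42),
  user_id = "demo")
print(tl)
#> Posting timeline for user 'demo': 401 posts, median latency 0.403 h, mean likes 4.76

compare_models(tl, seed = 1)
#> Model comparison for user 'demo' (best: rbar_full)
#>           variant k   nll   aic aic_weight
#>         rbar_full 3 200.5 407.1  1.000e+00
#>  null_no_learning 1 310.8 623.7  9.353e-48
```

The learning model wins decisively (Akaike weight 1.0): the user's
latencies carry the signature of reward learning. The fitted parameters
recover the generating ones:

```r
summary(compare_models(tl, seed = 1)$fits$rbar_full)
#> Latency model fit (rbar_full), user 'demo'
#>   intervals: 400, NLL: 200.5449, AIC: 407.0898 (k = 3)
#>   estimates: alpha = 0.005053, P = 0.9992, C = 0.287
#>   mean observed latency 0.7771 h; mean fitted latency 0.7799 h
#>   final rbar 3.472 (range 0 to 3.472)
```

`alpha` is estimated at 0.00505 (truth 0.005), `P` at 1.00 (truth
`log(3) = 1.10`), `C` at 0.29 (truth 0.25). The rising `rbar` is the
user's subjective average reward rate; as it grows, the model predicts —
and the data show — shorter latencies. Cohort-scale workflows run through
`generate_cohort()`, `fit_cohort()`, `group_comparison()`,
`mixed_model_latency()`, `cluster_parameters()` and `run_full_analysis()`;
the methods vignette (`vignettes/rbarl-methods.Rmd`) documents every model
assumption and study condition.

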