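---
title: "Deconvolutional exGaussian regression for naturalistic reading: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolutional exGaussian regression for naturalistic reading: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(cdrex)
```

# The problem

Readers slow down on rare words and on contextually unpredictable words.
Deciding whether these *frequency* and *predictability* effects are
separable phenomena requires relating an asynchronous stream of word events
(fixations, button presses) to reading-time responses without committing to
discrete-time dynamics, linearity, additivity, or constant variance. cdrex
implements the full analysis chain for that question: a continuous-time
deconvolutional regression whose impulse-response function (IRF) feeds the
parameters of an exGaussian predictive distribution, ablation-based model
comparison with paired permutation tests of held-out likelihood, and a
generative simulator with known ground truth against which every stage can
be validated.

# The model

Each response $y$ (a reading time in ms) observed at time $t$ is modeled as
exGaussian — the convolution of a Normal$(\mu, \sigma)$ with an
Exponential of mean $\tau$, so that $\mathbb{E}[y] = \mu + \tau$ and
$\tau$ governs the right tail. Each pre-link parameter is assembled from
the event history of the same participant and text:

$$\tilde\theta(t) \;=\; b_\theta \;+\; u_{\theta[p]} \;+\;
  \sum_{e\,:\,t_e \le t} g_\theta\!\left(x_e,\; t - t_e\right),$$

where $b_\theta$ is a population baseline, $u_{\theta[p]}$ a by-participant
random offset, $x_e$ the standardized predictors of event $e$, and
$g_\theta$ the IRF evaluated at the realized continuous delay. The links
are identity for $\mu$ and softplus for $\sigma$ and $\tau$ (with a 1 ms
floor, see *Numerical choices*), which keeps the positive parameters
positive without constraining the optimizer.

Two IRF families are provided:

* **Neural (`irf = "mlp"`)** — a small tanh network on
  $(x_e, d, \log(1+d))$ with a zero-initialized output layer, so training
  starts from the baseline-only model. This is the analysis model: it can
  express nonlinear, non-additive, delay-dependent effects on any
  distributional parameter.
* **Linear kernel basis (`irf = "linear"`)** — features
  $x_e \cdot e^{-r d}$ over a small set of fixed decay rates (default
  $r \in \{1, 3, 9\}$ s$^{-1}$, log-spaced over decay scales of roughly
  0.1–1 s), optionally augmented with within-network pairwise products.
  Contributions are exactly linear in the weights. This configuration
  exists for closed-form oracle tests and for simulation studies that need
  hundreds of fits.

A model may contain several IRF networks with different predictor sets and
different target parameters. That is how the null models are built:
dropping a predictor from all networks tests its overall contribution; the
two-network split (one network sees frequency + controls, the other
predictability + controls, with a matched two-network redundant
alternative) tests the frequency × predictability interaction while
letting both predictors interact freely with the controls; the
three-network per-parameter form with one predictor removed from a single
network tests an effect on one distributional parameter.

## Random effects

By-participant additive offsets on the three pre-link baselines, a
by-participant multiplicative gain on each network's output (a random
slope on the IRF as a whole), and by-token-position intercepts on $\mu$.
All are shrunk toward zero by an L2 penalty (`lambda`, default 0.01 on the
per-datapoint loss scale). The gains are centered within each network
before use: a free mean gain would trade off against the population IRF
scale and leave the effect curves unidentified.

## Training

Fits maximize the summed exGaussian log-likelihood by Adam (default batch
1024, learning rate 0.03) with early stopping on validation likelihood
(default: evaluate every 25 steps, patience 10), or by full-batch L-BFGS
for the linear configuration. Baselines are initialized from
method-of-moments estimates of the training responses, so optimization
starts near the intercept-only solution. Gradients of the exGaussian
log-likelihood are analytic (they use the inverse Mills ratio computed in
logs) and are verified against finite differences in the test suite. All
statistical tests aggregate over ensembles of 10 independently seeded
fits, which averages out variability due to stochastic optimization; the
ensemble's predictive distribution is the uniform mixture of member
densities, so its per-datapoint log-likelihood is the log of the mean
member density (not the mean log-density).

# Data handling

Responses are partitioned into train/validation/test by
$i = (s + p) \bmod 4$ on sentence index $s$ and participant index $p$:
train for $i \in \{0, 1\}$, validation for $i = 2$, test for $i = 3$. On a
complete grid with both dimensions multiples of 4 the fractions are
exactly 1/2, 1/4, 1/4. Filtering (RT bounds, boundary exclusions, outlier
saccades, blinks, accuracy, per-participant minima; presets for the six
public reading datasets are in `filter_preset()`) applies only to the
response vector — the event table, i.e. the predictor matrix, is always
retained in full, which is what makes valid deconvolution possible.

For eye tracking, the three fixation-duration measures are computed from
the scan path: scan-path duration (entry to a region until entry of a
different region, from either direction), first-pass duration (only visits
entered from the left to a not-previously-visited region), and go-past
duration (from first leftward entry until the first entry of any region to
the right, including regressive fixation time). Region entries are defined
by fixation onset times; visits whose rightward exit never occurs before
the record ends have no go-past duration and are reported as unresolved.
Record-final scan-path visits run until the end of the record and are
included.

# The synthetic-data generator

The generator is the package's ground truth. Its defaults describe a
self-paced-reading-like study: 10 participants × 20 texts × 100 words
(20,000 events), exponential inter-event intervals with mean 0.3 s,
sentences of 10 words. Two surprisal-scale predictors — unigram surprisal
(mean 10, SD 3) and contextual surprisal (mean 5, SD 2.5) — are bivariate
Gaussian with correlation 0.6, mimicking the strong empirical correlation
between word frequency and contextual predictability; a word-length
control is independent. Effects act through a peak-normalized exponential
kernel (rate 3 s$^{-1}$, so contributions decay to 20% by ≈0.54 s, inside
the 0.5–1 s range that naturalistic reading effects display), and are
placed on the skewness parameter $\tau$ by default (20, 30, and 8 ms per
SD for frequency, predictability, and length) — the distributional
placement that full-scale analyses of real reading data support. The
baseline exGaussian is $\mu = 250$, $\sigma = 40$, $\tau = 150$ ms;
by-participant offsets have SDs (15, 5, 15) ms. A configurable
frequency × predictability interaction (ms per SD², default 0) acts on
$\tau$. Effects pass through the same softplus links the model uses, so
generator and model are conjugate and parameter recovery is well-posed.

What the generator does *not* emulate: oculomotor dynamics (saccade
planning, landing positions, regressions arise only as synthetic region
sequences in the measure tests), token-position trends, autocorrelated
predictor streams, and any mismatch between the generator's kernel family
and the model's. Passing recovery tests therefore demonstrates that the
estimation machinery is correct and well-calibrated under the stated
generative assumptions — not that those assumptions hold of any real
dataset.

```{r generator}
cfg <- generator_config(n_participants = 4, n_texts = 2,
                        n_words_per_text = 50)
sim <- simulate_dataset(cfg, seed = 1)
head(sim$responses[, c("participant_id", "time_s", "duration_ms",
                       "partition")])
```

# Surprisal predictors

Frequency is operationalized as unigram surprisal — the negative natural
log of the word's relative corpus frequency (nats; any other base only
rescales coefficients). Contextual surprisal from a neural language model
is consumed from precomputed per-subtoken log-probabilities and aggregated
by the chain rule (the package never runs a language model). Bigram and
trigram surprisal come from the package's own count-based estimator:
interpolated absolute discounting with fixed discount $D = 0.75$, in which
the held-out mass of an observed context is spread over the lower-order
distribution and an unseen context backs off entirely, so conditionals
reduce toward the unigram estimate as context counts vanish. The base
unigram distribution reserves one unit of mass for an unknown-word symbol
(`1/(N+1)`), keeping every conditional a proper distribution; plain
unigram surprisal uses the maximum-likelihood estimate over the observed
vocabulary. We use count-based lower-order distributions rather than
continuation counts because the backoff target must *be* the unigram
frequency estimate for the frequency predictor and the backoff chain to be
mutually consistent; the implementation is verified against an independent
brute-force calculator on small corpora.

# Statistical testing

Two ensembles are compared by a paired permutation test of their
per-datapoint held-out log-likelihoods: the statistic is
$\sum_i (\ell^B_i - \ell^A_i)$, the null is generated by independently
swapping the two ensembles' scores per datapoint, and the two-sided
p-value uses the add-one correction, so the smallest attainable p is
$1/(n_{\mathrm{perm}}+1)$ (default $n_{\mathrm{perm}} = 10{,}000$).
Aggregate tests across datasets pool the per-datapoint differences and
apply the same scheme, reporting per-dataset contributions.

A caveat the package is explicit about: per-datapoint sign-flipping
assumes the paired differences are exchangeable across datapoints, but
differences between two fitted models are correlated through the shared
parameters. When the held-out sample is large relative to the training
noise, tiny systematic likelihood offsets between two equally-correct
models become detectable and the test rejects "exact equality" more often
than the nominal rate. The calibration simulation in the acceptance suite
therefore uses the regime in which the test is advertised to operate:
ensembles trained on independent response draws from the same generator
(about 800 training responses) and compared on a held-out sample of 100
datapoints, where seed- and sampling-noise dominates. The power
simulations use the standard protocol (both ensembles trained on the same
data, full test split). This sensitivity to the test-to-training size
ratio is a known limitation of datapoint-level permutation tests for model
comparison, and is the reason the package reports effect curves alongside
p-values.

# Numerical choices

* exGaussian log-density via `pnorm(log.p = TRUE)` on
  $z = (x-\mu)/\sigma - \sigma/\tau$; stable for $\tau \ll \sigma$ and far
  tails. Gradients use the inverse Mills ratio computed in logs.
* softplus links with a 1 ms floor on $\sigma$ and $\tau$: keeps the
  likelihood defined and its curvature bounded when a line search or early
  training step drives a dispersion toward zero. Durations are on the ms
  scale, so the floor is inert at any plausible optimum.
* By-participant gains are centered per network (see above); random
  effects of participants absent from training fall back to the
  population level and are counted.
* History windows (default 32 events / 20 s, whichever truncates first)
  bound compute; the default generator kernel is numerically zero well
  inside the window.
* Ensembled uncertainty: pointwise percentile bands across member curves.
  They quantify optimization-seed variability, not posterior uncertainty;
  zero-width bands (identical members) are flagged.
* Effect curves use an explicit reference convention, recorded in each
  curve's attributes: all predictors at their standardized means, zero
  random effects, a single conditioning event at the stated delay,
  deviations relative to the reference input.

# Problem sizes in the test and acceptance suites

Parameter recovery runs at the generator's full default (20,000 responses)
with ensembles of 10 reduced-size neural models (one hidden layer of 8
units, history window 6 events / 3 s, full-batch Adam, at most 400 steps);
these sizes recover the default effect curves with correlation well above
0.9 while keeping a 10-member ensemble to a few minutes. The permutation
calibration uses 200 simulated comparisons of 2-member linear-IRF
ensembles; interaction calibration uses 40; power checks use 3 runs each
at the full 20,000-response design, where the default effect sizes are
detected at the smallest attainable p. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities at the same sizes
(100 calibration comparisons) from scratch.

# Known limitations

* The neural IRF is fit by maximum likelihood with early stopping;
  uncertainty is ensemble spread, not a posterior.
* The permutation test's calibration depends on the held-out/training
  size regime, as discussed above.
* The n-gram estimator implements interpolated absolute discounting with
  count-based backoff, not modified Kneser–Ney; at the corpus scales the
  package targets (desk-scale counts, oracle-testable) the difference is
  a smoothing detail, but estimates on large corpora will differ from
  production language-model toolkits.
* The generator shares its link functions and kernel family with the
  model. Recovery results are therefore a best case; misspecification
  robustness is not claimed.

# A worked end-to-end example

```{r example, eval = FALSE}
preds <- c("unigram_surprisal", "gpt2_surprisal", "word_length")
cfg <- generator_config()            # the default 20,000-response study
sim <- simulate_dataset(cfg, seed = 1)
sp <- split_responses(sim$responses)

model_cfg <- cdr_config(preds, irf = "linear", history_n = 8,
                        history_t = 4, optimizer = "lbfgs",
                        max_steps = 200)
ens <- fit_ensemble(model_cfg, sim$events, sp$train, sp$validation,
                    n_members = 10, base_seed = 1)

# effect curves against ground truth
cu <- instantaneous_effect(ens, "gpt2_surprisal")
tr <- true_instantaneous_effect(sim$truth, "gpt2_surprisal")
cor(cu$estimate, tr$truth)

# frequency ablation test
pair <- build_null_config(model_cfg,
                          ablation_spec("drop_predictor",
                                        "unigram_surprisal"))
null_ens <- fit_ensemble(pair$null, sim$events, sp$train, sp$validation,
                         n_members = 10, base_seed = 100)
paired_permutation_test(test_loglik(null_ens, sim$events, sp$test),
                        test_loglik(ens, sim$events, sp$test),
                        n_permutations = 10000, seed = 1)
```
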