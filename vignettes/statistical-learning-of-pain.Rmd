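---
title: "Confidence-weighted statistical learning of pain sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted statistical learning of pain sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

painseq studies how observers extract temporal regularities from sequences
of noxious (heat-pain) stimuli, and how the resulting probabilistic
expectations and the observer's confidence shape both the *perception* of
the current stimulus and the *prediction* of the next one. This vignette is
the package's own account of the generative design, the five observer
models, the hierarchical estimation machinery, and the simulation studies
used to validate it; it also records the design decisions that were
genuinely open and the limitations a user should know about.

```{r setup}
library(painseq)
```

## The sequence design

Noxious input sequences are built from *chunks*: runs of trials sharing a
latent mean intensity $I$ drawn uniformly on $[3.5, 10.5]$ (so the design
is centred on level 7, the nominal pain threshold, by symmetry of the
support rather than by any post-hoc recentring). Two sources of
uncertainty are crossed in a 2x2 design:

* **Volatility** — how quickly the latent mean moves — is set by the mean
  chunk length $L$: 15 trials (high volatility) or 25 (low). Individual
  chunk lengths are drawn uniformly from $\{L-3, \dots, L+3\}$ so chunk
  boundaries are not predictable.
* **Stochasticity** — trial-wise observation noise — is the variance
  $\sigma^2$ of the Gaussian from which each trial's intensity is drawn
  around its chunk mean: 1.75 (high) or 0.25 (low).

Consecutive chunk means must differ by at least 2 intensity levels so that
a chunk transition is in principle noticeable; a freshly drawn mean is
rejected and redrawn against its immediate predecessor only (the
constraint is read as applying to *consecutive* chunks, not all pairs).
Trial values are rounded to the nearest integer level; a trial whose
rounded value leaves the valid range $[1, 13]$ is discarded and redrawn
individually, which preserves the chunk structure rather than rejecting
whole sequences. Chunks are drawn until the cumulative length reaches 80
trials and the last chunk is truncated to fit (the truncation rule is a
package choice; nothing observable depends on it beyond the final chunk's
length). Each 80-trial sequence is paired with a randomised schedule of
40 perception and 40 prediction probes.

```{r}
spec <- make_condition("high", "high")
spec
s <- generate_sequence(spec, seed = 7)
head(s, 4)
```

All randomness flows through explicit integer seeds; every generated
object records its seed, and generators restore the caller's RNG state.

## The five observer models

All models rate on a 0-100 scale (the response scale onto which inputs
are mapped; see below) and share the confidence-scaled response noise

$$\hat{P}_t \sim \mathcal{N}\!\left(P_t,\; \xi^2 \exp\{2 (1 - c_t)/C\}\right),$$

where $c_t \in [0,1]$ is the trial's confidence rating, $\xi > 0$ the
response noise, and $C > 0$ the confidence scaling factor: at full
confidence the sd is $\xi$; as confidence drops the sd inflates, the more
steeply the smaller $C$. Prediction ratings $\hat{E}_{t+1}$ use the same
law around the post-update expectation. Responses are modelled as
*untruncated* Gaussians even though the scale is bounded — the likelihood
is exactly the stated Normal, with no renormalisation at 0 or 100.

* **RL** (Rescorla-Wagner): point estimate $E_t$ updated by
  $E_{t+1} = E_t + \alpha (N_t - E_t)$; perception is veridical,
  $P_t = N_t$. Free parameters $\alpha, \xi, E_0, C$.
* **eRL**: perception is expectation-weighted,
  $P_t = (1-\gamma) N_t + \gamma E_t$, and the prediction error is taken
  from the weighted percept, $\delta_t = P_t - E_t$. Adds $\gamma$.
* **KF**: Bayesian filtering under a Gaussian random walk (drift sd $v$)
  observed with noise sd $s$. Belief mean $m_t$ and variance $w_t^2$
  update with gain $\alpha_t = w_t^2 / (w_t^2 + s^2)$ and
  $w_{t+1}^2 = w_t^2 (1 - \alpha_t) + v^2$; perception is veridical.
  Parameters $s, v, \xi, E_0, w_0, C$.
* **eKF**: the input is additionally treated as an imperfect indicator of
  the true pain level (subjective noise sd $\epsilon$). The percept mixes
  prior and input with trial-wise weight
  $\gamma_t = \epsilon^2 / (\epsilon^2 + s^2 + w_t^2)$, and the gain
  becomes $\alpha_t = w_t^2 / (\epsilon^2 + w_t^2 + s^2)$. Adds
  $\epsilon$.
* **random**: a baseline responding around a constant $R$ with the shared
  noise law; parameters $R, \xi, C$.

Two exact nestings anchor the implementation and are tested
trajectory-exactly: eRL with $\gamma = 0$ *is* RL, and eKF with
$\epsilon = 0$ *is* KF. Two further analytic facts are used as oracles:
with $v = 0$ the KF is conjugate-Gaussian updating (its final belief must
match the closed-form batch posterior to 1e-10), and the variance
recursion has the stationary point returned by
`kf_stationary_variance()`.

The belief is updated from the objective input $N_t$ on *every* trial,
whichever probe was shown; on prediction trials the modelled mean is the
post-update expectation $E_{t+1}$, evaluated before the next stimulus
arrives. Missing responses contribute nothing to the likelihood but do
not block belief updates.

## Input transform and model-naive performance

Inputs are discrete levels 1-13 while ratings live on 0-100, so each
participant's perception trials define a least-squares line mapping input
to rating; the direction (rating regressed on input) is forced by the
need to *map inputs onto the response scale*. If the fitted line sends
any observed input below 0, it is refit with the intercept constrained
non-negative (`minpack.lm`). Model-naive accuracy is the root-mean-square
error of perception ratings against the transformed input on the same
trial, and of prediction ratings against the *next* trial's input (the
final trial's prediction has no successor and is dropped).

## Hierarchical estimation

Each model is fit per condition to all participants jointly
(`sample_posterior()`), with the non-centred parametrisation: individual
parameter $= \text{link}(\mu_k + \sigma_k z_{ik})$, $z_{ik} \sim
\mathcal{N}(0,1)$, $\mu_k \sim \mathcal{N}(0,1)$, and the group scale
$\sigma_k$ given a half-Student-t(3,0,1) prior written in its
gamma-mixture form (precision $\lambda_k \sim$ Gamma(1.5, 1.5), scale
$=|$Normal$(0, \lambda_k^{-1})|$). Links: $(0,1)$-bounded parameters
($\alpha, \gamma$) use `phi_approx()`, the logistic approximation to the
standard-Normal CDF; strictly positive scale-type parameters
($\xi, s, v, w_0, \epsilon, C$) use $\exp$, the standard choice for scale
parameters and compatible with the N(0,1) group priors; response-scale
locations ($E_0, R$) are identity-linked with the raw N(0,1) prior
stretched by a factor of 100/2 = 50, giving a weakly-informative prior
spanning the rating scale (no tighter prior is defensible a priori, and
the data dominate it quickly).

Sampling is by the package's own Markov chain Monte Carlo scheme, built
for the specific geometry of these posteriors. The Kalman-filter models
leave the decomposition of total noise into $\epsilon$, $s$, $v$ (and
$w_0$) only weakly identified by 80 trials, which produces long, flat
ridges — within each subject, and collectively at the group level.
Componentwise samplers (single-site slice sampling or Metropolis) take
small random-walk steps along such ridges and mix far too slowly at desk
scale; gradient-based samplers are the usual answer, but the chosen
scheme achieves the same effect with three move types, each a valid
kernel on the joint posterior:

1. **per-subject joint Metropolis blocks** on the raw (unconstrained)
   individual values, with a proposal covariance learned during warmup
   (restarted mid-warmup to forget the initialisation transient) plus a
   group-scale-matched diagonal mixture component for prior-dominated
   directions — this moves along within-subject ridges;
2. **population translation and scaling moves** that shift, or contract/
   expand, the group location together with every subject's raw value
   (with the appropriate Jacobian), letting the whole population slide
   along group-level valleys that subject-wise moves cross only by slow
   collective diffusion;
3. a **conjugate/slice group step**: holding the raw individual values
   fixed, the group location has a conjugate Normal conditional (Gibbs
   draw) and the group scale a one-dimensional conditional sampled by
   slice sampling under its half-t prior.

Several subject sweeps and translation moves run per iteration. The
non-centred offsets are part of the model and are monitored and
diagnosed; the sampler merely navigates in the equivalent raw
coordinates. Chains are initialised mildly overdispersed, with the
response-scale location and response noise set from the data; all
chain RNG streams derive from the configuration seed, so fits are
bit-reproducible. The test suite cross-checks the sampler against an
independent MCMC engine (JAGS) running the identical generated model.

The desk-scale default is 4 chains x 1000 warmup + 1000 retained draws;
`fit_config(full_scale = TRUE)` switches to 4 x 6000/6000. Tree-depth
settings belong to Hamiltonian samplers and have no counterpart here, so
the configuration does not carry one. Convergence is monitored by
rank-normalised split R-hat and bulk/tail effective sample size,
implemented in the package (cross-checked against coda's PSRF in the
tests) and computed for *every* parameter: group locations and scales,
all non-centred offsets, and all natural-scale individual parameters.
The convergence criterion used throughout is max R-hat < 1.1.

Three identifiability remarks. First, $\xi$ and $C$ trade off when
confidence varies little within a subject (both only enter through the
response sd), so their individual-level recovery is expected to be weaker
than that of learning parameters. Second, the volatility-type parameters
($v$, $w_0$) are weakly constrained by 80 trials; this mirrors the
general experience that uncertainty parameters recover less well than
location-type ones. Third — and structurally — the KF/eKF response
likelihood depends on $\epsilon^2, s^2, v^2, w_0^2$ only through the
ratios inside $\gamma_t$ and $\alpha_t$: rescaling all four by a common
factor leaves every trial's modelled mean (and hence the likelihood)
exactly unchanged. The noise decomposition is therefore identified only
*relatively*; the absolute scale is anchored by the N(0,1) group priors.
Posterior point estimates of $\epsilon, s, v, w_0$ should be read as
prior-anchored ratios (e.g. $\gamma_t$, or $\epsilon/s$), not as absolute
noise magnitudes — which is also why the presence of expectation
weighting is established by model comparison (eKF vs KF), not by the
location of $\epsilon$'s posterior.

## Model comparison

`elpd_loo()` implements Pareto-smoothed importance-sampling leave-one-out
cross-validation from the stored pointwise log-likelihood draws: the
importance ratios of each observation unit are tail-smoothed by a
generalised Pareto fit (Zhang-Stephens profile posterior with the usual
weak shrinkage of the shape), weights are capped at the raw maximum, and
the unit's expected log predictive density is the weighted average
predictive density. The observation unit is one participant-trial
response, matching the per-trial likelihood; whether to hold out trials
or whole participants is genuinely open, and per-trial is the finer-
grained (and cheaper) choice. Units with Pareto $k > 0.7$ are flagged
with a warning, not refit. The test suite validates PSIS-LOO against
exact leave-one-out refits on an 8-unit toy problem.

`compare_models()` ranks fits by ELPD and reports, per model, the ELPD
difference to the best model, the SE of that difference computed from the
paired pointwise contributions, and the *sigma effect*
$|\Delta\text{ELPD}| / \text{SE}$; at least 2 sigma is read as a
significant difference. LOOIC $= -2\,$ELPD is carried for the
model-recovery winner rule. Between-condition differences of group-level
parameters use `hdi_contrast()`: the 95% highest-density interval of the
elementwise difference of merged-across-chains draws, significant when it
excludes zero. Differencing *interval endpoints* has no probabilistic
interpretation, so the contrast is built on the paired difference of
draws; draw vectors of unequal length are reconciled by seeded
subsampling of the longer one.

## Synthetic studies: what they emulate and what they do not

`simulate_study()` builds fully synthetic datasets: per subject it
generates a fresh sequence, a probe schedule, a linear input transform
drawn from a Gaussian over slope and intercept (defaults slope 5 ± 1,
intercept 15 ± 5 — synthetic stand-ins for coefficients that a real study
would estimate from its own participants; negative slopes are rejected),
confidence ratings, and model-generated responses. Confidence is
simulated as the lag-1 autocorrelation of a trailing 10-trial window of
the transformed inputs, mapped affinely from $[-1,1]$ to $[0,1]$ and
clipped; the window length is a package choice — shorter than a chunk at
either volatility level, so confidence tracks local stability — and the
affine map is the simplest monotone map onto the confidence scale (both
are configurable). Trials before the first complete window inherit the
first complete value; a zero-variance window maps to 0.5.

The group-level generative settings in `default_group_config()` were
chosen once to give plausible rating behaviour: response noise around 5
on the 0-100 scale, expectations starting near 50, subjective
stochasticity near the transformed trial-to-trial variability, and (for
the eKF) subjective noise $\epsilon \approx 8$, strong enough that
expectation weighting is behaviourally visible ($\gamma_t \approx 0.4$ at
the stationary belief variance).

What the synthetic data do *not* emulate: sensitisation and habituation
drifts, offset analgesia, sequential response biases, anchoring of the
rating cursor, lapses, or any mismatch between the assumed and actual
confidence process. Passing recovery tests therefore show that the
pipeline is *internally* consistent — the estimator recovers the model
that generated the data — not that real participants obey these models.

`parameter_recovery()` draws individual parameters from the group
distribution, simulates, refits, and correlates generating values with
posterior means (posterior means, not medians — the conventional point
estimate for roughly symmetric marginals), graded poor/fair/good/
excellent at 0.5/0.75/0.9. `model_recovery()` simulates from each model,
fits all candidates, and tallies LOOIC winners into a confusion matrix;
LOOIC ties (which can occur at tiny scale) split the count equally and
are flagged. One caution for interpreting confusion matrices in this
model family: the pairs are not all separable. The eKF nests the KF
($\epsilon = 0$) and can mimic a constant-learning-rate RL exactly
($\epsilon \to 0$ with the initial uncertainty at its stationary value),
and analogously eRL nests RL. On data generated from the *simpler* member
of such a pair, the LOOIC preference for the truth is only the small
Occam gap from the extra parameters' posterior spread, and at small
simulation scales the point winner can flip within noise. Rows generated
from models with a structural signature no other candidate can express —
expectation weighting present (eKF among unweighted candidates), or no
learning at all (random) — are the ones a desk-scale study can expect to
recover outright.

## Problem sizes and numerical choices

The validation suite runs at sizes chosen to keep a full check of the
pipeline comfortable on a single CPU: 200 sequences per condition for
generative statistics; the reference hierarchical eKF fit at 12 subjects
x 80 trials with 4 chains x 1000/1000 draws; the eKF-vs-KF comparison at
8 subjects with 2 chains x 500/500; near-zero-noise parameter recovery at
10 subjects; model recovery over RL, eKF and the random baseline at 5
subjects x 80 trials with 2 chains x 300/300. These sizes
are documented here as the package's validation conditions; all of them
scale up by changing `fit_config()` and the `n_*` arguments.

Other numerical conventions: discretisation is round-to-nearest (the
natural reading of mapping Gaussian draws to integer levels);
out-of-range trials are redrawn individually; `hdi()` uses the
shortest-window estimator on sorted draws; the ESS floor and cap follow
the usual rank-normalised formulation; R-hat of constant draws is NA and
excluded from the convergence maximum.

## Known limitations

* At very small problem sizes (2-3 subjects, a few hundred draws) the
  weakly identified directions — $\xi$ vs $C$ when confidence varies
  little, and the group scales under few subjects — can still show
  R-hat above 1.1. The desk-scale reference fit converges cleanly;
  always check `diagnostics()`.
* In the noise-free limit the (e)RL likelihood admits compensating
  (learning-rate, initial-expectation) modes for subjects whose early
  prediction trials are sparse; $E_0$ recovery should be judged with
  that in mind.
* PSIS-LOO with per-trial units assumes approximate factorisability of
  the predictive; with 80 trials per subject no unit is influential
  enough to matter, but on very small toys the PSIS-exact gap is visible
  (it is measured in the tests).
* The untruncated Gaussian response model puts (small) mass outside
  0-100; simulated responses can leave the scale, exactly as the
  likelihood assumes.
* Recovery of $v$, $w_0$, $C$ (and $\epsilon$ when weighting is weak) is
  limited at 80 trials; reported categories for those parameters should
  be read accordingly.
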