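---
title: "Discrete-time likelihoods, interpolation, and the piecewise-constant hazard model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time likelihoods, interpolation, and the piecewise-constant hazard model}
  %\VignetteEncoding{UTF-8}
---

## The modeling problem

hazardnet predicts conditional survival functions $S(t \mid x) = P(T^* > t \mid x)$
from right-censored data: for each individual we observe covariates $x_i$, a
time $t_i = \min(T^*_i, C^*_i)$, and an event indicator
$d_i = 1\{T^*_i \le C^*_i\}$ (an event and a censoring at the same time is
recorded as an event). Events and censorings are assumed conditionally
independent given $x$, so the event-time likelihood factors out and each
individual contributes $f(t_i \mid x_i)^{d_i}\, S(t_i \mid x_i)^{1-d_i}$.

Neural networks are fully parametric, which makes discrete-time survival
models a natural fit: a multilayer perceptron $\phi(x) \in \mathbb{R}^m$
emits one value per interval of a time grid
$0 = \tau_0 < \tau_1 < \dots < \tau_m$, and a link function turns those
outputs into distribution parameters. The package implements three such
heads, all trained by minimizing a mean negative log-likelihood:

* **Logistic-Hazard.** The discrete hazard
  $h(\tau_j \mid x) = P(T^* = \tau_j \mid T^* > \tau_{j-1}, x)$ gets a
  sigmoid link, $h_j = \text{logistic}(\phi_j)$. The negative
  log-likelihood decomposes into Bernoulli terms over the at-risk
  intervals $j \le \kappa(t_i)$ — binary cross-entropy with a single
  positive label at the event interval. Survival is the product
  $S(\tau_j \mid x) = \prod_{k \le j} (1 - h_k)$.
* **PMF.** The event-time mass $f(\tau_j \mid x)$ is a softmax over the
  network outputs augmented with a fixed zero logit; the extra class is the
  probability of surviving past $\tau_m$, so mass beyond the grid is
  explicitly allowed. Censored individuals contribute the log of the total
  mass beyond their interval (not a cross-entropy).
* **PC-Hazard.** A continuous-time model: the hazard rate is constant
  within each interval. The network parameterizes the cumulative-hazard
  increments $\tilde\eta_j = \eta_j \Delta\tau_j$ through a softplus link,
  and the exact censored-data likelihood uses the elapsed fraction
  $\rho(t) = (t - \tau_{\kappa-1}) / \Delta\tau_\kappa$ of the interval
  containing $t$. Survival is
  $\exp[-\tilde\eta_{\kappa(t)} \rho(t) - \sum_{j<\kappa(t)} \tilde\eta_j]$.

In principle the first two heads fit the same likelihood; in practice
over-parameterized networks stopped early need not land on the same answer,
which is why both are kept and compared.

## Discretization and the rounding convention

Continuous observation times must be mapped to the grid. The package uses
half-open intervals $(\tau_{j-1}, \tau_j]$ everywhere as the single
coordinate convention. Two grids are available:

* `make_equidistant_grid()`: equal-width intervals on $[0, \tau]$;
* `make_km_quantile_grid()`: cuts at quantiles of the marginal
  Kaplan-Meier estimate, so every interval carries the same drop in
  estimated survival. $\tau_j$ is the smallest observed time with
  $\hat S(t) \le \zeta_j$, $\zeta_j = 1 - j(1 - \hat S(\tau))/m$. Steep
  drops can hit several quantiles at one time; duplicate cuts are collapsed
  (with a message) rather than rejected.

For the discrete heads, an event in $(\tau_{j-1}, \tau_j]$ is moved to
$\tau_j$ and a censoring to $\tau_{j-1}$ — the convention of a study that
can only record status at visit times: a censored individual was last seen
alive at $\tau_{j-1}$, an event was first recorded at $\tau_j$. Censorings
in the first interval get index 0 and contribute nothing to the
likelihood; they are retained (with zero loss) so batch sizes stay stable.
A censoring exactly at a cut needs no rounding and keeps its index.

`discretize_labels()` therefore records *two* coordinates per individual:
the rounded index `idx` for the discrete heads, and the containing interval
`kappa` with fraction `frac` for PC-Hazard. The PC-Hazard likelihood uses
the containing interval for events and censorings alike — the exact
continuous-time likelihood — rather than the down-rounded censoring index;
rounding away the partial exposure $(\tau_{j-1}, t]$ would discard
information the continuous-time model is designed to use.

Grids are built from training data only and stored with the fitted model;
held-out durations beyond $\tau_m$ are clipped to $\tau_m$ (event status
preserved, warning emitted), since the model is only defined up to the end
of follow-up.

## Interpolation

Discrete survival estimates are step functions; on coarse grids this is a
large approximation error. `eval_survival()` offers two monotone
interpolation schemes between the stored values $s_0 = S(\tau_{\kappa-1})$
and $s_1 = S(\tau_\kappa)$:

* **CDI** (constant density): linear, $s_0 + \rho(s_1 - s_0)$;
* **CHI** (constant hazard): exponential, $s_0 (s_1/s_0)^{\rho}$,
  evaluated in log space.

Both reproduce the stored values exactly at the cuts (enforced bitwise at
$\rho = 1$). CHI applied to a PC-Hazard curve reproduces the model itself —
constant-hazard interpolation of a piecewise-constant-hazard model is an
identity the test suite checks to 1e-12. Degenerate intervals: if
$s_1 = 0$ the interval's hazard is infinite and CHI returns 0 for any
$\rho > 0$; if $s_0 = 0$ the whole interval is 0. Beyond $\tau_m$ all
schemes extend constantly at $S(\tau_m)$ — the model is silent past the end
of follow-up, and constant extension is the conservative monotone choice.

## Evaluation statistics

* **True-survival MSE** (simulated data only): mean over individuals and
  evaluation times of the squared difference to the known truth, with the
  discrete estimates represented as step functions.
* **Time-dependent concordance**: over comparable pairs — $T_i < T_j$ with
  $D_i = 1$, plus ties $T_i = T_j$ with $D_i = 1, D_j = 0$ — the fraction
  where $\hat S(T_i \mid x_i) < \hat S(T_i \mid x_j)$, with 0.5 credit for
  prediction ties. Verified against a literal double loop.
* **IPCW Brier score**: squared error at time $t$ weighted by the inverse
  censoring survival $G$, with $G(T_i{-})$ (left limit) for past events and
  $G(t)$ for individuals still at risk; $G$ is the Kaplan-Meier estimate
  with flipped indicators. Zero-weight contributions are dropped with a
  warning. The integrated score is a trapezoidal integral over 100
  equidistant points between the observed extremes, divided by the time
  span; the integration rule is a package convention (the point-average
  alternative differs only at edge spacing) and the grid is configurable.

Likelihoods on different grids are not comparable (they scale with grid
granularity), so `grid_search()` selects by validation likelihood only when
all candidates share one grid and switches to validation IBS otherwise.

## The simulator

`sample_surv_data()` draws event times from discrete per-step hazards on a
fine grid of 1,000 equidistant points over $(0, 100]$ — fine enough to act
as continuous time. The hazards are specified through their logit
$g(t \mid x)$, a softmax-weighted mixture of three components: a sinusoid
(periodic risk), a constant, and a linearly accelerating term
$\gamma_6 t - 10$. Nine affine functions $\gamma_1, \dots, \gamma_9$ drive
the components, each reading its own block of five covariates (45 total,
iid uniform on $(-1, 1)$), so amplitude, frequency, phase, levels, slope,
and the mixture weights all vary across individuals and the sampled curves
span a wide range of shapes. The default coefficients are fixed, versioned
constants (`default_gamma_spec()`); they were chosen once so that all three
components contribute visibly, and are not tuned thereafter.

Censoring is an independent constant per-step hazard; the default rate
(0.001102) was calibrated once by bisection so that a 100,000-draw sample
is about 37% censored, then frozen. Individuals reaching the end of the
grid without an event are administratively censored at $\tau_{1000}$; at a
tied step the event wins. The analytic truth
$S(\tau_j \mid x) = \prod_{k \le j}(1 - \text{logistic}(g(\tau_k \mid x)))$
is returned alongside the draws, enabling exact error measurement.

What the simulator does *not* emulate: correlated or discrete covariates,
covariate-dependent censoring, measurement error, and the heavy ties of
coarsely recorded registry data. Tests passing on this generator therefore
demonstrate correctness of the machinery and the qualitative
discretization effects, not performance claims about any particular
clinical dataset.

## Networks and training

The network is a standard MLP: per hidden layer a linear map, ReLU, then
optional batch normalization and dropout; a final linear layer emits the
$m$ logits. Forward, backward (including batch-norm backprop with biased
batch variance), Adam, and early stopping are implemented in plain R
matrix code; every gradient path is checked against central finite
differences in the test suite. Training is minibatch Adam (batch size 256)
with validation-loss early stopping; the returned parameters are those of
the best validation epoch. All randomness — initialization (He for hidden
layers), shuffling, dropout masks — flows from a single seed, so runs are
bitwise reproducible in single-threaded mode. A cyclic-restart schedule
and learning-rate range test would be natural extensions; plain Adam with
a fixed rate keeps the optimization protocol simple and deterministic and
does not change the methods under study.

`bias_only = TRUE` fits a network that ignores covariates. This is the
closed-form test vehicle: the bias-only Logistic-Hazard maximum likelihood
is $h_j = d_j / r_j$ (events over at-risk in interval $j$), i.e. the
Kaplan-Meier estimate of the discretized data, and the bias-only PC-Hazard
maximum likelihood is events over fractional exposure per interval. The
suite trains both to convergence and checks the fits against these closed
forms to 1e-3.

Defaults that matter, with the reasoning:

* `hidden = c(32, 32)`, `lr = 0.01` in `fit_surv_net()` — generic
  small-data defaults. The simulation-experiment protocol in
  `experiment_spec()` uses `hidden = c(64, 64)`, `lr = 0.005`,
  `epochs = 200`, `patience = 25`, chosen by a small search on validation
  loss at the 3,000-sample training size.
* `batch_norm = FALSE` in the experiment protocol: with plain fixed-rate
  Adam and these small covariate-standardized inputs, batch normalization
  consistently worsened validation loss and test error in our tuning runs,
  so the experiment protocol omits it. It remains available (and tested)
  as an architecture option.
* `dropout = 0` by default; 0.5 is the usual alternative in the
  hyperparameter grid.

## Numerical choices

All losses are computed from logits: Bernoulli terms via
$\log h = -\text{softplus}(-\phi)$ and $\log(1-h) = -\text{softplus}(\phi)$,
softmax terms via log-sum-exp with the appended zero logit, and
$\log \tilde\eta = \log(\text{softplus}(\phi))$ with a linear branch below
$\phi = -30$ where softplus underflows. Softplus itself uses the
overflow-safe form $\max(\phi, 0) + \log(1 + e^{-|\phi|})$. Survival
products are accumulated in log space. The PC-Hazard loss drops the
constant $d_i \log \Delta\tau_{\kappa}$ of the exact likelihood, so its
value can be negative and is comparable only within a fixed grid.

## Problem sizes

The test suite and the acceptance script run at desk scale, as the
package's own standard configuration: training sets of 3,000 (with 1,000
validation draws), uncensored test sets of 2,000 individuals scored at all
1,000 fine-grid times, 10 replications for the stochastic end-to-end
claims, and 100,000 draws for the Monte-Carlo consistency check of the
simulator. At these sizes the full suite completes in a few minutes on one
CPU.

## Known limitations

No left truncation, interval censoring, or competing risks; no
data-driven choice of the grid size $m$ (it is a hyperparameter to search);
no GPU path; the concordance implementation is $O(n^2)$ in test-set size;
and the simulator's covariate law is deliberately simple. The real-data
benchmark datasets used in the literature are distributed with third-party
packages and are outside this package's scope, though `read_survival_table()`
accepts any CSV of the standard (duration, event, covariates) shape.
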