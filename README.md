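# hazardnet

Neural time-to-event prediction built on the discrete-time survival
likelihood, for biostatisticians and epidemiologists who want flexible,
fully parametric survival curves from right-censored tabular data.

Most survival prediction still runs through the semi-parametric Cox model,
which fits awkwardly into gradient-based machine-learning frameworks.
Discrete-time survival models are fully parametric, so a neural network can
parameterize them directly. hazardnet implements the three heads built on
this idea, the time-discretization and interpolation machinery needed to
apply them to continuous-time data, the standard evaluation statistics, and
a simulator with known true survival curves for validating all of it.

## Models

With a grid 0 = τ₀ < τ₁ < … < τₘ and an MLP φ(x) ∈ ℝᵐ:

* **Logistic-Hazard** — sigmoid link on the discrete hazard
  h(τⱼ | x) = P(T\* = τⱼ | T\* > τⱼ₋₁, x) = logistic(φⱼ(x));
  the censored-data negative log-likelihood is binary cross-entropy over
  the at-risk intervals, and S(τⱼ | x) = ∏ₖ≤ⱼ (1 − hₖ).
* **PMF** — softmax over (φ₁, …, φₘ, 0) models f(τⱼ | x) = P(T\* = τⱼ | x)
  with the fixed zero logit carrying the mass of surviving past τₘ;
  censored individuals contribute log Σₖ>κ σₖ.
* **PC-Hazard** — a continuous-time model with piecewise-constant hazard:
  softplus link η̃ⱼ(x) = log(1 + exp φⱼ(x)) on the cumulative-hazard
  increments, exact likelihood
  η̃_κ^d · exp[−η̃_κ ρ(t) − Σⱼ<κ η̃ⱼ] with ρ(t) the elapsed fraction of the
  interval containing t, and S(t | x) = exp[−H(t | x)].

Around the heads: equidistant and Kaplan–Meier-quantile grids
(event times round up to the interval end, censorings down), constant-density
(piecewise-linear) and constant-hazard (piecewise-exponential) interpolation
of discrete curves, true-survival MSE, Antolini's time-dependent
concordance, the IPCW integrated Brier score, a logit-hazard mixture
simulator on a 1,000-point fine grid, and an MLP trainer (ReLU, optional
batch norm and dropout, Adam, validation-loss early stopping) written in
plain R with finite-difference-verified gradients. See
`vignettes/methods.Rmd` for the full account.

## Worked example

```r
library(hazardnet)

# 2,000 simulated individuals, ~37% censored, with known true curves
sim <- sample_surv_data(sim_config(2000), seed = 42)
#> <sim_surv> n = 2000, 38.1% censored, fine grid of 1000 points

grid <- make_km_quantile_grid(sim$data$durations, sim$data$events, 25)
fit <- fit_surv_net(sim$data, grid, head = "logistic_hazard",
                    hidden = c(64, 64), batch_norm = FALSE, lr = 0.005,
                    epochs = 200, patience = 25, seed = 1)
glance(fit)
#> # A tibble: 1 × 6
#>   head                m n_parameters epochs_trained best_epoch val_loss
#>   <chr>           <int>        <int>          <int>      <int>    <dbl>
#> 1 logistic_hazard    25         8729             30          5     2.33

# score against the simulator's analytic truth on fresh uncensored data
test <- sample_surv_data(sim_config(500, censor_rate = 0), seed = 7)
s <- predict(fit, test$data, times = test$times, scheme = "chi")
mse_true_survival(s, test$truth)
#> 0.0177
s_obs <- predict(fit, test$data, times = test$data$durations, scheme = "chi")
concordance_td(test$data$durations, test$data$events, s_obs)
#> 0.584
```

The fitted model stops after 5 epochs of improvement (30 trained, early
stopping with patience 25), and its mean squared error against the true
conditional survival curves, 0.018 averaged over 500 individuals × 1,000
time points, is well below the ≈0.021 of the covariate-free Kaplan–Meier
baseline — the network recovers individual-level structure the marginal
estimate cannot. `autoplot(fit)` draws the loss history;
`autoplot(predict(fit, test$data))` draws survival curves;
`tidy()`/`glance()` return tibbles.

A command-line interface wraps the same functions
(`exec/hazardnet simulate | fit | predict | evaluate | experiment`), with
models serialized as JSON and all tabular output as CSV.

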