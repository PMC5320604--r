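---
title: "Adaptive prediction-error coding: models, fitting, and the synthetic study"
author: "adaptivepe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive prediction-error coding: models, fitting, and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptivepe)
```

## The scientific problem

Dopaminergic prediction-error (PE) signals are thought to be *adaptively
coded*: the neural response to a PE of a given size is larger when rewards
are drawn from a low-variability distribution than from a high-variability
one, as if the PE were rescaled by the local reward spread. Behaviourally,
the same rescaling lets a learner restrain its updates when PEs fluctuate a
lot, stabilising predictions without ignoring genuine change.

`adaptivepe` implements the full computational pipeline for studying this
phenomenon with a rewarded prediction task:

1. a **task generator** - rewards drawn from six pseudo-Gaussian
   distributions crossing SD {5, 10, 15} GBP with EV {35, 65} GBP;
2. four **trial-by-trial learning models** of prediction behaviour;
3. **maximum-likelihood fitting** with AIC/BIC model comparison and a
   brute-force grid oracle;
4. **behavioural outcome statistics** (performance error, scaler
   contingency, covariate residualisation, group tests);
5. a trial-level **neural adaptive-coding analysis** - PE slopes per SD
   condition and PE sign, combined by inverse-SD contrast weights and
   compared across treatment groups with rank tests.

No participant-level data ship with the package; every analysis runs on
synthetic cohorts produced by its own generator, which makes every result
in the test suite reproducible from a seed.

## The task

Each synthetic experiment has three sessions of 62 trials. A session
interleaves two reward distributions ("pots") in alternating blocks of 4-6
trials; the two pots always differ in *both* EV and SD, and each of the six
distributions contributes exactly 31 trials per experiment. Cues signal
only the relative spread (small / medium / large), never the EV.

"Pseudo-Gaussian" is operationalised as *moment-matched* sampling: a
Gaussian sample is affinely rescaled so that its sample mean and SD equal
the nominal EV and SD exactly, redrawn if any value would leave the 0-100
GBP scale, and rounded to 0.1 GBP. Every agent therefore faces the nominal
statistics, which the behavioural metrics assume. The block schedule uses a
feasibility-constrained composition sampler so that *every* block has 4-6
trials while each pot still totals exactly 31 - naive truncation of the
last block can strand an unfillable remainder of 1-3 or 7 trials.

Incentive compatibility follows the task's payoff rules: 20% of trials
(`round(0.2 * N)` per session) are control trials paying 7.50 / 5.00 / 2.50
GBP for predictions within one SD / within two SDs / farther from the EV;
the other trials pay 10% of the drawn reward.

```{r task}
design <- generate_experiment(seed = 1)
table(design$dist_id)
control_payoff(c(37, 44, 50), 35, 5)
```

## The learning models

All four models share the delta rule
\(\mu_{n+1} = \mu_n + k_n\,\delta_n\), with \(\delta_n = r_n - \mu_n\), and
differ in the learning rate \(k_n\):

* **RW1** - constant rate \(k\);
* **RW2** - separate rates \(k_+\), \(k_-\) for positive and negative PEs;
* **PH1** - a Pearce-Hall dynamic rate,
  \(k_n = (1-\gamma)\,k_{n-1} + \gamma\,|\delta_n|/20\) (clipped to
  \([0,1]\)), initialised at \(k_1\): the rate rises after surprising
  outcomes and decays (constant \(\gamma\)) as PEs shrink, letting
  predictions stabilise under continuing noise;
* **PH2** - as PH1, but the PE entering the update is first divided by
  \(\log(\mathrm{SD})^{\nu}\). The scaling extent \(\nu \in [0,1]\) is the
  parameter of interest: \(\nu = 0\) means no scaling (PH2 reduces exactly
  to PH1), \(\nu = 1\) full log-SD scaling. Because \(\log 5 > 1\), scaling
  never amplifies a PE on this task.

One learner state is kept per distribution: the cue identifies the active
pot, so predictions for the two interleaved pots are tracked independently.
That is the only reading under which two distributions of different EV can
be predicted simultaneously.

Two numerical constants deserve comment, because the source equations leave
them open:

* **The associability reference error (20 GBP).** The Pearce-Hall drive is
  \(|\delta|\) relative to a reference PE at which the rate saturates.
  Normalising by the full 100-point scale would park the stationary rate at
  `mean(|PE|)/100` ≈ 0.05-0.15 - so sluggish that predictions cannot reach
  the EV within 31 trials and PE scaling *raises* performance error,
  inverting the behavioural effect the model family is meant to express
  (scaling and faster initial learning help performance). Typical PEs on
  this task are 5-15 GBP, so 20 GBP puts the stationary rate in the
  effective 0.2-0.6 band. The qualitative behaviour is robust to the
  precise value (we verified the scaling benefit at reference errors 12.5,
  20 and 33); it is a fixed constant, never fitted.
* **Response noise is observational.** Agents emit
  \(y_n = \mu_n + \varepsilon_n\), \(\varepsilon_n \sim N(0, \sigma^2)\),
  but the learning state updates on the latent \(\mu_n\). Letting motor
  noise feed back into the learned state turns predictions into a
  near-random walk (excursions of >10 GBP from the EV), which is neither
  what participants do nor a process the Gaussian observation likelihood
  describes. Under the observational assumption the fitted likelihood is
  correctly specified, and parameter recovery is excellent (see below).

```{r models}
m <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.7, sigma = 3)
trials <- simulate_agent(m, design, seed = 2)
head(trials[, c("session", "trial", "dist_id", "sd", "reward",
                "prediction", "pe", "payoff")])
```

## Fitting and model comparison

Predictions are modelled as \(y_m \sim N(\mu_m, \sigma^2)\). The variance
has a closed-form maximum-likelihood estimate (the mean squared residual),
so it is profiled out analytically and the optimiser searches only the unit
box of learning parameters (L-BFGS-B multi-start; Latin-hypercube starts
plus dedicated starts on the genuine boundary basins \(\nu = 0\) and
\(\gamma = 0\), and a Nelder-Mead polish because the \(|\delta|\) kink can
stall quasi-Newton steps). Each distribution's initial predicted mean is
anchored at its first observed prediction, removing an unidentifiable
initial condition. A variance floor of `1e-4` guards noiseless synthetic
input. `grid_oracle()` provides an independent brute-force check: the
optimiser must reach the best grid value to within `1e-3` nats, a contract
the test suite enforces on randomised datasets.

AIC and BIC use natural-log likelihoods, count \(\sigma\) as free (RW1: 2,
RW2: 3, PH1: 3, PH2: 4 parameters), and count only non-missed trials.
`compare_models()` reports mean pairwise criterion differences across
agents (negative favours the row model) and each agent's best model, ties
broken towards parsimony.

```{r fit}
fit <- fit_model("PH2", trials, restarts = 10, seed = 3)
fit
```

Parameter recovery at study scale (186 trials) is part of the acceptance
suite: the RW1 rate is recovered within ±0.1 in ≥90% of seeds, the PH2
scaling extent with a median error ≤0.15, scaler/non-scaler status ≥80%
correctly, and model comparison selects PH2 on cohorts PH2 generated.
Boundary estimates \(\hat\nu = 0\) are genuine maximum-likelihood outcomes;
an agent counts as a "scaler" when \(\hat\nu > 10^{-3}\).

## Behavioural statistics

*Performance error* is the mean absolute distance between predictions and
the active EV (the best possible prediction), overall and per SD condition.
The scaler/non-scaler split per treatment group is tested with a Pearson
chi-square **without** continuity correction - the only variant that
reproduces the canonical worked example (8/19 vs 2/20 non-scalers gives
\(\chi^2_{(1)} = 5.27\)):

```{r chi2}
pearson_chi2(matrix(c(8, 11, 2, 18), 2, byrow = TRUE))
```

Nuisance variables (e.g. the time between dosing and scan start, which
differs between groups) are removed by simple regression; group tests then
run on z-scored residuals. Behavioural measures use parametric tests
(one-way ANOVA, Welch t post hocs); non-normal extracted measures use
Kruskal-Wallis with rank-sum post hocs. Post hocs are restricted to placebo
versus each drug group at a Bonferroni-corrected threshold of 0.025.
`performance_regression()` regresses overall performance error on the
scaler indicator (presence/absence, not continuous \(\nu\)), \(k_1\) and
\(\gamma\), with group as a categorical covariate.

## The neural analogue

The package does not model BOLD time series. It keeps the *inferential
object* of the imaging analysis - PE regression slopes per SD condition and
PE sign, combined into a contrast and compared across groups - at the level
of trial-wise ROI summary responses:

\[ \text{response}_t = \beta_0 + \beta_v\, r_t +
   \beta_{PE}[\mathrm{sd}_t, \mathrm{sign}(\delta_t)]\,\delta_t +
   \varepsilon_t, \qquad
   \beta_{PE}[s] = \beta_{base}\Bigl(1 + a\bigl(\tfrac{5}{s}-1\bigr)\Bigr) \]

with adaptation strength \(a \in [0,1]\): at \(a = 1\) slopes are exactly
proportional to \(1/\mathrm{SD}\), at \(a = 0\) they are flat. Negative PEs
get a larger base slope than positive ones, mirroring the commonly stronger
responses to negative PEs. Slope estimation regresses the response on
outcome value and the PE *serially orthogonalised* against value, per
SD-by-sign cell (at least 5 trials per cell; zero PEs count as positive, a
deterministic convention for a measure-zero event).

The adaptive-coding contrast weights the per-SD slopes by \(1/\mathrm{SD}\),
mean-centred so a flat profile scores exactly zero and slopes that fall
with SD score positive:

```{r contrast}
round(contrast_weights(c(5, 10, 15)), 4)
slopes <- data.frame(sd = rep(c(5, 10, 15), 2),
                     pe_sign = rep(c("pos", "neg"), each = 3),
                     slope = rep(c(3, 2, 1), 2), n = 20L)
adaptive_contrast(slopes)
```

Group comparison of the contrasts is nonparametric (Kruskal-Wallis,
rank-sum post hocs at 0.025, optional covariate residualisation), plus a
one-sided signed-rank test that the placebo-group contrast exceeds zero.
Any affine-equivalent weight convention gives identical rank tests, so the
centred convention claims nothing about the scaling inside an imaging
package's internal contrast machinery.

## The synthetic cohort

`study_config()` fixes the study conditions: three groups (placebo,
sulpiride, bromocriptine) of 19 agents, 186 trials each. The per-group
generating regimes encode the direction of the reported group differences,
chosen once:

| regime | placebo | sulpiride | bromocriptine |
|---|---|---|---|
| P(nu = 0) | 0.10 | 0.40 | 0.15 |
| nu range (scalers) | 0.4-1.0 | 0.2-0.8 | 0.4-1.0 |
| k1 range | 0.5-0.9 | 0.35-0.75 | 0.45-0.85 |
| adaptation strength (mean, SD 0.1) | 0.8 | 0.15 | 0.7 |
| dose-to-scan (min, SD 12) | 150 | 160 | 145 |

gamma is Uniform(0.1, 0.5) and response noise Uniform(3, 6) GBP for all
groups. The non-scaler probabilities reflect the observed proportions
(8/19 under sulpiride, 2/20 under placebo); sulpiride's lower adaptation
strength and k1 encode its reported blunting of neural adaptive coding and
the trend-level learning-rate difference; bromocriptine is close to
placebo, matching its null effects. The dose-to-scan covariate differs
between groups so the residualisation stage has real work to do. Per-agent
seeds are derived deterministically from the study seed, so growing a
cohort never perturbs existing agents.

What the generator does **not** emulate: hemodynamics and preprocessing
artefacts, within-session non-stationarity of attention, trial-level
response-time structure, working-memory covariates, and any drug effect
beyond the parameter shifts above. Passing tests therefore demonstrate that
the pipeline recovers what its own forward model puts in - estimator
validity, power at the study's sample sizes, calibrated type-I error - not
that the pharmacological claims hold in vivo.

## Running the study end to end

```{r study, eval = FALSE}
summary <- run_study(study_config(), seed = 7, out_dir = "study_out")
```

`run_study()` writes the trial tables, per-agent fits, AIC/BIC comparison
matrices, cohort metrics, neural contrasts and a plain-text summary of every
statistic, and is byte-for-byte reproducible from its seed. Degenerate
small cohorts (an empty scaler column, a collinear regression, a sparse
slope cell) are reported as `NA` with a note rather than aborting the run;
group tests with fewer than five agents per group are flagged
under-powered.

## Numerical choices and limitations

* Currency is stored to 0.1 GBP; trials are 1-based within session; tables
  are long format, one row per trial, serialised as CSV with a fixed header.
* Missed trials (optional, default probability 0) carry no prediction,
  reward, PE or payoff, skip the model update, and are excluded from
  likelihoods and all metrics.
* The fitted \(\hat\nu\) distribution has genuine mass at the 0 boundary;
  classification uses \(\epsilon = 10^{-3}\).
* Test-suite problem sizes are chosen to characterise the estimators at the
  study's own scale: 100 agents for PH2 recovery, 50 seeds for RW1, five
  replicate cohorts of ten agents for model-selection recovery, ten
  replicate two-group cohorts (N = 19 each) for the neural pipeline's
  power, and 1000 null simulations for test calibration.
* The AIC/BIC differences reported on synthetic cohorts are not comparable
  in magnitude to values obtained from human data; only their sign
  structure (the adaptive model winning) is a stable prediction.
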