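# adaptivepe

Simulation and analysis of **adaptive prediction-error (PE) coding** in a
rewarded prediction task, for computational cognitive neuroscientists who
want a fully reproducible, parameter-recoverable version of the standard
pipeline: task generation → reinforcement-learning agents → maximum-
likelihood model fitting → behavioural group statistics → a trial-level
analogue of the fMRI adaptive-coding contrast.

## The science in brief

Participants (here: simulated agents) predict the magnitude of upcoming
rewards drawn from one of six pseudo-Gaussian distributions crossing
variability (SD £5 / £10 / £15) with expected value (EV £35 / £65); 31
trials per distribution over three sessions, two distributions per session
interleaved in blocks of 4–6 trials, 20% incentive-compatible control
trials. Prediction behaviour is modelled with four nested learning rules,
all of the delta-rule form μ' = μ + k·δ with δ = r − μ:

| model | learning rate k | free parameters |
|---|---|---|
| RW1 | constant | k, σ |
| RW2 | separate for δ ≥ 0 / δ < 0 | k₊, k₋, σ |
| PH1 | Pearce–Hall: kₙ = (1−γ)kₙ₋₁ + γ·\|δₙ\|/20 | k₁, γ, σ |
| PH2 | as PH1, update uses δ / log(SD)^ν | k₁, γ, ν, σ |

The scaling extent ν ∈ [0, 1] is the quantity of interest: ν = 0 means the
agent ignores reward variability ("non-scaler"), ν > 0 means PEs are
restrained when rewards fluctuate more. Fitting maximises the Gaussian
likelihood y ~ N(μ, σ²) with σ² profiled analytically, multi-start bounded
optimisation, a brute-force grid oracle as independent check, and AIC/BIC
model comparison.

On the neural side, synthetic ROI responses encode outcome value plus a PE
term whose slope can fall with SD; per-condition PE slopes (PE serially
orthogonalised against value, positive and negative PEs modelled
separately) are combined with mean-centred 1/SD weights into the
**adaptive-coding contrast** — exactly zero for flat slope profiles,
positive when PE coding sharpens as variability shrinks — and compared
across treatment groups (placebo, sulpiride, bromocriptine) with
Kruskal–Wallis and rank-sum post hocs at the Bonferroni-corrected 0.025
threshold.

## Worked example

```r
library(adaptivepe)

design <- generate_experiment(seed = 1)          # 186-trial task design
agent  <- model_params("PH2", k1 = 0.6, gamma = 0.3, nu = 0.7, sigma = 3)
trials <- simulate_agent(agent, design, seed = 2)
head(trials[, c("session", "trial", "dist_id", "sd", "reward",
                "prediction", "pe", "payoff")], 4)
#>   session trial  dist_id sd reward prediction    pe payoff
#> 1       1     1 EV35_SD5  5   41.5       48.0  -6.5    2.5
#> 2       1     2 EV35_SD5  5   41.3       52.5 -11.2    4.1
#> 3       1     3 EV35_SD5  5   32.7       44.9 -12.2    5.0
#> 4       1     4 EV35_SD5  5   33.7       39.5  -5.8    3.4
```

Each row is one trial: the reward drawn from the active distribution, the
agent's stated prediction, the on-screen PE (reward − prediction), and the
payoff (10% of the reward on test trials; £7.50/£5.00/£2.50 by accuracy on
control trials). Fitting the adaptive model back:

```r
fit_model("PH2", trials, restarts = 10, seed = 3)
#> PH2 fit for agent01: logLik -469.59 (M = 186), AIC 947.2, BIC 960.1
#>    k1 = 0.338, gamma = 0.391, nu = 0.700 , sigma = 3.021
```

The generating ν = 0.7 is recovered exactly to three decimals here; σ is
recovered to 0.02. Behavioural performance error (mean |prediction − EV|)
rises with SD, the task's manipulation check:

```r
round(performance_error(trials), 2)
#> overall     SD5    SD10    SD15
#>    5.18    3.91    4.86    6.76
```

The scaler contingency worked example — 8/19 non-scalers under sulpiride
versus 2/20 under placebo — gives the canonical Pearson χ² (df = 1, no
continuity correction):

```r
pearson_chi2(matrix(c(8, 11, 2, 18), 2, byrow = TRUE))
#> $statistic  5.267477
#> $df         1
#> $p_value    0.02172748
```

And the neural analogue, with adaptation strength 0.8: estimated PE slopes
fall with SD, and the inverse-SD weighted contrast is positive:

```r
gen    <- neural_gen_params(adaptation_strength = 0.8)
series <- simulate_roi_responses(trials, gen, seed = 4)
slopes <- estimate_pe_slopes(series, trials)
slopes
#>   sd pe_sign     slope  n
#> 1  5     pos 0.8384006 31
#> 2 10     pos 0.3825018 38
#> 3 15     pos 0.2889218 33
#> 4  5     neg 0.9927450 31
#> 5 10     neg 0.5112292 24
#> 6 15     neg 0.4528956 29
adaptive_contrast(slopes)
#> [1] 0.0407
```

`run_study(study_config(), seed = 7, out_dir = "study_out")` chains all of
the above for a full three-group cohort (19 agents per group) and writes
trial tables, fits, comparison matrices, behavioural and neural statistics,
and a plain-text summary, byte-for-byte reproducible from the seed. The
methods vignette (`vignettes/adaptive-pe-modelling.Rmd`) documents the
models, the numerical choices, the generator's group regimes, and what the
synthetic study can and cannot show.

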