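# ontopool

Simulation toolkit for **ontology-structured Bayesian hierarchical
meta-analysis of comorbidity-treatment interactions**.

Subgroup effects — does this drug work differently in patients with a given
comorbidity? — are notoriously hard to estimate: individual trials, and
even single-drug meta-analyses, are underpowered for treatment-covariate
interactions. If related drugs can be assumed to behave similarly in a
subgroup, a hierarchical model structured by an existing drug ontology (the
WHO-ATC classification: trials within drugs within ATC level-5 classes) can
partially pool interaction estimates across the whole network and buy
precision where it is scarcest — drugs with few or small trials.

`ontopool` is for biostatisticians and meta-analysts who want to study that
trade-off by simulation: it generates trial-level interaction estimates
over a realistic trial network, fits the full ontology-structured model and
conventional single-drug random-effects meta-analyses, and scores both on
the standard simulation-study performance measures with Monte Carlo
standard errors.

## The model

For trial *z* of drug *d* in class *c*, with observed interaction estimate
*y* and standard error *s*:

    y_zdc   ~ N(mu_zdc,  s_zdc^2)        trial estimate
    mu_zdc  ~ N(beta_dc, tau_dc^2)       between-trial variation
    beta_dc ~ N(gamma_c, sigma_c^2)      between-drug variation
    gamma_c ~ N(alpha,   zeta^2)         between-class variation

with `alpha ~ N(0, 2^2)` and independent half-normal(0, 1) priors on
`zeta`, each `sigma_c`, each `tau_dc`. The single-drug comparator is the
lowest two levels with `beta ~ N(0, 2^2)`. Inference is a collapsed
conjugate Gibbs sampler (Rcpp): trial means are integrated out, all
location parameters are drawn jointly from their exact Gaussian conditional
each sweep, and scale parameters are slice-sampled on the log scale. The
sampler is validated against a closed-form conjugate oracle and by
simulation-based calibration.

Trial-level SEs come from enrollment and comorbidity prevalence *p*:
`s = 2 / sqrt(n p (1 - p))` on a standardized outcome scale (balanced
two-arm least-squares interaction SE).

## Worked example

```r
library(ontopool)
net <- default_network()
net
#> <trial_network> 161 trials, 24 drugs, 7 classes, 210,046 participants

sc <- standard_scenarios()[["trial-high"]]
sc
#> <scenario> trial-high: SD class/drug/trial = 0.05/0.05/0.25, effect -0.10, prevalence 0.20

d   <- simulate_dataset(net, sc, seed = 1)
fit <- fit_full(d, settings = inference_settings(seed = 2))
fit
#> <ontopool_fit> full model, 64 parameters, converged: TRUE
#>    param    unit        mean         sd       q025        q975     rhat
#> 1  alpha         -0.06901114 0.05480093 -0.1722719 0.044186941 1.000394
#> 2  gamma   A10BA -0.07080048 0.08991247 -0.2452820 0.109881868 1.000355
#> ...
```

The packaged stand-in network (161 trials of 24 noninsulin glucose-lowering
drugs in 7 ATC classes; synthetic allocation matching the real aggregates)
includes taspoglutide with a single small trial — the regime where pooling
matters. Comparing the two models on the same simulated dataset:

```r
single <- fit_single(d, drug = "A10BJ07", settings = inference_settings(seed = 3))
#> taspoglutide (1 small trial):
#>   single-drug -0.491 (sd 0.782)   full model -0.095 (sd 0.109)   truth -0.086
```

The single-drug meta-analysis of one 392-participant trial is hopelessly
imprecise; the full model shrinks toward the GLP-1 class mean and lands
near the true simulated effect with a seven-fold smaller posterior SD.

Batch evaluation uses the same building blocks:

```r
cfg <- study_config(scenarios = c("all-low", "trial-high"), n_reps = 100,
                    output_dir = "study_out")
res <- run_study(cfg)
res$performance   # long table: scenario x measure x model, estimate + MCSE
```

Measures: bias, MSE, RMSE (delta-method MCSE), coverage (binomial MCSE),
relative precision `100 ((empSE_single / empSE_full)^2 - 1)` with jackknife
MCSE, and per-drug detection proportions (both / single-only / full-only /
neither).

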