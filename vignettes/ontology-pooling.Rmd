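---
title: "Ontology-structured partial pooling of comorbidity-treatment interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-structured partial pooling of comorbidity-treatment interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical guidance rarely says how well a drug works for patients with a
particular comorbidity, because single trials — and even single-drug
meta-analyses — are underpowered for treatment-covariate subgroup
interactions. If related drugs can be assumed to behave similarly in a
subgroup, a hierarchical model can borrow strength across them. The WHO
Anatomic Therapeutic Chemical (ATC) classification supplies a ready-made,
expert-curated structure for that borrowing: trials nest within drugs
(ATC level-7 codes), drugs nest within classes (ATC level-5 codes, e.g.
`A10BH`, the DPP-4 inhibitors).

`ontopool` is a simulation toolkit for studying how much that buys you. It
simulates trial-level comorbidity-treatment interaction estimates over a
network of trials with a realistic ontology structure, fits both the full
ontology-structured model and conventional single-drug random-effects
meta-analyses, and scores the two approaches on the standard
simulation-study performance measures.

## The model

Writing $y_{z,d,c}$ for the estimated interaction in trial $z$ of drug $d$
in class $c$, and $s_{z,d,c}$ for its standard error, the full model is

$$
\begin{aligned}
y_{z,d,c} &\sim N(\mu_{z,d,c},\, s_{z,d,c}^2) &\text{(trial estimate)}\\
\mu_{z,d,c} &\sim N(\beta_{d,c},\, \tau_{d,c}^2) &\text{(between-trial)}\\
\beta_{d,c} &\sim N(\gamma_c,\, \sigma_c^2) &\text{(between-drug)}\\
\gamma_c &\sim N(\alpha,\, \zeta^2) &\text{(between-class)}
\end{aligned}
$$

with priors $\alpha \sim N(0, 2^2)$ and independent half-normal$(0, 1^2)$
priors on $\zeta$, each $\sigma_c$ and each $\tau_{d,c}$. The location
prior encodes the belief that large interactions are uncommon on a
standardized scale; the half-normal scale priors are weakly informative
relative to generating values in the 0.05–0.25 range, so the model is not
handed the answer. The comparator single-drug model is the lowest two
levels applied to one drug's trials, with $\beta_{d,c} \sim N(0, 2^2)$.

One $\sigma_c$ per class and one $\tau_{d,c}$ per drug are estimated, as
the subscripts indicate. A drug represented by a single trial therefore has
its $\tau_{d,c}$ informed almost entirely by the prior — deliberately not
special-cased, because prior-dominated drug-level variances are exactly the
mechanism by which small drugs gain precision from their class.

## Data generation

`simulate_dataset()` mirrors the model: per class
$\gamma_c = \alpha_{\text{sim}} + N(0, \text{sd}_{\text{class}}^2)$, per
drug $\beta_{d,c} = \gamma_c + N(0, \text{sd}_{\text{drug}}^2)$, per trial
$\mu_z = \beta_{d,c} + N(0, \text{sd}_{\text{trial}}^2)$, and the observed
estimate $y_z = \mu_z + N(0, s_z^2)$. The overall effect
$\alpha_{\text{sim}}$ defaults to $-0.1$ standardized units — a modest but
plausibly decision-relevant subgroup difference. `standard_scenarios()`
returns the nine-scenario grid: all levels at 0.05 / 0.15 / 0.25 SD, and
each level in turn raised to 0.15 or 0.25 while the others stay at 0.05.

The trial-level SE comes from enrollment and comorbidity prevalence $p$
(default 0.20, with 0.10 and 0.50 as sensitivity values):

$$ s = \frac{2\,\sigma_y}{\sqrt{n\,p\,(1-p)}} $$

This is the least-squares SE of the arm-by-comorbidity interaction in a
balanced two-arm trial with a unit-variance outcome and 1:1 allocation: the
four design cells have sizes $np/2, np/2, n(1-p)/2, n(1-p)/2$, and
$\sum 1/n_{ij} = 4/(np(1-p))$. The test suite checks it against an
independent oracle that simulates patient-level data for such a balanced
design and reads the interaction SE off `lm()`; with exact cell counts, the
two agree to well under 2%. With Bernoulli-sampled cells the realized SE
is slightly larger (Jensen's inequality on random cell counts, noticeable
only when $np$ is a few dozen or less), which is why the oracle fixes the
design, not the outcomes. The formula lives in one replaceable function,
`interaction_se()`, so a different convention can be swapped in.

Prevalence enters only through $s$; no subgroup counts are materialized.

## The stand-in network

The packaged `default_network()` is a synthetic stand-in for the exemplar
network of 161 noninsulin glucose-lowering drug trials (24 drugs, 7 ATC
classes, 210,046 participants). The trial-level listing of the real network
is not redistributed; the stand-in reproduces the aggregates exactly and
the qualitative features the conclusions depend on: a right-skewed
trials-per-drug distribution (several single-trial drugs, a few programmes
with 14+ trials), right-skewed enrollments with a 300 floor and a handful
of cardiovascular-outcome-scale trials, classes ranging from one drug to
seven, and taspoglutide carried by a single small trial. Enrollments were
drawn log-normal (meanlog 6.6, sdlog 0.9 — median near 700 with a heavy
right tail, the shape of real phase-3 programmes) and rescaled to the exact
total. The allocation is frozen in
`inst/extdata/default_network.csv`; any real network can be supplied via
`read_network()` and flows through the whole pipeline unchanged.

Performance magnitudes that depend on the exact allocation (for example,
pooled coverage and the size of the relative-precision gain) will differ
between the stand-in and the real network; the orderings across scenarios —
where pooling helps most, and what it costs — are what the stand-in is
designed to preserve, and they are what the test suite asserts.

## Inference

The models are jointly Gaussian given their scale parameters, which makes a
collapsed conjugate Gibbs sampler natural (implemented in C++):

* the trial-level means $\mu_z$ are integrated out analytically, so the
  likelihood seen by the sampler is $y_z \sim N(\beta_d, s_z^2 + \tau_d^2)$;
* each sweep draws $(\alpha, \gamma, \beta)$ *jointly* from their exact
  multivariate-normal conditional given the scales — one precision-weighted
  message pass up the tree, then ancestral sampling back down;
* each scale parameter is updated by slice sampling on $\log(\text{SD})$
  (stepping-out with shrinkage, width 1), which is rejection-free and needs
  no tuning.

Integrating out $\mu$ removes the funnel coupling between $\tau_{d,c}$ and
the per-trial deviations that makes naive per-site Gibbs mix poorly,
especially for single-trial drugs. With the scales held fixed the location
draws are exact and i.i.d., which the engine test exploits: posteriors must
match a closed-form conjugate oracle (`fit_conjugate_oracle()`, a single
sparse precision-matrix solve over all location parameters) to 0.005 in
the mean and 2% in the SD. The decisive correctness check is
simulation-based calibration: on data generated from the model's own
priors, the 95% intervals for $\beta_{d,c}$ must cover the generating
values at the nominal rate.

Defaults are 2 chains of 5,500 iterations with 500 burn-in each (10,000
retained draws). An earlier design following the common 6,000-with-1,000-
burn-in convention was enlarged once the convergence thresholds were set at
split-chain $\widehat{R} \le 1.01$ and total ESS $\ge 400$ per reported
parameter: the slowest-mixing scale parameters needed the extra draws to
clear the ESS bar reliably. Flagged fits are never silently used;
`run_study()` counts them and aborts if more than 5% of fits are flagged.
Equal-tailed 95% intervals are used throughout. Scale parameters supplied
as exactly zero (degenerate levels) are floored at $10^{-4}$ SD — variance
$10^{-8}$, far below anything estimable here — to keep the precision
matrices well conditioned.

## Performance evaluation

Drug-level recovery is scored on bias, MSE, RMSE ($\sqrt{\text{MSE}}$, with
the delta-method MCSE $\text{MCSE}_{\text{MSE}}/(2\sqrt{\text{MSE}})$),
coverage (binomial MCSE), and relative precision
$100\,[(\text{empSE}_{\text{single}}/\text{empSE}_{\text{full}})^2 - 1]$
with a leave-one-replicate-out jackknife MCSE. Conventions worth making
explicit:

* **empSE** is the SD of the point estimates across stacked drug-replicate
  records — the `rsimsum` default — not the SD of errors. Because each
  drug-replicate has its own true value here, an errors-based variant is
  available via `errors_based = TRUE`; the default is kept for
  comparability with the standard summary-table convention.
* **Pooling** weights every drug-replicate estimate equally. Weighting by
  trials per drug would be defensible but is not the convention the
  summary tables use.
* **Detection** (`detection_classes()`) calls a drug detected in a
  replicate when its 95% interval excludes zero, and by default conditions
  on replicates whose true drug effect is $\le -0.10$ — at least as large
  as the overall effect, in the simulated direction. Both the threshold and
  the conditioning are arguments.

Comparisons are paired: the same simulated datasets are fitted by both
models, the natural workflow and the one that makes jackknife MCSEs for
between-model contrasts valid.

## Reproducibility and problem sizes

Replicate $i$ of a batch uses the deterministic child seed
$(\text{base} + 7919\,i) \bmod (2^{31}-1)$, so batches are reproducible,
order-independent and resumable by replicate index. `run_study()` writes a
manifest (seed, config hash, package version, network aggregates) alongside
its CSV artifacts.

The full study design is nine scenarios × 1,000 replicates. The package's
own checks run reduced designs chosen to keep Monte Carlo error small
relative to the quantities asserted: 250 replicates for the pooled-bias
checks (bias MCSE ≈ 0.0007 standardized units), 100 replicates for
ordering checks, 500 prior-predictive replicates (≈ 4,000 intervals) for
calibration, and shortened chains (2 × 2,800 with 300 burn-in) for fits
inside replication loops — enough for drug-level posterior means whose
Monte Carlo error is an order of magnitude below the between-replicate
spread.

## Limitations

The generator emulates trial-*level* estimates, not patient-level data:
within-trial estimation is represented only through the analytic SE, so
covariate imbalance, non-normal outcomes, missing comorbidity recording and
aggregate-only trials are outside what passing tests demonstrate. All
trials are single-comparison (drug versus placebo/usual care); network
structures with drug-drug arms, multiple interacting covariates, and
class-discordant effects (a drug truly unlike its class) are not simulated.
The stand-in network preserves aggregates and shape, not the real per-drug
allocation, so structure-dependent magnitudes should be recomputed on a
real network before being quoted.
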