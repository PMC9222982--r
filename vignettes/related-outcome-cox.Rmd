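---
title: "Incorporating related outcomes into Cox time-to-event models"
author: "roicox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incorporating related outcomes into Cox time-to-event models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roicox)
```

## The problem

Clinical cohorts increasingly record several related time-to-event
outcomes for the same patients — multifaceted endpoints of one disease
(overall survival, disease-specific survival, progression) or comorbid
events (heart failure, stroke). Conventional survival models predict one
outcome and ignore the rest. `roicox` implements a family of Cox
proportional hazards models in which a *compatible related outcome* (the
"auxiliary" outcome) is folded into the training loss to improve
prediction of the primary outcome, while prediction for a new patient
requires only the features: the auxiliary outcome is a training-time
device, never a test-time input.

Four models are provided, all built on the same partial-likelihood core:

* **CPH** — linear Cox model with an L2 penalty (weight
  $\lambda_1 = 10^{-4}$) on coefficients and bias.
* **CPH_ROI** — two linear Cox objectives, one per outcome, sharing a
  single bias $b$, combined as
  $(1-\lambda)\,\ell(\beta_1, b) + \lambda\,\ell(\beta_2, b)$ with
  $\lambda = 0.2$ by default.
* **CPH_DL** — a multilayer perceptron feature extractor $F$
  (100 units, dropout 0.5, 50 units, dropout 0.5, rectified-linear) with
  a Cox regression head on the embedding.
* **CPH_DL_ROI** — the same extractor feeding two Cox heads (one per
  outcome) that share a bias, trained on the weighted joint loss.

Each single-outcome objective is the negative log partial likelihood

$$
\ell(\beta, b) \;=\;
-\sum_{i:\,e_i = 1}\Big[h(x_i) - \log\!\!\sum_{j \in R(T_i)}\!\! e^{h(x_j)}\Big]
\;+\; \lambda_1\lVert \beta, b\rVert_2^2,
\qquad h(x) = \beta^\top x + b,
$$

with risk set $R(T_i) = \{j : t_j \ge t_i\}$ and the Breslow convention
for tied event times (tied events share one denominator). The log-sum-exp
is stabilized by shifting $h$ by its maximum.

## The shared bias, honestly

The only parameter the two linear objectives share is the bias $b$, and an
intercept cancels between the numerator and denominator of every partial
likelihood term. Its gradient therefore reduces to the penalty gradient
$2\lambda_1 b$, so the penalized optimum always has $b \approx 0$ (the
package asserts $|b| < 10^{-3}$ in its tests rather than "fixing" this).
A consequence worth stating plainly: at a converged optimum the primary
coefficients $\beta_1$ of the linear joint model solve exactly the same
problem as the plain CPH fit — the linear CPH_ROI and CPH models coincide
in their predictions up to optimizer tolerance, for any $\lambda$. The
package implements the joint objective verbatim and documents this
observation; any genuine coupling between the outcomes requires shared
capacity beyond the bias, as in the deep variant, whose two heads are
coupled through the common feature extractor $F$ that both gradients
shape. Whether that coupling improves the primary prediction depends on
the data; under the synthetic generator below, where the cohort already
carries a strong linear signal, the shipped benchmark finds the joint
variants matching rather than beating their single-outcome counterparts.

## Evaluation

Performance is Harrell's concordance index with the censored-earlier
discard rule: a pair contributes only if the patient with the earlier time
had an observed event (an event tied in time with a censoring counts as
earlier; two events tied in time are not compared). Concordant pairs score
1, score ties 0.5. `concordanceIndex()` returns the full pair counts;
1.0 is a perfect ranking and 0.5 is chance.

Model comparisons across tasks use the one-sided Wilcoxon signed-rank
test (`pairedModelComparison()`). Zero differences are dropped before
ranking. For $n \le 25$ nonzero differences the exact distribution of the
signed-rank statistic is computed by dynamic programming over doubled
midranks — exact even under rank ties, where the classical exact formula
(and `stats::wilcox.test`) falls back to an approximation; above 25 the
normal approximation with continuity and tie corrections is used.

## The synthetic-data generator

`generateSurvivalData()` emulates a high-dimensional cohort with two
related outcomes: $M = 300$ patients, $p = 150$ features drawn uniformly
on $[-1, 1]$; primary coefficients $\beta \sim U(-1, 1)$; auxiliary
coefficients $\beta' = \beta + \xi$ with $\xi \sim U(0, 1)$ per
coordinate, redrawn until $\mathrm{cor}(\beta, \beta') \ge 0.8$ (with
these supports the correlation is about 0.89 in expectation, so redraws
are rare). Event times follow an exponential Cox model,
$T_i = E_i / \exp(\beta^\top x_i)$ with $E_i$ exponential of mean 3000
days — proportional hazards with constant baseline rate $1/3000$ — drawn
independently per outcome. An administrative "end-of-study" cutoff at the
200th smallest latent time per outcome yields exactly 200 events and 100
patients censored at the cutoff. The two outcomes are related only through
the shared features and the correlated coefficients.

The generator choices the underlying description leaves open were fixed
once: the base support of $\beta$ is $U(-1,1)$; censored subjects are
assigned the cutoff time itself; the exponential draws are independent
between outcomes. What the simulation does **not** emulate: feature
correlation structure and heavy tails of real omics panels, missingness,
non-proportional hazards, informative censoring, and outcome pairs whose
relation is nonlinear. Passing the synthetic benchmark therefore shows the
machinery is correct under the stated generative model, not that the same
ranking of models holds on any particular clinical dataset.

## The experiment protocol

`runTask()` reproduces the evaluation protocol: stratified ten-fold
cross-validation (folds balanced on primary event status to within one
patient per class), per-fold feature standardization fit on the training
portion only (population-variance convention; a `"global"` switch exists
for the alternative reading, and the default avoids leakage), model
fitting on the training fold — joint models see auxiliary outcomes of
training patients only — and concordance on the held-out fold scored from
features alone. One C-index per task is the mean over fold-level
C-indices (the median is also reported); fold scores are not pooled.
A master seed deterministically derives the fold seed and one
initialization seed per model per fold.

Preprocessing operators for real tabular data mirror common omics
practice: `filterMissing()` (drop records with more than 20% missing
features, then drop incomplete features), `selectTopMad()` (top-$k$
unsupervised selection by mean absolute deviation, ties to the lower
index), and `qcTask()` (at least 50 patients, at least 20 events,
event-to-censored ratio at least 0.2, with $E/C = \infty$ when nothing is
censored). The additional published filter — dropping tasks whose baseline
CPH C-index is below 0.6 — needs a fitted model, so it is applied on CV
reports (`meanCIndex()`), not inside `qcTask()`.

## Numerical choices

* **Linear optimizer**: L-BFGS-B on the analytic gradient, projected
  gradient tolerance $10^{-6}$, at most 2000 iterations; coefficients
  initialized uniformly on $[-0.01, 0.01]$ from a stated seed, bias at 0.
  Non-convergence is a diagnostic flag, not an error. Fits are
  deterministic given seed and data.
* **Deep training**: full-batch Adam (step $10^{-3}$, 200 epochs by
  default). Full-batch because the partial likelihood's risk sets are only
  exact over the whole cohort; no early stopping or internal validation
  split — dropout and the L2 term are the regularizers. Weights use
  fan-in-scaled uniform initialization; the auxiliary head is initialized
  after all shared parameters so that a $\lambda = 0$ joint run consumes
  the shared parameters' random stream identically to a plain run.
  Training is bitwise reproducible given the seed.
* **Degenerate inputs**: zero events, all-events-at-one-time data, zero
  permissible pairs, and all-zero paired differences raise classed errors;
  zero-variance features standardize to zero rather than dividing by zero;
  a test fold with no permissible pairs is skipped with a warning and
  recorded as `NA`.
* **$\lambda_1$ for joint and deep fits**: the published value $10^{-4}$
  is stated for the linear baseline only; the package reuses it everywhere
  for consistency.

## Problem sizes in the shipped tests

The test suite validates the likelihood and concordance against
brute-force enumeration at $n \le 8$, the fitters against an independent
damped-Newton oracle and `survival::coxph` at small $n$, and runs the full
simulation benchmark at its native size (300 patients, 150 features,
ten folds, all four models) over ten generator seeds in both outcome
directions — the sizes the study conditions specify.

## Limitations

Only right-censored data with Breslow tie handling are supported; there is
no Efron correction, baseline-hazard or survival-curve estimation,
time-dependent covariates, competing-risks machinery, or IPCW-corrected
concordance. The deep extractor architecture is fixed to the published
100/50 design (widths and dropout are configurable, but no architecture
search is provided). Real-data cohort assembly (e.g. from public cancer or
sleep-study repositories) is out of scope; `readSurvivalCsv()` defines the
expected tabular interchange format.
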