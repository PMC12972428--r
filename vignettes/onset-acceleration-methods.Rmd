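---
title: "Modelling onset acceleration of age-associated disease with onsetrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling onset acceleration of age-associated disease with onsetrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetrisk)
```

## The model

`onsetrisk` treats ageing as a multi-task survival problem. For each of
$D$ disease conditions, an individual with traits $x_i$ has a
condition-specific log-risk $h^d(x_i)$, and the age at first diagnosis
$T^d_i$ follows a proportional-hazards law with **birth as the temporal
baseline**. Using birth rather than assessment time means the score
measures *onset acceleration* — how much earlier in life a condition is
expected to arrive — rather than short-term risk after a clinic visit.
Higher $h^d$ means earlier expected onset.

The network is trained by minimizing the multi-condition negative Cox
partial log-likelihood with weight decay,

$$
g^d(\theta) = -\frac{1}{N_{E^d=1}} \sum_{i:E^d_i=1}
  \Big( h^d_\theta(x_i) - \log \!\! \sum_{j \in R^d(T^d_i)} \!\!
  e^{h^d_\theta(x_j)} \Big),
\qquad
l(\theta) = \frac{1}{|D|} \sum_d g^d(\theta)
  + \lambda \lVert \theta \rVert_2^2,
$$

with risk set $R^d(t) = \{i : T^d_i \ge t\}$. The risk-set definition
uses $\ge$, i.e. Breslow handling of tied event times — chosen because
it is exactly the set form written above, and because the synthetic
cohorts can produce whole-year ties when diagnosis-date granularity is
emulated (`round_ages`). Efron weighting is available for the
prognostic module, where times are on the months scale.

Architecturally, each of the five trait groups (demographics `demog`,
basic body `bb`, summary body composition `bbc`, spatial body
composition `sbc`, blood biomarkers `blood`) has its own fully
connected encoder producing a $k$-vector; the encodings are
concatenated and a shared head emits one scalar log-risk per condition.
Sharing the representation across conditions lets sparse outcomes
borrow strength from common ones. Encoder depth/width, $k$, dropout and
the activation are configurable (`arch_config()`); the `identity`
activation yields an exactly linear model, which doubles as an analytic
reference in the saliency tests.

### Numerical choices

* The log-sum-exp in $g^d$ is stabilized by a max shift; the partial
  likelihood is invariant to constant shifts of $h$ (tested to 1e-10).
* Training uses mini-batch Adam; the partial likelihood is evaluated
  *within* mini-batches, the standard deep-survival approximation to
  the full-cohort likelihood. Conditions without events in a mini-batch
  are skipped with a warning (unavoidable once data are batched).
* Weight decay enters as the explicit penalty $\lambda\lVert\theta\rVert^2$
  whose gradient $2\lambda\theta$ joins the loss gradient — not as
  decoupled decay — so the optimizer minimizes exactly the stated
  objective.
* The best epoch is chosen on the validation objective with early
  stopping; a non-finite loss aborts with diagnostics rather than
  continuing silently.

### Evaluation

Discrimination is measured by Harrell's concordance index: among
comparable pairs, the fraction where the higher predicted risk has the
earlier event (score ties count one half; tied event times with two
events are excluded, and an event tied with a censoring time is
comparable). For large cohorts the C-index is computed in seeded
batches (default 2048) and the concordant / tied / comparable *counts*
are summed across batches before the final ratio. Count-summing was
chosen over averaging per-batch ratios because it degrades gracefully:
with `batch_size >= n` it reproduces the exact statistic bit-for-bit.
Both behaviours are available (`aggregate =`).

## The synthetic cohort generator

No individual-level data ships with the package; the generator is the
test bed, and its defaults are the study conditions for every check in
the test suite and the acceptance script.

Latent factors $z_i \sim N(0, I)$ induce disease clusters: every
condition maps to one factor, and traits load on factors with loadings
drawn from `trait_loading_range` (default 0.3–0.8) plus independent
noise. True log-risk is $\eta_{i,d} = w_d \cdot x_i + \gamma
z_{i,c(d)}$, and onset ages follow a Weibull proportional-hazards law,
inverted analytically:

$$ T = \big( -\ln U / (\lambda_0 e^{\eta}) \big)^{1/\kappa}. $$

Weibull PH was chosen because it satisfies the proportional-hazards
assumption *exactly*, making it the correct null for Schoenfeld
calibration and a fair recovery target for any Cox-based method.
Default parameters, with reasoning:

* `weibull_shape = 4` — a sharply age-increasing hazard, the typical
  shape for age-associated incidence.
* `weibull_scale = log(2) / 70^4` — baseline median onset 70 years.
* `censor_age = 80` — fixed administrative censoring, mimicking a
  registry cut-off; events after 80 are censored at 80.
* `assessment_age_range = c(45, 70)` and a blood-draw offset of about
  11 years before assessment, reflecting the typical gap between serum
  sampling and imaging in large biobank cohorts.
* `statin_fraction = 0.2` — roughly the fraction of statin users
  reported in the imaging-cohort literature; the flag is independent of
  risk, which suffices for exercising the exclusion plumbing.
* `n_conditions = 12` by default, scalable to 47; three latent factors
  in round-robin assignment.
* Spatial (`sbc`) traits are smooth per-tissue profiles over
  `sbc_slices` (default 370) vertical slices: a factor loading times a
  Gaussian bump plus noise.

What the generator does **not** emulate: real marginal trait
distributions, disease prevalences, informative censoring, missingness
mechanisms, competing risks (notably death before diagnosis), or
imaging artefacts. Passing tests therefore certify the *machinery* —
estimation, ranking, clustering, calibration — under a faithful PH
world, not epidemiological validity on any real cohort.

Pre-baseline diagnoses need no separate mechanism: they arise whenever
the simulated onset precedes the assessment age, exactly the situation
the prognostic module must filter out.

## Preprocessing, splits, leakage

Continuous variables are z-scored with mean/SD computed **from the
train-val rows only** (denominator $n-1$; the convention is stated
because nothing forces it); sex is one-hot encoded; each
non-demographic block is concatenated with its z-scored
measurement-age companions. Quartile bins (below) are likewise fitted
on train-val only. The test suite asserts both guards by mutating test
rows and recomputing.

Splits: individuals from the designated external center form the
external test set; the rest are split into train-val and internal test
by a seeded draw, and train-val into five folds. Fold assignment is an
unstratified seeded draw — stratification was considered and rejected
as an unforced addition.

## Risk quartiles and stratification

Scores are discretized with sex- and condition-specific quartile cut
points fitted on train-val. Binning is left-closed with ties to the
lower bin; a score equal to a cut point stays below it, and a fully
degenerate score distribution maps everyone to bin 1 with a warning.
Within train-val each (sex, condition) cell is balanced to 25% per
quartile up to one individual. A two-bin (median) variant supports the
binarized sensitivity analysis. Kaplan-Meier curves per quartile with
$k$-group log-rank tests quantify stratification; KM curves from birth
are computed without delayed-entry adjustment, matching the risk-set
definition $R^d(t) = \{i: T^d_i \ge t\}$.

## Inter-condition correlation clustering

Conditions with internal-test C-index $\ge 0.6$ (inclusive) are
retained. Pearson's $r$ is computed between the integer quartile
vectors of every retained pair — on quartiles, not raw scores, out of
fidelity to the stated method despite the discreteness — with statin
users excluded by default. Two-tailed p-values come from the
t-transform by default; a permutation scheme is available because the
choice is not forced. The Bonferroni family defaults to the **full
matrix entry count** (retained$^2$, diagonal included): for 38
conditions that is 1444 tests and a per-test level of 3.46e-5, the
combination that makes the printed numbers self-consistent.
Non-significant entries are zeroed, rows of the masked matrix are
compared by cosine distance, and UPGMA (average linkage) produces the
dendrogram; an all-zero row is an error naming the condition, since
its cosine direction is undefined. Edges with masked $r \ge 0.3$
export to a graph table.

## Prognostic pair models

For each (input A, outcome B) pair, a conventional adjusted Cox model
is fitted from the **assessment** baseline in months: exposure is the
risk quartile of A (Q1 reference; or the median split), time runs to
the first post-baseline diagnosis of B censored at 120 months,
individuals already diagnosed with B at baseline are excluded (the
same rule on the diagonal A = B), outcomes with more than 75% of
events in one sex keep the dominant sex only, and pairs with fewer
than 50 post-baseline events are skipped with a logged reason.
Primary adjustment uses demographic covariates; secondary adds basic
body covariates as a robustness probe. Ties use Efron weighting
(months-scale data have moderate ties); Breslow is a flag.
Proportional hazards are checked with scaled Schoenfeld residuals
against the Kaplan-Meier time transform (the common modern default;
identity and rank transforms available). Because the intended
multiplicity family for pair-level Bonferroni correction is an
analysis choice that cannot be derived from the pair count alone, the
family size is an explicit argument, and both the planned-fit count
and the user-declared family are reported.

## Saliency

Input importance is the mean over individuals of the absolute partial
derivative of each condition output with respect to each network
input, computed in evaluation mode against the standardized inputs the
network actually receives (gradients with respect to raw units would
conflate importance with measurement scale). One-hot indicators are
differentiated like any other column. Univariate traits and spatial
profiles are normalized separately, by the scope maximum by default
(sum-normalization available); normalization is monotone, so top-k
rankings are unaffected. Cross-condition summaries average the
normalized maps — averaging raw maps then normalizing is a different
summary, and the default is documented rather than silently chosen.
Sex-specific maps restrict the averaging population without
retraining.

## Problem sizes used in validation

The bundled checks run at sizes chosen to make every property sharp
yet quick on a laptop: oracle equivalence on instances of up to 20
rows against brute-force enumeration; batched-vs-exact concordance at
n = 4096; model recovery on n = 5000 with 10 traits and 3 conditions
(trained scores reach Spearman > 0.9 against the true log-risk and
C-index within 0.05 of the oracle ceiling); cluster recovery on
n = 8000 with 12 conditions and 3 latent factors (Rand index 1.0);
Schoenfeld and log-rank type-I calibration over 500 replicates under
exact PH nulls; hazard-ratio recovery of a planted threefold Q4 effect
at n = 5000; and saliency faithfulness over five seeds with 3
informative of 20 independent traits. The same computations are
re-run from scratch by `scripts/acceptance.R`.

## Known limitations

* The partial likelihood is approximated within mini-batches; very
  rare conditions may see few events per batch. Increasing
  `batch_size` tightens the approximation.
* No competing-risk correction: death before diagnosis is treated as
  censoring for every non-mortality condition.
* No time-varying covariates or interval censoring.
* Prognostic fits are association, not causation; the package makes no
  causal claims and exposes no tooling that suggests otherwise.
```{r session}
sessionInfo()
```
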