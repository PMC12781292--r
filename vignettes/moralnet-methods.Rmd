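---
title: "Methods: dose-response and network analysis of moral distress and compassion fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response and network analysis of moral distress and compassion fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralnet)
```

## The problem

Moral distress (MD) — the anguish of knowing the ethically right action but
being constrained from taking it — is endemic in intensive-care nursing, and
compassion fatigue (CF) — the combination of burnout, secondary traumatic
stress (STS) and eroded compassion satisfaction — is one of its suspected
drivers. `moralnet` implements the two complementary analyses used to study
this link in cross-sectional nurse cohorts:

1. a **dose-response analysis**: how does expected MD change across the CF
   range, and is the relationship nonlinear?
2. a **symptom-network analysis**: treating each questionnaire item as a
   binary symptom, which CF symptoms *bridge* into the MD symptom cluster,
   and which of them would — according to simulated interventions on the
   fitted network — most reduce moral distress if alleviated?

Because item-level survey data of this kind are rarely public, the package
ships a synthetic-cohort generator that reproduces the statistical structure
the analyses assume, so every stage is testable end to end.

## Instruments and scoring

The 30-item ProQOL contributes three 10-item subscales (CS, BO, STS), each
item rated 1–5. BO and STS are summed raw; CS items are reverse-scored
(`6 − x`) so that all three components point toward depletion, and
`cf_total = bo_sum + sts_sum + cs_reversed_sum` ranges 30–150. The 22-item
MDS-R rates each morally distressing situation for frequency (0–4) and
intensity (0–4); `md_total` is the sum of the per-item products, range
0–352.

```{r scoring}
score_proqol_cf(rep(1, 30))
score_mdsr(rep(4, 22), rep(4, 22))
```

For the network, items are dichotomized into present/absent symptoms: an
MDS-R item is present unless its frequency × intensity product is zero; a
ProQOL item is present unless the raw response is 1 ("never"). We apply the
ProQOL rule to the raw administered response for every item, including the
reverse-scored CS items, because the rule is stated in terms of the
response anchors; `dichotomize_cf(on_reversed = TRUE)` exposes the
alternative. The exact ProQOL item order is licensed and varies by
translation, so the item→subscale map is configurable
(`proqol_subscale_map()`); the default orders the composite CS (CF1–CF10),
BO (CF11–CF20), STS (CF21–CF30), and node labels follow positions in that
composite, MD1–MD22 then CF1–CF30.

## Dose-response: restricted cubic splines

`fit_rcs_model()` regresses MD on a 4-knot restricted cubic spline of CF by
ordinary least squares — unadjusted ("Model 1") or with dummy-coded
categorical covariates ("Model 2", first category as reference). Knots sit
at the (0.05, 0.35, 0.65, 0.95) sample quantiles of **CF** (the exposure;
placing them on the outcome would not make sense for a regression
smoother). With knots $t_1<t_2<t_3<t_4$ the basis is $x$ plus two nonlinear
truncated-power terms

$$S_j(x) = \frac{(x-t_j)_+^3 - (x-t_3)_+^3\,\tfrac{t_4-t_j}{t_4-t_3}
  + (x-t_4)_+^3\,\tfrac{t_3-t_j}{t_4-t_3}}{(t_4-t_1)^2},\qquad j = 1,2,$$

which vanish below $t_1$ and keep the function linear beyond $t_4$; the
$(t_4-t_1)^2$ scaling keeps all three coefficients on comparable scales.

Inference choices:

* **Nonlinearity**: joint F-test of the two nonlinear coefficients against
  the nested linear model, $F(2,\ \text{residual df})$.
* **Total effect**: the interquartile contrast — predicted MD at the 75th
  minus the 25th CF percentile, covariates at reference — with a
  delta-method SE and a z-based Wald interval ($\pm 1.96\,\mathrm{SE}$).
  The z convention is used throughout because it reproduces the style of
  interval printed in applied reports to two decimals.
* **Standardized fits** z-score both MD and CF before basis construction.
* **Prediction curves** are pointwise Wald bands from the coefficient
  covariance; they widen where CF data are sparse.

```{r rcs}
cohort <- simulate_dose_response_cohort(cohort_spec(), seed = 11)
fit <- fit_rcs_model(cohort, "md_total", "cf_total")
fit
total_effect(fit)
```

Two sample-size utilities mirror the planning stage of such studies:
`required_sample_size_f2()` scans $n$ upward until the noncentral-F power
of the overall regression test ($\lambda = f^2 n$, $df_1 = p$,
$df_2 = n-p-1$) reaches the target, and `heuristic_network_n()` applies the
10-participants-per-node rule with attrition inflation.

```{r power}
required_sample_size_f2(f2 = 0.10, alpha = 0.05, power = 0.95, n_predictors = 10)
heuristic_network_n(52)
```

## The Ising symptom network

The 52 binary symptoms are modelled with a `{0,1}`-domain Ising model:
$P(x) \propto \exp\!\big(\sum_i \tau_i x_i + \sum_{i<j} \omega_{ij} x_i x_j\big)$,
whose node-conditionals are logistic regressions with intercepts $\tau$
(thresholds) and coefficients $\omega$ (couplings). We use the 0/1 domain
(not ±1) because the dichotomization rules and the intercept-perturbation
interventions are native to it.

**Estimation** (`estimate_ising()`) is nodewise L1-penalized logistic
regression (eLasso): each node on all others along a 100-value log-spaced
penalty path (from the max-penalty null down to 1% of it), per-node penalty
chosen by the extended BIC with $\gamma = 0.25$, and AND-rule
symmetrization — an edge is kept only when both directed coefficients are
nonzero, with the mean as its weight. The OR rule and a plain
maximum-pseudo-likelihood mode (for small dense problems) are available via
`ising_config()`. These estimator settings are documented package defaults;
correctness is defined by parameter-recovery tests on planted models, not
by replicating any particular published network.

**Sampling** (`sample_ising()`) runs one independent single-site
Metropolis-within-Gibbs chain per observation: uniform random start, then
100 full sequential sweeps drawing each node from its conditional. Fresh
chains per observation make the observations independent, which the
downstream t-tests require. The sampler is compiled code with incremental
local-field updates, so large simulation batches are cheap.
`exact_distribution()` enumerates models up to 20 nodes and anchors the
sampler (and the intervention logic) in tests.

## Bridge centrality

`bridge_indices()` scores every node's connection to the *other* community:
strength (sum of |cross-weights|), expected influence (signed sum),
closeness (reciprocal mean geodesic distance to the other community) and
betweenness (frequency as an interior node on cross-community geodesics).
Geodesics use edge length $1/|\omega|$, the standard convention for
association networks; unreachable targets are skipped (a fully disconnected
node scores 0) and tied geodesics split betweenness credit equally, with
endpoints never counted as intermediates.

## Stability of centrality

`case_drop_bootstrap()` re-estimates the network and its bridge indices on
row subsamples, dropping 5%–75% of cases in 5% steps (500 subsamples per
fraction by default), and correlates each subsample's index vector with the
full-sample one (Spearman by default; Pearson available — note that rank
correlation over few nodes is granular). The CS coefficient is the largest
drop fraction at which ≥95% of subsamples stay at correlation ≥0.7;
`interpret_cs()` labels it strong (> 0.5), acceptable (0.25–0.5) or poor
(< 0.25), with boundary values 0.25 and 0.5 both "acceptable".

## Simulated interventions (threshold perturbation)

`run_scenarios()` implements the in-silico intervention logic: for each CF
node, shift its threshold by $\pm k \cdot s$ where $s$ is the sample SD
(n−1 denominator) of *all* thresholds and $k = 2$ by default — alleviating
lowers the threshold, aggravating raises it — then simulate 5,000
observations per scenario (one baseline + one per CF node; 31 scenarios per
direction for a 30-node CF community) and record each observation's MD sum
score. `compare_to_baseline()` runs Welch two-sample t-tests of every
scenario against baseline on the per-observation sums (the only formulation
with well-defined degrees of freedom) with Benjamini–Hochberg correction
applied within each direction separately, and `identify_core_targets()`
ranks the significant scenarios by |change in mean MD|.

One Ising-model subtlety surfaced while validating this machinery: because
couplings are symmetric, a bridge node with strong cross-edges receives
strong feedback *from* the nodes it drives. If that feedback saturates it
(activation probability near 1), a 2-SD threshold shift cannot move it and
the intervention silently does nothing. Effective alleviating targets are
symptoms that are prevalent but not saturated; the package's recovery tests
construct their ground-truth networks accordingly.

## The synthetic cohort generator

`simulate_dose_response_cohort()` emulates the features the dose-response
analysis relies on: CF totals from a truncated normal matched to a typical
cohort (median 82, SD backed out of an IQR of 24, range 35–139 — real CF
totals are not normal, but a truncated normal suffices to exercise the
spline); MD from a 4-parameter logistic curve of CF (lower plateau 25,
upper plateau 110, midpoint 75, scale 8 — a saturating shape that rises
sharply for CF ≈ 60–90 and flattens at both extremes), plus additive
covariate shifts and Gaussian noise (SD 15, a residual spread that leaves
the curve clearly visible but far from deterministic), truncated to
[0, 352]. Covariates are drawn independently from realistic ICU-nursing
marginals (88.4% female, mostly under 40, mostly undergraduate-educated);
only gender carries a nonzero default MD shift (−8 for male respondents),
reflecting that gender is typically the only significant demographic
covariate in this literature. A `curve = "linear"` option provides the
exact null of the nonlinearity test for size studies.

What the generator does **not** emulate: dependence between covariates
(only marginals are modelled), measurement error in the instruments,
item-level ordinal structure beyond what the dichotomization inverse
requires, and any particular study's empirical coefficients. Passing
recovery tests on these cohorts therefore demonstrates that the estimators
recover the structures they target under the stated generative assumptions
— not that any specific published estimate is reproduced.

`make_ground_truth_ising()` plants a two-community network with explicit
cross-community bridge edges, and `synthesize_item_responses()` inverts the
dichotomization rules (round-trip exact by construction), so the whole
scoring → network → intervention pipeline runs against known ground truth.

## Numerical choices and degenerate inputs

* Quantiles (knots, interquartile contrasts) use R's default type-7
  interpolation.
* Out-of-range or missing item responses, zero-variance nodes, collinear
  covariate dummies, non-increasing knots, and empty prediction grids all
  raise informative errors rather than producing silent output.
* A degenerate threshold vector (all equal) makes the ±k·SD perturbation
  undefined and errors.
* Ranking ties (equal centrality, equal |delta|) break by node label so
  every ordering is deterministic.
* All stochastic stages take explicit integer seeds; scenario sub-seeds are
  derived deterministically from the stage seed.

## Problem sizes used by the test suite

The suite favours small, exactly checkable problems: enumeration oracles up
to 12 nodes (5,000 sampled observations), eLasso recovery on 6–10 node
networks at n = 1,000–2,000, a 1,000-replicate size study of the
nonlinearity F-test at n = 645, a stability bootstrap on a 12-node planted
network at n = 1,000 (40 subsamples per drop fraction), and one full
52-node intervention run at 5,000 observations per scenario. These sizes
keep each property sharp enough to fail loudly while the whole suite runs
in well under two minutes.

## Limitations

Cross-sectional Ising networks are associational; the intervention
simulations explore the *fitted* model's behaviour, not causal effects in
nurses. The AND rule is conservative and can drop weak true bridges; the
eLasso thresholds absorb unmodelled heterogeneity. The generator's
independence assumptions (between covariates, and between observations)
are idealizations. None of the package's outputs should be read as
reproducing any specific cohort's estimates.
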