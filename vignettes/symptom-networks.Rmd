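---
title: "Symptom networks for antidepressant trials: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks for antidepressant trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrinet)
```

## The problem

Antidepressant trials conventionally compare arms on a *sum score* over the 17
interviewer-rated items of a depression rating scale. Item-level analysis is
more informative: the arm difference on one symptom may be a genuinely direct
pharmacological effect, or may be transmitted through the symptom's
correlations with other, directly affected symptoms. `ssrinet` implements the
network approach to this decomposition: at each assessment week, a **mixed
graphical model** is estimated over 18 nodes — the binary treatment indicator
plus the 17 symptom items — and

* **direct effects** are the treatment–symptom edges: the arm difference on a
  symptom *conditional on all other symptoms*;
* **indirect effects** are treatment-related change transmitted through
  symptom–symptom edges, summarized descriptively by two-path edge products;
* **overall effects** are the unconditional arm differences (Cohen's *d*),
  estimated in a parallel classical track for comparison.

## The estimator

The network is estimated by nodewise neighborhood regression. Each symptom
node is regressed on all other nodes with an L1 (lasso) penalty,

$$\min_{\beta_0, \beta}\; \frac{1}{2n}\sum_i\big(y_i - \beta_0 - x_i^\top\beta\big)^2 + \lambda \lVert\beta\rVert_1,$$

and the binary treatment node by the penalized logistic analogue (mean
negative log-likelihood plus the same penalty). Per node, $\lambda$ is chosen
by 10-fold cross-validation (held-out mean squared error, or mean deviance for
the treatment node); the loss-minimizing $\lambda$ is the default, with ties
broken toward the sparser model, and a 1-SE policy available
(`lambda_policy = "1se"`). Full-data refits at the selected penalties are
aggregated into an undirected network: under the default **AND rule** an edge
is kept only when both of the pair's nodewise coefficients are nonzero, and
its magnitude is the mean of their absolute values. The conservative AND rule
matches the regularized-network convention of setting very weak connections
exactly to zero.

Coefficient solutions come from a coordinate-descent solver written for this
package (compiled via Rcpp). Gaussian problems are solved in covariance form
— after centering, each coordinate update costs $O(p)$ — and the logistic node
by IRLS with active-set coordinate descent on the weighted subproblem. The
**subgradient (KKT) certificate** is the solver's contract: every returned
fit satisfies $|g_j| \le \lambda$ for zero coefficients and
$g_j = -\operatorname{sign}(\beta_j)\lambda$ for active ones, to $10^{-6}$
(`kkt_check()`), which the test suite verifies against random instances,
brute-force objective search, least squares at $\lambda = 0$, and an
independent implementation (glmnet).

Scaling convention: continuous columns are standardized once (unit SD,
denominator $n-1$); the treatment column stays on its 0/1 coding, so
treatment–symptom edges are in per-SD-of-symptom units. A consequence worth
knowing: in coefficient units the 0/1 column is penalized harder than a
unit-SD column by the factor $1/\operatorname{var}(\text{arm}) \approx 4.6$
at a 0.69/0.31 allocation, which is what makes small treatment edges (|w|
around 0.1) the detection-boundary cases discussed below.

## The synthetic-trial generator

The original patient-level data are industry-held, so the package ships a
generator (`make_ground_truth()` + `simulate_trial()`) that emulates the
study's structure; it is first-class, tested code, and every downstream stage
is exercised on it.

Per patient: arm ~ Bernoulli(0.686) (the analyzed 5424/2485 allocation), a
trial stratum out of 28 with a Normal(0, 0.1²) severity intercept, age ~
Normal(44, 14.5²) truncated to [18, 90], sex ~ Bernoulli(0.595). Per week,
the 17 symptoms are a latent Gaussian vector
$y = \mu + \text{arm}\cdot\delta_w + z$, $z \sim N(0, \Omega^{-1})$ with unit
marginal variances, discretized through per-item cutpoints onto the 0–2 or
0–4 ordinal scales (`latent_only = TRUE` skips discretization so the
estimation model holds exactly — recovery tests separate solver correctness
from discretization bias).

**Calibration.** The sparse precision matrix $\Omega$ carries the published
week-6 symptom–symptom partial correlations exactly (mood–anxiety 0.20,
anxiety–agitation and –somatic-anxiety 0.19, anxiety–guilt 0.12, anxiety–work
0.10, mood–cognitive spanning 0.20–0.31), plus unprinted plausible filler
(sleep-item triangle, a weak somatic cluster). The published treatment
numbers (mood −0.09 at week 1 to −0.17 at week 6; anxiety −0.09 at week 2 to
−0.11; genital +0.02 to +0.11; weight loss +0.16 to +0.03) are *conditional*
(direct, network-adjusted) effects, so the generator stores them as
`direct_targets` and derives the marginal shifts as
$\delta = \Sigma\,(\operatorname{diag}(\Omega)\cdot t)$. Two properties
follow by construction: every non-targeted symptom has conditional treatment
effect **exactly zero** (clean ground-truth-null edges, changing only through
its network connections — the indirect pathway), and the implied marginal
effects land on the published overall-effect scale without further tuning
(mood ≈ −0.36 vs the published Cohen's d −0.40; cognitive items ≈ −0.13 to
−0.19 vs −0.19 to −0.25). Anchors not printed for intermediate weeks are
linearly interpolated; the week-1 anxiety target is set to half its week-2
value (the effect is described as emerging at week 2).

Missingness is per assessment (a missed visit blanks all 17 items), applied
independently per week at one minus the published completeness fractions
(91.3%, 82.5%, 69.1%, 75.3%, 58.9%; week 0 at 99.9%) — independence rather
than monotone dropout because the published pattern is non-monotone (week 3
is less complete than week 4). Missing-completely-at-random is the default
and a modelling choice, not a claim about the real trials, whose missingness
mechanism is unknown; an outcome-dependent mode (`missing_mode = "MNAR"`,
logistic tilt on the latent mood score) exists for sensitivity exploration
but is off by default. Baseline means/SDs of the discretized items
approximate the published baseline table (e.g. depressed mood 2.8 (0.6)); the
cutpoints are a fixture, not a target.

What the generator does **not** emulate: drug-specific differences (one
pooled active arm, as in the source analyses), rater effects and item-level
measurement error, floor effects from severity-based inclusion criteria, and
any real-world missingness dependence. Passing recovery tests therefore shows
that the estimator recovers the assumed latent-Gaussian structure at trial
scale — not that real HDRS data satisfy that structure.

## The per-week pipeline

`run_pipeline()` chains the stages: per-week complete-case filtering (exactly
the patients with all 17 items at that week, so weekly sample sizes differ,
as in the source design) → independent per-week network estimation (no
smoothing across weeks; cross-week comparability relies on per-week
standardization) → direct-effect trajectories → indirect-effect tables →
consecutive-week Pearson correlations of the direct-effect profile (zeros
included, all 17 symptoms) → overall effects → the direct-vs-overall
comparison with an `indirect_dominant` flag (|d| ≥ 0.15 with a zero direct
edge) → optional bootstrap and covariate-adjusted sensitivity networks. Every
stage seed derives deterministically from the master seed, so each artifact
is a pure function of (scenario/input, config).

Indirect effects are quantified as two-path products
$w(T, m)\cdot w(m, s)$ — a transparent, testable surrogate labeled
descriptive in all outputs. The underlying cross-sectional networks cannot
support formal mediation claims, and the package makes none.

Covariate adjustment includes covariates (trial-id one-hot encoded with a
reference level dropped, age standardized) as penalized predictors in every
nodewise regression, without reporting covariate edges. This reproduces the
confound-removal function of adjustment without a multinomial group-lasso
node; it is an approximation, recorded here, since the original analysis does
not state how trial-id entered its sensitivity network.

## Bootstrap edge accuracy

`bootstrap_network()` resamples patient rows with replacement at the original
n and re-runs the entire estimation per replicate — standardization,
per-node cross-validation with replicate-derived fold seeds, refit,
aggregation; re-selecting $\lambda$ per replicate is the conservative default
(`reselect_lambda = FALSE` freezes the full-sample penalties for speed).
Intervals are raw percentile 5%/95% (type-7 quantiles), not BCa. When only
specific edges are summarized, only the incident nodewise regressions are
refit; edge values are identical to the full estimation because an edge
depends only on its two incident fits.

A behavior worth understanding when reading interval plots: under the AND
rule a replicate in which either incident lasso drops the edge contributes an
exact zero. For a true negative edge, the 95% quantile touches zero as soon
as ~6 of 100 replicates drop it. At n ≈ 1000 the logistic side of the
mood edge has z ≈ 3.9 and a per-replicate drop rate around 5%, so the
interval excludes zero in only about a third of runs — at the n ≈ 4900 scale
of the source data the same interval excludes zero reliably. The test suite
documents this boundary honestly: the scaled-down coverage check at n = 1000
is expected to fail, and the effect is a property of AND-rule percentile
intervals near the detection boundary, not of this solver, whose fits the
unit tests verify against KKT certificates, brute-force search and an
independent implementation at matched penalties.

## The classical track

Pooled-variance Student's t (Welch by flag; the equal-variance form is the
classical default and matches Cohen's d's pooled-SD denominator), Cohen's
d with the active-minus-placebo sign convention (negative = beneficial),
Pearson chi-square without continuity correction (samples in scope are
large), and a Bonferroni threshold of 0.05/17 (reported rounded to 0.003)
applied to the 17 baseline symptom screens only. Overall effects are
computed on whatever scores the dataset carries (ordinal by default, latent
under `latent_only`), on the same per-week complete cases as the network
track.

## Numerical choices and problem sizes

* Solver: convergence by coordinate-change < 1e-9 plus a full-sweep KKT
  verification; logistic outer loop iterates to an exact-gradient KKT
  certificate at 5e-7; penalty grids are 50 log-spaced values down to
  1e-4 of $\lambda_{\max}$.
* CV ties break toward the larger penalty; binomial folds with a constant
  training response are refolded from a derived seed, at most 10 times.
* Degenerate inputs fail fast with named errors: zero-variance continuous
  columns, non-0/1 binary columns, constant responses, missing values
  (with a pointer to the complete-case filter).
* Test problem sizes are chosen to keep the full suite at desk scale:
  recovery at n = 5000 per week over 20 seeds, null control at n = 2000,
  bootstrap coverage at n = 1000 with B = 100 over 20 seeds, the
  covariance-convergence check at n = 100 000. The acceptance script runs
  the recovery analysis at n = 5000 per week and the bootstrap at n = 1000.

## Known limitations

* Cross-sectional per-week networks; no lagged/longitudinal estimation.
* Ordinal items are treated as continuous by the estimator (as in the
  reference analyses); the generator's `latent_only` mode exists precisely to
  isolate this approximation.
* Edge magnitudes mix a per-SD gaussian coefficient with a log-odds logistic
  coefficient (mean of absolute values); signs and orderings are the robust
  read-outs, magnitudes are convention-dependent.
* The indirect-effect product is descriptive; no mediation inference.
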