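---
title: "Identifying treatment-benefit subgroups with a composite moderator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying treatment-benefit subgroups with a composite moderator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modstar)
```

## The problem

Two treatments can be equally effective on average and still be far from
interchangeable for individual patients. The motivating setting is an
8-week randomized comparison of two acute treatments for persistent
depressive disorder (PDD): the Cognitive Behavioral Analysis System of
Psychotherapy (CBASP) and escitalopram plus clinical management (ESC/CM).
With roughly 27 and 26 completers per arm, neither arm is better overall —
yet patient characteristics at baseline may *moderate* which arm helps
whom. `modstar` implements the paired-difference composite moderator
workflow for exactly this question: it screens candidate moderators, fuses
the promising ones into a single composite score M*, splits the sample at
the point where the arms' predicted outcomes cross, and quantifies how
much better matched patients (treated with their predicted-better arm)
fare than mismatched ones.

The outcome throughout is the percent change in the clinician-rated MADRS
depression score from baseline to week 8,

$$y = \frac{\mathrm{MADRS}_{8} - \mathrm{MADRS}_{0}}{\mathrm{MADRS}_{0}}
  \times 100\%,$$

so negative values are improvements. Response is a reduction of at least
50.0%, remission a week-8 score of at most 9, and patients improving by
less than 20.0% are the augmentation candidates of the original trial
design. All three boundaries are evaluated inclusively on unrounded
values.

## Pairwise moderator effect sizes

Every CBASP completer is paired with every ESC/CM completer
($27 \times 26 = 702$ pairs). Each pair carries

* the outcome difference $d_{ij} = y^{ESC}_j - y^{CBASP}_i$, and
* the average $\bar{x}_{ij}$ of each baseline variable.

The moderator effect size of a variable is the Spearman rank correlation
(average ranks for ties) between $d_{ij}$ and $\bar{x}_{ij}$ over pairs
with complete data. The subtraction order is a convention the estimator's
sign depends on; `modstar` fixes ESC/CM minus CBASP so that *negative*
correlations read "higher values or presence of this variable favor
ESC/CM" and positive ones "favor CBASP". Because pair values are
*averages*, the estimator is invariant under positive-slope *linear*
transformations of the variable or outcome (and flips sign under
negative-slope ones); it is **not** invariant under general monotone
transformations, since averaging does not commute with them — the test
suite pins down exactly this linear version.

Uncertainty is summarized by a 95% percentile bootstrap interval over 100
replications. Each replication resamples *patients* with replacement
within each arm (arm sizes preserved), rebuilds all pairs, and recomputes
the correlation. Resampling pairs instead of patients would pretend the
702 pair records were independent, which they are not — every patient
participates in 26 or 27 pairs. With only 100 replications a percentile
interval is stable where bias-corrected variants are not, which is why
the plain percentile construction is used. Replications with a degenerate
(constant) correlation are skipped and counted; more than half skipped is
an error.

Variables qualify for the composite when

1. they have at least 50 valid cases *or* at most 3 missing cases, and
2. their effect size reaches $|\rho| \ge 0.20$ (inclusive).

A diagnostic screen (`screen_outliers()`) reports $|z| > 3$ values and
skewness for the outcome and metric variables before any effect size is
computed; it never removes anything.

## The composite moderator M*

On the paired dataset, the outcome difference is regressed on the pair
averages of the preselected variables with an L1 (lasso) penalty.
Predictors are standardized internally for the penalty and the
coefficients are reported back on the original variable scale, so that a
binary variable naturally carries a larger raw weight than, say, age in
years. The penalty weight $\lambda$ is chosen by 10-fold cross-validation
as the strict minimizer of the mean-squared prediction error (MSPE); the
1-SE rule is available as an option (`one_se = TRUE`) but is not the
default. Folds partition the *pair records* by default. Pair records
sharing a patient are dependent, so a `grouped` option forms folds by
CBASP patient instead; the default mirrors standard practice for this
workflow, and the limitation is discussed below. The coordinate-descent
solver behind the fit is glmnet.

M* for a patient is the weighted sum of their baseline values over the
surviving moderators — no intercept, weights straight from the lasso.
Patients missing any weighted variable have no M* and are excluded with a
count. M* is equivariant: rescaling all weights by $c > 0$ rescales M*
and the cross-point by $c$ and leaves every subgroup assignment
unchanged.

On the unpaired dataset, ordinary least squares fits

$$y_i = \beta_0 + \beta_1 M^*_i + \beta_2 T_i + \beta_3 M^*_i T_i +
  \varepsilon_i,$$

with $T = 1$ for CBASP and $0$ for ESC/CM. The predicted outcomes of the
two arms intersect at the cross-point $M^*_\times = -\beta_2/\beta_3$.
The fit is refused as "near-parallel" when
$|\beta_3| < 10^{-8} \times \mathrm{SD}(y)$ — a relative tolerance, since
the outcome is on a percent scale. The side of the cross-point where the
predicted ESC/CM outcome is lower (CBASP minus ESC/CM prediction equals
$\beta_3 (M^* - M^*_\times)$, so the side is the sign of $\beta_3$) is
labeled `benefit_ESC_CM`, the other `benefit_CBASP`; patients exactly at
the cross-point go to `benefit_ESC_CM` by convention and are counted.

## Evaluating the subgroups

Crossing the benefit subgroup with the randomized arm yields four
clusters; the two concordant ones pool into the *matched* group, the
discordant ones into *mismatched*. Cluster summaries report n, means and
SDs of the baseline score, week-8 score and percent change, and response
and remission rates in percent (rates computed from unrounded counts).
Pooling is available directly on summary rows through the exact two-level
variance decomposition

$$s^2_{pool} = \frac{\sum_i (n_i - 1) s_i^2 + \sum_i n_i (m_i - m)^2}
  {N - 1},$$

which makes pooled rows reproducible from printed per-cluster tables
alone, and equal (to numerical precision) to the direct patient-level
computation — a two-route identity the tests assert.

Baseline comparisons between the two subgroups use

* pooled-variance (Student) two-sample t-tests for metric variables —
  the equal-variance form, with the $t_{n_1+n_2-2}$ quantile for the 95%
  interval, is the only variant whose intervals reproduce from printed
  group summaries alone;
* Fisher's exact test (two-sided, point-probability) for binary
  variables, with a Wald $\pm 1.96$ interval for the difference in
  percentages as the presentation-layer interval;
* the ordinal treatment-history variables dichotomized at $\ge 1$
  previous treatment and compared like binary ones.

Within each subgroup the treatment contrast is Cohen's
$d = (\bar{y}_{ESC} - \bar{y}_{CBASP}) / s_{pool}$ — the same subtraction
order as the pair differences — with the normal-approximation interval
$d \pm 1.96 \, \mathrm{SE}(d)$,
$\mathrm{SE}(d) = \sqrt{(n_1+n_2)/(n_1 n_2) + d^2 / (2(n_1+n_2))}$.

The augmentation sub-analysis counts, among patients improving by less
than 20.0%, how many had been mismatched — the question being whether
initial non-response is largely a story of having started on the
personally less suitable arm.

## The synthetic trial generator

Patient-level data from such trials are typically not shareable, so the
package carries a generator (`generate_trial()`) whose defaults emulate
the completer sample the analysis targets: arms of 27 and 26; 50% female;
age truncated-normal with mean 42.9 and SD 10.8 on [18, 75] (the SD
chosen consistent with the two subgroup SDs of about 10.8 and 9.9); 58%
early onset; baseline MADRS truncated-normal 26.6 (8.6) on [10, 60]; 70%
childhood trauma; 48% Axis-I and 38% Axis-II comorbidity; previous
suicide attempts and adverse life events as Poisson counts with means 0.3
and 1.8; and the observed category frequencies for the two ordinal
treatment-history variables. Female gender, childhood trauma, suicide
attempts and adverse life events co-occur in such samples, so these four
load on a shared latent Gaussian factor (Gaussian copula) with a default
pairwise latent correlation of 0.3 — modest, and switchable to full
independence with `latent_cor = 0`.

The outcome is generated directly on the percent-change scale,

$$y_i = \mu_0 + \tau T_i + \gamma^\top x_i + T_i\, \delta^\top x_i +
  \varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2),$$

and a week-8 score is back-computed as
$\mathrm{MADRS}_0 (1 + y/100)$, clipped to [0, 60], with $y$ recomputed
from the clipped score. The clipping is the one place the realized
outcome can deviate from the linear generating model; truncation of the
baseline marginal guarantees a positive baseline. Generating on the
outcome scale avoids inventing a longitudinal score model the analysis
never uses. The interaction weights $\delta$ default to zero (a null
trial); the main effects $\gamma$, arm effect $\tau$, intercept $\mu_0 =
-20$ and noise $\sigma = 25$ are set to produce overall improvement
levels and outcome spreads of the magnitude such trials report.

What the generator does **not** emulate: dropout mechanisms and the
28-week extension phase, item-level MADRS structure (scores are
continuous unless the user rounds), rater error, and any
moderator-moderator structure beyond the single latent factor. Passing
tests on synthetic trials therefore demonstrate that the *estimators
recover the structure they assume*, not that real PDD data satisfy those
assumptions.

## The parameter-recovery experiment

The recovery experiment (`simulate_recovery()`) plants one true moderator
(age, $\delta_{age} = -1.2$, so that higher age favors CBASP and the
age effect size is positive) in otherwise-noise variables, runs the full
chain on trials of 27/26, and scores (a) whether the true moderator
survives the lasso and (b) the fraction of patients assigned to their
truly better arm, known from the generating model as the sign of
$\tau + \delta^\top x$.

One design point deserves emphasis. How the moderator is planted matters:
with $\gamma = 0$ the moderation lives entirely in the CBASP-specific
term, the pair outcome difference $d_{ij} = -\tau - \delta^\top
x^{CBASP}_i$ then depends on the CBASP member alone, and a regression on
pair *averages* can never represent it exactly — even at $\sigma = 0$,
spuriously preselected noise variables retain genuine within-sample
predictive value, and assignment accuracy plateaus near 0.93. Planting
the same moderation symmetrically, $\gamma = -\delta/2$ (equivalently,
coding treatment $\pm 1/2$ in the generating model), makes
$d_{ij} = -\tau - \delta^\top \bar{x}_{ij}$ *exactly* the estimand the
paired-average regression targets — the pure-moderator construction this
framework is built around. Under that construction the chain is exact in
the noiseless limit: across 30 noiseless trials the true moderator always
survives and every patient is correctly assigned; accuracy degrades
gracefully with noise (about 0.80 at $\sigma = 15$, 0.66 at $\sigma =
30$, against a 0.5 chance level), and some high-noise trials correctly
refuse with "no moderator survives". The experiment sizes — 30 noiseless
and 50–100 noisy trials — keep the whole suite comfortably within a few
tens of seconds while leaving the pass/fail margins far wider than the
Monte-Carlo error.

## Numerical choices and degenerate inputs

* Ties in ranks: average-rank method, matching the tie convention of the
  Spearman estimator used throughout.
* A constant variable or constant outcome difference makes the
  correlation undefined; the effect is recorded as 0 and flagged
  `degenerate`, and degenerate variables never pass preselection.
* Missing baseline values: pairwise deletion per variable for effect
  sizes (each variable uses all pairs with complete data on it);
  complete-case restriction for M* (a patient missing any weighted
  variable has no M*). This maximizes data use during screening while
  keeping M* a plain weighted sum.
* An arm absent from a subgroup makes its Cohen's d undefined; the row is
  flagged rather than extrapolated.
* Report tables round to one decimal; every computation runs on unrounded
  values.

## Known limitations

The paired dataset has $n_1 n_2$ rows but only $n_1 + n_2$ independent
patients; cross-validation folds drawn at the pair level therefore leak
patient information between training and validation, and the
MSPE-minimizing $\lambda$ is liberal — at study scale the lasso
frequently retains small-weight noise variables alongside true
moderators (the grouped-fold option does not remove the leakage, since
both pair members carry it). Selection at $n \approx 53$ is unstable
across seeds; individual moderator lists should be read as exploratory,
which is also why no post-selection inference on the lasso weights is
offered. The Wald interval for proportion differences and the
normal-approximation interval for Cohen's d are presentation choices
adequate at these sample sizes, not exact small-sample constructions.
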