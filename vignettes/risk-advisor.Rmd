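---
title: "From published dose-response evidence to a complication risk advisor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From published dose-response evidence to a complication risk advisor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabrisk)
```

diabrisk turns published evidence about how single risk factors move the
risk of single diabetes complications into a multi-factor risk advisor. The
pipeline has four stages, each usable on its own: evidence tables are
flattened into dose-response datasets; seven candidate regression patterns
are fitted and compared per factor-complication pair; the per-factor curves
for one complication are combined into a posterior by naive-Bayes inversion
against population priors; and the per-complication combiners are compiled
into a discrete Bayesian network that answers patient-level queries by
exact enumeration. A seeded synthetic cohort generator with known ground
truth closes the loop, standing in for the longitudinal patient database
that the population priors and the external validation would normally come
from.

## Evidence tables

Source studies report relationships in many shapes; the common denominator
is a "from-to" record: when the factor moves from one value to another, the
complication risk moves from one percentage to another. Each record is kept
three-dimensional on ingestion and flattened to its two endpoints for curve
fitting — no interpolation is invented between them, and duplicate factor
values contributed by different studies are all retained with equal weight,
because the patient-level data needed to weight studies against each other
is not available. Risks are percentages but are deliberately not capped at
100: incidence expressed per 100 patient-years can exceed it, and the
packaged HbA1c-NPDR example contains a 51.

Two small conversion helpers belong to this stage. `scale_by_anchor()`
rescales studies that only report multiplicative changes in risk, given the
absolute risk of their first point. `mean_arterial_pressure()` collapses a
blood-pressure reading to MAP = DP + (SP − DP)/3, the single scalar used as
the blood-pressure factor.

## Seven regression patterns and their diagnostics

For each factor-complication dataset, seven shapes are fitted by ordinary
least squares: linear, logarithmic, quadratic and cubic on the raw risk
scale, and power, S and exponential via the classical linearization — OLS
on the log response. Diagnostics are reported on the fitting scale, which
is why the standard error of the estimate of a log-scale fit (around 0.5)
is not commensurable with a raw-scale one (around 8) on the same data.

The diagnostic block per fit is: R² = SS_M/SS_T; the F-ratio
MS_M/MS_R with its exact p-value; Wherry's adjusted R²
`1 − (1 − R²)(n − 1)/(n − k − 1)` (the population-shrinkage correction that
SPSS prints as "Adjusted R Square"); Stein's cross-validation adjusted R²
`1 − [((n−1)/(n−k−1)) ((n−2)/(n−k−2)) ((n+1)/n)](1 − R²)`; and the
Durbin-Watson statistic `Σ(e_t − e_{t−1})²/Σe_t²` with the conventional
1.5-2.5 acceptance band for independent errors. Durbin-Watson requires a
stated residual order; datasets are stored sorted ascending by factor
value, and that row order is the one used.

**Model selection.** `select_best()` maximizes Wherry's adjusted R², not
raw R². The choice is forced: the polynomial patterns are nested, so a
cubic can never score below the linear fit it contains on raw R², and raw
R² would therefore always prefer cubic among the polynomials. Adjusted R²
penalizes the extra coefficients and reproduces the winners the
model-comparison tables this design follows actually highlight (a
quadratic preferred over a cubic that has nominally higher R²). Ties break
toward fewer coefficients, then toward the earlier pattern in the
canonical order. One caveat is inherited knowingly: adjusted R² of a
log-scale fit and of a raw-scale fit are compared directly, as the source
tables do, although the two response scales differ.

A minimal neural-network baseline (`train_ann()`) is included as the
comparison arm: one hidden tanh layer, linear output, full-batch gradient
descent on standardized inputs, seed-deterministic. It is a baseline, not a
contender — with 15-20 point datasets the regression patterns are expected
to win, and the historical comparison software's architecture is not
published, so no attempt is made to reproduce its exact scores.

## Naive-Bayes combination

Each fitted curve, evaluated at a patient's factor value and divided by
100, is read as q_k = P(C = yes | f_k). Bayes' theorem inverts it to the
class-conditional P(f_k | C) = P(f_k) P(C | f_k) / P(C)
(`invert_conditional()`), and class-conditional independence multiplies the
inverted conditionals into the two class scores. `combine_posterior()`
evaluates the chain in log space and normalizes over the two classes
(yes/no), so the result is a genuine probability:

    s_yes = p^(1−n) Π q_k,   s_no = (1 − p)^(1−n) Π (1 − q_k),
    posterior = s_yes / (s_yes + s_no).

Two consequences are worth stating. First, the factor marginals P(f_k)
appear in both class scores and cancel in the normalization, so the
combiner needs only the class prior — the marginals still matter, but only
as root-state distributions of the network. Second, with a single factor
the posterior reduces exactly to q_1, and uninformative evidence
(q_k = p for all k) returns the prior unchanged. The source derivation
displays only the unnormalized "yes" product and leaves its worked example
unevaluated; the two-class normalization is this package's addition,
needed because classification there is defined as maximizing the posterior
over classes, which requires both class scores.

Curves are unconstrained regressions, so predictions can leave [0, 100]%;
they are clipped to [1e−4, 100 − 1e−4] percent with a warning before use
as probabilities, and the per-factor q_k to [1e−6, 1 − 1e−6]. Log-space
evaluation keeps the combination finite for dozens of factors.

## The discrete network

Continuous factors enter the network as half-open, left-open right-closed
bins ]lo, hi], so a value equal to a shared edge belongs to the lower bin.
Each bin carries a representative value — midpoint by default, explicit
where a bin is open-ended — at which the dose-response curves are evaluated
when that bin stands for its whole range. A complication node's CPT
enumerates the Cartesian product of its parents' states and fills each row
with `combine_posterior()` at the representative values.

Complication-to-complication edges (the albuminuria stages feeding the
retinopathy nodes) have no dose-response table of their own; they are
quantified through a `parent_value_map` that places each yes/no state on
the albumin-excretion-rate scale (defaults: micro yes/no at 100/15 mg/day,
macro at 500/15), so the child's AER curve supplies the conditional. These
representative values, like all default bin edges, are package
configuration — clinically plausible, not published estimates.

`infer()` answers queries by brute-force summation over the joint
distribution of the query node's ancestor set: observed factors are fixed
to their bins, unobserved factors are summed over the root-state
distributions, and complication-valued ancestors over their CPTs. On a
discrete DAG of this size that is exact — and deliberately so: mixing a
complication parent's *marginal* yes/no probability into the child's CPT
would be wrong whenever parent and child share factor ancestors, which is
precisely the retinopathy configuration. The test suite holds inference to
within 1e−12 of an independent full-joint enumeration on fork, chain and
diamond topologies.

## Evaluation

Continuous probabilities become yes/no calls at a cut-off: `p ≥ cutoff/100`
classifies positive, inclusively, so at cut-off 100 only probability
exactly 1 is called. The default sweep grid is 60-100% in steps of 10.
Sensitivity, specificity, precision and accuracy follow their standard
definitions; an empty denominator yields `NA`, never a silent zero. The
textbook baseline — an all-negative classifier on 10 positives and 90
negatives scoring 90% accuracy with zero sensitivity — is kept as a test
anchor for why accuracy alone is not reported.

## The synthetic cohort and what passing tests show

Real population priors and external validation would require a
longitudinal diabetes cohort; none ships with the package. The generator
(`generate_cohort()`) draws factor values independently from configured
marginals (defaults: HbA1c and MAP truncated normal, duration uniform, AER
truncated log-normal — chosen as plausible clinical ranges), computes each
patient's true outcome probability by the same naive-Bayes combination the
predictor uses, and draws Bernoulli outcomes. Independence across factors
matches the combiner's assumption by design, so that end-to-end tests are
well-specified; a Gaussian-copula correlation knob exists precisely to
*break* that assumption in violation studies, and is off by default.
Truncated sampling is inverse-CDF, so cohorts are a deterministic function
of the seed.

What the synthetic cohort does not emulate: real sampling designs, real
prevalences, measurement error, correlated factors (by default), or
informative missingness. Passing tests therefore demonstrate internal
consistency — the pipeline recovers what it itself generated — not clinical
validity on real patients.

**Parameter-recovery design.** The canonical recovery experiment
(`recover_pattern()`) draws 50,000 patients with a uniform factor, bins
them (15-25 equal-width bins depending on the pattern), converts bin
outcome proportions to an empirical dose-response table and refits the
generating pattern. The per-pattern truth curves and ranges in
`recovery_design()` were fixed once, at design time, by a small power
analysis: each coefficient's magnitude must clear the binomial sampling
error of binned proportions at that cohort size by a comfortable margin,
otherwise no fitting method could recover it to 10% relative error — the
intercept of log-scale patterns, for instance, is only identifiable when
the factor range approaches the point where the log term vanishes, which
is why the power and exponential designs use duration-like ranges starting
near zero. Uniform factor sampling keeps bin midpoints unbiased as
representative values.

## Numerical choices and degenerate inputs

* Exact fits (SS_R = 0): F is `Inf`, the p-value 0, adjusted R²s 1, and
  Durbin-Watson `NA` — the statistic is undefined on all-zero residuals
  and is rejected rather than faked when called directly.
* A constant response (SS_T = 0) rejects: R² is undefined.
* Rank-deficient designs reject rather than silently dropping terms.
* Log-requiring patterns reject non-positive values naming the offending
  point; `fit_all()` downgrades those rejections to warnings and skips.
* Empty factor bins in prior estimation get Laplace add-one smoothing
  (applied across that factor's bins so they still sum to 1); degenerate
  all-yes/all-no class priors are smoothed to (k+1)/(n+2).
* Predictions outside the training domain are allowed with a warning —
  the evidence base is sparse at the extremes and silent extrapolation
  would hide that.

## Problem sizes

The shipped tests and the acceptance script run the recovery experiment at
50,000 patients per pattern, oracle comparisons over 100 randomized
combiner toys and 30 small networks, and the end-to-end sweep on a
400-patient cohort with a 5,000-patient cohort behind the default network's
priors — sizes at which every stochastic check has comfortable margin while
a full run stays in seconds.

## Worked example

```{r example, eval = FALSE}
library(diabrisk)

# 1-1 stage: fit and compare the seven patterns on the packaged dataset
fits <- fit_all(hba1c_npdr())
fit_summary(fits)
best <- select_best(fits)
glance(best)

# n-1 stage: combine per-factor curves for one complication
combine_posterior(
  "micro",
  c(HbA1c = 7.8, Duration = 8),
  default_truth_curves()$micro,
  p_yes = 0.15
)

# n-k stage: compile the default network and score a patient
net <- default_compiled_network(n_patients = 5000, seed = 20)
infer(net, c(HbA1c = 7.8, AER = 21, Duration = 8))
```

## Known limitations

Beyond the synthetic-data caveats above: the adjusted-R² comparison across
fitting scales is inherited from the source design rather than defensible
from first principles; binned CPTs discard within-bin variation, so
probabilities are step functions of the factors; only two-state
complications are supported; and categorical factors (such as smoking) are
representable as named-category bins but excluded from the default
configuration because no dose-response dataset backs them.
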