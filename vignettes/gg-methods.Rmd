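---
title: "Learning curves, gait association, and predictor comparison: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning curves, gait association, and predictor comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gglearn)
```

## The behavioural model

The Goalkeeper Game is a penalty-prediction task with three response
options, played in three stages: a cued motor baseline (5 trials), an
uncued learning phase over a deterministic kick sequence (20 trials), and
a memory phase (5 trials). The raw datum is a per-trial success indicator
$X_t \in \{0, 1\}$. Within one patient-stage we model

$$\lambda_t = (t - 1)\,\beta - \log(3\gamma - 1), \qquad
  \Pr(X_t = 1) = \gamma\,\frac{e^{\lambda_t}}{1 + e^{\lambda_t}},$$

with trials conditionally independent given $(\beta, \gamma)$. The
parameterization has two properties that make the parameters directly
interpretable:

* at $t = 1$ the success probability is exactly $1/3$ — chance with three
  options, before any information has been gathered — for *every* valid
  parameter pair, because $e^{\lambda_1}/(1+e^{\lambda_1}) = 1/(3\gamma)$;
* as $t \to \infty$ (for $\beta > 0$) the probability rises strictly
  monotonically to the asymptote $\gamma$, the patient's *total learning*
  in that stage, while $\beta$ sets how many trials are needed to get
  there (*rate of learning*).

The algebra requires $\gamma > 1/3$: a patient cannot asymptote below
chance under this curve. $\beta \ge 0$ is the default (learning, not
forgetting); `lc_params(..., allow_negative_beta = TRUE)` opens the sign
for sensitivity analyses. We note that the constraint set is the honest
domain of the model, not a numerical convenience — fits are computed on
this domain directly.

## Bayesian estimation by deterministic quadrature

Each patient-stage series is fit separately (no hierarchical pooling, by
design: the analysis treats the nine resulting variables as independent
patient descriptors). Priors are weakly informative on the constrained
domain:

* $\gamma \sim \mathrm{Uniform}(1/3, 1]$;
* $\beta \sim \text{half-Normal}(0, 2)$, truncated at $12$ (six prior
  scales) for integration.

The posterior is two-dimensional and smooth, so instead of MCMC we
integrate it deterministically: a 61-point-per-axis midpoint grid over
the full domain locates the region within 25 log-units of the posterior
mode; a 64-point tensor Gauss–Legendre rule over that (slightly
expanded) box then yields posterior means, standard deviations, and
central credible intervals from the weighted marginals. This makes every
fit exactly reproducible — no chains, no seeds, no convergence
heuristics — and costs a few milliseconds per series. The point estimate
is the posterior mean; the level of the central interval defaults to
90%.

Two diagnostics are attached to each fit. A *weak identification* flag
is raised when the credible interval is wider than half of the matching
central prior interval — routine for the 5-trial stages, where the data
cannot pin both parameters; the short stages are still fit as such
because the downstream analysis consumes their posterior means as
features, shrinkage included. The refinement box and the log evidence are
reported for inspection.

Numerical notes: the log-likelihood surface is evaluated on vectorized
parameter grids; an all-failure series drives the posterior against the
$\gamma = 1/3$ boundary, which the adaptive box handles but which demands
extra resolution from any *fixed* reference grid (the test suite uses a
600-point grid for that case, 200 points elsewhere). Parameter regions
with long flat likelihood ridges (very low $\gamma$ together with large
$\beta$) are intrinsically hard for any quadrature; at the parameter
ranges this cohort occupies the two-pass scheme agrees with dense
reference grids to well under $10^{-2}$ in both coordinates.

The nine-variable profile per patient is $(\beta_1, \beta_2, \beta_3,
\gamma_1, \gamma_2, \gamma_3, \bar t_1, \bar t_2, \bar t_3)$, where
$\bar t_s$ is the plain arithmetic mean response time of stage $s$ — no
trimming, consistent with the heavy-tailed spreads such data show.

## The synthetic cohort

The generator emulates a 74-patient Parkinson cohort (Hoehn–Yahr 1–3)
playing the 5/20/5 design, with known ground truth:

* $\beta$ is lognormal and $\gamma$ logistic-normal on $(1/3, 1]$ per
  stage, with latent parameters solved (by quadrature and Nelder–Mead)
  so the *back-transformed* means and standard deviations equal the
  published cohort summaries (means 1.74/1.76/2.00 for $\beta$,
  0.68/0.64/0.78 for $\gamma$);
* response times are lognormal with patient-level means moment-matched
  to the published 4.47/3.28/2.52 (s.d. 6.21/3.78/2.40) seconds and a
  within-patient log-s.d. of 0.4 — right-skewed, s.d. exceeding the
  mean, as observed;
* the Dynamic Gait Index (DGI, 0–24) arises by thresholding a standard
  normal latent trait $z$ at cut points that reproduce a discretized
  N(19, 4) marginal — a mildly impaired cohort; the trait is a weighted
  sum of *standardized feature latents*, dominated by the memory-stage
  asymptote $\gamma_3$ with the secondary weights proportional to the
  published correlation pattern ($\gamma_1$ positive, $\bar t_1, \bar
  t_3$ negative);
* MoCA (truncated to 21–30 by the dementia-screen inclusion rule) shares
  the trait weakly through its own latent.

Because DGI is produced by thresholding a latent trait, the generator is
*coherent with the downstream analysis*: the polyserial/polychoric
estimators and the cumulative-logit model both assume exactly this
construction. The two link strengths were calibrated once by
`calibrate_link()` (Monte-Carlo root finding with common random numbers
at $n = 20\,000$) so that the large-sample polyserial correlation
between *true* $\gamma_3$ and DGI is 0.39 and the polychoric MoCA–DGI
correlation is 0.20; the resulting defaults (`link_scale = 0.408406`,
`moca_link = 0.211481`) are frozen in `cohort_config()`.

What the generator does *not* emulate: within-patient correlation of
parameters across stages is zero by default (a `stage_param_cor` knob
exists, because such dependence is plausible but unreported);
demographics are decorative and unlinked to performance; response times
enter the trait through their patient-level latent, not the realized
trial means; there is no item-level structure in DGI or MoCA, no
practice or fatigue effects, and no missingness. Passing tests on this
cohort therefore demonstrate the *machinery* — identifiability,
calibration, null behaviour — not that real gait data follow a
latent-normal single-trait model.

A consequence worth stating explicitly: because the link targets the
*true* $\gamma_3$, the correlation carried by the *estimated*
$\hat\gamma_3$ is attenuated — five memory-phase trials only partially
identify the asymptote, and the posterior mean is shrunk toward the
prior. The feature-based analyses on synthetic cohorts therefore see
weaker signal than the published table values, which is the honest
consequence of the design rather than a fault of the fitter.

## Association analyses

The ten-row association table pairs DGI with MoCA and the nine game
variables, in the published order. MoCA–DGI, a discrete–discrete pair,
gets the polychoric correlation; the nine continuous game variables get
polyserial correlations — the only assignment consistent with the two
estimators' definitions. Both estimators are two-step maximum
likelihood: thresholds from the ordinal marginal cumulative proportions
(hence invariance to any strictly increasing relabeling), then a
one-dimensional likelihood search over the latent correlation on
$[-0.995, 0.995]$, with estimates beyond $|0.99|$ flagged as boundary
cases. The zero-correlation p-value is a likelihood-ratio test with one
degree of freedom. The bivariate normal rectangle probabilities inside
the polychoric likelihood use a vectorized Gauss–Legendre evaluation of
the tetrachoric integral (48 nodes on the correlation path), accurate to
about $10^{-12}$ over the relevant range and cross-checked against
`mvtnorm` in the tests. Complete cases only; exclusions beyond 10%
produce a warning.

The proportional-odds model for DGI is a cumulative-logit fit
$\mathrm{logit}\,\Pr(Y \le j \mid x) = \zeta_j - x^\top b$ with parallel
slopes, written in-package: thresholds are optimized on a log-difference
parameterization (so their ordering can never break), BFGS is followed
by Newton polishing in the direct parameterization, and Wald p-values
come from the observed information. With a two-category response this is
ordinary logistic regression, and the implementation reproduces `glm`
coefficients to $10^{-6}$; with three or more categories it matches
`MASS::polr` (which itself refuses binary responses — the reason the
fitter is written out). Predictors enter raw (per-unit coefficients) by
default. Raw p-values are reported without multiplicity correction,
matching the descriptive use of the table.

## Classifier comparison

DGI is dichotomized at the sample median, *above* read strictly, ties to
the lower class (the rule is logged via the `class_balance` attribute).
Both arms — the nine game features, and MoCA alone — are evaluated by
stratified 10-fold cross-validation repeated 10 times by default, with
identical fold assignments across arms (all partitions are drawn before
any fitting). The game arm is elastic-net logistic regression (mixing
parameter 0.5) with the penalty chosen by an inner 5-fold
cross-validation on each training fold only; the MoCA arm is plain
logistic regression, penalization being inert for a single predictor.
Accuracy is the fraction of correct out-of-fold predictions at
probability threshold 0.5, averaged over repeats; the exact binomial
test compares the rounded correct count against a fair coin, two-sided
by default. ROC curves come from a full threshold sweep, and the AUC
equals the Mann–Whitney statistic with half credit for ties — computed
via average ranks so the identity is exact. The paired AUC comparison is
DeLong's test on placement values, one-sided by default in the direction
"features beat the single score".

One structural property of this design deserves emphasis. On a discrete
25-category score, the median category carries non-trivial mass, and the
tie rule pushes all of it into the lower class, so the dichotomized
labels are systematically imbalanced (roughly 55/45 under the default
DGI marginal). A classifier with no signal collapses, via the inner CV,
to the intercept and predicts the majority class everywhere; its
accuracy then concentrates at the majority share rather than at 50%.
The null-calibration test in the acceptance suite measures exactly this
(and the binomial test inherits the same offset). The threshold-free
AUC does not suffer from it, which is one reason the comparison carries
both metrics.

## Problem sizes used by the test suite

All simulations are sized to run the whole suite on a single CPU in
roughly a quarter hour: likelihood normalization is enumerated up to 10
trials; oracle agreement uses five series against a $200 \times 200$
reference grid; recovery and coverage use 100 series of 200 trials;
correlation recovery uses 200 replicates at $n = 2000$; the null and
strong-link cohort experiments use 200 cohorts of 74 patients each with
2 CV repeats and a coarsened (31/32-node) quadrature whose per-fit error
is far below what classification can resolve; DeLong calibration uses
500 null replicates. The end-to-end reproducibility check runs the full
default cohort twice and compares output files byte for byte.

## Known limitations

* The two 5-trial stages cannot identify $(\beta, \gamma)$ jointly;
  their fitted values are prior-shrunk by construction and flagged as
  weakly identified. Any downstream use inherits that attenuation.
* The latent-trait generator is single-factor; real gait–cognition
  dependence is surely richer, and nothing here validates the
  latent-normal assumption on real data.
* The polyserial estimator treats the continuous variable as marginally
  normal; for strongly skewed inputs (raw mean response times) the
  latent correlation is recovered only approximately.
* Accuracy at a fixed 0.5 threshold is a coarse metric under class
  imbalance — see above; AUC-based conclusions are the more stable ones.
* The proportional-odds fitter assumes parallel slopes and does not test
  that assumption.
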