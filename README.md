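# gglearn

Trial-level analysis of Goalkeeper Game performance and its association
with gait in Parkinson's disease.

The Goalkeeper Game is a penalty-prediction videogame (three response
options) played in three stages — cued motor baseline (5 trials),
uncued learning of a deterministic kick sequence (20 trials), and a
memory phase (5 trials). Clinicians would like to know whether the
learning profile it measures tracks gait performance (the Dynamic Gait
Index, an ordinal 0–24 score) better than a standard global cognition
screen (MoCA). `gglearn` implements the full analysis chain for that
question, plus a synthetic-cohort generator with known ground truth so
every stage of the chain can be validated without patient data.

## The model

Within one patient-stage, trial successes $X_t \in \{0,1\}$ follow a
constrained Bernoulli learning curve,

$$\lambda_t = (t-1)\,\beta - \log(3\gamma - 1), \qquad
  \Pr(X_t = 1) = \gamma\, \frac{e^{\lambda_t}}{1+e^{\lambda_t}},$$

which pins the first trial at chance ($1/3$, three options and no
information) and rises monotonically to the asymptote $\gamma \in
(1/3, 1]$ ("total learning") at a rate set by $\beta \ge 0$. Each
patient-stage is fit by Bayesian deterministic quadrature (uniform
prior on $\gamma$, half-normal on $\beta$), giving the nine-variable
profile $(\beta_{1..3}, \gamma_{1..3}, \bar t_{1..3})$ — the $\bar t_s$
are mean response times. Downstream:

* **association**: polyserial correlations (game variables vs DGI),
  polychoric correlation (MoCA vs DGI), and a cumulative-logit
  proportional-odds model for DGI;
* **prediction**: elastic-net logistic classifiers of DGI dichotomized
  at its median — nine game features versus MoCA alone — under repeated
  stratified cross-validation with shared folds, compared by exact
  binomial tests, ROC/AUC, and DeLong's paired one-sided AUC test.

## Worked example

Fit one simulated learning-phase series:

```r
library(gglearn)
y <- simulate_stage(lc_params(beta = 1.76, gamma = 0.64), 20, seed = 8)
y
#>  [1] 0 1 0 0 1 0 1 0 0 0 1 1 1 1 1 0 1 1 1 1
fit_stage(y)
#> posterior: beta = 1.211 [0.100, 3.586], gamma = 0.687 [0.463, 0.938] (90% CI)
#> note: weakly identified (credible width > half the prior width)
```

Twenty trials bracket the true asymptote (0.64) but leave it uncertain,
and the fit says so. The per-trial success curve behind the data starts
exactly at chance:

```r
round(success_probability(lc_params(1.76, 0.64), c(1, 2, 3, 5, 10)), 3)
#> [1] 0.333 0.553 0.623 0.639 0.640
```

Run the whole pipeline on the default synthetic 74-patient cohort
(simulate, fit 222 patient-stage posteriors, associate, classify):

```r
res <- run_gg_pipeline(seed = 1)
res$comparison
#> GG features: accuracy 58.4% (binomial p = 0.201), AUC 0.520
#> MoCA:        accuracy 58.8% (binomial p = 0.13), AUC 0.359
#> DeLong one-sided (GG > MoCA): p = 0.0468
head(res$associations, 3)
#>   variable    estimate   p_value     method
#> 1     moca  0.16627212 0.1591874 polychoric
#> 2    beta1 -0.07576615 0.5226372 polyserial
#> 3   gamma1 -0.01933533 0.8704226 polyserial
```

On synthetic cohorts the estimated memory-phase asymptote
$\hat\gamma_3$ carries the strongest game-variable correlation with DGI
(0.21 for this seed), attenuated from the generating truth of 0.39
because five memory trials only partially identify the asymptote — see
the methods vignette (`vignettes/gg-methods.Rmd`) for why, and for every
modelling choice and its alternatives.

The numbered drivers under `analysis/` run the same chain step by step
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_fit_learning_curves.R
Rscript analysis/03_associations.R
Rscript analysis/04_classification.R --seed 1
```

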