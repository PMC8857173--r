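---
title: "Methods: a Bayesian hierarchical qAOP model for developmental neurotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Bayesian hierarchical qAOP model for developmental neurotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(qaopdnt)
```

## The scientific problem

Developmental neurotoxicity (DNT) is rarely tested in vivo, and no single
mechanistic pathway explains it.  The adverse outcome pathway (AOP)
framework organizes the available mechanistic evidence as causal chains
from molecular initiating events through key events to an adverse
outcome.  This package quantifies one simplified biological path through
the DNT AOP network, built from three *common key events* (CKEs) that
many linear AOPs share:

1. **BDNF** — reduction of brain-derived neurotrophic factor
   (molecular level; informed by physicochemical and ADMET predictors),
2. **SYN** — decrease of synaptogenesis (cellular level; informed by a
   high-content imaging assay in rat primary cortical cells),
3. **NNF** — decrease of neural network formation (network level;
   informed by microelectrode-array recordings),

followed by the adverse outcome **DNT** itself.  The chain
BDNF → SYN → NNF → DNT is a directed acyclic graph; each key event
relationship is treated as a linear, additive effect on the logit scale.
Given a per-compound table of predictors and (partially missing) binary
labels, the model predicts, per compound, the probability of inducing
each CKE and the AO, with credible intervals that honestly propagate
missing-data uncertainty.

## The model

For compound $i$, each key event $k \in \{\mathrm{BDNF}, \mathrm{SYN},
\mathrm{NNF}\}$ has a design row $x_{ik}$ (standardized predictors) and
a coefficient vector $\beta_k$.  Writing the block contribution
$c_{ik} = x_{ik}^\top \beta_k$, the linear predictors chain down the
pathway:

$$
\theta^{\mathrm{BDNF}}_i = c_{i1}, \qquad
\theta^{\mathrm{SYN}}_i  = c_{i2} + \theta^{\mathrm{BDNF}}_i, \qquad
\theta^{\mathrm{NNF}}_i  = c_{i3} + \theta^{\mathrm{SYN}}_i,
$$
$$
\theta^{\mathrm{DNT}}_i =
\theta^{\mathrm{BDNF}}_i + \theta^{\mathrm{SYN}}_i + \theta^{\mathrm{NNF}}_i
\;=\; 3c_{i1} + 2c_{i2} + c_{i3}.
$$

The adverse outcome has no coefficient block of its own: its predictor
is solely the sum of the key-event predictors.  All four binary labels
are Bernoulli with an inverse-logit link,
$Y^{k}_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\theta^k_i))$.
A Bernoulli parameter must lie in $[0,1]$ and the AO combination is a
logistic regression of the chained predictors, so $\theta$ lives on the
logit scale throughout; the synthetic-data generator and the fitter
share this link through a single internal constant.

Partial pooling: every coefficient, across all three blocks, is shrunk
towards one global pair of hyperparameters,

$$
\mu \sim \mathrm{Normal}(0,\, 0.1), \qquad
\sigma \sim \mathrm{HalfNormal}(1), \qquad
\beta_{kj} \sim \mathrm{Normal}(\mu,\, \sigma),
$$

with the second Normal parameter a standard deviation.  These are
weakly informative on standardized predictors: they regularize a model
whose scalar parameter count (hyperparameters, coefficients, latent
imputed cells) is large relative to the number of compounds, trading a
little bias for much less variance.

Missing predictor cells are imputed during inference.  Each design
block with masked cells gets one hyperparameter pair and one latent
scalar per cell:

$$
\mu_{X\mathrm{miss}} \sim \mathrm{Normal}(0, 0.1), \quad
\sigma_{X\mathrm{miss}} \sim \mathrm{HalfNormal}(1), \quad
x^{\mathrm{miss}} \sim \mathrm{Normal}(\mu_{X\mathrm{miss}},
\sigma_{X\mathrm{miss}}),
$$

so a compound with unobserved predictors receives a full posterior over
its plausible design values, and its probability intervals widen
accordingly.  Missing binary predictors are imputed on the same
continuous standardized scale as continuous ones — one imputation
scheme for all of $X$.

Missing labels are handled differently, and this is a deliberate
modelling decision.  In the chain above the labels have no children:
$\theta$ feeds forward, $Y$ does not.  A missing label therefore
contributes a constant factor to the likelihood and can be marginalized
out exactly; the package drops unobserved labels from the likelihood and
emits their Bayesian imputations afterwards as posterior-predictive
Bernoulli draws (`posterior_predict_labels()`).  An alternative reading
would chain the latent labels themselves as predictors of the next
event; the displayed structure chains $\theta$, and that is what is
implemented.  The in vivo DNT label is required for every compound and
always conditions the fit, even though $\theta^{\mathrm{DNT}}$ has no
coefficients of its own.

Counting named building blocks: 2 hyperpriors + 3 coefficient blocks +
4 likelihoods = 9 for any complete-data model, independent of $n$;
imputation blocks come and go with the missingness pattern.
`count_parameters()` reports both this census and the free-scalar total.

## Data conventions

The CSV schema (`dnt_schema()`) mirrors how such evidence is collected:
identifiers, the in vivo DNT classification (never missing), LogD,
blood–brain-barrier permeability, Cbrain/Cblood, three P-glycoprotein
indicators, the BDNF literature label, and per-assay viability, effective
concentrations and activity labels.  Empty cells are the sole encoding
of missingness; treating assay-inactive compounds as missing is applied
by the data preparer upstream.

The default predictor assignment follows the levels of the pathway:
chemical/ADMET properties feed the molecular event (BDNF block); each
assay's viability and EC summaries feed its own key event.  The
assignment is a config object (`default_predictor_spec()`) and can be
overridden.  Numerical conventions:

* **EC columns** (`syn_ec30_um`, `nnf_ec50min_um`, `nnf_ec50max_um`,
  µM) span orders of magnitude and are log10-transformed before
  standardization.
* **Continuous columns** are z-scored over observed entries with the
  sample (n−1) standard deviation; the per-column location/scale is
  stored for exact round-tripping.  Binary predictors stay 0/1.
* **Intercepts**: one per block, constant 1, never standardized, its
  coefficient pooled like any other.  Binary outcomes have base rates,
  so an intercept is needed unless the predictors happen to be centered
  at the right log-odds; `default_predictor_spec(intercept = FALSE)`
  gives the literal interceptless variant.
* **EDA** uses pairwise-complete Pearson correlations; a pair with
  fewer than two complete observations is *undefined* (`NA`), never 0.

## Sampling

The posterior is explored with the package's own No-U-Turn sampler
(dynamic Hamiltonian Monte Carlo) implemented in C++: multiplicative
step-size adaptation by dual averaging (target acceptance 0.9 by
default), diagonal metric estimation in expanding warmup windows, slice
tree sampling with a maximum depth of 10, and a divergence flagged
whenever the Hamiltonian error exceeds 1000 on a leapfrog step.
Defaults are 4 chains × 1000 warmup × 1000 kept draws.  All randomness
flows through R's RNG, so a fixed seed reproduces draws bit for bit.

Two numerical choices matter:

* **Non-centered parameterization.**  Coefficients are sampled as
  $\beta = \mu + \sigma\,\tilde\beta$ with $\tilde\beta \sim
  \mathrm{Normal}(0,1)$ (and likewise for latent imputed cells).  The
  posterior is identical, but the geometry avoids the prior funnel that
  a centered hierarchy develops when the data are weak — including the
  $n = 0$ limit, where the sampler must reproduce the prior exactly
  (and is tested to, against the closed-form half-normal mean
  $\sqrt{2/\pi}$).
* **Positivity by transform.**  Scales are sampled on the log scale
  with the Jacobian included, so no boundary rejections occur.

The plain-R joint density (`log_joint_density()`) is implemented
independently of the compiled one; tests verify the two agree up to the
unconstraining Jacobian, check the compiled gradient against numerical
differentiation, compare the MCMC posterior mean against 10,001-point
grid integration on a one-parameter model, and cross-check posterior
means against an independent Gibbs implementation (JAGS) on a complete
small dataset.

## Diagnostics and model comparison

`diagnose_fit()` computes, per scalar parameter, the rank-normalized
split $\widehat R$ (the larger of the bulk and folded statistics; the
plain Gelman–Rubin statistic misses scale-only disagreements, so the
rank-normalized variant is the package's documented choice), the Geyer
initial-monotone-sequence effective sample size, and the Monte Carlo
standard error, defined exactly as posterior sd / $\sqrt{\mathrm{ESS}}$.
Zero-variance chains yield `NA` ("undefined"), never a reassuring 1.

Predictive accuracy uses per-compound pointwise log-likelihoods (each
compound's observed labels summed):

* **PSIS-LOO**: importance weights smoothed by a generalized Pareto fit
  (Zhang–Stephens profile likelihood) to the upper tail, shape
  diagnostic $k$ reported per compound, $k > 0.7$ flagged unreliable.
  A degenerate zero-variance tail (constant weights) reports `NA` for
  $k$ and reduces exactly to the pointwise log-likelihood.
* **WAIC**: lppd minus the per-point posterior variance penalty.  Both
  criteria are reported on the deviance scale (−2 × elpd) with the elpd
  scale also exposed, and are tested against closed-form constant cases
  and against exact leave-one-out refits (by quadrature) on a toy model.
* **Brier score** per node, computed from posterior-mean probabilities
  against observed labels only (compounds with a missing label are
  skipped for that node).

`sensitivity_analysis()` refits under alternative hyperprior scales and
tabulates these three metrics plus per-compound predictive-mean deltas.
The settings are configurable; the pipeline default multiplies the
half-normal scale by {0.5, 1, 2}, a placeholder for "two additional
weakly-informative hyperpriors" whose exact values are a free choice.

## Predictions and hazard classes

Per compound and node, `predict_report()` summarizes the probability
draws by their mean and a 95% interval.  The default interval is
equal-tailed — bounded by the 2.5th and 97.5th percentiles, which is how
the reported 95% interval is defined here — with a true
highest-density interval available by flag (for symmetric posteriors
the two coincide; for skewed ones the HDI is never wider).

Two thresholds split compounds into low/medium/high hazard classes.
Their derivation from the predicted posterior distributions is
under-determined, so the default is the empirical tertiles of the
per-compound mean DNT probabilities, with fixed user thresholds
accepted verbatim.  Boundaries are inclusive on the upper class side: a
mean exactly at $t_{\mathrm{low}}$ is `medium`, at $t_{\mathrm{high}}$
is `high`.  Confusion-matrix metrics (sensitivity, specificity,
accuracy, balanced accuracy) binarize at a configurable decision cutoff,
0.5 by default; with no observed positives (or negatives) the
corresponding rate is undefined and reported `NA`.

## The synthetic study

No public per-compound table accompanies the modelled study — its final
dataset exists only as supplementary material — so the package carries a
generator (`simulate_dnt_data()`) that draws from the model's own
generative process and defines the study conditions used by every test:

* 88 compounds by default, mirroring the study size;
* continuous predictors standard normal on the design scale, mapped
  back to laboratory units (LogD around 2 ± 1.5, viabilities in % of
  control, ECs log-normal in µM with the two network-formation EC50
  summaries sorted so min ≤ max); binary predictors Bernoulli(0.5);
* true coefficients drawn from Normal(0, 0.5), keeping effects inside
  the weakly-informative prior's plausible range;
* labels drawn from Bernoulli(inverse-logit θ) with the same chain and
  link as the fitter;
* missing-completely-at-random blanking with per-column defaults chosen
  to resemble the study's composition: half the compounds lack BDNF
  literature evidence, ~8% lack in silico ADMET predictions (e.g.
  inorganics), and each in vitro assay leaves about a quarter of
  compounds without usable results.  The exact real-data rates are not
  recoverable from text, so these defaults are a fixed, documented
  choice.  The in vivo DNT label is never blanked.

What the generator does *not* emulate: chemistry-aware correlations
between predictors, the two source assays' concentration–response
designs, informative (MNAR) missingness, or the exact composition of
the real compound list (74% in vivo positives).  Passing tests
therefore demonstrate that the machinery is correct and calibrated
under the stated generative assumptions — not that the real-data
headline numbers are reproduced.  In particular the synthetic
classification accuracy is typically *higher* than a real-data fit,
because the labels are drawn from the very model being fitted.

A consequence of the model structure worth stating explicitly: a
missing *label* alone barely widens that compound's own predictive
interval (the chain feeds forward through $\theta$, so the only effect
is the loss of the compound's own likelihood terms).  The broad
intervals seen for poorly characterized compounds are driven by missing
*predictors*, whose latent imputations carry posterior spread into
$\theta$ directly.  The interval-widening test therefore runs at the
study-like missingness composition (predictor and label missingness
together) and compares compounds with any missing information against
fully complete ones.

## Problem sizes used by the test-suite

Oracle comparisons use tiny instances (1 free parameter, 5–10
compounds) where grid integration and exact leave-one-out are feasible;
parameter-recovery runs use 20 seeds of $n = 300$ complete datasets
with short chains (2 × 400), which keeps the whole battery comfortably
under typical CI budgets while leaving each posterior accurate enough
for 95%-interval coverage.  These sizes are the package's own choices
and are asserted nowhere; larger runs only sharpen the same checks.

## Known limitations

* The causal chain is fixed and linear on the logit scale; no
  interactions, no kinetics, no exposure metrics.
* MCAR is the only missingness mechanism offered; informative
  missingness (e.g. assays more often inactive for weak compounds)
  would bias both the fit and the generator's calibration experiments.
* The tertile threshold default is a stand-in for an unspecified
  derivation; fixed thresholds should be preferred when screening
  decisions matter.
* With heavily missing labels for one node (as for BDNF), that node's
  confusion-matrix metrics rest on few compounds and its predictive
  distribution is dominated by pooling and imputation priors.

## A worked run

```{r, eval = FALSE}
sim <- simulate_dnt_data(seed = 1)           # 88 compounds, study-like gaps
dm  <- build_design_matrices(sim$data)
fit <- fit_dnt(dnt_model(dm), seed = 2)
glance(fit)                                  # divergences, rhat, ess
diagnose_fit(fit)                            # loo / waic / brier battery
predict_report(fit)                          # per-compound classes
evaluate_fit(fit)                            # confusion-matrix metrics
```

The same stages are scriptable end to end through `run_pipeline()` with
a `pipeline_config()` or a YAML file, each stage writing its artifact
(dataset CSV, EDA JSON, posterior container, diagnostics JSON,
prediction CSV, metrics JSON, sensitivity CSV) plus a log line carrying
the configuration hash and seed.
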