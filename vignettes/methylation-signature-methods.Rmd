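---
title: "Methods: discovering CpG methylation signatures with cpgmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering CpG methylation signatures with cpgmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

cpgmark discovers minimal CpG methylation signatures of a binary mutation
status from Illumina 450K-style β-value matrices, and evaluates them with
differential-methylation, classification, expression-correlation and
survival tooling. This vignette documents the statistical model behind
each stage, the numerical choices made in the implementation, and the
design and limits of the synthetic-cohort generator that makes the whole
pipeline testable end to end.

## The data model

A methylation array reports, for each CpG probe and sample, a β-value
$\beta = M/(M+U) \in [0,1]$ — the fraction of methylated signal. The
central biological expectation encoded throughout the package is that
loss of a gene-body-associated chromatin mark produces **hypomethylation
at gene-body probes** (Δβ < 0, case − control) and, secondarily,
**hypermethylation at promoter probes** (TSS200/TSS1500). Probes carry a
manifest with genomic coordinates and one of seven Illumina region
classes (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, IGR).

## Differential methylation: the moderated t-test

With a few hundred samples and hundreds of thousands of probes, per-probe
variance estimates are noisy. `moderated_t_test()` shrinks them toward a
common prior. For probe $g$ with pooled two-group variance $s_g^2$ on
$d_g$ degrees of freedom, we posit the scaled inverse-chi-square prior
$1/\sigma_g^2 \sim \chi^2_{d_0}/(d_0 s_0^2)$ and use the posterior
variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},$$

giving a moderated statistic
$t_g = \Delta\beta_g / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ referred to a
t distribution on $d_g + d_0$ degrees of freedom. The hyperparameters
$(d_0, s_0^2)$ are fitted by the method of moments on $z_g = \log s_g^2$:
under the model, $\mathrm{Var}(z_g) = \psi'(d_g/2) + \psi'(d_0/2)$ and
$\mathrm{E}(z_g)$ involves $\psi(d_g/2)$ and $\log s_0^2$, where $\psi$
and $\psi'$ are the digamma and trigamma functions. Solving the variance
identity requires inverting the trigamma function, done by a Newton
iteration (`trigamma_inverse()`). Two limits are exposed for testing and
transparency: `prior_df = 0` recovers the ordinary pooled Student t, and
`prior_df = Inf` uses a single common variance for all probes. When the
observed spread of $z_g$ is no larger than its sampling noise the moment
equation has no positive root; the fit then falls back to $d_0 = \infty$
with a warning, which is the correct limiting behaviour for homoscedastic
probes.

This moment-on-log-variance estimator differs from limma's F-distribution
fit, but the shrinkage structure is identical; the test suite verifies
near-perfect rank agreement of the two statistics on simulated cohorts.

Multiplicity is controlled by Benjamini–Hochberg (`bh_adjust()`, a
validated wrapper of `stats::p.adjust`), and `call_dmps()` declares a
probe differentially methylated when its adjusted p is **strictly below**
α (0.05), splitting calls by the sign of Δβ. A zero Δβ with a significant
p is refused as an error rather than silently binned. Region enrichment
of a probe set (`region_enrichment()`) is a two-sided Fisher exact test
per region class; `pan_negative_compare()` repeats the moderated test
after excluding control samples that carry confounder mutations, the
analysis that disentangles a mutation-specific signal from a co-occurring
one.

## The signature engine

`fit_cpg_signature()` is the package's central fitting function. It
returns a classed object with `print`, `summary`, `coef`, `predict` and
`plot` methods, in the tradition of R modelling functions. Internally it
composes exported building blocks, so every stage can also be driven (and
tested) separately:

1. **Repeated stratified random sampling** (`run_resampling()`): for each
   training-set size and replicate, draw a stratified train/test split.
2. **Inner model selection** (`cross_validate_hyperparams()`): inside the
   training set only, rank probes by $|t_g|$ (moderated t), keep the top
   `n_keep`, and fit elastic-net logistic regressions (glmnet) over a
   grid of mixing α and penalty λ; choose the combination minimising
   mean out-of-fold binomial deviance across stratified folds. The
   screening is re-run inside every fold, so no test information leaks
   into feature selection.
3. **Refit and score**: refit on the full training set at the selected
   hyperparameters and record held-out misclassification (threshold
   0.5), Brier score and mean absolute error.
4. **Size selection** (`summarize_sizes()`, `select_best_model()`): mean
   error per size with a t-based 95% confidence interval; the winning
   size is the one with the lowest CI **upper bound** (ties to the larger
   size — more training data at equal evidence), and the final model is
   the winning size's candidate with the lowest misclassification (ties:
   fewer features, then larger penalty, then lower replicate index —
   always preferring the sparser, more regularised model).
5. **Inclusion probability** (`inclusion_probability()`): the fraction of
   the winning size's candidate models in which each CpG has a nonzero
   coefficient — a stability measure that separates reproducibly selected
   probes from one-off picks.
6. **Threshold tuning** (`tune_threshold()`): the classification cut-off
   on the predicted probability is chosen to maximise balanced accuracy
   over all midpoints of consecutive distinct predicted probabilities
   (plus 0.5), with ties resolved toward the threshold closest to 0.5.

Prediction (`predict_signature()`) is plain logistic scoring
$p = \mathrm{logit}^{-1}(\beta_0 + \sum_j w_j \beta_j)$ with a sample
called *case* when $p$ is at or above the threshold; missing β-values at
signature probes are imputed with the training means stored in the
signature, so a fitted signature is self-contained.

## Evaluation, expression and survival

- `confusion_metrics()` treats *case* as the positive class and reports
  sensitivity, specificity, false-negative rate, accuracy and balanced
  accuracy. `roc_auc()` computes the Mann–Whitney AUC with midranks
  (half credit for ties) and the full ROC step curve.
- `bayes_posteriors()` converts sensitivity, specificity and a prior
  prevalence into the posterior probability of true mutation given a
  positive or a negative prediction, via the law of total probability —
  the quantity that tells a screening user how much a wild-type call can
  be trusted.
- `pca_projection()` projects samples on the signature probes (centred,
  unscaled principal components) to visualise separation along PC1.
- `flanking_pairs()` pairs probes with genes whose transcription start
  site lies within an inclusive ±250 kb window on the same chromosome;
  `correlate_pairs()` computes Pearson correlations of β against
  log1p(expression) with BH adjustment, skipping (and counting)
  degenerate pairs.
- `maxstat_cutoff()` finds the maximally selected log-rank statistic: the
  linear log-rank (Savage) scores $a_i = \delta_i - \hat\Lambda(t_i)$
  (Nelson–Aalen cumulative hazard) are accumulated over β-sorted samples,
  so all admissible cuts are evaluated in one $O(n\log n)$ pass, each
  standardised by the permutation variance
  $\frac{n_1 n_2}{n(n-1)}\sum_i (a_i - \bar a)^2$. Because the cut is
  chosen to maximise |Z|, the naive log-rank p at the chosen cut is
  anti-conservative; the reported p is instead a permutation p over the
  **maximum** statistic, $(1 + \#\{\max Z^{perm} \ge Z^{obs}\})/(B+1)$,
  which is valid by construction and never returns an impossible zero.
  Candidate cuts are midpoints between consecutive distinct marker
  values with both groups at least `minprop` (default 10%) of the
  cohort. `km_estimate()` and `logrank_test()` wrap the survival
  package's product-limit estimator and log-rank test.

## The synthetic-cohort generator

`simulate_cohort()` draws a cohort whose defaults **are** the package's
study conditions: 60 cases vs 140 controls, 2,000 probes, 3 planted
hypomethylated gene-body probes with Δβ = 0.3, 2% missingness. Design
choices, in the order they matter:

- **Bimodal background.** Real 450K data are strongly bimodal; unplanted
  probes get baseline means drawn near 0.15 or 0.85, and each β-value is
  drawn from a Beta distribution with that mean.
- **Planted structure mirrors the biology.** Hypomethylated signal probes
  are forced into the Body region class with case means shifted down from
  0.80; hypermethylated ones into TSS200/TSS1500, shifted up from 0.15.
  Shifts that would push a group mean outside (0,1) are rejected at
  configuration time.
- **Concentration 12.** The Beta concentration (a+b) controls biological
  spread: concentration 12 gives within-group standard deviations of
  roughly 0.10–0.14, in line with the probe-level spread seen in tumour
  cohorts, where cellular heterogeneity and purity variation blur group
  differences. Much larger concentrations make cohorts nearly separable
  and every downstream error collapse to zero, which would trivialise the
  size-selection machinery the package exists to exercise.
- **Confounder mutations.** Controls can carry a confounder mutation
  (default co-occurrence 0.6 in cases, 0.10 in controls) driving its own
  probe set, so `pan_negative_compare()` has a real signal to remove.
- **Linked layers.** Gene transcription start sites are anchored near
  probes so cis pairs exist; `simulate_expression()` adds expression with
  a per-pair slope on β (validated to lie within the cis window), and
  `simulate_survival()` draws exponential event times with hazard
  $\lambda_0\exp(\sum c_j \beta_j)$ plus independent exponential
  censoring.
- **Limits.** The generator has no batch effects, no probe cross-
  reactivity, no purity covariate, MCAR-only missingness, and
  independence across probes conditional on the planted structure — so it
  validates algorithmic correctness and statistical calibration, not
  robustness to array artefacts.

## Numerical and reproducibility choices

- Coefficients below 1e-10 in absolute value from the coordinate-descent
  fit are treated as exact zeros; glmnet occasionally stores O(1e-15)
  dust that would otherwise corrupt feature counts and inclusion
  probabilities.
- All tie-breaks are deterministic and documented (probe id, size, number
  of features, penalty, replicate index), so results are invariant to
  input order.
- All randomness flows from one master seed through
  an internal seed-derivation step (a seeded `sample.int` of the 31-bit
  integer range), giving every replicate an independent, reproducible
  stream; two runs with the same seed are bit-identical.
- Permutation p-values use the add-one estimator $(1+x)/(B+1)$.
- Problem sizes used throughout the documentation and tests — 200-sample
  cohorts, 500–2,000 probes, training sizes spanning 20–80% of the
  cohort, 8–50 replicates per size — were chosen so a full
  `fit_cpg_signature()` run completes in seconds to a couple of minutes
  on one CPU while leaving every selection mechanism (screening, CV,
  size choice, stability) non-trivially exercised.

## A worked run

```{r, eval = FALSE}
library(cpgmark)
co <- simulate_cohort(sim_config(seed = 7))
fit <- fit_cpg_signature(co$betas, co$samples$status,
                         sizes = c(40, 80, 120, 160), replicates = 8,
                         grid = signature_grid(n_keep = c(10, 25),
                                               alpha = c(0.5, 1)),
                         seed = 7)
print(fit)
plot(fit)                      # mean error vs training size with 95% CIs
pred <- predict(fit, co$betas, type = "both")
confusion_metrics(co$samples$status, pred$label)
```
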