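---
title: "Methods: Rasch person fit and a micro-CNN for four-quadrant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rasch person fit and a micro-CNN for four-quadrant screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmh)
```

`elmh` classifies respondents of a 44-item, 8-domain Likert
questionnaire into four mental-health classes by crossing a latent
severity measure with a person-fit statistic, and then compresses the
classification into a 108-parameter convolutional network. This
vignette is the package's account of the science: the models, the
parameters that matter, the simulator the tests rest on, and the
numerical and design choices that were genuinely open.

## The measurement model

Responses are treated as continuous scores in a bounded range
$[m, M]$ (by default the 1–5 Likert range). A person with severity
$\theta_i$ (logits) answering an item of difficulty $\delta_j$ is
expected to score

$$E_{ij} = m + (M - m)\,\sigma(\theta_i - \delta_j),
  \qquad \sigma(x) = \frac{1}{1+e^{-x}},$$

a scaled-logistic item characteristic curve: the familiar Rasch
structure (only the difference $\theta-\delta$ matters, so the model
family is translation invariant) extended to a continuous bounded
response. `fit_rasch()` estimates all $\theta_i$ and $\delta_j$ by
joint maximum likelihood — alternating damped Newton updates on the
unidimensional score equations
$\sum_j (O_{ij} - E_{ij}) = 0$ and $\sum_i (O_{ij} - E_{ij}) = 0$ —
until the largest parameter change falls below `tol` (default `1e-6`,
at most 500 sweeps; on cohorts of a few hundred persons convergence
takes well under ten sweeps). Difficulties are centred to mean zero
after every sweep; that centring is the scale anchor that makes
"0 logits" a meaningful cut. Non-convergence returns the last iterate
with a warning and `converged = FALSE`.

### The variance function and its dispersion constant

The model variance enters only through the person-fit statistic. We
write it as

$$W_{ij} = \frac{(M-m)^2\,p_{ij}(1-p_{ij})}{\nu},
  \qquad p_{ij} = \sigma(\theta_i - \delta_j),$$

with a dispersion constant $\nu > 0$. The bare form ($\nu = 1$) is the
variance of a single Bernoulli step scaled to the full range — it is
what `expected_and_variance()` returns by default, and it is the right
object when the "response" genuinely is a two-point outcome stretched
over $[m,M]$. For Likert data it is far too large: at $p = 0.5$ on a
1–5 scale it equals 4, which exceeds even the variance of a uniform
random response (2), so *no* realistic responder could reach the
nominal outfit expectation of 1 and random responders would appear to
*underfit*. Reading a $K$-category Likert item as $K-1$ unit Bernoulli
steps (the binomial-trials view of a rating scale) gives
$\nu = M - m$, i.e. $W = (M-m)\,p(1-p)$ — about 1 at the scale centre
— and restores the standard person-fit calibration: conforming
responders have outfit near 1, uniform random responders near 2–3.
`fit_rasch()` therefore defaults to $\nu = M-m$ (equivalently,
dispersion 1 on a response already scaled to $[0,1]$). The constant
only rescales the fit statistics; the maximum-likelihood point
estimates of $\theta$ and $\delta$ do not depend on it.

### Person fit and the four quadrants

The outfit mean square of person $i$,

$$\mathrm{outfit}_i = \frac{1}{L}\sum_{j=1}^{L}
  \frac{(O_{ij}-E_{ij})^2}{W_{ij}},$$

is outlier-sensitive (unweighted across items) and has expectation
$\approx 1$ under the model. `classify_person()` crosses the measure
(cut at 0 logits) with the outfit (cut at 2.0):

| quadrant | measure | outfit | reading | confidence |
|----------|---------|--------|---------|------------|
| II  | > 0 | < 2.0 | mental illness | high |
| III | ≤ 0 | < 2.0 | health / MI-free | high |
| I   | > 0 | ≥ 2.0 | "false MI" | low |
| IV  | ≤ 0 | ≥ 2.0 | "false health" | low |

Boundary ties are fixed and documented rather than left to floating
point: a measure exactly at the cut falls on the low side, an outfit
exactly at the cut counts as misfit. The four predicates are mutually
exclusive and exhaustive for any finite pair, and raising the outfit
cut can only move people *out* of the misfit classes — both properties
are tested.

Why fit the Rasch model on the 44 raw items rather than on the eight
aggregated domain scores? Person-fit detection is the point of the
misfit axis, and aggregation destroys it: a careless responder's
*domain means* sit near the model expectation even though the
item-level pattern is noise, so an outfit computed over eight domain
scores barely moves. Item-level residuals keep the signal
(44 squared residuals, each with the right variance scale). The
domain-score path remains available — `fit_rasch()` accepts any
persons × items real matrix with its range, e.g. Bartlett scores
rescaled to $[0,1]$ — but the canonical pipeline, and the generator's
truth labels, use the raw items.

### Extreme response patterns

All-minimum or all-maximum rows (and columns) have no finite maximum
likelihood estimate. They receive a 0.3-score-unit adjustment toward
the interior, spread evenly over the items, before estimation — the
conventional fractional-score correction — so every person gets a
finite, strongly negative (or positive) measure.

### Rating-scale category curves

For display, `rating_scale_curves()` evaluates the rating-scale-model
category probabilities
$P(k \mid \theta) \propto \exp\sum_{h\le k}(\theta-\delta-\tau_h)$
on a measure grid. Rows sum to exactly 1 by construction, and adjacent
categories $k-1, k$ are equiprobable at $\theta = \delta + \tau_k$;
the tests verify both and check the closed form against a brute-force
enumeration of the category likelihoods.

## Factor scoring

`extract_factors()` uses principal-component extraction from the item
correlation matrix with varimax rotation. Factor retention follows the
eigenvalue-$\ge 1$ rule (inclusive; `retain_factors()` warns when
nothing qualifies). Extraction and rotation method were open choices —
only "exploratory factor analysis with the eigenvalue rule" was fixed
— so the most common default was taken and exposed as an argument;
orthogonal rotation is required by the scoring algebra below and
leaves communalities untouched (tested to 1e-8).

Bartlett weighted-least-squares scores
$F = (\Lambda'\Psi^{-1}\Lambda)^{-1}\Lambda'\Psi^{-1} z$ are
conditionally unbiased given the true factor and are computed from the
cohort's own item means and SDs; those statistics are persisted in the
model JSON so a *single* new respondent is standardized consistently.
Because varimax factors come in arbitrary order and sign,
`elmh_model()` aligns each questionnaire domain with the factor
carrying the largest squared-loading mass on its items (greedy,
largest domains first) and orients it so that higher raw responses
raise the score — making the per-domain regressions comparable across
cohorts.

For deployed scoring without a response matrix, each domain's factor
score is approximated by an ordinary least-squares regression on the
domain raw sum (`fit_score_regressions()`). The package ships a fixed
default mapping (`default_score_regression()`), e.g. domain 1:
$F_1 = -3.2516 + 0.08190 \cdot \mathrm{sum}_1$; all eight shipped
slopes are positive, so scores increase strictly with the raw sum.

## The micro convolutional network

The supervised stage is intentionally minimal — small enough to audit
cell by cell in a spreadsheet, hence "micro":

1. the 44 responses are rescaled to $[0,1]$ and placed row-major into
   a 10×10 grid, the remaining 56 cells exactly zero;
2. per class $c$: a 3×3 filter + bias, valid convolution (stride 1,
   10 → 8), sigmoid activation;
3. 2×2 non-overlapping max pooling (8 → 4), flattened to 16 values;
4. per class: a fully connected layer (16 weights + bias) and a
   sigmoid output;
5. prediction = arg max over the four class outputs (ties to the
   lowest index). Outputs are independent sigmoids, not a softmax, and
   are not normalized to sum to one.

Parameter accounting: $4\times(3^2+1) + 4\times(16+1) = 108$. The
10×10 row-major arrangement is a design choice — the input geometry
for 44 items is otherwise unconstrained — and it is the smallest
square grid whose conv+pool chain produces the 16-element pooled layer
that makes the 4×(10+17) accounting come out exactly.

Training (`train_cnn()`) minimizes the mean-over-persons summed
squared error against one-hot labels by full-batch gradient descent
with a fixed learning rate (default 2; the loss is mean-scaled, so the
rate is independent of cohort size), from a seeded uniform(−0.5, 0.5)
initialization. Gradients flow through the pooling by argmax routing;
`cnn_gradient()` exposes the analytic gradient, which the tests check
against central finite differences to better than 1e-5 relative error.
Descent with a fixed step is not guaranteed monotone, so the trainer
tracks and returns the best parameters seen — the returned loss never
exceeds the initial loss. Stopping: `max_epochs` (default 3000) or a
loss improvement below 1e-8. No train/test split is performed by
default; reported accuracy is apparent (resubstitution) accuracy,
matching how such small fully-specified models are usually audited,
and a holdout can be made trivially by subsetting before calling
`train_cnn()`.

The discriminant baseline (`discriminant_baseline()`) is classical
equal-prior linear discriminant analysis: class means, pooled
within-class covariance, linear scores
$x'S^{-1}\mu_k - \tfrac12 \mu_k' S^{-1}\mu_k$. Equal priors were
chosen because the four classes are highly unbalanced and a
prior-weighted rule would mostly relabel everything to the majority
class; a singular pooled covariance (e.g. duplicated features) is
ridge-regularized with 1e-6 on the diagonal, with a warning. The tests
cross-check it against an independent LDA implementation. Adding the
outfit as a ninth feature alongside the eight factor scores gives the
discriminant direct sight of the misfit axis; the tests confirm the
9-feature set beats or ties the 8-feature set on average over 20
simulated cohorts.

`required_sample_size()` implements the worst-case-proportion survey
formula $n_0 = z^2 p(1-p)/d^2$ with finite-population correction
$n = n_0/(1+(n_0-1)/N)$, $z = 1.959964$ at 95% confidence, ceiling
rounding: $N = 1521$ gives 307, $N \to \infty$ gives 385. Note that
grossing a required sample up for an anticipated 40% refusal rate is
$307/0.6 \approx 512$, not any other figure.

## The cohort simulator

`simulate_cohort()` generates the conditions the pipeline assumes, so
every downstream stage can be tested against known truth:

* **n_persons = 352, 44 items in domains 16/5/4/4/5/4/4/2** — the
  reference cohort geometry;
* **trait_mean = −0.9, trait_sd = 1** (logits): a mostly-healthy
  workforce; about 18% of conforming respondents sit above the 0-logit
  cut, giving a roughly 1:4 split between quadrants II and III;
* **domain_sd = 0.5**: each person carries an independent per-domain
  trait component on top of the shared severity, so domains form
  correlated item blocks (a shared-severity-dominant structure);
  setting `trait_sd` near 0 with `domain_sd` around 1 instead yields
  eight nearly independent block factors, the configuration the
  factor-retention tests use;
* **difficulty_spread = 1**: item difficulties equally spaced in
  $[-1, 1]$ — deterministic and easy to document;
* **noise_sd = 0.8**: conforming persons respond with
  $E_{ij} + \mathcal N(0, \mathrm{noise\_sd}^2)$, rounded and clipped
  to the Likert range. The value is derived, not tuned: averaging the
  model variance $W = (M-m)p(1-p)$ over the default trait/difficulty
  distribution gives $\bar W \approx 0.69$, and subtracting the
  rounding variance $1/12$ leaves a noise SD of
  $\sqrt{0.69 - 1/12} \approx 0.78 \approx 0.8$. Matching the noise to
  the model variance is what "model-conforming" means — it makes the
  outfit statistic calibrated (cohort mean in $[0.8, 1.2]$), which the
  acceptance tests verify at $n = 1000$;
* **aberrant_fraction = 0.07**: careless responders answer uniformly
  at random over the Likert range — the simplest mechanism that
  inflates outfit (their residual variance ≈ 2 against $W \approx
  0.8$–1 puts their outfit near 2.2–2.5, mostly past the 2.0 cut).

Truth labels (`true_quadrant`) are assigned by running the package's
own Rasch fit and cutoffs on the generated cohort — not from the
aberrant flag — mirroring how a real cohort would be labelled; the
classifier-equals-truth test then checks pipeline wiring end to end.
Identical configurations (including the seed) reproduce byte-identical
cohorts, and the generator restores the caller's RNG state.

Under the defaults the simulated class structure lands near
8/69/264/11 out of 352 — the intended shape: a dominant healthy class
(~75%), a substantial symptomatic class, and a small low-confidence
fringe driven by the planted careless responders.

**What the simulator does not emulate.** Real questionnaire data have
skewed category usage, item-specific discriminations, local item
dependence within wordy subscales, demographic heterogeneity and
missingness; the generator has none of these. Passing tests therefore
demonstrate internal correctness and behaviour under the stated
conditions, not instrument validity on field data.

## Problem sizes and numerical choices

The test suite simulates at $n$ = 352 for pipeline checks, 500 for
parameter recovery (measure–trait correlation > 0.9), 1000 for outfit
calibration, 400 (half aberrant) for misfit separation, and 20 seeds
of 352 for the discriminant feature-set comparison; the micro-CNN
end-to-end check trains 3000 epochs on one 352-person cohort
(training accuracy ≥ 0.85, typically ≈ 0.94), and the network-versus-
discriminant ordering sweep uses 10 seeds at 1500 epochs (the loss
curve is essentially flat after ~1000 epochs). These sizes keep a full
run at a few minutes on one core while leaving the statistical margins
wide.

Numerical notes: Newton steps are clamped to ±1 logit per sweep;
probabilities inside initialization are clipped to $[10^{-4},
1-10^{-4}]$; the rating-scale numerators are max-shifted before
exponentiation; degenerate inputs (all-identical responses,
zero-variance items, zero uniqueness, empty confusion matrices,
non-dividing pool geometries) raise early, named errors. All model
artifacts serialize to schema-versioned JSON, and the CNN loader
rejects files whose parameter count disagrees with their declared
geometry.

## Known limitations

* Joint maximum likelihood is consistent in items only as $L$ grows;
  with 44 items the measures carry the usual small JML bias —
  irrelevant for classification at a 0-logit cut, but the measures are
  not bias-corrected.
* The continuous-response formulation (scaled-logistic mean,
  binomial-trials variance) is one concrete, testable choice among
  several continuous Rasch variants; alternatives differ mainly in the
  variance function, which here is absorbed into the dispersion
  constant.
* Infit, standardized fit statistics and differential item functioning
  are out of scope, as are oblique rotations and confirmatory factor
  models.
* The micro-CNN is a classifier of the quadrant labels, not an
  independent diagnostic: it can at best reproduce the Rasch-side
  labels it was trained on.
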