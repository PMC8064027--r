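---
title: "Methods: case-series analysis of a multi-domain visual battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-series analysis of a multi-domain visual battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseseries)
```

## The analytic problem

After posterior cerebral artery stroke, patients can present anywhere on a
continuum from fully preserved visual recognition to severe impairment of
reading, object recognition and face recognition. Two analytic traditions
answer different questions about such cohorts. A *data-driven* group
analysis asks what dimensions organise the variation in performance across
the whole battery; a *single-subject case-series* analysis asks, for every
patient individually, whether they are impaired in each domain and whether
domains dissociate. This package implements both tracks over the same
cohort object and joins their outputs, so concordance between them is a
result, not an assumption.

The cohort is a wide table: one row per participant (controls and patients
with left, right or bilateral lesions), demographic covariates, and one
column per test measure (`<test>__<measure>`). A battery schema declares
each test's domain (word / object / face / low-level), its measures with
their direction (accuracy-like or RT-like), and whether it enters the
domain composites. The default schema has 22 tests; four per higher-level
domain are composite-flagged so that task demands are matched across
domains.

## Imputation by probabilistic PCA

Missing scores (about 3% of cells in the motivating application, whether
from technical failure or patient fatigue) are completed before any factor
analysis. We fit probabilistic PCA — the latent Gaussian model
$x = W z + \mu + \varepsilon$, $z \sim N(0, I_k)$,
$\varepsilon \sim N(0, \sigma^2 I)$ — by EM over the observed cells only,
treating both the latent scores and the missing cells as latent variables.
This makes the observed-data log-likelihood non-decreasing across
iterations, which the object records (`loglik_trace`) and the tests assert.
Initialisation is a seeded random orthonormal basis; convergence is a
relative log-likelihood change below `tol` (default 1e-6, maximum 1000
iterations); $\sigma^2$ is floored at 1e-12 so exactly low-rank input
cannot produce a degenerate model.

The component count $k$ is chosen by element-wise cross-validation:
observed cells are partitioned into folds (each fold leaving every row and
column observed at least once), each fold is masked in turn, the model is
refitted, and held-out cells are scored by RMSE; the chosen $k$ minimises
the mean RMSE with ties broken toward the smaller count. We hold out
*cells* rather than rows because a fully removed row has no observed
anchor from which reconstruction could be scored without a separate
predictive rule; a `mode = "rows"` variant (self-reconstruction of
held-out rows) is provided for comparison. The number of fold-assignment
redraws is configurable; the pipeline default (5) is deliberately smaller
than what one would use for a single definitive analysis (100 or more),
because rank selection on these matrices is stable across redraws.

Two modelling choices matter here. First, patients and controls are
imputed by *separately* fitted models: patient pathology should never
shape what is filled in for a control, and vice versa. Second, since PPCA
assumes isotropic residual noise, columns are z-scored before fitting
(accuracy percentages and RTs in milliseconds otherwise differ in scale by
orders of magnitude) and imputed values are mapped back afterwards.
Observed cells are returned bitwise unchanged.

## Preprocessing

RT-like measures are negated so that every column is uniformly
higher-is-better; the operation rewrites the measure directions, so it is
idempotent by construction. Tests with several measures are collapsed to
one column: measures are z-scored, scored on the first unrotated principal
component of their correlation matrix, sign-fixed so the accuracy measure
loads positively, and rescaled to unit variance. Collapsing runs *after*
imputation on the completed matrix. The collapse weights are estimated on
the rows entering the downstream analysis — patients for the group PCA,
everyone for the composites — and the stored plan maps any other rows
(e.g. controls projected into the patient PCA space) through the identical
transformation.

## Group PCA with control projection

The patient-only score matrix, z-scored to the patient group, is
eigen-decomposed via its correlation matrix. Sampling adequacy is
summarised by the Kaiser-Meyer-Olkin statistic computed from the
anti-image partial correlations; we refuse to compute it on a singular
correlation matrix rather than silently ridging it. Components with
eigenvalue strictly greater than 1 are retained (with a retain-one
fallback so degenerate input cannot yield an empty solution), and loadings
are varimax-rotated with Kaiser row-normalisation. Rotation is delegated
to `stats::varimax` behind the package's surface; our wrapper sign-fixes
each column (largest-magnitude loading positive), reorders factors by
post-rotation variance explained, and verifies orthogonality, so
communalities and total variance explained are conserved to 1e-8. The
test suite checks the rotation against a 0.01-degree brute-force grid
maximiser of the varimax criterion.

Factor scores use the regression method, $W_s = R^{-1}\Lambda$ — the
common default of mainstream factor-analysis software and therefore the
natural reading where the method is otherwise unspecified. Controls are
z-scored with the *patient* means and SDs, mapped through $W_s$, and
summarised per factor by their mean and SD; the impairment cutoff is the
control mean minus two control SDs. Two readings of that cutoff are
implemented: `score_sd` (default) takes the SD of the per-control factor
scores; `projected_pseudosubject` projects a synthetic subject sitting two
control SDs below the control mean on every test. The two coincide for
the mean (projection is linear) but not for the spread; we default to
`score_sd` because it uses the empirical distribution of actual control
scores rather than a worst-case-on-every-test profile.

## Composites and single-case inference

Per domain, the composite is the first unrotated principal component of
the composite-flagged tests, computed over controls *and* patients,
sign-fixed so the mean loading is positive and standardised over that
fitting sample. A non-parametric variant (`rank_sum`) averages per-test
ranks instead; the two should and do produce largely coincident deficit
flags (the suite checks agreement on synthetic cohorts).

Each patient's composite is compared to the controls by a Bayesian test
for a deficit allowing for covariates: a Monte-Carlo posterior under
non-informative priors on the control regression of score on covariates.
Per draw, the residual variance is sampled as $SSE/\chi^2_\nu$
($\nu = n - c - 1$), coefficients from a multivariate normal around the
least-squares estimate, and the case's conditional lower-tail probability
recorded; the reported $p$ is the posterior mean with a 95% interval from
the draw percentiles (widened, if necessary, to contain the point
estimate, which pure percentiles need not when the draw distribution is
extremely skewed). With no covariates this construction reproduces the
analytic single-case t-test (the suite holds them within 0.005 of each
other at 100,000 draws), and its one-tailed type-I error at $\alpha=.05$
calibrates into [0.042, 0.058] in simulation at $n = 46$ controls.

Age is the default covariate: control performance declines with age in
all three domains, in the motivating data and in the generator. Education
is deliberately not included — it did not correlate with domain
performance in the motivating data — and missing covariate values for any
participant entering a covariate-adjusted test are an error, not imputed.

Dissociations between domain pairs are tested with the Bayesian
standardised difference test allowing for covariates: per draw the
residual covariance of the bivariate control regression is sampled from an
inverse-Wishart (scale = residual cross-product, df $= n - c - 1$; the
"standard-theory" prior), coefficients from the matching matrix normal,
and the case's standardised difference
$(z_x - z_y)/\sqrt{2 - 2\rho}$ converted to a normal tail probability.
A `calibrated` prior variant is reserved in the interface but not
implemented; its exact construction is not recoverable from the method
descriptions available to us, so rather than guess we expose the
standard-theory posterior and document its simulated two-tailed null
rejection rate (within [0.03, 0.07] at $n = 46$ — mild prior sensitivity
is known for this family).

A patient is *classified* as follows: deficit flags per domain are
$p < \alpha$ (one-tailed lower, $\alpha = .05$, no multiple-testing
correction — matching the apparent practice of the motivating analysis; a
Bonferroni switch would be trivial but is off by default). The eight flag
combinations map to pattern labels NONE, W, O, F, WO, WF, OF, WOF. Only
patients with at least one deficit enter dissociation testing. A
*classical* dissociation on ordered pair (X, Y) requires: (1) a
significant deficit on X; (2) Y within the control range, operationalised
as deficit-test $p \ge \alpha$ on Y — the same inferential machinery as
criterion 1, rather than a separate ±2 SD band; (3) a significant
standardised X-Y difference (two-tailed by default; the tail is
configurable since the motivating description does not state it). When
both tasks are impaired but criterion 3 holds, the pair is labelled a
*differential* dissociation. The overlay report joins each patient's
factor scores, cutoff flags, laterality, lesion volume and pattern label
for the side-by-side view of the two tracks.

## The synthetic cohort generator

Real patient-level data of this kind cannot be publicly archived, so the
package carries a generator that emulates the cohort's statistical
structure with ground truth attached, and the whole test surface runs on
it. Per participant, a latent ability pair (word/object, face/object) is
drawn from a bivariate normal with correlation 0.25; each test's latent
score is its loading-weighted ability plus an age effect on z-scored age
plus independent noise; two-measure tests emit accuracy and RT measures
correlated at 0.8; 3% of cells are masked completely at random.

Defaults (all overridable, chosen once as a realistic regime and then
left alone):

* group sizes 46 controls / 32 left / 23 right / 9 bilateral;
* loadings: word tests (0.8, 0.1), face tests (0.1, 0.8), object tests
  (0.5, 0.5), low-level tests (0.3, 0.3) — objects deliberately split
  across both factors;
* age slope −0.15 per test, so control-score-age correlations are
  negative for every test and around −0.3 at the composite level;
* noise SDs word 0.35, object 0.40, face 0.45, low-level 0.55, giving
  controls the least variability on word tests and the most on face and
  low-level tests. These values come from a design-time eigen analysis of
  the implied correlation matrix: they put the third population
  eigenvalue near 0.55 so that the Kaiser rule retains exactly two
  components in ≥95% of samples at n = 63. A noisier first choice let the
  third *sample* eigenvalue cross 1 in roughly a fifth of samples, which
  would have made retention a coin toss rather than a property;
* lesion shifts of 0.6 latent SD on factor 1 (left), factor 2 (right) or
  both (bilateral), scaled by a lognormal lesion volume relative to the
  patient median; demographic marginals (age, education, lesion volume,
  time since stroke) match the cohort summary table they emulate.

Planted category-selective cases receive an extra deficit of $\Delta$
control SDs on every test of their domain and are recorded in the truth
object together with each participant's latent abilities and applied
shifts, plus the complete pre-masking matrix (so imputation error against
truth is measurable).

One measurement-design point: planted-case *sensitivity* and the null
false-positive rate are evaluated on cohorts generated with the lesion
shifts set to zero. With shifts on, a planted left-hemisphere case is
also pushed down on object tests by its ordinary group effect, so
"word-only" recovery would confound the classifier's selectivity with the
generator's laterality structure. Factor-structure recovery (retention
and loading congruence) is evaluated under the full defaults, where the
group shifts are part of the structure being recovered.

What the generator does *not* emulate: realistic RT distributions
(negation of a Gaussian stands in for the monotone map; no log transform,
matching the minimal treatment in the motivating analysis), missingness
related to severity (MNAR) — the generator is MCAR by construction and
the MCAR property is itself tested — and lesion geometry. Passing
recovery tests on this cohort therefore demonstrates that the pipeline's
inferential machinery is correct and calibrated under the assumed
structure, not that the assumptions hold in any particular clinical
dataset.

## Numerical and design notes

* Every stochastic stage derives its seed from the master seed by a fixed
  offset scheme, so adding a stage never perturbs earlier streams and a
  re-run is bit-identical (asserted in the suite, including written CSVs).
* Problem sizes in the test suite are scaled to what a laptop runs in
  minutes: calibration uses 5,000 null cases at 10,000 Monte-Carlo draws,
  rank-recovery 100 seeds of a 40 x 8 fixture, end-to-end retention 40
  cohort draws. The reported analyses default to 100,000 draws per test.
* The EM core is a small C++ routine (RcppArmadillo); the R wrapper owns
  validation, initialisation and the RNG.
* Ties in the Kaiser rule (eigenvalue exactly 1) are not retained
  (strictly greater than 1); CV ties prefer the smaller rank; varimax
  column order ties are broken by the post-rotation variance explained.
* Degenerate inputs fail loudly with coordinates: all-missing rows or
  columns, constant columns, collinear covariate designs, singular
  correlation matrices, conditional task correlations at ±1.

## Known limitations

The single-case tests are this package's formalisation of the cited
Bayesian method family under non-informative priors; the original
reference implementations are closed-source executables, so agreement is
established against the analytic covariate-free limit and by simulation
calibration rather than file-for-file comparison. The standardised
difference test inherits the family's known prior sensitivity (its null
rejection rate is near, not exactly at, the nominal level). KMO on
near-singular correlation matrices is refused rather than regularised.
The generator's effect sizes are tuning constants of a plausible regime,
not estimates of any study's parameters.
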