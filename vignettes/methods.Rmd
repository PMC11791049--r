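---
title: "Methods: simulating and decomposing infant gaze phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decomposing infant gaze phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

twingaze re-creates, end to end, a twin-design analysis of infant eye
movements during free viewing of dynamic scenes: raw 120 Hz gaze streams are
classified into fixations, scored against dynamic areas of interest (AOIs),
screened and residualized, and finally decomposed into genetic and
environmental variance components with cluster-robust association analyses
alongside. Because infant gaze cohorts are not publicly shareable, every
stage is exercised on synthetic data whose generative structure is known —
which is also what makes each stage testable. This vignette explains the
models, the generator, the numerical choices, and what the package's tests
do and do not establish.

## The twin model

For a pair of twins, the stacked phenotype vector (twin 1 traits, then
twin 2 traits) is modelled as multivariate normal. Phenotypic (co)variance is
decomposed through lower-triangular path matrices $a$, $c$ (or $d$), $e$
into additive-genetic ($\Sigma_A = aa^\top$), shared-environment
($\Sigma_C = cc^\top$) or dominance ($\Sigma_D = dd^\top$), and
non-shared-environment ($\Sigma_E = ee^\top$) components. The within-twin
covariance block is $\Sigma_A + \Sigma_C + \Sigma_D + \Sigma_E$; the
cross-twin block is $k_A\Sigma_A + \Sigma_C + k_D\Sigma_D$ with
$(k_A, k_D) = (1, 1)$ for monozygotic (MZ) and $(0.5, 0.25)$ for dizygotic
(DZ) pairs. $C$ and $D$ are not jointly identifiable from twin data, so a
model family contains at most one of them (ACE, ADE, AE, CE, E).

Estimation is full-information maximum likelihood (FIML): each pair
contributes the Gaussian deviance of its *observed* phenotype subvector, so
pairs with a missing co-twin (or a missing single trait) stay in the
likelihood. Internally the deviance is evaluated on per-missingness-pattern
sufficient statistics (count, sum, cross-product matrix per pattern), which
makes the objective cost independent of cohort size — fits on 100,000 pairs
take well under a second. Tests verify the grouped deviance against an
independent per-pair dense implementation to relative error below $10^{-8}$.

The optimizer (`nlminb`) works on unconstrained path coefficients, so any
iterate implies a positive semi-definite component; diagonal paths are
sign-normalized afterwards to remove reflection invariance. Five
deterministic starts are used: a Falconer-style moment decomposition of the
complete-pair covariance blocks, three fixed rescalings of it, and an
equal-split start. Convergence tolerance is $10^{-10}$ on the relative
deviance. Standardized components are path-variance shares of the total,
with $E$ computed as the residual share so the components sum to one
exactly.

The *saturated* benchmark estimates separate means and unstructured pair
covariances per zygosity (closed form with complete pairs; log-Cholesky
optimization otherwise). The *constrained* saturated model equates means,
variances, the phenotypic correlation and the cross-twin cross-trait (CTCT)
correlations across twin order and zygosity, leaving within-trait cross-twin
correlations zygosity-specific; the published workflow leaves the exact
constraint list partially implicit, and this literal reading is the one the
package adopts — the free/constrained likelihood-ratio test (the
"twin-assumption test") is always reported so the contrast is visible.
Model families are compared by AIC (lower wins; ties break toward fewer
parameters; differences under 2 are flagged as comparable fit) and by LRT
against the saturated model. When $r_{MZ} > 2 r_{DZ}$ suggests non-additive
effects, the selection layer still reports an ACE-family model by default,
mirroring the convention of reporting ACE rather than ADE in modest samples.

Confidence intervals: univariate standardized components get
profile-likelihood intervals (the component is fixed, the remaining
parameters — mean, total variance, and the other component's share on a
logit scale — are re-optimized, and the bounds are where the profiled
deviance rises by 3.841); bounds are clipped to $[0, 1]$ and flagged
one-sided at the boundary. Bivariate fits report delta-method Wald
intervals, which are cheaper and adequate at the sample sizes where the
bivariate model is used here.

## Cluster-robust associations

Association analyses use independence-working generalized estimating
equations: point estimates equal ordinary least squares, and inference uses
the cluster-robust sandwich covariance with the finite-cluster
$G/(G-1)$ adjustment and $t_{G-1}$ reference distribution — without the df
correction the test size is visibly inflated below ~100 clusters.
Clustering is on twin pair for between-subject questions and on individual
for the within-subject condition contrast (run separately per twin slot, so
pair dependence cannot leak in). For the condition contrast the two
condition measures are standardized *jointly* — per-condition z-scoring
would erase the level difference being tested. Polygenic-score associations
adjust for age, sex and 10 ancestry principal components and are flagged at
the raw 0.05 level and at a Bonferroni level of $0.05/4 = 0.0125$; the
divisor 4 follows the convention of the workflow being reproduced even
though seven scores are tested, so it is a config value and a warning is
emitted whenever it does not match the number of scores.

## The synthetic cohort

The generator is first-class, tested code. Its defaults are the study
conditions:

* **Pairs**: 146 MZ + 139 DZ (~285), ~6% with one co-twin missing.
* **Fixation-duration traits**: bivariate AE model, trait order (abstract,
  naturalistic), standardized genetic variances 0.25 and 0.30, genetic
  cross-covariance 0.17, unique-environment cross-covariance 0.16 (implied
  phenotypic correlation 0.33). Latent traits map to subject-level mean
  fixation durations of 552.53 ± 115.77 ms (naturalistic) and
  602.84 ± 149.87 ms (abstract).
* **Face-looking trait**: univariate AE with $A = 0.19$.
* **Scenes**: three actors side by side in a 1310 × 737 px panel centred in
  a 1920 × 1080 screen; 350 × 262 px face boxes whose centre sits one third
  of the box height above the face centre; activity alternates through
  all-inactive, mixed and all-active segments at 25 fps over 21 s. The
  original videos' layouts are unpublished, so these are plausible stand-in
  geometries; abstract videos share their naturalistic counterparts'
  geometry and dynamics, as digital scrambling preserves both.
* **Gaze streams**: 120 Hz fixation/saccade alternation. Within-subject
  fixation durations are lognormal (shape 0.5, right-skewed as in the
  cohort's descriptives), truncated to the analysable range 100–2358 ms,
  with the location solved per subject so the *truncated* mean equals the
  subject's latent mean — this is what makes downstream mean recovery
  unbiased by construction. Saccades are 20–80 ms linear ramps. Fixation
  targets are drawn from the AOIs conditional on the frame state at onset:
  inactive-actor looks land on the face with probability 0.60, and looks
  starting in mixed frames target an active actor with probability 0.71.
  Isotropic per-sample noise is calibrated so the successive-sample RMS is
  0.66 px (per-axis SD = RMS/2).
* **Wandering gaze**: interleaved smooth meandering segments at 400–900
  px/s (above any realistic velocity threshold, below saccadic speed), with
  a per-subject time fraction drawn from a Beta distribution centred on
  0.5. Infants spend much of a trial in gaze that classifiers do not count
  as fixations; modelling it reproduces the cohort's fixation-count
  distribution (~44 ± 28 per condition despite only ~10% missing samples)
  and — critically — gives the count large variance *independent* of the
  duration trait. Without it the count is a near-deterministic function of
  mean duration, and the quality-covariate residualization step would
  remove most of the true signal, which no real cohort shows.
* **Missing data**: ~10% of samples, inserted as short (2–8 sample)
  dropout runs strictly interior to fixations with clean margins, so the
  classifier's 75 ms gap-merge rule can repair the split. Long look-aways
  that censor fixation boundaries are deliberately *not* modelled: they
  would bias duration recovery in ways no classifier can undo, and the
  recovery tests are about the classifier. The trailing part of a video
  that cannot hold one more complete fixation is filled with wander or
  marked invalid rather than emitting a duration-censored fixation.

What the generator does **not** emulate: real saccade main-sequence
dynamics, smooth pursuit locked to the actors, calibration drift, binocular
disparity, or look-away censoring. Consequently, passing recovery tests
shows the pipeline is internally consistent and unbiased under this
generative model — not that it reproduces every property of real infant
data.

## Fixation classification

The classifier is an adaptive identification-by-velocity-threshold (I-VT)
procedure specified by this package (the published workflow delegates to an
external package whose exact behaviour is not reproduced; parity with it is
a non-goal — the implemented contract is the quoted behaviour that noisier
data yield more conservative thresholds):

1. Speeds are centered finite differences over runs of consecutive valid
   samples, smoothed with a 3-sample centered moving average; speeds never
   bridge invalid gaps.
2. The threshold iterates $T_{k+1} = \text{mean} + 6\,\text{SD}$ of speeds
   below $T_k$ from $T_0 = 250$ px/s until the change is below 1 px/s (50
   iterations cap), then is clamped from below by five times the
   sub-threshold median speed and an absolute floor of 10 px/s (the floor
   handles noise-free synthetic data, where the iteration collapses to 0).
3. Sub-threshold runs become candidate fixations. Because the smoothed
   centered difference smears saccade velocity over ~2 samples on each
   side, run edges are reclaimed when their one-sided step speed toward the
   run is sub-threshold — saccade-ramp samples never are, so reclamation
   restores the true boundary without swallowing saccades.
4. Runs separated by invalid or supra-threshold gaps shorter than 75 ms
   with centroid displacement under $0.7 \times 1.77 \times \sqrt{2}$ px
   are merged (blink repair). Offsets are the last run sample plus one
   sample period, so durations count whole sample windows.

Filters keep fixations with duration in $[100, 2358)$ ms (the lower bound
inclusive, the upper exclusive, matching "shorter than" / "longer than"
exclusion wording) and within-fixation RMS $\le 1.77$ px (inclusive). The
RMS is computed over adjacent valid sample pairs only. The 1.77 px cut is
printed in pixels in the source workflow while the cohort's mean RMS is
0.66 px; both are treated in pixels here and the cut is a config value.

On clean streams the classifier recovers ≥99% of generator boundaries to
within ~one sample period (the half-open tolerance accounts for the
continuous event boundary falling between grid samples) and the
cohort-level grand mean duration to within ~4 ms at 500 subjects — inside
the ±10 ms band the recovery suite demands.

## AOI scoring and exclusions

Fixation dwell is apportioned to video frames by overlap length; AOI
membership is evaluated at the fixation centroid (robust to sample noise,
matching the fixation-level phrasing of the scored measures), while actor
activity is read per frame, so a fixation straddling a transition
contributes dwell under both states. Face-looking proportion is face dwell
over inactive-actor dwell; active-looking proportion is active-actor dwell
over all dwell in mixed frames (the denominator includes dwell outside all
AOIs — the alternative reading, AOI-only dwell, is narrower and was not
adopted). Both are computed from the naturalistic videos. Frame-resolved
activity attribution slightly attenuates both proportions relative to
their generative probabilities (fixations chosen in one state straddle
into another); the recovery tests therefore check exact recovery on a
transition-free scene and bounded recovery on dynamic scenes.

Condition-level measures are excluded above 45.6% / 47.6% missing data
(naturalistic / abstract) or below 5 / 3 fixations — the source cohort's
95th/5th percentile cuts, taken here as fixed defaults with an optional
recompute-from-cohort mode — and proportions exactly 0 or 1 are dropped.

## Preparation

Each measure is screened against the gaze-quality covariates (fixation
count, mean RMS, missing proportion) with pair-clustered regressions;
covariates significant at two-sided 0.05 are regressed out, age and sex are
always included, residuals are z-scored, and wide pair tables are built
with twin order assigned deterministically by subject id (pairs whose twins
differ in age use the pair mean age). Residualize-then-model keeps the
likelihood mean structure trivial; the alternative (covariates inside the
FIML means model) was not adopted. Note the arithmetic consequence worth
knowing: OLS residualization scales the heritability of the residual by
$1 - R^2$ of the measure-on-covariates regression, so heritability
estimated downstream is attenuated exactly to the extent that quality
covariates genuinely share variance with the measure. In the demo cohort
(~285 pairs) this, plus sampling error at that size, is why single-run
estimates scatter around the generative values where the large-n recovery
suite pins them tightly.

## Problem sizes and determinism

All randomness flows from per-call integer seeds; identical seeds give
identical cohorts, and the optimizer's multi-starts are deterministic. The
recovery suite uses 50,000 pairs per zygosity for variance-component
recovery (estimates land within ±0.02–0.03 of the generative values), 500
subjects × 3 videos for pipeline mean recovery, and 2,000 replicates for
the likelihood-ratio and sandwich-test calibration checks; the
demonstration analysis under `analysis/` uses the study-scale cohort of 285
pairs × 6 videos. These sizes were chosen so each check's Monte-Carlo error
is small against its tolerance.

## Known limitations

* The constrained-saturated constraint set follows one literal reading; a
  different equating (e.g. variances free across zygosity) would change the
  assumption-test df.
* Profile CIs are univariate-only; bivariate components get Wald intervals.
* The scene geometries and activity schedules are invented stand-ins, so
  AOI-level results demonstrate the scoring machinery, not the original
  stimuli.
* The generator links conditions only through the latent bivariate trait;
  no within-session carry-over (order effects, fatigue) is modelled, and
  the two fixed presentation orders are recorded as metadata only.
* Sex-limitation models, liability-threshold models and >2-trait Cholesky
  decompositions are out of scope.
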