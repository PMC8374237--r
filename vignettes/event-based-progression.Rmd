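---
title: "Event-based modelling of Huntington's disease biomarker progression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based modelling of Huntington's disease biomarker progression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `hdebm`, the assumptions
behind them, the tunable parameters, the synthetic-data generator used to
validate the pipeline, and the numerical and design choices that were
genuinely open.

## The event-based model

Huntington's disease (HD) is caused by a CAG trinucleotide expansion in the
huntingtin gene; carriers progress from a premanifest period (PreHD) through
motor diagnosis (manifest HD) over decades, with regional brain atrophy
measurable years before clinical change. The event-based model (EBM) treats
progression as a fixed ordered sequence $S = (S(1), \dots, S(K))$ of
*events*, each event being the transition of one biomarker from its healthy
to its abnormal distribution. A subject at stage $k$ has experienced exactly
the first $k$ events. Given per-marker densities $p(x \mid E)$ (abnormal)
and $p(x \mid \neg E)$ (healthy), the likelihood of a subject's biomarker
vector $x$ under sequence $S$, mixing uniformly over the unknown stage, is

$$
p(x \mid S) \;=\; \frac{1}{K+1} \sum_{k=0}^{K}
  \prod_{i \le k} p\!\left(x_{S(i)} \mid E\right)
  \prod_{i > k} p\!\left(x_{S(i)} \mid \neg E\right),
$$

and the data log-likelihood is the sum of $\log p(x \mid S)$ over subjects
(`sequence_log_likelihood()`, computed with a log-sum-exp over stages).
Markers missing for a subject contribute a factor of 1 at every stage, so
they are simply uninformative rather than disqualifying.

Key assumptions: a single event ordering shared by the whole population,
monotone biomarker change (an abnormal marker stays abnormal), and
cross-sectional independence of markers given the stage. The model orders
events but carries no notion of the time between them.

## KDE mixture models of healthy and abnormal distributions

The component densities are estimated per marker from a reference cohort as
a two-component mixture whose components are *weighted kernel density
estimates* (Gaussian kernel, Silverman's rule-of-thumb bandwidth on the
weighted sample, using the effective sample size $1/\sum w_i^2$). KDE
components accommodate the skewed, floor-effected clinical scores for which
a two-Gaussian mixture is a poor description.

`fit_kde_mixture()` alternates component re-estimation with responsibility
updates, initialized from clinical labels: control rows are anchored to the
healthy component throughout, patient rows start split at the threshold
(control median + 1 control SD). One subtlety dictated the design: with two
*nonparametric* components and free soft weights, the mixture is not
identifiable — the healthy KDE can simply absorb the entire bimodal
marginal, and the EM slides to $\pi_{\text{abnormal}} \to 0$ (we observed
exactly this collapse with a soft-weight scheme). The fit therefore uses
hard (classification-EM) assignments during iteration, so the two
components keep disjoint patient support, and constrains patient
responsibilities to be monotone non-decreasing in the (oriented) marker
value via isotonic projection — the mixture-level counterpart of the
monotone-abnormality assumption. After convergence the *reported*
responsibilities are the soft, monotone-projected posteriors under the
final components, and $\pi_{\text{abnormal}}$ is their mean. If the fitted
abnormal component lies below the healthy one (weighted medians), the
components are swapped.

Mixtures are fitted on the reference cohort's baseline HC and HD rows only
(the groups that best sample the two ends of the distribution) and reused
for every cohort, so that all cohorts are scored on a common density scale.
Density evaluations are floored at $\varepsilon = 10^{-12}$ (configurable)
to keep log-likelihoods finite for outliers far outside the support.

## Covariate adjustment and orientation

Before any mixture fitting, each marker is adjusted by regressing against
covariates on baseline healthy-control rows of each cohort separately
(ordinary least squares): imaging markers on age, sex, site, total
intracranial volume and scanner field strength (the latter only binds in
cohorts acquiring at more than one strength); clinical markers on age, sex,
site and education. All rows — controls and carriers — are then
residualized with the control-fitted coefficients and z-scaled by the
control residual SD. Two choices here are additions on top of plain
adjustment, both motivated by the cross-cohort transfer of mixture fits:
z-scaling puts every cohort on a common scale, and a fixed a-priori
orientation sign per marker (atrophying volumes and declining cognitive
scores $-1$; enlarging ventricles and the rising motor score $+1$) makes
larger always mean more abnormal, removing a component-labelling ambiguity
from the mixtures. Covariates that are constant among a cohort's controls
(site in a single-site cohort, field strength at a single magnet) are
dropped with a warning; site levels never seen in a cohort's controls map
to the reference level with a warning. Baseline-only control rows are used
for fitting, matching the baseline-anchored design of the rest of the
pipeline.

The helper `disease_burden(age, cag)` returns the standard genetic-exposure
proxy $\text{age} \times (\text{CAG} - 35.5)$.

## Sequence inference: greedy ascent and MCMC

The maximum a-posteriori sequence is searched by greedy ascent over
pairwise position swaps from `n_starts` random initializations (default
16): all $K(K-1)/2$ swaps are scored and the best strictly-improving one is
applied until none improves. Equal-likelihood swaps are rejected, which
keeps the search deterministic given the seed; in flat regions of the
likelihood (events never observed abnormal in a cohort) the returned order
among those events is therefore start-dependent, which is faithfully
reported as ordering uncertainty by the sampler.

Ordering uncertainty is quantified by Metropolis–Hastings over
permutations: symmetric proposal (swap two uniformly chosen positions),
acceptance $\min(1, e^{\Delta \ell})$, uniform prior over sequences and
over stages including stage 0 — the standard EBM priors, adopted in the
absence of any contrary statement. Defaults are 100,000 iterations with
50,000 burn-in (one chain, seeded); the bundled analysis scripts use 20,000
/ 10,000, which is ample for $K = 8$ where the posterior is sharply
concentrated. The positional variance diagram $P[i,j]$ — the posterior
probability that event $i$ occupies position $j$ — is the fraction of
retained samples placing it there, and is doubly stochastic by
construction. The reported MAP is the best sequence seen anywhere (greedy
result or any MCMC state).

Cohort sequences are compared with Kendall's $\tau = 1 - 4d/(K(K-1))$,
where $d$ counts discordant pairs; $\tau = 1$ for identical and $-1$ for
reversed orderings. Because "tau distance" and "tau correlation" are used
interchangeably in parts of the literature, the normalized distance
$d / \binom{K}{2}$ is also exposed (`method = "distance"`).

## Staging

Given a fixed sequence (typically the MAP), the stage posterior of one
subject-visit is $p(k) \propto \prod_{i \le k} p(x_{S(i)} \mid E)
\prod_{i > k} p(x_{S(i)} \mid \neg E)$ over $k = 0..K$. Two summaries are
used: the maximum-likelihood stage (ties broken toward the *lower* stage —
the conservative choice for subjects whose data are compatible with several
stages), and the expected stage $\sum_k k\,p(k)$, a continuous measure that
carries staging uncertainty into downstream regression. Every visit is
staged independently; no within-subject monotonicity is imposed at
inference time, so longitudinal consistency is an emergent check rather
than a constraint. Each cohort is staged under its own MAP sequence for
cohort-level summaries, and additionally under the reference cohort's
sequence so that the pooled progression models operate on one common stage
scale.

## Progression models

For each integer CAG repeat length, expected stage is regressed on age with
a polynomial mixed-effects model (REML, `lme4`): `stage ~ age [+ age^2] +
(1 | subject)`, using gene carriers with at least one follow-up visit.
Degree 1 vs 2 is selected by the smaller mean width of the 95% confidence
band of the fitted mean curve over the observed age range — our concrete
reading of selecting the better-constrained fit; ties go to the linear
model. Coefficient-CI width would be a defensible alternative and is easy
to compute from the returned covariance. Groups with fewer than 3 subjects
with follow-up are skipped with a warning, since such fits are dominated by
individual trajectories.

The age at which a CAG group reaches a target stage (default stage 5, the
motor-score event position in the default panel — the model-based proxy
for motor onset) is the smallest real root of the fitted mean curve at
that stage, searched within the observed age range ±10 years; uncertainty
comes from a seeded parametric bootstrap (1,000 multivariate-normal draws
of the fixed effects, percentile 2.5/97.5). On noise-free linear data the
mixed fit degenerates (zero residual variance); the implementation then
falls back to ordinary least squares with a zero random-intercept variance,
which reproduces the generative line exactly.

## The synthetic multi-cohort generator

No public HD cohort data exist (the real studies are available only under
data-sharing agreements), so validation uses a generator that reproduces
the *structure* the EBM assumes, with known ground truth:

- **Panel**: five volumetric markers (putamen, caudate, pallidum, global
  white matter, lateral ventricles; ml) and three clinical scores (TMS,
  SDMT, SWRT; native units), with healthy means/SDs chosen at plausible
  magnitudes and pathological directions fixed from HD pathology.
- **True sequence** (default): putamen → caudate → pallidum → white matter
  → TMS → SDMT → SWRT → lateral ventricles, i.e. subcortical/white-matter
  atrophy before clinical change, the motor score fifth, ventricles last.
- **Stage dynamics**: stage$(t) = \mathrm{clip}(\mathrm{round}(r\,(CAG -
  35.5)(\text{age} - \text{age}_0)), 0, K)$ with onset age
  $\text{age}_0 = a_0 - a_1 (CAG - 35.5)$ — the simplest monotone
  mechanism in which longer repeats mean earlier onset *and* faster
  progression. Defaults $a_0 = 70$, $a_1 = 4$, $r = 0.05$ events/year per
  burden unit were calibrated once against the demographic structure of
  the real cohorts (manifest-HD baseline ages in the late 40s–early 50s at
  CAG ≈ 43–44, overlapping the control age range; CAG-40 carriers reaching
  the subcortical stages around age 70, CAG-49 carriers in their
  twenties).
- **Cohorts**: a TRACK-like balanced cohort (100/104/80 HC/PreHD/HD, 4
  sites), a PREDICT-like PreHD-heavy cohort (36/132/3, 20 sites, mixed
  1.5T/3T), and an IMAGE-like small single-site cohort (22/28/27) — 532
  subjects in total, up to 3 annual visits. Baseline stages are drawn
  uniformly over 0–4 for PreHD and with weights 0.35/0.30/0.20/0.15 over
  stages 5–8 for HD (observational HD cohorts recruit early-manifest
  patients). Group labels follow the generative convention: HC iff
  non-carrier, HD iff baseline stage has passed the motor-score event,
  PreHD otherwise — a simulation convention that mimics, but does not
  replicate, diagnostic-confidence-based criteria.
- **Covariates**: additive site offsets (drawn once per site × marker),
  sex, TIV and field-strength effects on imaging markers, education on
  clinical markers, all expressed in control-SD units (defaults 0.2–0.5);
  an optional per-cell missingness rate (default 0) and an optional
  right-skewed (shifted-lognormal) component family exercise the missing-
  data contract and the non-Gaussian case that motivates KDE components.

What the generator does *not* emulate: real per-marker effect sizes (the
default 2.0 control-SDs separation is a convention, not an estimate),
within-subject correlation of markers beyond the shared stage, measurement
floor/ceiling artefacts, scanner drift, and dropout. Passing tests on this
generator therefore demonstrate correctness of the machinery and
recoverability under the stated conditions — not performance on real
cohort data.

## Numerical choices and degenerate inputs

- Likelihood computed in log space; per-marker log-densities are clamped at
  $-700$ before the cumulative-sum matrix products (below the exp
  underflow threshold, and it avoids $-\infty \cdot 0$ NaNs).
- ML-stage ties break to the smallest stage; greedy ties reject the swap.
- Degenerate mixture inputs (all values identical) error; an all-control
  sample yields $\pi_{\text{abnormal}} \approx 0$ with the abnormal
  component anchored to the upper tail so densities remain evaluable.
- Singular adjustment designs drop the offending covariate (warning);
  aliased coefficients are zeroed (warning); unseen factor levels map to
  the reference level (warning).
- All randomness is seeded; the pipeline fans one global seed out to
  per-stage substreams, so stages can be re-run independently and a full
  rerun is bit-identical (verified by checksum in the test suite).
- Serialized mixture fits store doubles at 17 significant digits, so
  likelihood matrices recomputed from JSON are bit-identical.

## Problem sizes used in validation

The test suite and acceptance script run entirely on generated data:
oracle checks enumerate all permutations for $K \le 5$; MCMC calibration
uses a $K = 3$ instance against the exactly enumerated posterior (50,000
retained samples); sequence-recovery uses 20 replicates of a 300-subject
reference cohort at $K = 8$; cross-study checks use the full 532-subject
three-cohort design; progression checks use 50–200 subjects per fit and
200 replicates for bootstrap-coverage calibration. These sizes were chosen
to make every Monte-Carlo margin comfortable at desk scale.

## Known limitations

- The basic cross-sectional EBM recovers order, not the time between
  events; extending to temporal or subtype-aware variants is out of scope.
- A single sequence is assumed for the whole population; heterogeneous
  subtypes would be averaged over.
- Events essentially unobserved in a cohort (e.g. late events in a cohort
  with 3 manifest-HD subjects) have near-flat likelihood contributions;
  their MAP positions are then arbitrary and only the positional variance
  diagram conveys that honestly.
- The real studies' printed results (between-cohort tau of 0.5–0.57,
  age-at-onset figures) depend on restricted data; the package reproduces
  the *procedure* and validates it on synthetic ground truth instead.
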