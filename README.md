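# hdebm

Event-based modelling of imaging and clinical biomarker progression in
Huntington's disease (HD), across multiple observational cohorts.

HD is caused by a CAG repeat expansion in the huntingtin gene. Regional
brain volumes (putamen, caudate, pallidum, white matter, lateral
ventricles) and clinical scores (UHDRS Total Motor Score, Symbol Digit
Modalities Test, Stroop Word Reading Test) become abnormal in a
characteristic order as carriers progress from premanifest (PreHD) to
manifest disease. Knowing that order — and how fast carriers with
different CAG lengths move through it — matters for choosing endpoints and
recruiting participants in clinical trials. This package is for
biostatisticians and imaging researchers who want to infer that ordering
from cross-sectional cohort data, stage individuals along it, compare
orderings across studies, and relate progression to genetic burden.

## The model

The event-based model (EBM) treats progression as a fixed sequence
`S = (S(1), ..., S(K))` of biomarker abnormality events. With per-marker
densities `p(x|E)` (abnormal) and `p(x|¬E)` (healthy), a subject's
likelihood mixes uniformly over the unknown stage `k`:

    p(x | S) = 1/(K+1) * sum_{k=0..K} prod_{i<=k} p(x_S(i)|E) * prod_{i>k} p(x_S(i)|¬E)

The pipeline:

1. **Adjust** each marker for covariates (age, sex, site, TIV, field
   strength, education) against baseline healthy controls per cohort;
   z-scale and orient so larger = more abnormal.
2. **Fit KDE mixtures** — two-component mixtures with weighted
   kernel-density components — per marker on a reference cohort's HC and
   HD rows, and reuse them for every cohort.
3. **Infer the sequence** per cohort: greedy ascent for the MAP ordering,
   Metropolis–Hastings over permutations for uncertainty (positional
   variance diagrams), Kendall's tau between cohort sequences.
4. **Stage** every subject-visit: maximum-likelihood and expected stage
   from the stage posterior.
5. **Model progression**: per CAG repeat length, a polynomial
   mixed-effects regression of expected stage on age with subject random
   intercepts, and the bootstrap age at which each CAG group reaches the
   motor-score stage.

Because the real HD cohorts are available only under data-sharing
agreements, the package ships a synthetic multi-cohort generator
(`generate_multi_study()`) with known ground truth — a TRACK-like balanced
cohort, a PREDICT-like PreHD-heavy cohort and an IMAGE-like small
single-site cohort, 532 subjects in total — on which the whole pipeline is
validated.

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `06_progression.R`), writing artifacts under
`results/analysis/`. Running them in order prints, among other things:

```
$ Rscript analysis/01_simulate.R
Simulated 532 subjects, 1596 subject-visits across 3 cohorts
Ground-truth sequence: putamen -> caudate -> pallidum -> white_matter -> tms -> sdmt -> swrt -> lateral_ventricles

$ Rscript analysis/04_fit_sequences.R
TRACK    MAP: putamen -> caudate -> pallidum -> white_matter -> tms -> sdmt -> swrt -> lateral_ventricles
Pairwise Kendall tau between cohort MAP sequences:
        IMAGE PREDICT TRACK
IMAGE   1.000   0.786 0.929
PREDICT 0.786   1.000 0.714
TRACK   0.929   0.714 1.000

$ Rscript analysis/05_stage.R
Median ML stage by group at baseline (own-cohort sequence):
        HC HD PreHD
IMAGE    0  5     3
PREDICT  0  5     2
TRACK    0  6     2

$ Rscript analysis/06_progression.R
 cag degree n_subjects slope ri_sd resid_sd age_at_stage5 lower upper
  40      1        118 0.158 0.392    1.083          77.2  76.0  78.7
  43      1         44 0.263 0.638    0.933          54.5  53.5  55.8
  46      1         14 0.340 0.905    1.807          40.7  38.0  46.9
  49      1          5 0.537 0.000    0.803          23.6  22.8  24.6
Age at motor-score stage (5) is strictly decreasing in CAG.
```

Reading this: the reference cohort recovers the generative event order
exactly; the PreHD-heavy cohort (3 manifest HD) places the late events
less reliably, so its tau against the other cohorts is lower — the same
behaviour the multi-study literature reports on real data. Healthy
controls stage at 0, PreHD at intermediate and HD at late stages, and
carriers with longer CAG repeats are predicted to reach the motor-score
stage decades earlier (CAG 49 at ~24 y vs CAG 40 at ~77 y in this
simulation), with steeper fitted slopes.

The same workflow is available as a single call:

```r
library(hdebm)
res <- run_pipeline(run_config(sim = sim_config(), out_dir = "results/run", seed = 1))
res$tau                 # pairwise Kendall tau between cohort MAP sequences
res$sequences$TRACK$map # MAP event order of the reference cohort
head(res$staged)        # per subject-visit ML and expected stages
```

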