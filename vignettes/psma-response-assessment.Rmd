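---
title: "Quantitative whole-body PSMA-PET response assessment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative whole-body PSMA-PET response assessment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmaburden)
```

## The problem

In metastatic castration-resistant prostate cancer (mCRPC), treatment
response after PSMA-targeted radioligand therapy is conventionally
monitored with the serum PSA value. PSA is a single systemic marker: it
can move discordantly with the actual burden of viable, PSMA-expressing
tumour. Whole-body PSMA-PET offers a direct alternative — quantify the
total tumour burden on the pre-therapy scan and again on the follow-up
scan, and classify response from the relative change.

`psmaburden` implements that pipeline end to end:

1. **SUV quantification** — body-weight SUV conversion of activity maps
   and the voxel geometry needed for volumes.
2. **Segmentation** — fixed-threshold whole-body lesion segmentation
   with mask-based exclusion of physiological uptake and a relative
   threshold for liver disease.
3. **Burden metrics** — per-lesion and whole-body molecular tumour
   volume (MTV, mL) and total lesion PSMA (TLP, mL × SUV).
4. **Response classification** — modified PERCIST on ΔTLP/ΔMTV with a
   new-lesion override; PCWG3 bands on ΔPSA.
5. **Statistics** — method concordance, Spearman correlation screens,
   cohort summaries, Kaplan–Meier and log-rank survival stratification.
6. **Synthetic data** — phantoms and cohorts with exact ground truth so
   each stage is testable without any image download.

A packaged 17-patient mCRPC cohort (per-patient pre/post TLP, MTV and
PSA after one cycle of alpha/beta tandem radioligand therapy, with
new-metastasis flags) serves as the built-in worked example and
regression fixture; see `table2_fixture()`.

## SUV and geometry

Images are plain 3-D arrays of body-weight SUV,

$$\mathrm{SUV} = \frac{c \,[\mathrm{Bq/mL}]\; \cdot\; w \,[\mathrm{g}]}
  {A_{\mathrm{inj}} \,[\mathrm{Bq}] \cdot 2^{-\Delta t / T_{1/2}}},$$

with the injected activity decay-corrected from injection to scan start
(default half-life 67.71 min, the 68Ga value, overridable for other
isotopes). Lean-body-mass SUV variants are out of scope: SUVbw is the
standard reporting convention for [68Ga]Ga-PSMA-11. Grids use the
voxel-centre convention (physical position = origin + index × spacing)
and masks must share the exact grid — a mismatch is an error, never a
silent resample, because a resampled mask silently changes lesion
volumes. NIfTI-1 is the interchange format; spacing comes from the
header `pixdim` and the origin from the xform translation.

## Segmentation model

A voxel is a lesion candidate when its SUV is **at or above 3.0**. The
comparison is inclusive; vendor tools commonly implement "threshold 3.0"
this way, and no cohort value sits on the boundary, so the choice is
behaviour-neutral in practice. Percentage-of-maximum isocontours (41% /
50%) are deliberately not offered: they underestimate volume for the
heterogeneous, confluent uptake typical of heavily pre-treated disease,
which is the very reason a fixed threshold is used here.

Physiological uptake (bladder, kidneys, salivary glands, ...) is removed
by caller-supplied binary masks, mirroring the manual exclusion step of
the clinical workflow; the package does not attempt automatic organ
detection. Two mask names are special:

* `healthy_liver` — a lesion-free liver reference region;
* `liver` — the liver itself, segmented separately at
  `1.5 × mean SUV(healthy_liver)` because normal hepatic background
  sits near or above SUV 3, which would swallow liver metastases under
  the global rule. Supplying a `liver` mask without `healthy_liver` is
  an error: the relative threshold would be undefined.

Candidate voxels are grouped by 26-neighbourhood connected components
(configurable to 6 or 18); the minimum component size defaults to one
voxel — nothing is dropped, matching the reference workflow. Per lesion
the package records MTV, SUV\_mean, SUV\_max, SUV\_peak and the physical
centroid. SUV\_peak is the mean over a 1 mL sphere (radius 6.204 mm)
centred at the hottest voxel, voxelised by centre-inclusion and clipped
at the grid edge — a PERCIST-style convention adopted because the
quantity is reported in practice without a standard published recipe.

**New lesions.** Clinically, the appearance of new metastases is a
reader's call. The package provides an automatic surrogate — greedy
nearest-centroid matching of pre and post lesions within a configurable
radius (default 15 mm on co-registered frames); unmatched post-therapy
lesions are new-metastasis candidates — but a manual per-patient flag
always takes precedence in classification.

## Burden metrics

For lesion $i$ with voxel count $n_i$, voxel volume $v$ and mean uptake
$\bar{s}_i$:

$$\mathrm{MTV} = \sum_i n_i v, \qquad
  \mathrm{TLP} = \sum_i n_i v \,\bar{s}_i
              = \sum_{\text{lesion voxels } j} s_j \, v .$$

The second equality — lesion-wise TLP equals the flat voxelwise sum of
SUV × voxel volume — is an exact algebraic identity and the prime
internal consistency check of the implementation; the test suite
asserts it to double precision on multi-lesion noisy phantoms. TLP is
reported in mL × SUV and MTV in mL; exports round to one decimal, all
internal arithmetic stays in double precision.

## Response classification

Imaging (modified PERCIST, applied to whole-body ΔTLP and ΔMTV
independently):

* **PR** — decrease of more than 30%, and no new metastases;
* **PD** — increase of more than 30% *or* new metastases (the override
  dominates any burden change, including a PR-magnitude shrinkage —
  no such case exists in the packaged cohort, but the rule is applied
  as stated);
* **SD** — otherwise.

Biochemical (PCWG3 bands on ΔPSA): PR below −50%, PD above +25%, SD
between. Following the reference clinical workflow, the classification
uses a single follow-up PSA without the confirmatory second measurement
full PCWG3 recommends — a documented deviation.

All band edges are strict inequalities (exactly −30% or +25% is SD),
reading "decrease of more than 30%" literally. No cohort value lies on
a boundary, so the choice cannot flip a packaged-cohort call. The
headline imaging verdict is the TLP call; the MTV call is carried
alongside and a disagreement is visible, not resolved (the two are
fully concordant in the packaged cohort).

## Statistics

* **Concordance** — elementwise agreement fraction with the full 3 × 3
  PR/SD/PD cross-table; the trace is the agreement count and the
  marginals reproduce the per-method frequency tables.
* **Spearman correlation** — Pearson on midranks. The p-value uses the
  exact full-permutation null for n ≤ 10 and the
  $t = r\sqrt{(n-2)/(1-r^2)}$ approximation above; the packaged cohort
  (n = 17, and 13 complete pairs for the chemotherapy-PFS covariate)
  always takes the t path, the exact path serves small ad-hoc
  analyses. The correlation screen is pairwise-complete and reports raw
  per-cell p-values without multiplicity adjustment, matching how such
  screens are reported in this literature — at 17 patients it is an
  exploratory screen, not a confirmatory analysis.
* **Survival** — overall survival measured from therapy start; death is
  the event, start of a different treatment and last study visit are
  right-censorings (the standard reading of an endpoint definition that
  lists all three as interval ends without labelling events versus
  censorings). Kaplan–Meier estimation
  and the log-rank test go through the `survival` package; the median
  CI is the Brookmeyer–Crowley construction (intersecting the
  log-transformed Greenwood band with 0.5), the common default when no
  method is mandated. A median the curve never reaches is reported
  as "not reached" (`NA`).

One caution the package makes explicit: baseline correlations computed
from the packaged table differ slightly from values computed on
unrounded source data (the table rounds entries above 15 to integers).
The baseline-correlation driver therefore reports Spearman and Pearson
side by side rather than silently absorbing the difference.

## The synthetic-data generator

`generate_phantom()` builds whole-body-like SUV volumes: uniform
background (default SUV 1), ellipsoidal physiological organs with
matching masks, ellipsoidal lesions of known analytic volume
$\tfrac{4}{3}\pi abc$ and uniform uptake, optional isotropic Gaussian
smoothing as a partial-volume stand-in, and additive Gaussian noise in
SUV space clipped at zero. Structures are painted by overwriting
(organs first, lesions last), so a lesion's nominal uptake is exactly
its voxel value and segmentation accuracy can be judged against clean
ground truth. Poisson/reconstruction noise and realistic anatomy are
intentionally out of scope: the generator exists to validate
quantification arithmetic, threshold behaviour and the longitudinal
logic, not scanner physics — passing phantom tests therefore shows the
pipeline is correct on its own model, not that a SUV-3.0 threshold is
clinically optimal.

`generate_paired_study()` rescales each lesion's volume (radii by the
cube root of the multiplier, centroid preserved) and uptake, optionally
adds new lesions, and returns the analytic ΔTLP/ΔMTV for end-to-end
recovery tests. `generate_cohort()` draws latent response classes (PR /
SD / PD / PD-by-new-lesion), log-normal baseline TLP truncated to
7×10² – 1.4×10⁴ mL × SUV — the magnitude range of heavily pre-treated
cohorts, so synthetic and fixture tests exercise the same scales — MTV
as TLP over a burden-weighted mean SUV in 6–9, log-normal PSA
independent of burden by default (reflecting the observed near-zero
baseline TLP–PSA correlation; a Gaussian-copula coupling is available),
per-class percent changes drawn strictly inside the response bands so
the latent class is recoverable by construction, and exponential
survival per class (defaults 0.03/month for PR vs 0.10/month otherwise,
a hazard ratio large enough to separate arms at a few hundred patients)
with independent exponential censoring calibrated to a target censoring
fraction (default 20%). Every generator takes a single integer seed and
is bit-for-bit reproducible; the caller's RNG state is left untouched.

## Numerical and degenerate-input choices

* Empty segmentations are valid: burden 0, TLP 0, and an empty lesion
  table — not an error.
* Percent change requires a strictly positive baseline; offending
  cohort records are rejected individually with identification and the
  run continues.
* Zero observed events make the log-rank statistic undefined; it is
  reported as `NA` with a note, not silently zero.
* A constant vector makes Spearman r undefined; reported as `NA`.
* Component labelling assigns labels deterministically in order of the
  smallest linear voxel index, so outputs are stable across runs.
* Problem sizes used in the validation suite: phantoms up to 72³ voxels
  at 1–2 mm spacing, synthetic cohorts up to n = 1000, log-rank
  operating characteristics at 200–1000 replicates, KM median recovery
  averaged over 15 cohorts of n = 500 — sizes at which Monte-Carlo
  error is small relative to the asserted tolerances.

## Worked example

```{r example, eval = FALSE}
library(psmaburden)

fx <- table2_fixture()
a <- assess_cohort(fx$records)
a
#> <cohort_assessment> n = 17
#>  method response count  percent
#>     tlp       PR     5 29.41176
#>     tlp       SD     7 41.17647
#>     tlp       PD     5 29.41176
#>     mtv       PR     5 29.41176
#>     mtv       SD     7 41.17647
#>     mtv       PD     5 29.41176
#>     psa       PR     5 29.41176
#>     psa       SD     8 47.05882
#>     psa       PD     4 23.52941

concordance(a$calls$tlp_response, a$calls$mtv_response)$fraction  # 1.0
concordance(a$calls$tlp_response, a$calls$psa_response)$fraction  # 0.7058824
```

## Known limitations

* Segmentation quality on real scanners (partial volume, reconstruction
  noise, motion) is outside what the phantom model can certify.
* The new-lesion matcher is a geometric surrogate for expert reading;
  on real longitudinal data it requires co-registered frames and a
  sensible radius, and the manual flag should be preferred when
  available.
* The published cohort's survival endpoints cannot be reproduced here
  because per-patient survival times are not published; the survival
  stage is validated against analytic ground truth on synthetic
  cohorts instead.
* Alternative response frameworks (RECIP, PPP, RECIST) and Cox
  modelling are out of scope.
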