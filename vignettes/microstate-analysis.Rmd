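---
title: "Resting-state EEG microstate analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstates)
library(dplyr)
```

## The model

Spontaneous EEG does not wander continuously through topography space:
the momentary scalp potential field stays quasi-stable for roughly
50–120 ms, then switches abruptly to another configuration. During a
stable period the *shape* of the topography is fixed while its polarity
inverts with the oscillation of the dominant generators. These periods are
EEG microstates, and in eyes-closed resting recordings four prototypical
map configurations recur so reliably that they carry conventional letters:

* **A** — diagonal field axis, positive pole right-anterior;
* **B** — the mirrored diagonal, positive pole left-anterior;
* **C** — symmetric anterior–posterior axis;
* **D** — fronto-central extreme.

This package implements the standard analysis chain for a two-group
resting-state study on a 16-channel 10–20 montage, together with a
synthetic cohort generator that plants known microstate dynamics so the
entire chain is testable end to end without external recordings.

The chain is:

1. **Preprocessing** (`bandpass_filter()`, `average_reference()`): a
   zero-phase 2–20 Hz band-pass and common average reference. Every
   topography below is a zero-mean vector across channels.
2. **GFP and peak selection** (`compute_gfp()`, `find_gfp_peaks()`): the
   global field power `GFP(t)` is the spatial standard deviation of the
   momentary map. Topography is stable around GFP maxima and transitions
   happen in the troughs, so only peak maps enter clustering.
3. **Polarity-invariant modified K-means** (`modified_kmeans()`): peak
   maps are clustered into `k = 4` classes treating `m` and `-m` as the
   same state. Fit quality is the global explained variance
   `GEV = sum((gfp_m * corr(map_m, template_label(m)))^2) / sum(gfp_m^2)`.
4. **Cross-subject alignment** (`align_subject_templates()`): each
   subject's four templates arrive in arbitrary order and polarity; an
   iterative permutation search maximises the common variance across
   subjects, and `assign_class_letters()` letters the resulting mean maps
   against canonical references.
5. **Back-fitting and segmentation** (`backfit_labels()`,
   `segment_runs()`, `compute_profile()`): every sample receives a class
   label, maximal same-class runs become microstates, and each subject is
   summarised per class by mean duration (ms), occurrence (runs/s) and
   coverage (% of analysed time). No minimal duration is imposed and
   single-peak microstates are kept.
6. **Syntax** (`transition_stats()`): fractions of the 12 ordered class
   doublets and 36 triplets (no immediate repeats), counted within epochs
   only and pooled per subject.
7. **Group statistics** (`mixed_anova()`, `posthoc_ttests()`,
   `ttest_from_summary()`, `spearman_severity()`, `syntax_ttests()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| band | 2–20 Hz | analysis band; the carrier and microstate dynamics live here |
| `k` | 4 | number of classes; 4 is the resting-state standard and the only lettered configuration |
| `n_restarts` | 20 | random restarts of the clustering; each starts from k distinct observed maps |
| `tol` | 1e-6 | relative GEV improvement at which iteration stops |
| `gfp_weighted` | TRUE | template update weights maps by GFP² (see below) |
| `labeling` | nearest-peak | how non-peak samples inherit labels |
| sampling rate | 200 Hz | synthetic epochs: 512 samples = 2.56 s |
| `snr` | 2 | generator signal RMS over in-band noise RMS |
| `oscillation_freq_hz` | 10 | generator carrier (eyes-closed alpha) |

## The synthetic generator

`generate_cohort()` emulates a two-group design: 18 subjects per group,
each with 18–61 artifact-free 2.56-s epochs. For every epoch a hidden
state sequence is drawn: class durations come from a normal distribution
with group-by-class means and SDs (defaults are the package's reference
patient/control values, class A ≈ 64 vs ≈ 55 ms), truncated below at two
sampling intervals; successive classes always differ, with uniform
transitions by default. Each state renders as its prototype map times a
10-Hz sinusoid with fresh random amplitude and phase per state — so the
topography is fixed within a state while polarity inverts, and there is
no artificial continuity across boundaries. A 10-Hz carrier yields GFP
peaks every ~50 ms, matching the microstate time scale.

Noise is spatially white Gaussian, band-limited to the 2–20 Hz analysis
band before being scaled to the configured SNR. Defining SNR on in-band
noise keeps the parameter meaningful after filtering: broadband noise
would be largely removed by the 2–20 Hz filter, so a nominal broadband
SNR would say little about the difficulty of the clustering problem the
pipeline actually faces. At the default in-band SNR of 2 the per-subject
GEV lands in the mid-0.8s, comparable to the ~0.75–0.80 reported for real
eyes-closed recordings.

Severity grades (1–4) are drawn independently of the dynamics by
default, since resting studies typically find no severity correlation; a
`severity_slope_ms` switch plants a monotone severity→class-A-duration
effect for power-testing the Spearman stage.

What the generator deliberately does *not* emulate: volume-conduction
head modelling, non-stationary broadband/1-f background, artifacts
(blinks, muscle), and imperfectly separated sources. Passing tests
therefore demonstrate correctness of the algorithms under the stated
generative model, not robustness to every property of real EEG.

## Numerical and design choices

* **Filter realisation.** The band-pass is the squared magnitude response
  of a 4th-order Butterworth applied in the frequency domain with mirror
  padding — the same zero-phase transfer function as running the IIR
  filter forward and backward, but vectorised across channels. Zero phase
  matters because segmentation depends on the timing of topographic
  features. The test suite cross-checks this realisation against an IIR
  forward–backward reference.
* **GFP convention.** GFP divides by the channel count (spatial standard
  deviation). The alternative (n−1) convention only rescales GFP and
  moves no peak, so all derived quantities are unaffected.
* **Plateau ties.** A flat GFP plateau that is a strict local maximum
  yields its centre sample, left-biased on even lengths — deterministic
  and order-independent. Endpoints are never peaks. No amplitude
  threshold is applied to peaks.
* **Polarity-invariant template update.** Cluster templates are the
  dominant eigenvector of the GFP²-weighted scatter of assigned maps; an
  arithmetic mean would let polarity-inverted members cancel. The GFP²
  weighting is the classical formulation (it equals the eigenvector of
  the raw, un-normalised map scatter) and makes GEV provably
  non-decreasing over iterations, which the tests assert; an unweighted
  variant is available via `gfp_weighted = FALSE`.
* **Empty clusters** are re-seeded with the currently worst-explained map.
* **Clustering scope.** Templates are fitted per subject and then
  aligned, rather than pooling all subjects' peak maps; per-subject
  fitting respects between-subject map variability and the alignment step
  recovers the common classes. `k` is fixed at 4 — no automatic model
  selection is attempted.
* **Alignment.** All 24 permutations per subject are enumerated (cheap at
  k = 4; no heuristic needed). Mean maps are eigenvector averages with the
  sign fixed so the largest-magnitude channel is positive; initialisation
  is from the first subject in sorted id order, making the whole procedure
  deterministic. On small instances the iterative search is verified
  against exhaustive search over all (k!)^S permutation combinations.
* **Back-fitting.** Clustering used only peak maps, so labels are defined
  at peaks and extended to the nearest peak's label (midpoint ties to the
  earlier peak; edges take the nearest peak's label). Direct per-sample
  correlation labelling is available (`mode = "per-sample"`). No temporal
  smoothing is applied, and edge-truncated runs enter all three profile
  measures; whether durations count the inter-peak extension or only
  peak-to-peak spans is a convention, and the nearest-peak choice is
  recorded in the output metadata.
* **Occurrence denominator** is the total analysed time pooled over a
  subject's accepted epochs; transitions are never counted across epoch
  boundaries because accepted epochs are temporally discontinuous.
* **ANOVA error terms.** The split-plot model (between factor group,
  within factor class, `aov` with an `Error(subject)` stratum) is the
  default; with two groups of 18 its interaction denominator df is
  (4−1)(36−2) = 102. Some reports use the pooled (k−1)·N = 108
  convention instead, so both denominators and p-values are returned
  rather than forcing one to agree with the other.
* **t-tests** are pooled-variance Student tests (df = n₁+n₂−2 = 34 at
  18 per group), which is the form that reproduces published group
  comparisons from printed means and SDs. No multiple-testing correction
  is applied to the 12+36 syntax tests — the conventional analysis reports
  them uncorrected and compares the significant count to the 36 × 0.05
  chance expectation — but a Bonferroni column is included.
* **Spearman severity correlations** use midranks and the t
  approximation, computed per class × measure over patients only,
  uncorrected and flagged as exploratory in the output.

## Problem sizes used in tests

The test-suite and acceptance simulations use sizes chosen to exercise
the full design at desk scale: 50 planted-effect replicates of 18 + 18
subjects with 18 epochs each (the lower end of the per-subject epoch
range), 40-epoch single subjects for template recovery, and 12-subject
cohorts for explained-variance checks. Monte-Carlo tolerances
(±2 % on 10,000 truncated-normal draws, ±5 % on 500-epoch duration
convergence, ±15 % on single-subject duration recovery) reflect the
sampling noise at those sizes.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(n_subjects_per_group = 6, epochs_per_subject = 10,
                    snr = 2, seed = 1)
cohort <- generate_cohort(cfg)
report <- run_pipeline(cohort, seed = 2)
glance(report)
report$stats$posthoc |> filter(measure == "duration_ms")
autoplot(report)           # group profiles
autoplot(report$mean_maps) # lettered mean topographies
```

## Known limitations

* The generator's linear instantaneous mixing and single-sinusoid carrier
  make the clustering problem cleaner than real EEG; GEV values at a given
  SNR are not directly comparable to empirical reports.
* Back-fitting couples classes weakly at run boundaries: a planted state
  too short to contain a GFP peak is absorbed by its neighbours, so a
  strong duration effect in one class can bias neighbouring-class duration
  estimates by a fraction of a millisecond. With many epochs per subject
  this is small relative to between-subject variation but can nudge
  nominal false-positive rates slightly above 5%.
* Letter assignment needs canonical reference maps; the built-in
  references are the package's own schematic prototypes, and studies with
  other montages should supply their own.
* Only the 16-channel 10–20 montage ships with the package; the epoch
  container accepts any montage tibble, but prototype construction is
  defined for this one.
* EDF input is not supported; epochs are exchanged as plain TSV matrices
  with a manifest (`write_cohort()` / `read_cohort()`).
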