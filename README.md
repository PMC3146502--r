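# microstates

Resting-state EEG microstate analysis for two-group studies, with a
synthetic cohort generator that makes the whole pipeline testable end to
end.

## The problem

Spontaneous EEG parses into *microstates*: ~50–120 ms periods during which
the scalp potential topography stays quasi-stable while its polarity
inverts with the underlying oscillation. In eyes-closed resting EEG four
prototypical map classes (conventionally lettered A–D) explain most of the
topographic variance, and their temporal parameters — mean **duration**
(ms), **occurrence** (states/s), **coverage** (% of analysed time) — and
transition **syntax** differ between clinical groups. This package is for
researchers who want that full analysis chain in R: from multichannel
epochs on the 16-channel 10–20 montage to group-level statistics.

## The method

For each subject, every artifact-free 2.56-s epoch is band-pass filtered
(2–20 Hz, zero phase) and average-referenced. The global field power

```
GFP(t) = sqrt( (1/N) * sum_ch (v_ch(t) - mean_ch v(t))^2 )
```

is the spatial standard deviation of the momentary map; only topographies
at GFP maxima enter clustering. A polarity-invariant **modified K-means**
assigns each peak map to the template with maximal squared spatial
correlation and recomputes each template as the dominant eigenvector of
the GFP²-weighted scatter of its assigned maps, maximising the global
explained variance

```
GEV = sum_m ( GFP_m * corr(map_m, T_label(m)) )^2 / sum_m GFP_m^2 .
```

Per-subject template sets are aligned across subjects by exhaustive
permutation search maximising the common variance, lettered A–D against
canonical references, and back-fitted onto every sample (nearest-GFP-peak
labelling, no minimum duration, no smoothing). Maximal same-class runs
give the duration/occurrence/coverage profile; consecutive runs give the
12 doublet and 36 triplet transition fractions. The statistical layer is
the standard one for this design: split-plot ANOVA (group between,
class within), unpaired pooled-variance t-tests (also computable straight
from published summary tables via `ttest_from_summary()`), Spearman
severity correlations, and per-transition t-tests.

The synthetic generator (`synth_config()`, `generate_cohort()`) plants
known prototype maps, truncated-normal state durations with group×class
means/SDs, a 10-Hz carrier with per-state random phase and amplitude, and
band-limited noise at a configurable SNR — so every stage can be verified
against ground truth.

## Worked example

```r
library(microstates)

cfg <- synth_config(n_subjects_per_group = 6, epochs_per_subject = 10,
                    snr = 2, seed = 1)
cohort <- generate_cohort(cfg)          # tibble: one row per subject
report <- run_pipeline(cohort, seed = 2)

report
#> <ms_report> 12 subjects, k = 4, mean GEV = 0.854
#> classes: D C B A
#>   duration_ms group x class: F(3,30) = 21.16, p = 0.000
#>   occurrence group x class: F(3,30) = 0.98, p = 0.415
#>   coverage group x class: F(3,30) = 4.34, p = 0.012

glance(report)
#> # A tibble: 1 × 5
#>   n_subjects     k mean_gev  sd_gev alignment_objective
#>        <int> <dbl>    <dbl>   <dbl>               <dbl>
#> 1         12     4    0.854 0.00418               0.999

dplyr::filter(report$stats$posthoc, measure == "duration_ms")
#> # A tibble: 4 × 11
#>   class measure     mean_1  sd_1   n_1 mean_2  sd_2   n_2     t    df    p.value
#>   <chr> <chr>        <dbl> <dbl> <int>  <dbl> <dbl> <int> <dbl> <dbl>      <dbl>
#> 1 A     duration_ms   67.0  1.62     6   57.4  1.13     6 12.0     10    2.91e-7
#> 2 B     duration_ms   61.6  3.62     6   65.7  1.86     6 -2.48    10    3.28e-2
#> 3 C     duration_ms   67.7  2.51     6   69.5  3.25     6 -1.06    10    3.14e-1
#> 4 D     duration_ms   86.8  3.19     6   76.8  2.46     6  6.05    10    1.23e-4
```

The per-subject GEV of ~0.85 says the four fitted templates explain 85 %
of the GFP-weighted topographic variance at the GFP peaks. The default
generator plants longer class A durations in patients (≈64 vs ≈55 ms);
the post-hoc table shows the pipeline recovering that difference
(`t = 12.0` on 6 + 6 subjects; `t` is patient minus control). `autoplot(report)`
draws the group profile figure and `autoplot(report$mean_maps)` the
lettered mean topographies.

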