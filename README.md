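# plinet

Phase lag index (PLI) connectivity and weighted small-world network
analysis of resting-state EEG, with a ground-truth coupled-oscillator
simulator for end-to-end validation.

## What problem this solves

Resting-state EEG studies of cognitive decline (e.g. amnestic mild
cognitive impairment versus cognitively normal controls) ask whether
the brain's functional network is losing its organization: weaker
synchronization between regions, less local clustering, longer paths.
Scalp EEG makes this hard to measure honestly, because volume
conduction and the shared reference spread every source into many
electrodes and create spurious zero-lag synchronization. plinet
implements the analysis chain built around an index designed for this
problem, for researchers who want the whole pipeline — preprocessing,
connectivity, network metrics, statistics — reproducible and testable
in R.

The core quantity is the **phase lag index** between channels $i$ and
$j$:

$$\mathrm{PLI}_{ij} = \left|\langle \mathrm{sign}\,\Delta\phi(t_k)\rangle\right|,
\qquad \Delta\phi = \phi_i - \phi_j \ \text{wrapped to } (-\pi,\pi],$$

the absolute mean sign of the phase differences: 0 for no coupling or
zero-lag (conduction-driven) coupling, 1 for perfect locking at a
nonzero lag. Phases are analytic-signal (Hilbert) phases of the
band-filtered channels, in six bands from delta (1–4 Hz) to gamma
(30–45 Hz). The PLI matrix is summarized three ways: global mean,
region-grouped short/long-distance averages over a 10-10 montage, and
weighted graph metrics — mean clustering coefficient

$$C_i = \frac{\sum_{k\ne i}\sum_{l\ne i,k} w_{ik}w_{il}w_{kl}}{\sum_{k\ne i}\sum_{l\ne i,k} w_{ik}w_{il}}$$

and characteristic path length $L$ (inverse mean inverse shortest path
over edge lengths $1/w$, Latora–Marchiori style). Group contrasts use
Welch t-tests (PLI measures) and Mann–Whitney U-tests (graph metrics);
network–cognition association uses pooled Pearson correlation.

## Worked example

Simulate a small two-group cohort with weakened lower-alpha coupling in
group B, run the connectivity + network + statistics chain:

```r
library(plinet)

spec <- demo_cohort_spec(seed = 7)       # 8 channels, 9 Hz coupling, 20 s
spec$n_group_a <- 6L; spec$n_group_b <- 8L
cohort <- simulate_cohort(spec)

metrics <- subject_metrics(cohort$recordings, bands = "lower_alpha",
                           include_distance = FALSE)
head(metrics, 4)
#>   subject_id band        global_mean_pli      C     L
#> 1 S01        lower_alpha           0.205 0.100   4.05
#> 2 S02        lower_alpha           0.179 0.0869  5.07
#> 3 S03        lower_alpha           0.217 0.218   3.88
#> 4 S04        lower_alpha           0.173 0.0501  5.01

report <- run_group_analysis(metrics, cohort$manifest)
report$global_pli_tests
#>          band statistic  p_value mean_a mean_b significant
#> 1 lower_alpha      11.7 6.28e-06  0.188 0.0855        TRUE
report$graph_tests
#>          band measure statistic p_value median_a median_b significant
#> 1 lower_alpha       C        19 0.56128   0.0762   0.0643       FALSE
#> 2 lower_alpha       L         0 0.00241   4.9105   8.9801        TRUE
report$correlations
#>          band measure statistic p_value
#> 1 lower_alpha       C     0.187 0.52150
#> 2 lower_alpha       L    -0.678 0.00766
```

Reading the output: group A (intact coupling, mean global PLI 0.19)
synchronizes more than the weakened group B (0.09), and the Welch test
flags it. Group B's network pays for the lost coupling with a longer
characteristic path length (median 8.98 vs 4.91, Mann–Whitney
significant), and across all 14 subjects the path length correlates
negatively (r = −0.68) with the simulated cognitive score — subjects
with less optimal networks score lower. At this small n the clustering
contrast points the right way but is not individually significant;
the full 12-vs-16 recovery rates are quantified in the test suite.

The same analysis runs end-to-end from a config via
`run_pipeline(pipeline_config(...))`, which writes connectivity
matrices, the metrics table, the four statistics reports and a
reproducibility manifest; a thin CLI lives at `inst/cli/plinet.R`.
Real recordings enter through `read_recording()` (EDF or delimited
text) instead of the simulator.

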