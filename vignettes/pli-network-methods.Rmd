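---
title: "Methods: PLI connectivity and weighted network analysis of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLI connectivity and weighted network analysis of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plinet)
```

## The analysis in one paragraph

plinet quantifies resting-state EEG functional connectivity with the
phase lag index (PLI), summarizes it over scalp regions, condenses the
resulting all-to-all network into two weighted small-world descriptors —
the mean clustering coefficient $C$ and the characteristic path length
$L$ — and compares these quantities between two groups of subjects and
against a cognitive score. Because scalp EEG mixes every cortical source
into every electrode (volume conduction) and shares its reference
signal across channels, naive synchronization measures such as
amplitude correlation or coherence report spurious zero-lag coupling.
The PLI is built to ignore exactly that: it measures only the
*asymmetry* of the phase-difference distribution, which zero-lag mixing
cannot create.

## Phase lag index

For two channels with instantaneous phases $\phi_i(t_k)$ and
$\phi_j(t_k)$, write $\Delta\phi(t_k) = \phi_i(t_k) - \phi_j(t_k)$,
wrapped to $(-\pi, \pi]$. Then

$$\mathrm{PLI}_{ij} = \left| \langle \mathrm{sign}\, \Delta\phi(t_k) \rangle \right| \in [0, 1].$$

A PLI of 0 means the phase differences are symmetric around $0 \bmod
\pi$ — either no coupling, or coupling at zero lag (the volume-conduction
signature). A PLI of 1 means one signal consistently leads or lags the
other at a nonzero offset. Samples with $\Delta\phi$ exactly $0$ or
$\pi$ contribute zero to the mean (the mathematical sign convention;
such samples are measure-zero in real data but matter for constructed
test series, so `pli()` wraps first and treats the wrapped value $\pi$
explicitly).

Phases come from the analytic signal: the band-filtered channel is
extended to a complex signal whose negative frequencies are zeroed (an
FFT realization of the Hilbert transform), and the phase is its complex
argument. The method of phase extraction is a genuine design choice —
wavelet phase would be an alternative — and the Hilbert/analytic-signal
route was chosen because it is the standard realization for PLI
analyses of band-limited EEG. One second at each end of the series is
excluded from every PLI average to remove filter and analytic-signal
edge transients.

PLI is computed per band on the single extracted segment as one window,
for the six canonical bands: delta 1–4, theta 4–8, lower alpha 8–10,
upper alpha 10–13, beta 13–30 and gamma 30–45 Hz.

## Preprocessing chain

The conditioning chain mirrors standard resting-state practice, in this
order: channel selection, re-referencing to the mastoid average,
downsampling to 250 Hz, a 50 Hz notch, optional amplitude-threshold
epoch rejection, fixed-length segment extraction (default 3 min), and
band filtering.

Numerical choices, since the processing chain's filter family is a free
design decision:

* **Band filters.** Zero-phase filtering with the squared-magnitude
  response of a 4th-order Butterworth band-pass (the response that a
  forward–backward application yields), realized as a frequency-domain
  multiply. Phase preservation is non-negotiable here — any phase
  distortion would bias $\Delta\phi$ and hence the PLI. The
  frequency-domain realization was chosen over a time-domain `filtfilt`
  recursion because the 8-pole recursion for a narrow low band (1–4 Hz
  at 250 Hz sampling) is numerically ill-conditioned: its deviation
  from exact linearity is around $10^{-7}$ relative, while the FFT
  realization is linear to about $10^{-13}$ and meets the package's
  $10^{-9}$ linearity contract. The cost is circular edge behavior,
  which is irrelevant because one second per edge is discarded anyway.
* **Notch.** A 2nd-order IIR notch (RBJ biquad, quality factor 30)
  applied forward–backward; attenuation at the line frequency exceeds
  99% while the passband outside ±2 Hz stays within 1 dB.
* **Downsampling.** Integer factors use a zero-phase 8th-order
  Butterworth anti-alias low-pass at 80% of the target Nyquist followed
  by sample picking; non-integer ratios fall back to polyphase
  resampling. Anti-aliasing protects the gamma band when decimating
  1000 to 250 Hz.
* **Artifact handling.** The original acquisition context used an
  unpublished decomposition-based artifact rejector; plinet instead
  offers a simple optional amplitude-threshold segment search (off by
  default — simulated data are clean). When enabled, the first window
  containing no sample above threshold is used and the error message of
  an unsatisfiable request reports the longest clean stretch.

## Region-grouped connectivity summaries

Channels of the 10-10 montage are grouped into frontal, central,
temporal and occipital regions per hemisphere (midline `z` channels
carry no region). Three families of averages summarize the matrix:

* **short distance** (8 values): mean PLI over pairs within one region
  of one hemisphere;
* **long intra-hemispheric** (12 values): pairs spanning two different
  regions of the same hemisphere;
* **long interhemispheric** (4 values): pairs spanning homolog regions
  of the two hemispheres. Non-homolog cross-hemisphere pairs belong to
  no group.

The global mean PLI averages *all* $N(N-1)/2$ pairs, midline channels
included; midline exclusion applies only to the regional grouping. Two
open choices are worth flagging. First, the parietal row has no
unambiguous home between "central" and "occipital" grouping
conventions; plinet's default map places `P`/`PO` channels with the
occipital group, and the map is an ordinary data frame that users can
replace. Second, the default 59-channel montage is a conventional
10-10 subset (14 frontal, 18 central, 6 temporal, 14 occipito-parietal,
7 midline); any labeled montage parseable by the 10-10 prefix rules
works.

Region groups with fewer than two channels (short) or an empty pair set
(long) yield `NA`, never a fabricated zero.

## Weighted graph metrics

The PLI matrix is used directly as a weighted graph — nodes are
channels, edge weights are PLI values, and no threshold is applied (a
binary graph would make every result depend on an arbitrary cutoff).

The weighted clustering coefficient of node $i$ is

$$C_i = \frac{\sum_{k \ne i}\sum_{l \ne i, l \ne k} w_{ik} w_{il} w_{kl}}
             {\sum_{k \ne i}\sum_{l \ne i, l \ne k} w_{ik} w_{il}},$$

and $C$ is the mean over nodes. A node with fewer than two weighted
neighbors has a zero denominator and is assigned $C_i = 0$, the
standard convention for degree-deficient nodes. With weights in
$[0,1]$, $C_i \in [0,1]$, and scaling all weights by $\alpha$ scales
every $C_i$ by exactly $\alpha$ — a property the test suite checks
exactly, since it follows algebraically from the formula.

Edge lengths are inverse weights, $L_{ij} = 1/w_{ij}$ (infinite for
zero weight), and pairwise distances are shortest paths over these
lengths (Dijkstra; multi-hop detours are permitted and frequently
shorter than direct edges). The characteristic path length aggregates
harmonically, in the efficiency sense of Latora and Marchiori:

$$L = \frac{1}{\frac{1}{N(N-1)} \sum_i \sum_{j \ne i} 1/L_{ij}}.$$

This form is well defined on graphs with unreachable pairs (they
contribute $1/L_{ij} = 0$); a fully disconnected graph yields an
explicit flagged `Inf` rather than a numeric sentinel, because for
fully weighted PLI graphs disconnection indicates degenerate input
worth surfacing. The printed-formula reading is ambiguous about the
outer inverse; plinet applies it, consistent with the cited
efficiency-based approach, so that higher $L$ means worse integration.

## Statistics

Three families, each reported as a tidy table with descriptives and a
significance flag at $\alpha = 0.05$ per test:

* **Welch t-tests** (two-tailed, unequal variances,
  Welch–Satterthwaite degrees of freedom) for PLI measures: the global
  mean per band and each of the 24 regional summaries per band.
* **Mann–Whitney U-tests** for the graph metrics $C$ and $L$, which are
  not Gaussian at these sample sizes. The reported statistic is
  $\min(U_a, U_b)$, with both one-sided $U$ values carried alongside
  because the convention differs between software packages. The
  two-tailed p is exact by enumeration when $n_a + n_b \le 12$ with no
  ties, otherwise the normal approximation with tie and continuity
  correction.
* **Pearson correlations** of $C$ and $L$ with the cognitive score,
  both groups pooled, p from the t-transform with $n-2$ degrees of
  freedom.

No multiple-comparison correction is applied by default — the
replicated analysis design uses $\alpha$ per test across bands and
regions — but a Benjamini–Hochberg column is available
(`fdr = TRUE`).

## The synthetic cohort generator

No public EEG accompanies the study design this pipeline replicates, so
validation rests on a generator whose ground truth is known exactly.

Each channel carries a unit-amplitude oscillator
$x_i(t) = \cos\theta_i(t)$ with

$$\theta_i(t) = 2\pi (f_0 + \delta f_i)\, t + \varphi_i + W_i(t),$$

where $f_0$ is the carrier (default 9 Hz, strictly inside the lower
alpha band so filtering preserves it), $\delta f_i$ a fixed
per-oscillator detuning, $\varphi_i$ a random initial phase and $W_i$ a
Wiener phase-noise process. A coupling edge $(a, b, \kappa, \delta)$
replaces channel $b$'s oscillation by

$$x_b = \kappa \cos(\theta_a - \delta) + (1 - \kappa)\cos(\theta_b),$$

a phase-lagged copy of the source carrier mixed with $b$'s own
independent oscillator. Subtracting $\delta$ from the instantaneous
phase realizes the lag $\delta / (2\pi f_0)$ seconds exactly at the
carrier frequency without sample-grid quantization. White sensor noise
(sd `noise_sd`, default 0.5) is added per channel, and an optional
broadband common source is mixed in at zero lag to emulate volume
conduction.

Two generator parameters deserve their rationale spelled out:

* **Detuning** (`detune_hz`, default 0.45 Hz): the per-oscillator
  natural frequencies are an evenly spaced grid across
  $\pm$`detune_hz`, randomly assigned to channels and jittered by up to
  a quarter grid step. Heterogeneous natural frequencies are the
  standard ingredient of coupled-oscillator models, and the grid (as
  opposed to i.i.d. draws) guarantees every channel pair a nonzero
  relative detuning, so uncoupled pairs sweep full relative-phase
  cycles and their PLI decays toward zero as recording length grows.
  With i.i.d. detunings, occasional near-degenerate pairs would retain
  high spurious PLI for minutes — not wrong physically, but fatal for a
  ground-truth benchmark that wants "uncoupled" to mean "PLI near 0".
* **Wiener phase noise** (`phase_noise_sd`, default 0.01 rad per
  sample): slow within-recording phase wander. It is kept small
  deliberately: a diffusion-dominated relative phase stalls and
  recrosses rather than sweeping, which inflates the variance of the
  sign-mean and with it the null PLI. Decorrelation is therefore
  carried by the detuning; the Wiener term adds realism without
  dominating.

The cohort layer (`cohort_spec`) assigns group B a signed shift of
every $\kappa$ (clipped to $[0,1]$) and draws each subject's cognitive
score from

$$\text{score} = \beta_0 + \beta_1 \,\overline{\kappa} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma_s^2),$$

linear in the subject's mean coupling strength because the downstream
analysis tests *linear* (Pearson) correlation — a linear generative
model makes sign recovery a fair test. Defaults: 12 subjects in group A
versus 16 in group B, base $\kappa = 0.7$, shift $-0.4$ (so the
weakened group sits at $\kappa = 0.3$), $\beta_0 = 18.95$,
$\beta_1 = 11.5$, $\sigma_s = 1.5$ — which puts the group score means
near 27.0 and 22.4 points on a 30-point screening scale, matching the
kind of control-versus-aMCI contrast the pipeline is designed to
analyze. The effect size is a calibration choice, not an empirical
estimate: no physical-unit effect size exists to copy, and it was fixed
once, before the recovery studies were run.

Per-subject seeds derive deterministically from the cohort seed, so
identical specs reproduce bit-identical cohorts while subjects remain
independent streams.

### What the generator does and does not emulate

It emulates: narrowband oscillatory coupling at fixed nonzero lags,
graded coupling strength, uncoupled background channels, sensor noise,
zero-lag common-source contamination, a two-group coupling contrast and
a score linearly tied to coupling. It does **not** emulate: 1/f
broadband background, multiple simultaneous rhythms per channel,
realistic artifacts (blinks, EMG, electrode pops), non-stationarity
across minutes, or any head-geometry forward model. Passing the
recovery tests therefore demonstrates that the *pipeline* is correct
and sensitive under its own model assumptions — it does not certify
effect sizes or significance levels on real patient EEG.

### Problem sizes used in the validation studies

The replicate studies (group-difference power, type-I error,
correlation-sign recovery) run on a compact configuration chosen to
keep hundreds of end-to-end replicates cheap: 8 channels (two per
region per hemisphere: F3/F4, C3/C4, T7/T8, O1/O2), four coupled edges
at 9 Hz with $\delta = \pi/2$, 20-second recordings at 250 Hz, and the
12-versus-16 group layout (`demo_cohort_spec()`). The full-scale
condition — 59 channels, 3 minutes, 250 Hz — is the generator's default
and exercises the identical code path; the reduced montage changes only
the problem size, not the analysis. Recovery results: with the default
$\kappa$ contrast, the weakened group shows lower lower-alpha global
PLI (significant), lower $C$, higher $L$, and the pooled correlations
of score with $C$ and $L$ recover positive and negative signs
respectively, each in well over 80% of replicates; under the null
(no shift, zero score slope) the global-PLI Welch test keeps its
nominal 5% level. These rates are computed by the test suite itself.

## Known limitations

* PLI discards zero-lag *true* coupling along with zero-lag artifacts;
  that is inherent to the index, not to this implementation.
* The exact Mann–Whitney path refuses nothing but is only exact without
  ties; heavily tied metric tables silently use the corrected
  approximation (the `exact` flag in the result says which path ran).
* EDF support is plain continuous EDF, 16-bit, one-second records, a
  shared sampling rate across channels; EDF+ annotations and
  discontinuous files are out of scope.
* The 10-10 prefix parser covers conventional labels (`Fp1` … `POz`);
  exotic montages need an explicit region map.
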