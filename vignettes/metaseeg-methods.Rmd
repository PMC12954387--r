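---
title: "Static and dynamic connectivity of intracerebral EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic connectivity of intracerebral EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaseeg)
```

# The analysis

`metaseeg` analyses 60-s segments of multichannel intracerebral EEG recorded
under three conditions per subject — interictal rest, the minute preceding a
minor electrical discharge (pMED), and the minute preceding a major seizure
(pMS) — with a subset of contacts labelled as belonging to the epileptogenic
zone (EZ). Two complementary layers describe the network in each frequency
band:

* **Static functional connectivity (sFC).** Pairwise amplitude envelope
  correlation (AEC) after leakage orthogonalization, averaged over
  non-overlapping 5-s epochs, summarised with weighted graph metrics.
* **Dynamic functional connectivity (dFC).** The per-sample instantaneous
  amplitude correlation (IAC), compressed into data-driven stable windows, a
  recurrence plot across windows, community detection over the recurrence
  plot to find *meta-states*, and two summary statistics of the resulting
  per-sample state sequence: mean dwell time and Lempel–Ziv complexity.

A Friedman / Benjamini–Hochberg / Wilcoxon cascade compares the three
conditions across bands and metrics, and Pearson correlations relate the
static and dynamic summaries.

Because clinical stereo-EEG cannot be redistributed, the package ships a
synthetic cohort generator whose planted structure exercises every stage;
all validation is against that generator's ground truth plus independent
brute-force oracles.

# Preprocessing

Recordings are decimated to 250 Hz with a zero-phase FIR anti-aliasing
filter and band-filtered into six canonical bands (delta 1–4, theta 4–8,
alpha 8–13, beta1 13–19, beta2 19–30, gamma 30–48 Hz). Filters are
windowed-sinc FIR designs applied forward and backward; the pass is executed
as one FFT convolution with the filter's autocorrelation, which is exactly
filtfilt with zero initial conditions but remains fast for the ~3000-tap
delta filter. The filter order uses a transition width of 25 % of the band's
low edge and at least three cycles of that edge. No published filter order
exists for this design, so these are package choices. Amplitude envelopes
are the magnitude of the analytic signal of the whole 60-s trace (computing
them before epoching avoids per-epoch transients); the first and last second
are flagged as edge-affected, and the dynamic windowing never places a
boundary in the first or last half second.

# Static layer

For each pair the zero-lag projection of one filtered signal on the other is
removed before correlating envelopes, in both directions, and the two
directed estimates are averaged; this suppresses reference- and
volume-conduction leakage, which inflates zero-lag correlations in a
referential montage. The epoch-averaged correlation is rectified (absolute
value) by default because the graph metrics need nonnegative weights; signed
weights can be kept with `rectify = "none"` in `analysis_config()`.

Graph topology is summarised by global strength, nodal strength,
betweenness centrality, the Onnela weighted clustering coefficient (weights
rescaled by the graph maximum, keeping values in [0, 1]), and characteristic
path length. All metrics except global strength are computed after
rescaling the matrix to unit total strength, and networks are equalized in
size by sampling 4 EZ + 44 NEZ nodes (stratified, without replacement) 100
times and averaging the metrics over repetitions. Shortest-path edge
lengths are `1/w` by default; `1 - w` is selectable because the literature
uses both and the choice is rarely reported.

# Dynamic layer

The IAC of a pair at sample *t* is the product of the two z-scored
(population SD) envelopes after pairwise orthogonalization, averaged over
the two directions. Its time mean is algebraically identical to the static
whole-segment envelope correlation, which the test suite asserts to 1e-9.

**Windowing.** The per-sample connectivity vectors are compressed into
contiguous windows by a greedy rule: a window grows while the Spearman
correlation between the incoming sample's vector and the running window
mean stays at or above `window_threshold`; it closes when the correlation
drops, provided the window has reached `min_window_samples`. The defaults
are a threshold of 0.35 and a 88-sample (~0.35 s) minimum. These two
numbers matter and were calibrated on the synthetic generator: a window
must span several correlation times of the band envelope before its mean
vector rises above sampling noise (at a 7-Hz envelope bandwidth the
envelope decorrelates in roughly 20–40 samples), and per-sample similarity
to the running mean rarely exceeds ~0.5 even inside a perfectly stationary
regime, so a high threshold would simply close every window at the minimum
length. Short windows make the recurrence plot noise-dominated regardless
of implementation correctness.

**Meta-states.** Window-mean vectors of the three concatenated conditions
form a recurrence plot (Spearman correlations between windows), which is
treated as a signed weighted graph. Communities are found by Louvain
maximizing signed modularity — positive and negative weights get separate
null terms, each weighted by its total — with 20 random restarts plus a
flat refinement pass; the number of states is not preset. A community's
topography is the duration-weighted mean connectivity of its member
windows.

**TAS, dwell time, complexity.** Every original sample is assigned the
meta-state whose topography correlates best (Spearman) with the sample's
connectivity vector, ties to the lowest index. Dwell time is the mean
maximal-run length of this temporal activation sequence in seconds;
complexity is the LZ76 phrase count, computed on the symbol sequence
directly. Both are computed within each 60-s condition block, never across
block joins. The whole pipeline is repeated with EZ contacts removed (the
NEZ network); an EZ-only analysis is not offered because a handful of
contacts cannot support a stable recurrence structure.

A property of the per-sample assignment rule worth knowing: the
single-sample product of z-scored envelopes is extremely noisy (its
informative content is concentrated in moments when the envelopes are
high), so at desk-scale channel counts the absolute dwell time of the TAS
is dominated by assignment noise and sits far below the dwell of any
planted regime. Condition *contrasts* in dwell and complexity survive —
they are what the statistics layer tests — but absolute dwell recovery is
only meaningful at the window level, which is how the planted-regime
recovery experiment evaluates it.

# Surrogates

Amplitude-adjusted Fourier transform surrogates destroy genuine dynamics
while keeping each channel's amplitude distribution exactly; one shared
phase-randomization sequence across channels preserves cross-channel linear
correlation and hence static connectivity. Dynamic metrics are divided by
the mean over the surrogate ensemble (100 by default; the acceptance
experiments use 20 with a correspondingly widened tolerance), so values
near 1 indicate behaviour a stationary linear process would produce.
Meta-states are refitted on every surrogate by default — the conservative
choice, since the normalized quantity is then an end-to-end null — and
reusing the original states is selectable
(`refit_surrogate_states = FALSE`).

# Statistics

For each analysis family (all bands × all metrics within a layer), a
Friedman test per cell is followed by Benjamini–Hochberg correction across
the family; cells passing at α = 0.05 get post hoc pairwise Wilcoxon
signed-rank tests (exact for ≤ 12 untied non-zero differences, normal
approximation with tie correction otherwise), themselves BH-corrected
within their own family. Pairwise corrections are kept in a separate family
from the Friedman gate; pooling them is a defensible alternative, but
separate families match the two-stage gating structure. Degenerate cells
(all blocks fully tied) report a statistic of 0 and p = 1.

# The synthetic cohort generator

Each channel is a sum over bands of a band-limited Gaussian noise carrier
multiplied by a slow nonnegative envelope, plus white observation noise.
Carriers are independent across channels, so planted connectivity lives
entirely in the envelopes — the quantity AEC/IAC measure — and phase-based
coupling is absent by construction. Envelopes are rectified low-pass
Gaussian processes whose cross-channel correlation follows the coupling
matrix of the currently active planted state; states switch as a
semi-Markov process with geometric dwell. Condition effects enter only
through the dwell/state-count plan and NEZ coupling, never through the EZ
labels, so any EZ/NEZ contrast found downstream is discovered, not copied.

Defaults: 250 Hz, 60-s segments, 4 EZ + 44 NEZ contacts, dynamics confined
to beta2 and gamma, three states at rest and pMS with 0.5-s dwell versus
two states with 1.5-s dwell before a minor discharge, block coupling 0.95,
baseline coupling 0.2, 7-Hz envelope bandwidth, noise SD 0.05. The first
three state topographies are the three balanced pairings of four fixed NEZ
quarters, so any two states agree on exactly half the channel pairs —
maximally distinct under bipartition coupling. The envelope bandwidth is
deliberately at the high end of what a beta2/gamma carrier supports: a
slower envelope carries so few independent samples per window that planted
regimes are undetectable in principle, not just in practice.

What the generator does *not* emulate: ictal waveform morphology, spikes,
1/f background, non-stationary artifacts, volume-conduction mixing (the
orthogonalization is therefore tested as a no-harm transform, not as a
leakage remover), and heterogeneous per-subject electrode geometry. Passing
tests show the pipeline recovers the statistical structure it assumes; they
cannot show robustness to clinical artifacts.

# Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` recompute, at desk scale:

* graph metrics against a brute-force Floyd–Warshall/triangle oracle on 200
  random graphs of ≤ 8 nodes;
* LZ76 against an independent parser on all 8190 binary strings of length
  ≤ 12;
* the IAC/AEC time-mean identity on 10 synthetic recordings (|Δ| < 1e-9);
* AAFT contracts (exact amplitude multisets; cross-correlation drift
  < 0.05 over 100 seeds) and null calibration of surrogate-normalized
  dwell/complexity (5 segments of statically correlated Gaussian noise ×
  20 surrogates, mean in [0.9, 1.1]; note that the cohort generator's
  amplitude-modulated signals are *not* a linear null — AAFT correctly
  reports their envelope dynamics as genuine);
* planted 3-regime recovery (2-s dwell, gamma band, 48 contacts, 6
  segments): window-label ARI ≥ 0.8 and pooled dwell within 10 % of the
  planted sequence's;
* Friedman/Wilcoxon/BH against textbook formula and exhaustive enumeration
  oracles, and the empirical type-I error of the gate at n = 20 over 400
  null cohorts;
* the end-to-end contrast: one 20-subject cohort (4 EZ + 28 NEZ contacts,
  block coupling 1.0, pMED dwelling 2.5 s in two states versus 0.4 s across
  three states elsewhere), analysed over all six bands in the NEZ network;
  detection means at least one beta2/gamma cell survives the full cascade
  for both pMED contrasts while rest–pMS and the low bands stay null.

The end-to-end experiment uses one cohort realization per run: a full
six-band, 20-subject dynamic analysis takes on the order of ten minutes on
one CPU, which is also why the experiment's channel count sits at the
bottom of the realistic range rather than at the clinical mean of ~120
contacts (where the contrast is stronger but a run would take hours).

# Known limitations

* Louvain is a greedy heuristic: on small adversarial signed graphs it can
  land ~0.02 below the exhaustive modularity optimum; on recurrence plots
  with real block structure it is reliable across restarts.
* The greedy windowing cannot represent regimes shorter than
  `min_window_samples`; with geometric dwell a fraction of planted runs is
  necessarily below any minimum, which biases window-level dwell upward and
  is the main contributor to the 10 % recovery band.
* EDF support covers the standard 16-bit single-rate case only (no EDF+
  annotations, no mixed sampling rates).
* p-values from the normal-approximation Wilcoxon branch are approximate
  for heavily tied data; the exact branch covers n ≤ 12.
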