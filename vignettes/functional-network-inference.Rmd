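---
title: "Inferring functional networks from calcium imaging of rhythmic neural tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional networks from calcium imaging of rhythmic neural tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respnet)
```

## The problem

Brainstem respiratory circuits — the preBötzinger complex (preBötC), which
generates the inspiratory rhythm, and the CO₂-chemosensitive pFRG/RTN —
contain hundreds of cells whose coordinated calcium activity can be followed
by time-lapse fluorescence imaging at frame intervals of 0.1–2 s. A common
way to characterize such circuits is to treat each cell as a node and ask
which pairs of cells show correlated activity: the resulting *functional
graph* can then be summarized by small-world statistics (clustering, path
length) and by simple counts (active cells, correlating pairs,
connectivity). `respnet` implements this analysis chain end to end, together
with a synthetic-recording generator with known coupling topology so every
stage can be validated against ground truth.

## The analysis model

Given a matrix of per-ROI fluorescence traces `F` sampled every
`frame_interval` seconds, the chain estimated by `fnet()` is:

1. **ΔF/F₀ normalization** (`normalize_dff`). For each cell and frame,
   `F0(t)` is the mean intensity within ±30 s of `t` (centered window,
   truncated at the recording edges, the frame itself included — including
   or excluding one sample changes `F0` negligibly at these frame rates),
   and the normalized value is `(F(t) − F0(t)) / F0(t)`. The result is
   invariant under per-cell multiplicative gain, which is why downstream
   statistics do not depend on illumination or dye loading. Cells whose
   baseline is not strictly positive anywhere cannot be ratio-normalized
   and are flagged out with a warning.
2. **Event detection** (`detect_events`). Events are local maxima of the
   ΔF/F₀ trace with a prominence of at least `threshold_frac = 0.20`
   (a minimum 20% increase above baseline) over a running baseline, taken
   as the 10th percentile of the trace in a sliding 60 s window — a robust
   floor that tracks residual drift without following the transients
   themselves. Maxima closer than `min_separation = 2` s (shorter than the
   slowest transient decay) are merged, keeping the larger. A cell with at
   least one event is *active*. With the default imaging noise this
   threshold sits at ten noise standard deviations; at the benchmark noise
   level (peak SNR ≈ 5) it sits at two, and some noise maxima are counted —
   a property of the 20%-above-baseline rule itself, not of the
   implementation.
3. **Pairwise Pearson correlation** (`correlation_matrix`) between all
   pairs of ΔF/F₀ traces. Constant or flagged traces have undefined
   correlations and are excluded from all pair counts.
4. **Scrambled-trace null cut-off** (`scrambled_cutoff`). In each of
   `n_scrambles = 100` realizations every trace is independently
   *circularly shifted* by a uniform random offset in `[1, n_frames − 1]`.
   Circular shifting preserves each trace's marginal distribution and
   autocorrelation while destroying cross-cell alignment, which makes it a
   proper null for rhythmic signals. The 99th percentile (linear
   interpolation) of the pooled off-diagonal correlations is recorded per
   realization; the cut-off is the mean of these percentiles. By
   construction about 1% of truly independent pairs exceed it (measured
   ≈ 1% in the test suite). The null is built within-recording; pooling
   across recordings is available by computing cut-offs per recording and
   averaging.
5. **Graph construction** (`build_graph`). Nodes are the active cells; an
   undirected edge joins two cells when their correlation meets or exceeds
   the cut-off. The threshold is applied to signed r — anti-correlated
   pairs are not edges — and edge weights keep r for visualization.
6. **Small-world summary** (`normalize_metrics`). The mean local clustering
   coefficient `C` (nodes of degree < 2 contribute 0) and the mean shortest
   path `L` (over connected pairs only; the unreachable fraction is
   reported separately) are normalized against `n_random = 100`
   degree-preserving randomizations of the same graph (double-edge swaps,
   10·|E| attempted swaps each; degree sequences are asserted identical per
   realization): `λ = L/⟨L_rand⟩`, `σ = C/⟨C_rand⟩`, and the small-world
   parameter `γ = σ/λ`. The ratio is the standard small-world index and is
   the form consistent with published value tables for these circuits;
   `gamma_form = "product"` gives `σ·λ` for comparison with sources that
   combine them that way. Graphs whose degree sequence admits no
   double-edge swap (star-like graphs) fall back to density-matched random
   graphs with a warning; graphs with all degrees ≤ 1 report `σ = γ = 0`,
   flagged undefined.
7. **Frequency statistics** (`frequency_and_cv`). Per-cell frequency is
   `(n − 1)/(t_last − t_first)` in mHz — the `(n−1)/span` form avoids the
   edge bias of `n/duration` — and regularity is the CV of inter-event
   intervals in percent, with `CV ≤ 50%` (configurable) calling a cell
   regularly spiking.

`fnet()` returns a classed fit; `summary()`, `coef()`, `plot()` and
`simulate()` (a parametric-bootstrap-style generator over the inferred
adjacency) expose the results.

## The synthetic-recording generator

`generate_network()` + `simulate_recording()` produce recordings whose
statistical structure matches what the analysis assumes:

* **Topology**: ring lattice, Watts–Strogatz small world (lattice plus
  probabilistic rewiring), Erdős–Rényi, planted clusters with an exact
  number of bridge edges, or empty. Small-world coupling with a few
  bridging hubs is the structure reported for these circuits.
* **Pacemakers**: a fraction (default 0.31, matching the share of cells
  that keep rhythmic calcium activity under synaptic block) of cells fire
  autonomously with gamma-distributed inter-event intervals (default rate
  50 mHz, interval CV 0.2 — the reported regular-spiking regime is
  ~50–100 mHz). The first event falls at a uniformly random phase within
  one period: independent oscillators carry no common phase reference, and
  a shared start time would phase-lock unrelated cells and inject
  correlations that are not in the coupling graph. Event counts over a
  fixed duration are phase-invariant at zero jitter (e.g. always 3 events
  in 60 s at 50 mHz).
* **Transmission**: every autonomous event propagates once (single hop, no
  cascading) to each coupled *non-pacemaker* neighbour with probability
  0.8 after a jittered delay (0.2 ± 0.05 s). Pacemakers are modeled as
  autonomous oscillators whose trains are unaffected by incoming input —
  this keeps "pacemaker frequency" a well-defined invariant under coupling
  perturbations, at the cost that pacemaker–pacemaker edges carry no
  correlated signal.
* **Traces**: baseline 1.0 plus 0.5 × unit-peak difference-of-exponentials
  kernels (rise 0.3 s, decay 2 s, typical cytosolic calcium transient
  scale) at the event times, a slow sinusoidal drift (amplitude 0.05,
  period equal to the recording, random phase per cell — deliberately slow
  enough to stress the ±30 s baseline window) and Gaussian noise
  (SD 0.02, i.e. peak SNR 25 for a well-loaded preparation; benchmark runs
  use SD 0.1 for peak SNR 5). Defaults: 0.5 s frames, 300 s duration —
  long enough for ~15 pacemaker cycles while keeping simulation and
  analysis fast.
* **Perturbations** mirror the classic pharmacology: `decouple_all`
  (synaptic block — TTX-like), `delete_edge_fraction` (gap-junction
  block-like), `scale_rate` (opioid / high-K⁺ rate changes),
  `add_tonic_rate` (uncoordinated background activity), each applied from
  an onset time.
* `render_stack()` turns a recording into an image stack (2-D Gaussian
  footprints scaled by the traces) to exercise the ROI-extraction path,
  which segments cells on the per-pixel SD-over-time image (Gaussian
  smoothing, Otsu threshold, connected components filtered by area).

What the generator does **not** emulate: biophysical membrane dynamics,
photobleaching trends beyond the slow drift, motion, overlapping ROIs,
signal saturation, and distinct astrocyte kinetics. Passing the recovery
benchmarks therefore shows the chain is correct for its own statistical
assumptions, not that it is robust to every artifact of real microscopy.

## What edge recovery can and cannot achieve

With single-hop transmission, a follower–follower coupling edge is visible
to zero-lag correlation only through events the two cells receive from a
*shared* pacemaker. A non-edge pair of co-followers of the same pacemaker
receives correlated input by exactly the same mechanism, with the same
strength (measured: mean r ≈ 0.45 for both classes on the standard
benchmark). No threshold on zero-lag Pearson r can separate these two
classes, so edge recovery on the planted small-world benchmark (n = 100,
k = 6, rewiring 0.1, transmission 0.8, peak SNR 5) plateaus at
F1 ≈ 0.6–0.7 (precision ≈ 0.6, recall ≈ 0.7) regardless of tuning. The
package reports this honestly; resolving it would require lagged or
partial correlation, which is outside this package's scope. Coarser
structure survives: the recovered graph's normalized clustering σ tracks
the truth graph's σ closely, cluster structure is recovered essentially
exactly in planted-cluster simulations, and all perturbation effect sizes
(pair-count collapse under decoupling, pacemaker-rate invariance under
edge deletion, frequency doubling under rate scaling) are reproduced.

## Numerical and design notes

* **Percentile definition**: linear interpolation (R's default type 7),
  over the pooled upper-triangle correlations of one scramble realization.
* **Low-pass printed value**: nerve/population traces are conditioned by
  `rectify_smooth()` — 2nd-order zero-phase Butterworth at 0.06 Hz,
  full-wave rectification, 1 s moving average. A 0.06 Hz *low*-pass
  attenuates respiratory burst rhythms (~0.05–0.13 Hz), so the corner is
  also exposed as a high-pass (`mode = "high"`, baseline removal), which
  is the mode useful before burst detection; the printed low-pass remains
  the default. Because the corner sits far below the signal band, the
  filter is applied to the mean-removed signal and the DC component is
  restored through the filter's exact DC gain, avoiding the large edge
  transient that zero-padded `filtfilt` would otherwise leave.
* **Correlation input**: Pearson r is computed on the continuous ΔF/F₀
  traces (the event-detection stage feeds activity flags, not the
  correlation); correlating binary event trains instead would discard
  amplitude information and was not adopted as the default.
* **Ties and degenerate inputs**: peak merging keeps the larger maximum
  (first by amplitude, then earlier index); empty trace sets, edgeless
  graphs, single-node graphs, and all-constant stacks all return defined,
  flagged results rather than errors.
* **Determinism**: every stochastic stage takes an explicit seed;
  recordings derive per-cell sub-seeds from the recording seed, so reruns
  are bit-identical and whole-pipeline outputs (CSV artifacts) are
  byte-identical. `analyze_recording()` writes a provenance JSON (config,
  parameters, cut-off, package and R versions) sufficient to reproduce a
  run.
* **Problem sizes**: the bundled tests and the acceptance script use
  recordings of 10–100 cells, 150–600 s at 0.5 s frames, 15–100 scramble
  realizations and 5–30 graph randomizations — sizes chosen so the full
  validation suite runs in well under a minute of compute per stage while
  keeping Monte-Carlo error far below the asserted tolerances.

## Worked example

```{r, eval = FALSE}
net <- generate_network(60, "small_world", k = 6, rewire_p = 0.1, seed = 1)
rec <- simulate_recording(net, dynamics_spec(), seed = 1)
fit <- fnet(rec$traces, seed = 1)
summary(fit)
plot(fit)

# perturbation experiment: synaptic block at t = 0
dec <- simulate_recording(net, dynamics_spec(),
                          perturbation("decouple_all", onset = 0), seed = 1)
summary(fnet(dec$traces, seed = 1))
```

## Known limitations

* Zero-lag Pearson cannot separate shared-input correlation from direct
  coupling (above); inferred edges are functional, not anatomical.
* The reported connectivity follows its literal definition — correlating
  pairs over all pairs of active cells — and is therefore bounded by the
  graph density; published tables for these circuits report much higher
  connectivity values than that definition can produce from their own
  pair and cell counts, and no attempt is made to reconcile the two.
* Mean shortest path is computed over connected pairs only; strongly
  fragmented graphs report the unreachable fraction but their λ should be
  interpreted with care.
* ROI extraction assumes non-overlapping, roughly convex cells that are
  active enough to stand out in the SD image; silent cells are invisible
  by construction.
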