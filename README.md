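# respnet

Functional network inference from time-lapse calcium imaging of
rhythmically active neural tissue, built for brainstem respiratory
circuits (preBötzinger complex, pFRG/RTN) and any preparation with a
similar activity structure: hundreds of ROIs, rhythmic Ca²⁺ transients in
the tens-of-mHz range, and locally clustered, hub-linked (small-world)
coordination.

Given per-ROI fluorescence traces (or a TIFF stack), the package

1. normalizes each trace to ΔF/F₀ with a sliding ±30 s baseline,
2. detects Ca²⁺ transient events (local maxima ≥ 20% above a running
   baseline),
3. computes all pairwise Pearson correlations `r_ij`,
4. derives a significance cut-off as the mean 99th percentile of
   correlations among *scrambled* traces (independent random circular
   time shifts, which preserve each trace's autocorrelation but destroy
   cross-cell alignment),
5. builds the functional graph (edge ⇔ `r_ij ≥ cutoff` between active
   cells), and
6. summarizes it: correlating pairs, active cells, mean degree,
   connectivity = pairs / C(n_active, 2), and the small-world metrics
   `λ = L/⟨L_rand⟩`, `σ = C/⟨C_rand⟩`, `γ = σ/λ` against degree-preserving
   randomized networks, plus per-cell frequency (mHz) and inter-event
   interval CV (%).

A synthetic-recording generator (`generate_network()`,
`simulate_recording()`, `render_stack()`) produces recordings with known
coupling topology, pacemaker labels and event times — including
perturbation scenarios that mirror the classic pharmacology (synaptic
decoupling, edge deletion, rate scaling) — so every stage of the chain is
testable against ground truth.

## Worked example

```r
library(respnet)

net <- generate_network(60, "small_world", k = 6, rewire_p = 0.1, seed = 1)
rec <- simulate_recording(net, dynamics_spec(), seed = 1)
fit <- fnet(rec$traces, seed = 1)
summary(fit)
#> Functional network summary
#>   Correlating cell pairs               174
#>   Active cells                         57
#>   Correlations per active cell         6.105
#>   Connectivity                         0.109
#>   Mean shortest path length (lambda)   1.814
#>   Clustering coefficient (sigma)       6.988
#>   Small-world parameter (gamma)        3.853
#>   population mean frequency: 69.7 mHz; 29 regularly spiking cell(s)
```

174 of the 1596 possible pairs among the 57 active cells correlate above
the scramble-derived cut-off (connectivity 0.109). Clustering is ~7×
that of degree-matched random networks at a modestly above-random path
length (λ 1.81), giving a small-world parameter γ ≈ 3.9 — the inferred
graph reproduces the small-world character of the planted coupling. The
population rhythm (~70 mHz here, pacemakers at 50 mHz plus convergent
input to followers) sits in the expected tens-of-mHz range.

`plot(fit)` draws the correlation-colored edge map over the ROI
centroids; `coef(fit)` returns the summary as a named vector;
`simulate(fit)` generates new recordings from the inferred adjacency.
`analyze_recording(config)` runs the same chain from a JSON config and
writes CSV artifacts plus a provenance record; `report_summaries()`
aggregates many recordings into a mean ± SD table. A thin command-line
front end with `simulate` / `analyze` / `report` subcommands is installed
at `inst/cli/respnet.R`.

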