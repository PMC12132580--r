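# lamwave

Structure-function analysis of laminar high-density (Neuropixels-style)
extracellular recordings from primary visual cortex, for electrophysiologists
who want to go from spike-sorted output to candidate cell classes and their
functional signatures in one reproducible pipeline.

Cortical cell classes differ in action-potential shape, laminar position,
tuning, firing statistics and connectivity. `lamwave` ties these together:

* **WaveMAP clustering** — normalized soma waveforms are embedded with UMAP
  and the *fuzzy neighbor graph* (not the 2-D projection) is partitioned with
  Louvain community detection; resolution is chosen by a subsampled
  modularity sweep, and cluster separability is checked with cross-validated
  gradient-boosted trees.
* **Laminar anchoring** — current source density from the five-point stencil
  (−1, 16, −30, 16, −1)/12h², σ = 120 µm spatial smoothing; the lower edge of
  the dominant sink anchors the 4C–5/6 border, and unit depths are scaled
  piecewise-linearly onto common boundaries. Layer distributions are tested
  with χ² = Σ(O−E)²/E against uniformity.
* **Tuning** — PSTHs (13 ms Gaussian kernel, 67 ms screen-delay correction),
  response latency, DI = (FR_pref − FR_null)/(FR_pref + FR_null) over
  opposite drift directions, OI over orthogonal orientations, and the
  modulation ratio F1/F0 (simple > 1 > complex).
* **Bursting** — inter-spike-interval histograms (0.4 ms bins, max = 1),
  ISI-PCA, and the bursting index l₁ − l₃ with label-shuffle tests
  (500 shuffles, 2.5/97.5 percentile bands).
* **Propagation** — per-channel trough times across the soma ±5 channels,
  inverse velocities (ms/mm) from OLS above and below the soma, and the
  asymmetry index SI = (x₀ + y₀)/√2, the orthogonal distance of
  (velocity⁻¹_below, velocity⁻¹_above) from y = −x; bootstrap comparisons
  (500 resamples).
* **Connectivity** — trial-based cross-correlograms
  CCG(τ) = Σᵢ Σₜ x_j(t) x_k(t+τ) / (M θ(τ) λ_j λ_k) with θ(τ) = N − |τ|,
  analytic 25 ms interval-jitter correction, 7 SD excitatory / 5 SD inhibitory
  classification against the 50–100 ms noise band, the lead–lag index
  CA = (R − L)/(R + L), and a directed cluster-pair graph from signed-rank
  tests of CA.

A first-class synthetic module (`make_cohort()`, `synth_spikes()`,
`synth_lfp()`) generates seeded cohorts with planted waveform classes, depth
distributions, tuning, bursts, propagation profiles and pairwise coupling, so
every estimator is validated against known ground truth without any download.

## Worked example

```r
library(lamwave)

cfg <- pipeline_config(
  synthetic = list(
    archetypes = default_archetypes()[c("NS-1", "NS-3", "BS-2", "BS-4")],
    n_per_class = 15L,
    schedule = stimulus_schedule(directions_deg = seq(0, 330, by = 30),
                                 spatial_frequencies_cpd = 1, repeats = 10)),
  seed = 3, n_shuffles = 100L, n_resamples = 100L,
  stages = c("curate", "cluster", "laminar", "tuning", "isi", "propagation"))
report <- run_pipeline(cfg)
print(report)
print(report$laminar$ns_layer_test)
```

```
<analysis_report> 60 units, 2 clusters, 50% narrow-spiking
chi^2 (2, 30) = 29.4000, p = 4.13e-07
```

Sixty units pass curation; at the default resolution the waveform graph
splits into a narrow- and a broad-spiking community, and the narrow-spiking
units concentrate in layers 4A/B + 4C strongly enough to reject a uniform
laminar distribution (χ² against uniform over {2/3, 4, 5/6}).

Per-archetype medians of the downstream estimates recover the planted
structure:

```r
arch <- vapply(report$ground_truth$cohort$units, `[[`, "", "archetype")
tab <- data.frame(archetype = arch, report$tuning[, c("DI", "OI", "latency_ms")],
                  bursting = report$isi$table$bursting_index,
                  v_below = report$propagation$table$v_inv_below,
                  si = report$propagation$table$si_unsigned)
aggregate(. ~ archetype, tab, median)
```

```
  archetype   DI   OI latency_ms bursting  v_below   si
1      BS-2 0.17 0.37         74    -1.00  0.0e+00 0.42
2      BS-4 0.20 0.29         72    -1.42  1.1e-15 0.21
3      NS-1 0.29 0.69         64     3.18  5.9e-01 0.84
4      NS-3 0.77 0.55         53    -0.44 -8.0e-01 0.00
```

NS-3 was planted direction-selective (target DI 0.8) with a symmetric
multichannel profile (negative below-soma inverse velocity, SI ≈ 0); NS-1 was
planted bursty (high l₁ − l₃), orientation-selective (target OI 0.7) and
unidirectional (positive below-soma slope); the BS classes propagate toward
the pia only (below-soma slope ≈ 0). Latency estimates at 10 repeats per
condition are rough (planted 40–55 ms).

A cross-correlogram with all of its positive mass at positive lags gives the
lead–lag extreme:

```r
lead_lag_index(list(lags_ms = seq(-100, 100),
                    corrected = c(rep(0, 101), rep(0.2, 10), rep(0, 90))))
```

```
CA = 1 band = synaptic
```

## Command line

```sh
Rscript inst/cli/lamwave-cli.R simulate --out session/ --seed 3 --units 10
Rscript inst/cli/lamwave-cli.R run --input session/ --out results/ --seed 3
```

`simulate` writes a Kilosort-style plain-text session (spike_times,
spike_clusters, templates, channel_positions as CSV, plus a trials table and a
ground-truth JSON sidecar); `run` executes the analysis stages and writes one
CSV per stage.

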