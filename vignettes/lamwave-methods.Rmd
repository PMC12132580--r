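---
title: "lamwave: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lamwave: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lamwave` implements a structure-function analysis pipeline for laminar
high-density extracellular recordings from primary visual cortex: curation of
spike-sorted units, waveform-shape clustering into candidate cell classes,
laminar anchoring by current source density, and functional characterization
(tuning, bursting, multichannel propagation, pairwise connectivity). This
vignette documents the models behind each stage, the parameters that matter,
and the design decisions taken where the procedure was genuinely open. It
states no empirical result that the test suite does not itself compute.

## The synthetic cohort: a stated world, not a dial

Every downstream estimator is validated against seeded synthetic cohorts with
planted ground truth (`make_cohort()`, `synth_template()`, `synth_spikes()`,
`synth_lfp()`). The generator emulates:

* **Nine waveform archetypes** (`default_archetypes()`): four narrow-spiking
  (trough-to-peak 0.18-0.30 ms), four broad-spiking (0.45-0.60 ms), one
  tri-phasic (0.17 ms, two peaks flanking the trough), plus a positive-spiking
  white-matter class. Soma waveforms are differences of Gaussians (a
  three-lobe variant for the tri-phasic class; time-reversed for positive
  spikes); the peak offset is calibrated numerically so the realized
  trough-to-peak width matches the archetype. A parametric curve was chosen
  because no generative waveform model is prescribed anywhere; it gives direct,
  smooth control of width and repolarization.
* **Multichannel layout**: 11 channels (soma plus or minus 5) at 20 um pitch and a
  30 kHz sampling rate (Neuropixels 1.0 conventions; both configurable),
  amplitude decaying exponentially with distance from the soma channel
  (length constant 60 um) and per-channel time shifts following the planted
  propagation profile (unidirectional, asymmetric-above, symmetric, flat)
  with inverse velocities of 0.3-0.8 ms/mm. Offsets are signed positive
  toward the pia.
* **Laminar structure**: class-specific layer weights (narrow-spiking classes
  concentrated in 4A/B and 4C, one broad class infragranular, positive spikes
  in white matter) inside a five-compartment boundary set
  (2/3 | 4A/B | 4C | 5/6 | WM) whose 4C-5/6 border is the common anchor.
* **Tuning**: baseline plus evoked Poisson rates during each 1 s drifting
  grating (36 directions in 10 degree steps, four spatial frequencies, 0.25 s
  inter-stimulus interval, 5-10 repeats, 67 ms screen-update delay). The
  direction/orientation concentrations of the von Mises-style gain are solved
  in closed form so the *measured* DI and OI (which include the baseline) hit
  the planted targets.
* **Burstiness**: a compound model - each seed spike spawns, with probability
  `burst_prob`, a burstlet of Poisson(`burst_size_mean` - 1) extra spikes at
  ~`intra_burst_isi_ms` intervals. This reproduces the "peaky ISI within
  10 ms" signature without committing to a biophysical mechanism.
* **Coupling**: directed excitatory edges insert a target spike at a fixed lag
  (2-3 ms typical) with probability `efficacy` per source spike; inhibitory
  edges delete target spikes in a 3 ms window after the lag.

What the generator does **not** emulate: spike-sorting errors and drift,
eye-condition differences, biophysical LFP, refractory periods in the
non-bursty ("poisson") trains, and cross-trial adaptation. A green recovery
test therefore establishes estimator correctness under the stated statistical
structure, not robustness to real-recording artifacts.

## Curation and waveform features

SNR is defined as template trough-to-peak amplitude divided by the standard
deviation of spike-to-spike residuals on the soma channel (the generator
plants this quantity directly); no definition is prescribed, and this matches
the noise-relative-amplitude reading of the filtering rule. Units are retained
when `0 < SNR <= 3.7` (exclusive low, inclusive high - the boundary convention
is our choice). Polarity is positive when the global maximum precedes the
global minimum; tri-phasic units need two flanking local maxima at or above
0.3 of the trough magnitude (the threshold is exposed because only "two major
peaks" is prescribed) and are aligned to the trough. Alignment shifts repeat
edge samples rather than wrapping, avoiding spurious discontinuities in the
normalized shape. Template amplitudes convert to microvolts with the
acquisition scale factor 2.3. Feature extraction uses parabolic sub-sample
interpolation of extrema so that widths of very narrow units (5-6 samples at
30 kHz) are measured to better than half a sample.

## WaveMAP clustering

`build_wavemap()` applies UMAP (`n_neighbors = 20`, `min_dist = 0.2`,
backed by `uwot`) and passes the resulting fuzzy simplicial-set graph - not
the 2-D projection - to Louvain community detection (`igraph`,
`resolution = 1.0` by default). The 2-D embedding is kept for visualization
only and is initialized with scaled PCA, which is deterministic and robust
when well-separated families disconnect the fuzzy graph; labels never depend
on the layout. Cluster-count behavior follows igraph's gamma
parameterization: the count is non-decreasing in the resolution. (The
alternative "time" parameterization runs in the opposite direction; a Leiden
backend is acceptable as a drop-in only if its resolution semantics match.)

`resolution_sweep()` re-clusters 25 random 80% subsamples per grid point and
reports, for each resolution, the mean and SD of the **standard** (gamma = 1)
modularity of the found partition plus the cluster count; standard modularity
is used so values are comparable across the grid, and the chosen resolution is
the argmax (ties to the smallest grid value, favoring coarser, more stable
partitions).

One behavior deserves emphasis because it shapes what a green test can claim:
modularity maximization on k-nearest-neighbor-style graphs subdivides large
homogeneous point clouds into spatial parcels. On synthetic data with two
tight 100-unit families the parceled partition has strictly higher modularity
than the two-family split, at every resolution, so the recovered clustering is
a *refinement* of the planted families (each recovered cluster nests inside
one family; collapsing clusters by majority family separates the families
perfectly) rather than an exact recovery. The test suite asserts exactly this
refinement property; an adjusted-Rand-style exact-recovery bound is left
failing by design with the analysis recorded in the project notes. The same
behavior is why real recordings yield many clusters from largely unimodal
feature distributions, and why merging clusters into broader groups
(`merge_map()`, `canonicalize_clusters()`) is part of the method.

Cluster separability is assessed with five-fold cross-validated
gradient-boosted decision trees. No boosted-tree library is assumed: the
classifier is an in-package one-vs-rest logistic gradient-boosting machine on
exhaustively searched depth-1 trees (50 rounds, shrinkage 0.1). Only the model
family is prescribed; stumps with shrinkage are the simplest faithful member
and separate planted families at greater than 99% while scoring at chance on
permuted labels.

## Laminar anchoring

The CSD is minus the five-point second spatial difference
(-1, 16, -30, 16, -1)/(12 h^2) of the stimulus-triggered LFP (edges
truncated), spatially smoothed with a sigma = 120 um Gaussian renormalized
over valid channels; sinks are negative. The dominant sink is the connected
negative region of the time-averaged profile (0-100 ms window, configurable)
with the largest integrated magnitude, and the laminar anchor is the linearly
interpolated zero crossing below its extremum. The synthetic LFP plants the
sink as an antisymmetric Gaussian sink/source pair about the requested lower
edge, built from the exact second antiderivative
`H(x) = x * pnorm(x/s) + s^2 * dnorm(x, sd = s)`, so the zero crossing is
invariant under the symmetric spatial smoothing and the closed loop recovers
the planted edge to within one channel pitch.

Depth scaling maps each session's layer intervals piecewise-linearly onto a
common reference (the arithmetic mean of session boundaries after flipping
inverted calcarine sessions), fixing shared boundaries exactly. Layer
distribution tests are Pearson goodness-of-fit chi-squares against uniform
expected counts with `df = groups - 1`.

## Tuning and response timing

PSTHs are spike-count histograms over [-50, 500] ms around the
screen-corrected onset (nominal onset + 67 ms), divided by trial count and bin
width, Gaussian-smoothed with a 13 ms kernel whose edge bins are renormalized
so spike mass is conserved to within 1%. DI and OI follow the standard
(pref - null)/(pref + null) forms: the direction null is the opposite drift at
the preferred orientation; the orientation null is 90 degrees away, with each
orientation's response averaged over its two drift directions (an averaging
rule that is our choice). Preferred-condition ties break to the lowest
condition index. The modulation ratio F1/F0 takes F0 as the mean evoked rate
and F1 as twice the magnitude of the spike-phase vector at the grating
temporal frequency (a cycle-resolved estimate, robust at 5-10 repeats);
ratios above 1 are "simple", below 1 "complex".

Responsiveness and latency have no prescribed criteria and are the package's
own, fully configurable: responsive means a one-sided rank-sum test of
per-trial evoked vs baseline rates at p < 0.05 *and* a mean excess of at least
1 spike/s; latency is detected as the first sustained (>= 10 ms) excursion
above baseline mean + 3 SD and then *reported* as the half-rise time (first
crossing of halfway between baseline and response maximum). The refinement
matters: a symmetric 13 ms kernel advances the threshold crossing by roughly
one kernel width, whereas the half-rise time of a smoothed step is unbiased;
with the detection rule alone, planted latencies were recovered ~10-20 ms
early.

## ISI structure and the bursting index

ISI histograms use 0.4 ms bins capped at 100 ms (the cap is ours: PCA on
unbounded support is dominated by tail mass) and are normalized by their
maximum bin ("relative probability", peak = 1), resolving the internally
contradictory normalization wording in favor of max-normalization. PCA is run
on the mean-centered histograms exactly as produced (not re-normalized to
unit area).

PCA signs are arbitrary, so the component orientations are fixed conventions:
PC3 is oriented so its mean over the first 10 ms is negative (the short-ISI
"dip" bursty units load negatively on), and PC1 is oriented so its short-ISI
mean exceeds its overall mean - the short-ISI-concentration direction is
positive. The second rule deviates deliberately from a simpler
"PC1 mean positive" convention: on populations dominated by exponential-ISI
units, the mean-positive direction aligns with the regular-spiking units
(whose max-normalized histograms carry more total mass), which inverts the
bursting index `l1 - l3`; the concentration-anchored rule reproduces the
conventional orientation on peaked-ISI populations and keeps the index
increasing with burstiness in both regimes. Shuffle tests permute cluster
labels (500 shuffles), preserving cluster sizes, and flag clusters whose
observed median falls outside the 2.5-97.5 percentile band; under an
exchangeable null the per-cluster false-positive rate is ~5%.

## Multichannel propagation

Per-channel trough times (sub-sample interpolated, soma trough = 0) are
regressed on signed channel offset in mm, separately above and below the soma;
the slopes are inverse velocities in ms/mm. The 95% central-trough-time trim
is applied per channel across units within a cluster (the reference population
is not prescribed; per-unit trimming is available). The asymmetry index is the
signed orthogonal distance of `(v_below, v_above)` from the y = -x diagonal,
`SI = (x0 + y0)/sqrt(2)`; with offsets positive toward the pia, that diagonal
is the locus of perfectly symmetric bidirectional propagation, unidirectional
profiles land at `x0 > 0` and symmetric ones at `x0 < 0`. Velocities are
fitted per unit and aggregated (a per-cluster-mean mode exists for
comparison). Bootstrap comparisons resample units within cluster (500
resamples): cluster SDs from the resampled means, pairwise differences at a
99% percentile CI, below-soma slopes against zero at 95%. Percentile bootstrap
CIs are anti-conservative for very small clusters (at ~15 units the pairwise
false-positive rate is ~3% rather than 1%); calibration tests use realistic
cluster sizes (~60 units).

## Cross-correlograms and connectivity

The raw CCG of an ordered pair (reference j, target k) is the trial-summed
binary-raster cross-product at each lag, divided by `M * theta(tau) *
lambda_j * lambda_k`, with `theta(tau) = N - |tau|` the triangular overlap
correction and lambda the mean spikes per analysis bin - so independent
stationary trains sit at baseline 1, and positive lags mean the reference
leads. Analysis bins are 1 ms over the 0.4-1.0 s post-onset window with lags
to +/-100 ms (the bin and span are forced by the 50-100 ms noise band and the
+/-10 ms extremum rule). The per-bin-rate product is the primary
normalization; a geometric-mean variant is available as a switch since the
prose and the formula disagree.

Jitter correction subtracts the *analytic* expectation of the CCG under
interval jitter: spikes redistributed uniformly within non-overlapping 25 ms
windows (anchored at the window start), independently per train, preserving
per-window counts. The expectation is computed exactly from per-window counts
via FFT cross-correlation, so correction is deterministic - no Monte-Carlo
surrogates. This removes rate covariation slower than the window; the
suppression tests measure the comodulation component at its own period
(a matched projection), because the maximum absolute corrected value is
limited by sampling noise rather than residual slow structure.

Significance uses noise statistics from the corrected CCG at 50-100 ms lags,
both signs pooled (the pooling is our resolution of an ambiguity): excitatory
when the peak within +/-10 ms exceeds 7 noise SDs, inhibitory when the trough
falls below 5 (both assessed on the corrected CCG). The lead-lag index CA
rectifies the corrected CCG within +/-10 ms (window and rectification are our
choices; neither is prescribed) and forms (R - L)/(R + L), so CA = +1 when
the reference fully leads; |CA| <= 0.3 is read as common input and
|CA| >= 0.4 as consistent with a synaptic interaction. Cluster-pair summaries
take the median CA over significant excitatory pairs per ordered cluster pair
(antisymmetric by construction), test it against zero with a two-sided
Wilcoxon signed-rank test, and emit a directed edge from the leading side
(thin p < 0.01, bold p < 0.001).

## Degenerate inputs and numerical conventions

Constant waveforms refuse polarity classification; all-zero waveforms refuse
normalization; pairs with no spikes in the analysis window are skipped and
logged; a zero noise SD yields a flagged non-significant classification; zero
rectified CA mass yields a flagged `NA`. Identical waveform sets short-circuit
to a single cluster. Seeded determinism is global: every stochastic routine
takes a seed, derives child seeds below 2^31, and restores the caller's RNG
state.

## Known limitations

Exact reproduction of the published real-data numbers (9 clusters on 801
waveforms, 88% classifier accuracy, the laminar concentration percentages)
requires the archived recordings and is out of scope at desk scale. The
manual two-rater curation is replaced by the rule-based SNR filter; ensemble
consensus clustering is not implemented. The non-bursty synthetic trains are
memoryless (no refractory period), which is precisely why the bursting-index
sign convention had to be anchored to short-ISI concentration rather than to
the overall mean.
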