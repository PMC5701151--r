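---
title: "Brain-network topology from phase-lag-index connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network topology from phase-lag-index connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebnt)
```

## The problem

Resting-state EEG studies of neurodevelopmental conditions repeatedly find
that *connectivity strength* between sensors differs between groups, but
strength alone says little about how the brain network is *organised*. This
package implements a complete sensor-space analysis chain for that question:
phase-synchronization connectivity between all channel pairs, followed by
three complementary graph characterizations — the weighted graph, the
density-thresholded binary graph, and the spanning-tree backbone — and the
two-group statistics to compare them. A synthetic cohort generator with
known, band-specific phase coupling provides ground truth so that every stage
of the chain can be validated end to end.

## Connectivity: the phase lag index

For two signals with instantaneous phases $\phi_x(t_k)$, $\phi_y(t_k)$ and
wrapped differences $\Delta\phi(t_k) \in (-\pi, \pi]$, the phase lag index is

$$\mathrm{PLI} = \left| \langle \mathrm{sign}\, \Delta\phi(t_k) \rangle \right|
  \in [0, 1].$$

PLI is 1 when one signal consistently leads the other (perfect phase locking
at any nonzero lag) and 0 either for independent signals or for coupling
whose phase difference is centred on $0 \bmod \pi$. That blindness to
zero-lag coupling is the point: instantaneous volume conduction spreads one
source across many electrodes with *zero* lag, and PLI discards exactly that
component.

Implementation choices the formula itself leaves open:

* **Phase extraction** is by the analytic signal (frequency-domain Hilbert
  construction) applied to each already band-passed segment.
* **`sign(0)` contributes 0** (three-valued sign), so `pli(x, x)` is exactly
  0 rather than an arbitrary small value.
* Phase differences are wrapped into $(-\pi, \pi]$ before taking signs.
* Segments are analysed whole; no samples are trimmed after filtering. The
  phase tests therefore use interior windows when asserting pointwise phase
  relations, and the PLI of finite independent signals has a noise floor of
  roughly $\sqrt{2/\pi n_\mathrm{eff}}$ set by the number of effectively
  independent phase samples, not by the nominal sample count.

Connectivity per subject and band is the arithmetic mean of per-segment PLI
matrices over non-overlapping 5-s segments (`segment_length = 5`, the
conventional compromise between stationarity and phase-estimate stability).

## Preprocessing

The conditioning chain is re-reference (mean of named reference channels),
downsample (zero-phase FIR anti-alias at 80% of the new Nyquist, integer
decimation), notch (band-stop, default 48–52 Hz), band-pass into the five
clinical bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
30–48 Hz), then segmentation. All filters are windowed-sinc FIR applied
forward and backward by FFT convolution, with odd-symmetric edge padding:
linear-phase FIR run in both directions is exactly zero-phase, which matters
because any phase distortion would bias PLI directly. Transition bandwidth is
25% of the lower band edge and the order follows the Hamming rule
$\approx 3.3 f_s / \Delta f$, capped at a third of the signal length for
short inputs. Synthetic recordings are generated clean at 250 Hz, so
re-referencing and notching are identity-safe no-ops there but remain
available for real recordings read from the plain-text cohort container.

## Weighted graph

With PLI weights $w_{ij}$, per-node clustering is

$$CC_i = \frac{\sum_{k \ne i}\sum_{l \ne i, l \ne k} w_{ik} w_{il} w_{kl}}
              {\sum_{k \ne i}\sum_{l \ne i, l \ne k} w_{ik} w_{il}},$$

averaged over nodes ($CC_i = 0$ for isolated nodes — bounded and
conventional). Path length uses distances $d_{ij} = 1/w_{ij}$, Dijkstra
shortest paths $l_{ij}$, and the harmonic mean

$$PL = \Big[ \tfrac{1}{N(N-1)} \sum_i \sum_{j \ne i} 1/l_{ij} \Big]^{-1},$$

chosen precisely because disconnected pairs contribute $1/l = 0$ instead of
an infinity. Because both measures scale with overall weight
($CC \mapsto cCC$, $PL \mapsto PL/c$), they are normalized by the mean over
an ensemble of 100 surrogate networks obtained by reshuffling the
upper-triangle edge weights (preserving the weight multiset and graph size
only — not the degree sequence, which is what plain edge-weight reshuffling
means). The normalized ratios are scale-invariant, with expectation 1 for an
already-random network.

## Binary graph

Comparing binary graphs at a fixed *absolute* threshold confounds topology
with overall connectivity strength (the weaker group simply has fewer
edges), so graphs are binarized at fixed **link density**: the
$\mathrm{round}(d \cdot N(N-1)/2)$ strongest edges are kept, over the grid
$d = 0.2, 0.25, \ldots, 0.9$ (15 densities). Binary clustering is the
fraction of existing edges among a node's neighbours (0 for degree < 2);
binary path length is the harmonic mean of BFS distances, again absorbing
the disconnected pairs that necessarily appear at low densities. Ties at the
density cutoff are broken deterministically by (weight descending, node pair
ascending), so results are platform-independent; both measures depend only
on the rank order of weights. Absolute-threshold binarization is exposed as
a utility (`binarize_by_threshold`) but is not used in the group pipeline.
At high densities almost all non-adjacent pairs sit at graph distance 2, so
binary path length can become a deterministic function of the (fixed) edge
count; such zero-variance comparisons are reported as `degenerate` rather
than tested.

## Spanning-tree backbone

With similarity weights, minimizing total link cost (inverse connectivity)
is the same as maximizing total PLI weight, so the backbone is the
maximum-weight spanning tree built by Kruskal's algorithm with union-find
cycle rejection and the same deterministic tie rule (tie-affected trees are
flagged, since the tree is then non-unique). The tree always has $N$ nodes
and $N-1$ edges, making subjects directly comparable without thresholds or
normalization. Its shape is summarised by:

* **leaf number / leaf fraction** — degree-1 nodes; 2 for a line,
  $N - 1$ for a star. The fraction divides by $N$ (the literal fraction of
  leaf nodes); dividing by $N-1$ is available as an option.
* **maximum betweenness centrality** $BC_{\max}$ — per node, the fraction of
  the $(N-1)(N-2)/2$ node pairs whose unique tree path crosses it (computed
  from subtree sizes; 1 at the hub of a star).
* **tree hierarchy** $TH = LN / (2 (N-1) BC_{\max})$, balancing integration
  (many leaves) against hub overload. The $(N-1)$ edge-count factor in the
  denominator is required for the measure's stated behaviour — star trees
  give exactly 0.5, long lines tend to 0, and the range is $(0, 1]$; without
  it a star would score $(N-1)/2$, contradicting those limits. Line-like
  trees are decentralized and inefficient; star-like trees are integrated
  but hub-overloaded.

## Group statistics

Per measure, band (and density), groups are compared with an independent
two-sample t-test (pooled variance by default — the plain reading of
"independent t-test" — with Welch available), after an advisory
Shapiro–Wilk normality screen. Bonferroni correction is applied within
measure families: the two weighted measures per band, the two tree measures
per band, the binary sweep's 2 measures × 15 densities, and the global mean
PLI across the analysed bands. Corrected p < 0.01 is reported as
significant and 0.01–0.05 as marginal, keeping both tiers visible. Edgewise
connectivity maps use per-edge t-tests with Benjamini–Hochberg FDR at 0.05
(an edge-level map over ~$N^2/2$ tests is exactly the setting FDR is made
for), with zero-variance edges flagged rather than tested.

## The synthetic cohort generator

Each channel receives independent broadband Gaussian noise
(`noise_sd`, default 1) plus, per configured band, a unit-variance
band-limited Gaussian carrier. A coupled pair mixes a time-shifted copy of
the *source* channel's carrier into the *target*: the shift is
$\tau = \mathrm{lag} / (2\pi f_c)$ seconds at the band centre frequency
(lag $\pi/4$ in alpha ≈ 3 samples at 250 Hz), which produces the consistent
nonzero-lag phase distribution PLI rewards. Configurations with lag
congruent to 0 mod $\pi$ and nonzero strength are rejected outright — PLI
could never verify them. Group-2 subjects have all coupling strengths in
affected bands multiplied by `group_effect` (default 0.5 in theta and
alpha, mirroring the reduced low-band connectivity phenotype the pipeline
is designed to detect).

Three structural choices deserve justification:

* **Graded couplings.** Per-pair strengths are `strength` ×
  U(1/3, 1) rather than one uniform value. A two-valued weight
  distribution rescaled by a group factor preserves the rank order of all
  edges, and every rank-preserving change leaves the spanning tree — and
  hence all tree metrics — identical. Real connectivity is graded; the spread
  also lets a multiplicative reduction push the weak tail of true couplings
  below the PLI noise floor, which is the mechanism by which tree topology
  degrades.
* **Hub-biased layout.** Sources are drawn with probability `hub_bias`
  (default 0.75) from `n_hubs` designated hub channels (default N/16),
  emulating the hub-organised backbone of resting-state networks; a uniform
  layout produces trees with no star-like structure to lose. Source and
  target roles are disjoint channel sets: if a target re-sources its own
  (coupling-diluted) carrier, the group effect on that edge can invert,
  which is a generator artifact rather than a property of interest.
* **Unit-variance mixing.** The target keeps $\sqrt{1 - \sum_p s_p^2}$ of
  its own carrier, so band power is identical in both groups and any group
  difference is purely one of phase coupling, not amplitude.

What the generator does **not** emulate: volume conduction and electrode
geometry (no forward model), artifacts (blinks, EMG, line noise), 1/f
background spectra, non-stationarity, and within-group heterogeneity of the
coupling layout (all subjects share one layout, differing only in carriers
and noise). Passing the recovery tests therefore shows the chain detects
lagged phase coupling and its topological consequences under clean
conditions; it does not certify performance on artifact-laden clinical
recordings.

## Problem sizes and what the validation shows

The package's validation suite uses: exhaustive spanning-tree enumeration on
7 nodes (all $7^5$ labelled trees) against Kruskal; triple-loop and
Floyd–Warshall oracles on 6–8-node graphs; a parameter-recovery cohort of
20 + 20 subjects, 32 channels, 60 s at 250 Hz with alpha coupling halved
(seed fixed a priori); and 50 null cohorts (8 + 8 subjects, 16 channels,
20 s) for type-I calibration, bounding each family's familywise error at
the nominal 0.01 plus three binomial standard deviations. At this scale the
recovery run flags the alpha mean PLI, normalized clustering/path length
and tree hierarchy as significant reductions with gamma fully null, while
the alpha leaf-fraction reduction has the correct sign but only reaches the
marginal tier (corrected p ≈ 0.014) — tree measures need either stronger
contrast or larger cohorts than connectivity measures, which is itself a
finding worth knowing before applying tree statistics to small clinical
samples.

## Known limitations

* Sensor-space only: no source projection, leakage correction beyond PLI's
  zero-lag insensitivity, or electrode-geometry awareness.
* The harmonic-mean path length convention makes disconnected graphs
  comparable but is not the only convention in the literature; values are
  not directly comparable to giant-component means.
* Kruskal ties make the spanning tree non-unique; the deterministic tie rule
  picks one reproducibly and flags the condition, but tie-heavy matrices
  (many exactly equal PLI values) deserve caution.
* Downsampling requires an integer rate ratio.
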