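# ebnt — EEG brain-network topology from phase-lag-index connectivity

`ebnt` is an R package for sensor-space brain-network analysis of
multichannel resting-state EEG, aimed at group studies (e.g. patients vs
controls) that ask not just *how strongly* brain regions are coupled but
*how the coupling network is organised*. It implements the full chain:

1. **Preprocessing** — re-reference, downsample, notch, zero-phase FIR
   band-pass into the five clinical bands (delta 1–4, theta 4–8, alpha 8–13,
   beta 13–30, gamma 30–48 Hz), 5-s segmentation.
2. **Connectivity** — the phase lag index between all channel pairs,

   PLI = |⟨ sign Δφ(t_k) ⟩| ∈ [0, 1],

   the absolute mean sign of the wrapped instantaneous phase difference:
   1 for a consistent nonzero lag, 0 for independence *or* zero-lag
   (volume-conduction-like) coupling. Per-segment matrices are averaged to
   one N × N matrix per subject and band.
3. **Graph topology**, three ways:
   - *weighted graph*: clustering coefficient
     CC_i = Σ w_ik w_il w_kl / Σ w_ik w_il and harmonic-mean path length
     over inverse-weight shortest paths, normalized by 100 edge-reshuffled
     surrogate networks;
   - *binary graph*: strongest-edge binarization at fixed link density over
     the 15-point grid 0.2–0.9, binary clustering and BFS path length;
   - *spanning tree*: maximum-weight spanning tree (Kruskal), leaf
     number/fraction, maximum betweenness centrality, and tree hierarchy
     TH = LN / (2 (N−1) BC_max) — 0.5 for a star, → 0 for a line.
4. **Group statistics** — Shapiro–Wilk screening, independent t-tests per
   measure × band (× density), Bonferroni correction within measure
   families, FDR-corrected edgewise difference maps.

A synthetic cohort generator (`cohort_config()` / `generate_cohort()`)
produces two-group cohorts with known band-specific lagged phase coupling —
hub-biased, graded couplings whose strength is reduced in group 2 — so the
entire pipeline can be validated against ground truth. See the methods
vignette (`vignettes/eeg-network-topology.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

Generate a small cohort in which alpha-band coupling is halved in group 2,
and run the full analysis in the alpha and (uncoupled) gamma bands:

```r
library(ebnt)

cfg <- cohort_config(
  n_subjects_per_group = 6, n_channels = 16, duration = 30,
  band_coupling = list(alpha = list(strength = 0.9, lag = pi/4, fraction = 0.1)),
  group_effect  = c(alpha = 0.5), seed = 11)
cohort <- generate_cohort(cfg)
cohort[[1]]
#> <recording> subject g1_s01 (group 1): 16 channels x 7500 samples @ 250 Hz (30.0 s)

res <- analyze_cohort(cohort, bands = c("alpha", "gamma"),
                      densities = c(0.3, 0.5, 0.7), n_surrogates = 50, seed = 1)
res
#> <bna_analysis> 6 + 6 subjects, bands: alpha, gamma
#>   22 comparisons: 3 significant, 1 marginal
summary(res)
#> Brain-network group analysis: 6 + 6 subjects
#> Significant / marginal group differences (Bonferroni-corrected):
#>   band       measure density mean_group1 mean_group2 t_stat     p_raw p_corrected n_comparisons        tier
#>  alpha       cc_norm      NA      1.1296      1.0151  8.156 9.935e-06   1.987e-05             2 significant
#>  alpha leaf_fraction      NA      0.6979      0.5000  3.348 7.386e-03   1.477e-02             2    marginal
#>  alpha      mean_pli      NA      0.1745      0.1554  5.995 1.329e-04   2.658e-04             2 significant
#>  alpha       pl_norm      NA      0.9260      0.9967 -7.696 1.651e-05   3.301e-05             2 significant
```

Reading the output: group 2's global alpha connectivity (`mean_pli`) is
significantly reduced; its normalized clustering drops towards 1 and its
normalized path length rises towards 1 — the signature of a network sliding
from small-world organisation towards a random network — and its spanning
tree loses leaves (more line-like, less hub-centred). The gamma band, where
no coupling was injected, shows nothing. Positive `t_stat` means
group 1 > group 2.

Lower-level entry points are exported too: `pli()`, `subject_connectivity()`,
`weighted_clustering()`, `surrogate_normalize()`, `density_sweep()`,
`mst_metrics()`, `edgewise_group_comparison()`, and
`write_cohort()`/`read_cohort()` for a plain-text cohort container.

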