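# dynflex

Flexibility analysis of dynamic functional brain networks in R.

Resting-state fMRI studies increasingly ask not just *which* brain regions
are functionally connected, but *how stable* those connections are over the
scan. `dynflex` implements the standard pipeline for that question, for
researchers analysing ROI time series from multi-site case–control cohorts:

1. **Sliding-window connectivity** — overlapping windows (default 100 s =
   50 TRs, step 1 TR) of Pearson correlations between all ROI pairs form a
   multilayer network `G = (G_t)`, one layer per window.
2. **Multilayer community detection** — every node in every layer is
   assigned a community by maximizing multilayer modularity with ordinal
   inter-layer coupling,

   `Q = (1/2mu) * sum_{ijsr} [ (A_ijs - gamma * k_is * k_js / (2 m_s)) * d_sr
        + d_ij * omega * 1{|s-r|=1} ] * d(g_is, g_jr)`

   via a generalized Louvain algorithm (re-implemented here in Rcpp, with an
   exhaustive-enumeration reference for small instances).
3. **Flexibility** — the switching rate of node *i* is `f_i = N_i / (T - 1)`,
   the fraction of adjacent layer pairs where its community changes,
   averaged over repeated optimizer runs and aggregated to six functional
   subnetworks and a global mean. The packaged Dosenbach 160-ROI functional
   atlas provides the parcellation and subnetwork assignment.
4. **Group statistics** — Welch t / chi-square demographic comparisons,
   covariate-adjusted ANCOVA (age, sex, mean framewise displacement,
   dummy-coded site) with Benjamini–Hochberg FDR across subnetworks or
   nodes, partial Pearson correlations with symptom scores, quality-control
   subject filters, and a motion/sex-matched sensitivity subset.

Because real multi-site cohorts cannot ship with a package, `dynflex` also
includes a first-class synthetic cohort generator with planted time-varying
community structure: every node's per-TR community switching probability is
known ground truth, groups can differ by a planted `delta_p` on one
subnetwork, and sites, sex ratios, ages, head motion and symptom scores
mirror a typical case–control sample. Every downstream stage is validated
against this ground truth.

## Worked example

```r
library(dynflex)

atlas <- dosenbach_atlas()
print(atlas)
#> <flex_atlas> 160 ROIs, 6 subnetworks
#>      default mode         occipital cingulo-opercular   fronto-parietal
#>                34                22                32                21
#>      sensorimotor        cerebellar
#>                33                18

# one synthetic subject with a known switching rate of 0.05 per TR
model <- planted_model(n_nodes = 160, n_communities = 4, t_scan = 200,
                       switch_prob = 0.05, within_corr = 0.6, seed = 1)
truth <- generate_partition_sequence(model)
ts    <- generate_timeseries(model, truth)

net <- build_dynamic_network(ts)          # 151 layers of 160 x 160
print(net)
#> <dyn_network> subject 'synthetic': 160 nodes x 151 layers (width 50, step 1 TRs)

parts <- run_ensemble(net, modularity_params(seed = 1), n_runs = 10)
flex  <- run_averaged_flexibility(parts, atlas)
print(flex)
#> <flex_result> 160 nodes, 151 layers, 10 runs; global flexibility = 0.0296
#>      default mode         occipital cingulo-opercular   fronto-parietal
#>            0.0305            0.0305            0.0291            0.0282
#>      sensorimotor        cerebellar
#>            0.0289            0.0304
```

The planted per-TR rate of 0.05 appears as a window-smoothed flexibility of
about 0.03: the 50-TR window and the inter-layer coupling compress the
scale, which is why validation checks ordering (higher planted rates give
higher recovered flexibility, Spearman ≥ 0.9 across nodes) rather than
absolute values.

A full cohort analysis — subject QC filters, per-subject flexibility,
ANCOVA at global/subnetwork/nodal levels with FDR, symptom correlations and
the matched-subset re-analysis — runs through `run_cohort()`; see the
vignette (`vignettes/dynamic-network-flexibility.Rmd`) for the model,
parameter and design details.

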