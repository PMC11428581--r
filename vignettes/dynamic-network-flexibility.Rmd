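---
title: "Flexibility analysis of dynamic functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility analysis of dynamic functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynflex)
```

## The model

Resting-state fMRI yields, for each subject, a $T_{scan} \times N$ matrix of
BOLD signals over $N$ regions of interest (ROIs). `dynflex` implements the
standard dynamic-connectivity account of how stable each region's network
affiliation is over the scan:

1. **Sliding-window connectivity.** The scan is cut into overlapping windows
   (default width 50 TRs = 100 s at TR = 2 s, step 1 TR). Within each
   window, the Pearson correlation of every ROI pair gives one $N \times N$
   connectivity matrix; the ordered stack of $T$ window-wise matrices forms a
   multilayer network $G = (G_t)_{t = 1 \dots T}$ with
   $T = \lfloor (T_{scan} - w)/s \rfloor + 1$. Trailing partial windows are
   dropped rather than padded, because a shorter window changes the sampling
   distribution of the correlations.

2. **Multilayer community detection.** Every node in every layer is assigned
   a community by maximizing multilayer modularity with ordinal inter-layer
   coupling,
   $$Q = \frac{1}{2\mu} \sum_{ijsr} \left[ \left( A_{ijs} - \gamma
   \frac{k_{is} k_{js}}{2 m_s} \right) \delta_{sr} + \delta_{ij}\,\omega\,
   \mathbb{1}\{|s - r| = 1\} \right] \delta(g_{is}, g_{jr}),$$
   using a generalized Louvain algorithm. $\gamma$ controls the intra-layer
   resolution and $\omega$ rewards a node for keeping its community label in
   adjacent layers; both default to 1, the customary choice when no other is
   specified. Negative correlations are clipped to zero by default because
   the Newman–Girvan null term is not defined for sign-mixed strengths; a
   `keep` policy is available for sensitivity analyses.

3. **Flexibility.** The flexibility (switching rate) of node $i$ is
   $f_i = N_i / (T - 1)$, the number of adjacent layer pairs in which its
   community label changes, divided by the number of opportunities. Because
   individual optimizer runs differ, the detection is repeated (100 runs by
   convention; `n_runs` in `flex_config()`) and flexibilities averaged
   across runs, then aggregated to six functional subnetworks (default mode,
   occipital, cingulo-opercular, fronto-parietal, sensorimotor, cerebellar)
   by unweighted node means, and to a global mean over all nodes.

4. **Group statistics.** Flexibility at the global, subnetwork and nodal
   level is compared between groups by ANCOVA — ordinary least squares on
   group plus age, sex (female = 1), mean framewise displacement, and
   dummy-coded site (alphabetically first site as reference); the group F is
   the squared t of the single-df group coefficient. Families of tests
   (6 subnetworks; N nodes) are corrected by Benjamini–Hochberg FDR; the
   single global test is reported uncorrected and flagged as such.
   Associations with symptom severity (ADOS total) use partial Pearson
   correlations after residualizing both variables on the same covariates,
   run in the entire sample and in patients only. A sensitivity subset
   retains all patients and drops high-motion controls (males above 0.05 mm,
   females above 0.06 mm mean FD, strict inequalities), after which the
   significant comparisons are repeated.

## The optimizer

The generalized Louvain implementation alternates two greedy phases until
neither improves $Q$: *tuple sweeps* move one node-layer tuple at a time to
the best of its candidate communities (its intra-layer neighbours'
communities and the same node's communities in adjacent layers); *community
sweeps* move a whole community at a time, which is exactly the move class
obtained by collapsing communities into super-nodes and recursing, but is
evaluated directly against the connectivity tensor so the dense aggregated
null-model matrix is never materialized. Every accepted move strictly
increases $Q$ (gains are recorded in `q_trace`); ties keep the current
community, and among new communities the lowest id wins, so a run is fully
reproducible from its seed. The sweep budget is `max_sweeps = 1000` with a
gain tolerance of $10^{-10}$; if the budget is exhausted the best partition
so far is returned with `converged = FALSE` rather than an error. The
returned `q_value` is always recomputed from the final labels through
`modularity_value()`, and on instances small enough to enumerate
(`exhaustive_optimum()`), seeded runs attain the global optimum in at least
95 of 100 runs.

Windowed correlations are computed incrementally (one row leaves the
window, one enters), which is algebraically identical to recomputing each
window from scratch; the test suite asserts equality with a literal
textbook correlation at $10^{-12}$.

## The synthetic cohort generator

Real multi-site cohorts cannot ship with a package, so validation runs on
synthetic cohorts with known ground truth. For one subject
(`planted_model()`):

* nodes start evenly split across $K$ communities (default $K = 4$);
* at every TR, node $i$ reassigns with probability $p_i$ (default 0.05) to a
  uniformly chosen other community — switching is memoryless, so the planted
  per-TR switching probability is directly comparable to the measured
  flexibility, and realized switch counts are Binomial($T_{scan}-1$, $p_i$);
* the signal is $x_i(t) = a\,\sigma\,(\sqrt{w}\, s_{g_i(t)}(t) +
  \sqrt{1-w}\, \varepsilon_i(t))$ with fresh standard-normal community
  signals each TR, so two nodes sharing a community have expected window
  correlation $w$ (default 0.6, a clearly detectable but not trivial
  community structure).

A cohort (`cohort_spec()`, `generate_cohort()`) adds the confound structure
of a multi-site case-control comparison, with defaults mirroring a typical
ASD/TD sample: a male-skewed patient group (86% vs 75% male), comparable
ages (≈16 years), higher patient head motion (0.09 vs 0.06 mm mean FD),
patient symptom scores around 8.5 versus near zero in controls, per-site
amplitude/noise offsets, and head motion linearly inflating the subject's
noise scale. Patients carry `delta_p` (default +0.04) extra switching
probability on the nodes of one subnetwork (default: default mode),
mirroring the direction of the motivating clinical finding (higher
default-mode flexibility in patients). Every subject is reproducible from
the model seed and its index alone.

What the generator does **not** emulate: hemodynamic autocorrelation
(community signals are white, which keeps window-correlation expectations
analytic; an autoregressive option was considered and left out), scanner
drift, realistic BOLD spectra, or spatially structured noise. Passing the
recovery tests therefore shows that the estimator chain is correct and
well-calibrated under the planted model — not that real resting-state data
meet its assumptions.

## What recovery looks like, and the sizes used

Window smoothing compresses the planted switching rates: with a 50-TR
window and $\omega = 1$, planted $p_i \in \{0.01, \dots, 0.12\}$ map to
recovered flexibilities of roughly 0.013–0.032. Recovery is therefore
assessed by order (strictly increasing group means; Spearman correlation
between planted and recovered rates at least 0.8 across nodes), not by
absolute value.

The validation suite runs at sizes chosen to exercise the full pipeline in
reasonable time while keeping statistical checks meaningful; they are
stated here as the package's own choices:

* *Rate recovery*: 160 nodes, $K = 4$, $T_{scan} = 200$, $w = 0.6$, 20
  subjects, 10 optimizer runs each, five planted rate levels.
* *Null calibration*: a 36-node proportional subsample of the packaged
  atlas, $T_{scan} = 150$, 40 + 40 subjects over two sites, 2 runs;
  response-level ANCOVA replicates use 1000 draws.
* *Effect detection*: a 64-node subsample (14 default-mode nodes),
  $T_{scan} = 250$ — the upper end of the scan lengths the generator
  emulates, where window-level sampling noise leaves adequate power for the
  fixed planted effect — 40 + 40 subjects, 3 runs, `delta_p = +0.04`.

## Degenerate inputs and numerical choices

* A zero-variance node inside a window is an error naming the node and
  window, not a silent NaN.
* An empty layer (zero total strength after clipping) is a degenerate-layer
  error: the null model divides by layer strength.
* Scans shorter than one window fail that subject with an explicit message;
  in `run_cohort()` such failures are logged and other subjects proceed.
* A constant covariate or a site perfectly confounded with group makes the
  ANCOVA design rank-deficient; this errors naming the collinear columns
  rather than silently dropping terms.
* Cohorts filtered to empty produce a warning, not an exception.
* Per-subject seeds are `base_seed` plus a stable hash of the subject id,
  so adding or removing subjects never shifts another subject's results.

## A small end-to-end example

```{r example, eval = FALSE}
atlas <- dosenbach_atlas()
model <- planted_model(n_nodes = 160, n_communities = 4, t_scan = 200,
                       switch_prob = 0.05, within_corr = 0.6, seed = 1)
spec  <- cohort_spec(n_per_group = 10, sites = c("S1", "S2"),
                     delta_p = 0.04, effect_subnetwork = "default mode")
cohort <- generate_cohort(spec, model, atlas)

config <- flex_config(n_runs = 10, base_seed = 1)
res <- run_cohort(cohort$cohort, cohort$timeseries, atlas, config)
res$subnetwork          # ANCOVA per subnetwork, BH-FDR corrected
res$correlations$entire # partial correlations with the symptom score
```

## Limitations

The package deliberately stops upstream of image processing: it consumes
ROI time series, not 4-D volumes, and it implements exactly the statistical
battery described above — no mixed-effects site models, no harmonization,
no permutation inference, no consensus clustering across optimizer runs.
The resolution and coupling parameters $\gamma, \omega$ are exposed but
their defaults are conventions, not estimates; conclusions that depend
sensitively on them should be checked across a grid.
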