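---
title: "Single-subject grey matter similarity networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-subject grey matter similarity networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

## The method

Most structural brain graphs are built at the group level: cortical regions
become connected when their thickness or volume covaries *across subjects*.
That construction cannot say anything about an individual. `gmnet`
implements the single-subject alternative: a graph is extracted from one
grey-matter segmentation by exploiting the similarity of local cortical
structure *within* that brain.

The pipeline is:

1. **Nodes.** The native-space grey-matter volume is tiled into
   non-overlapping 3×3×3 voxel cubes (`extract_cubes()`). Each cube keeps
   the three-dimensional arrangement of its 27 grey-matter values, so
   geometric information enters the similarity measure. Cubes with fewer
   than `min_mask_voxels` voxels inside the grey-matter mask, or with zero
   variance across their 27 values (for which a correlation is undefined),
   are dropped.
2. **Edges.** Similarity between two cubes is the Pearson correlation of
   their value vectors, maximized over rigid rotations of one cube
   (`max_rotation_correlation()`). The cortex is curved, so two locally
   similar patches may be oriented differently; the rotation maximum makes
   the measure orientation-tolerant. On a voxel lattice the exact rigid
   rotations are the 24 right-angle rotations of the cube, each a
   permutation of the 27 voxel positions (`rotation_set()`; reflections are
   available but off by default, since mirrored cortex is not the same
   structure). The set is closed under inversion, which makes the maximum
   symmetric in its arguments without any averaging.
3. **Threshold.** The similarity matrix is binarized at a per-subject
   threshold calibrated so that a fixed proportion (default 5%) of the
   retained edges is expected by chance (`permutation_threshold()`). The
   null model permutes the 27 within-cube values of randomly sampled cube
   pairs — destroying spatial structure while preserving each cube's value
   distribution — and pushes the permuted pairs through the same
   rotation-maximized correlation. The threshold is the smallest value at
   which (expected surviving null correlations) / (surviving real
   correlations) drops to the target: an empirical false-discovery
   proportion on edges. Only positive similarities can become edges.
4. **Properties.** The binary graph is summarized by size, connectivity
   density, degree, Watts–Strogatz clustering, characteristic path length,
   and betweenness centrality (`graph_report()`); hubs are nodes more than
   one standard deviation above mean betweenness. Clustering and path
   length are normalized against degree-preserving randomized reference
   graphs (`small_world()`): γ = C/⟨C~rand~⟩, λ = L/⟨L~rand~⟩, and the
   small-world coefficient σ = γ/λ, with σ > 1 the small-world criterion.
5. **Regional summaries and statistics.** Nodal properties are averaged
   over the cubes of each atlas region (`summarize_regions()`), and group
   or brain–behaviour comparisons use rank-transform ANCOVA, Levene
   checks, Pearson/partial-Spearman correlations, forward nested
   regression, and Benjamini–Hochberg FDR (`ancova_group()` and friends).

## Why threshold per subject rather than fixing density

Enforcing a common connectivity density across subjects forces the same
number of edges on everyone; in a group with genuinely fewer strong
similarities this packs the graph with spurious edges and *manufactures*
a more random topology. Calibrating the expected chance-edge proportion
instead keeps the evidential standard constant across subjects and lets
size and density vary, which is the method's point.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `target_spurious` | 0.05 | expected chance fraction of retained edges |
| `n_null_pairs` | 100,000 | null sample size for threshold calibration |
| `min_mask_voxels` | 14 | in-mask voxels (of 27) for a cube to count as cortical |
| `offset` | (0,0,0) | cube-grid origin; partial boundary cubes are discarded |
| `include_reflections` | FALSE | add the 24 improper rotations |
| `n_reference` | 20 | randomized reference graphs for γ, λ |
| `swaps_per_edge` | 10 | Maslov–Sneppen swap attempts per edge |

`min_mask_voxels` deserves a note. A cube overlapping the mask by one or
two voxels consists mostly of background; such cubes are near-duplicates
of one another both in the data and in the value-permuted null, so they
concentrate the null's upper tail near 1 and can push the calibrated
threshold to the point of an empty graph on sharply masked volumes. We
therefore require a strict majority of cortical voxels by default. On
smoothly varying segmentations (real tissue-probability maps) lower values
are workable and the parameter is exposed.

The number of reference graphs (20) is enough for stable normalization:
the ensemble standard deviations reported by `small_world()` shrink as
1/√n~reference~ and are small relative to between-subject differences at
20; the tests check this behaviour at 5 vs 20 vs 80 references.

### Numerical choices

* Ties at the threshold: edges use strict `S > t`, and candidate
  thresholds sit just below each distinct real similarity value, so a
  whole tie group enters or leaves together. With fully separated real and
  null distributions this yields a threshold just below the smallest real
  similarity and an achieved spurious proportion of exactly 0.
* When no threshold meets the target (real ≈ null, i.e. no signal), the
  maximum real similarity is returned with a warning and the graph is
  empty rather than arbitrary.
* The similarity matrix is computed per rotation as one standardized
  cross-product and the maximum accumulated across rotations; symmetry is
  exact because the final matrix is the elementwise maximum of itself and
  its transpose (mathematically a no-op for a rotation set closed under
  inversion, numerically a guard against summation-order noise).
* Path length on disconnected graphs averages finite pairs only and
  reports the component count and the number of unreachable pairs; the
  characteristic path length is the pooled mean over connected ordered
  pairs, not a mean of per-node means (identical on vertex-transitive
  graphs, not in general). Per-node values average that node's finite
  distances.
* The hub rule uses the sample (n−1) standard deviation; a constant
  betweenness vector yields no hubs.
* Reference graphs are not forced to be connected: Maslov–Sneppen swaps
  preserve degrees, not connectivity, and the finite-pairs policy handles
  occasional fragmentation consistently on both sides of the ratio.
* In the ANCOVA only the response is rank-transformed (average ranks for
  ties); covariates enter on their original scale. The group test is the
  partial F of the group term added last.

## The synthetic generator

No imaging data ships with the package; instead `synthetic_spec()` /
`generate_volume()` build a miniature "cortex" with known ground truth:

* a **template anatomy**, fixed by `template_seed`: a smoothly undulating
  sheet (the mask) and a small set of latent morphological components,
  each with a smooth spatial loading map over the cube grid and a fixed
  27-voxel pattern. Cubes whose loading vectors align have correlated
  contents, so smooth loadings produce locally clustered, lattice-like
  similarity — which is exactly what makes the extracted control graphs
  small-world;
* **subject variation**: a smooth subject-specific perturbation of the
  loading maps, a smooth random intensity field, and i.i.d. voxel noise;
* a **disease effect** for the patient group: a fraction
  (`disease_fraction`, default 0.3) of cubes have their loading vectors
  *polarized* — raised elementwise to `disease_power` with sign kept and
  total loading energy renormalized — so their similarity concentrates
  onto their single dominant latent mode. Connectivity centralizes on hub
  communities; the graph's clustering falls relative to degree-matched
  random references (γ ↓) and paths shorten relative to them (λ ↓) at
  comparable density: topology moves toward random, while total grey
  matter is conserved (patterns are zero-mean), so the effect is not an
  atrophy artefact and survives volumetric covariate adjustment.

The polarization exponent defaults to 4, chosen so that the standardized
group differences in γ and λ sit at the scale such a study would report as
a strong effect (Cohen's d around 1.5–3 at the default volume size); the
direction-of-effect tests then detect both at n = 15 per group.

Two alternative patient manipulations are included for completeness and
experimentation. A literal within-cube value shuffle
(`shuffle_fraction`) destroys the affected cubes' similarity altogether;
under the per-subject chance-edge calibration those cubes simply
disconnect, which *raises* γ (the intact core looks more clustered than
its sparser random references) — focal disconnection, not randomization.
Swapping whole cube contents between positions is a pure node relabelling
(topology depends only on cube contents), hence a no-op. Both facts are
easy to miss and motivated the polarization design. A global intensity
scale (`atrophy_scale`) adds volumetric atrophy separately, to exercise
covariate adjustment.

Cognitive scores follow `score = intercept + slope·λ + noise` with the
subject's *realized* λ, so brain–behaviour correlation recovery can be
tested end to end. Defaults (intercept −48.3, slope 60, noise SD 2.2)
put control scores near 28 on a 0–30-like scale and give a within-sample
score–λ correlation near 0.5 at the default λ spread.

What the generator does *not* emulate: cortical folding geometry, partial
volume effects, scanner noise physics, spatial inhomogeneity of
segmentation quality, and any real anatomy. Passing tests therefore show
that the estimator chain is correct and well-calibrated on data with a
known similarity structure — not that any particular clinical effect will
replicate on real MRI.

## Problem sizes used in the tests

The default synthetic volume is 30×30×18 voxels (≈ 300 cube nodes after
masking), for which a full single-subject pipeline — extraction,
100,000-pair threshold calibration, metrics, and 20-reference
normalization — runs in about a second. Threshold calibration is
additionally validated at ≈ 1,400 nodes (51×51×21 voxels). The
direction-of-effect study uses 20 replicate cohorts of 15 + 15 subjects
at the default volume size with 5,000 null pairs per subject, and the
type-I-error check runs the rank-ANCOVA on 500 simulated null cohorts of
nodal-level summaries. These sizes were chosen so the whole suite stays
interactive while every estimate remains comfortably inside its
Monte-Carlo tolerance.

## Known limitations

* 45° (interpolated) rotations are out of scope; the rotation set is the
  exact lattice rotation group.
* The null model for thresholding (within-cube value permutation of
  sampled pairs) is one defensible choice; other permutation nulls exist
  and would shift thresholds slightly. The sample size is exposed.
* Betweenness, clustering and path length are binary-graph quantities
  here; weighted variants are deliberately not implemented.
* Regional summaries assign each cube to the majority label among its 27
  voxels (ties to the lowest label); cubes straddling boundaries are not
  split fractionally.
* On graphs with isolated nodes the finite-pairs path-length policy makes
  L systematically optimistic; the component count and unreachable-pair
  count are always reported so this is visible.
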