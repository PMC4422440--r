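---
title: "Connectivity-based parcellation with split-half stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation with split-half stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cbparc)
```

## The problem

Probabilistic tractography run from every voxel of a seed region (for
example a cytoarchitectonically defined frontal-pole mask in 2 mm standard
space) to the rest of the brain produces, per participant, a seed-voxel by
target-voxel matrix of streamline visit counts. Voxels with similar rows —
similar *connectivity fingerprints* — are presumed to belong to the same
functional subregion. `cbparc` turns a group of such matrices into a
parcellation of the seed and a set of statistics that say how many parcels
the data support, how nested successive solutions are, how symmetric the
two hemispheres are, and where each parcel's tracts differ from the others'.

## The procedure

1. **Correlation profiles.** Each participant's count matrix is reduced to
   the seed-by-seed Pearson cross-correlation of its rows
   (`cross_correlate()`), Fisher-Z transformed (`fisher_z()`, arctanh with
   clipping at `1 - clip_epsilon` so perfect correlations stay finite), and
   averaged entrywise across participants (`average_group()`). Target
   spaces may first be downsampled by integer block sums
   (`downsample_targets()`), the usual storage reduction; row totals are
   conserved exactly and the blocks are anchored at the grid origin so the
   operation is reproducible.
2. **Clustering.** Rows of the averaged Fisher-Z matrix are clustered with
   Lloyd's k-means under uniformly drawn distinct data rows as initial
   centroids, repeated (1000 replicates at study scale) with the
   minimum-inertia replicate kept (`kmeans_replicates()`). Replicates that
   end with an empty cluster are restarted with fresh centroids. k-means++
   seeding is available behind `init = "plusplus"` but is not the default,
   which stays with the plain random-restart scheme.
3. **Choosing K.** For each of (by default) 100 repetitions, participants
   are split into two disjoint halves, each half's profiles are averaged
   and parcellated at every K in 2..8, and the variation of information
   (VI) between the two half-solutions is recorded (`split_half_vi()`).
   VI = H(C) + H(C') − 2I(C, C') is a metric on partitions, zero exactly
   when the halves agree up to relabeling and bounded by log(n). The same
   splits are reused across K, so VI(K) − VI(K−1) is a paired sample, and
   each step is tested with a one-sided paired t-test of "VI increased".
   The optimal K is the smallest K > 2 whose step did not significantly
   increase VI (`select_optimal_k()`); if every step increases
   significantly, the largest K is returned with a no-selection flag. A
   step whose difference is identical in every repetition has no variance
   to test; its sign is taken as conclusive.
4. **Characterizing solutions.** `hierarchy_index()` measures, for each
   cluster of a (K+1)-solution, the largest fraction inherited from a
   single cluster of the K-solution (1 = perfectly nested);
   `symmetry_index()` mirrors the right-hemisphere mask across the
   midsagittal plane (world x to −x), restricts to voxels present in both
   hemispheres, pairs clusters by maximum-overlap assignment
   (`match_labels()`), and reports the fraction of agreeing voxels;
   `summarize_clusters()` reports world-space centers of gravity; and
   `dilate_labels()` thickens label maps by a spherical kernel for
   cross-participant overlap displays.
5. **Tract contrasts.** Per-cluster tract volumes are normalized by the
   total possible streamline count, thresholded at 1% (kept continuous for
   testing, binarized for overlap maps), and each cluster is contrasted
   against the mean of the others with a one-sample sign-flipping
   permutation test on the participant-wise difference maps
   (`contrast_cluster_vs_rest()`). Family-wise error is controlled by the
   permutation distribution of the maximum |t| over voxels, which gives
   exact control under exchangeability without tunable enhancement
   parameters.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_range` | 2..8 | candidate cluster counts; must start at 2 so the first tested step is 3 vs 2 |
| `n_replicates` | 1000 | k-means restarts per clustering; inertia is non-increasing in it |
| `n_repetitions` | 100 | split-half repetitions; 25 is enough for the paired tests on clean synthetic data |
| `alpha_k` | 0.05 | one-sided level of the VI step test |
| `log_base` | 10 | VI logarithm base; with 93 elements the bound log10(93) prints as 1.96. Natural log is conventional elsewhere, so the base is explicit everywhere |
| `clip_epsilon` | 1e-7 | Fisher-Z clip; leaves every &#124;r&#124; ≤ 1 − 1e-6 unchanged at double precision |
| `tract_threshold` | 0.01 | proportion cutoff on normalized tract maps (boundary value survives) |
| `consistency_cutoff` | 0.5 | minimum fraction of participants carrying a tract |
| `alpha_fwe` | 0.01 | family-wise error level of the max-t contrast |

Zero-variance seed rows (voxels with no streamline contrast) make Pearson
correlation undefined; the package raises an error naming the voxels by
default, with an opt-in `"drop"` policy that removes them consistently and
records them in the run report, since silently imputing them would distort
clusters.

## What the synthetic generator emulates

No imaging data ship with the package; `synthetic_config()` /
`simulate_group()` generate groups whose statistical structure matches what
the pipeline assumes of real tractography:

* Each of `k_true` parcels has a connectivity fingerprint over targets, and
  all rows of a parcel share it. Fingerprints are **two-level block
  patterns**: targets are split into exactly equal per-parcel blocks (a
  seeded random permutation assigns them; remainder targets stay at the
  baseline), parcel 1 forms one supercluster and parcels 2..k the other,
  and a parcel elevates its supercluster's blocks by `fingerprint_scale`
  and its own block by a further `fingerprint_scale` over a baseline of
  `3 * (fingerprint_scale + noise_scale)` counts.
* Each participant perturbs every parcel fingerprint (s.d. `noise_scale`)
  and every matrix entry (s.d. `noise_scale`); values are rounded absolute
  values, so files are valid nonnegative streamline counts.
* Seed voxels are laid out as a compact blob on a 2 mm grid whose left- and
  right-hemisphere affines are exact mirror images, so the spatial
  operations (centers of gravity, dilation, midline mirroring) are
  exercised for real.
* `simulate_hemisphere_pair()` plants a controllable left-right agreement:
  a fraction `1 - symmetry_level` of voxels is relabeled to a different
  parcel, so recovered symmetry should track `symmetry_level` exactly at
  zero noise.
* `hierarchy_split = c(p, m)` subdivides parcel p into m nested children
  whose fingerprints share the parent's blocks plus half-scale sub-blocks.

The block design is a deliberate choice rather than i.i.d. random
fingerprint vectors. The split-half K-selection rule needs under-clustered
solutions (K below the planted number) to be *unstable*: both halves see
the same parcels, and the only way their coarse solutions can disagree is
if the choice of which parcels to merge is not structurally determined.
With i.i.d. fingerprints the chance geometry of the draws fixes a preferred
merge order that both halves share, every K < k_true is then perfectly
stable, and the selection rule degenerately stops at 3. The two-level block
model instead makes the supercluster split (K = 2) structurally stable, the
intermediate K a three-way tie decided by participant noise, and K = k_true
stable again — the rise-then-drop VI profile the selection rule is designed
to read. Equal parcel sizes (the label generator assigns parcels in
balanced random order) and equal block sizes are part of the same tie
construction: a single extra voxel or target per parcel acts as a
deterministic tie-break shared by both halves and re-locks the coarse
solutions.

What the generator does **not** emulate: spatial smoothness and
distance-dependent tractography artifacts, inter-voxel connectivity
gradients within a parcel, heavy-tailed count distributions, registration
error, or unbalanced parcels. In particular, planted-K recovery is only
guaranteed when `n_seed_voxels` is a multiple of `k_true`; real data break
ties with genuine heterogeneity instead. Passing tests therefore show the
machinery is correct and calibrated, not that any particular real dataset
has a recoverable K.

## Numerical choices and degenerate inputs

* VI values below 1e-10 are snapped to zero before the paired tests:
  identical half-solutions otherwise leave round-off dust of order 1e-16
  that a zero-variance paired test would happily call significant.
* Lloyd iterations stop when assignments are unchanged or after 300
  iterations; empty-cluster replicates are retried up to 20 times and then
  discarded.
* Cluster-label matching maximizes total overlap by exhaustive enumeration
  of injective assignments, exact for the cluster counts used here (≤ 10).
* Dilation resolves conflicts by nearest labeled voxel in world-space
  distance, processing equidistant shells together with ties to the lower
  label id.
* The permutation test computes permuted t-statistics from sign-flipped
  means only (the sum of squares is sign-invariant), reports
  `(1 + #{max-null ≥ observed}) / (n_permutations + 1)`, and treats a
  zero-variance voxel as t = 0 when its mean is also zero.
* Probability maps for masks may be on a 0-1 or 0-100 scale; any value
  above 1 flags the percent convention. A voxel exactly at threshold is
  included.

## Problem sizes used in the checks

The packaged checks run the full machinery at desk scale: groups of 20
participants, 60-160 seed voxels, 150-400 targets, 25 split-half
repetitions with 100 k-means replicates for K-selection experiments, 200
null datasets with 500 permutations for the family-wise-error calibration,
and exhaustive oracles (all 52 partitions of 5 elements; all bipartitions
of up to 8 points) for the metric and clustering cores. Study-scale
defaults (1000 replicates, 100 repetitions) remain the package defaults.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_participants = 20, n_seed_voxels = 60,
                        n_targets = 150, k_true = 4, rng_seed = 1001)
truth <- make_planted_labels(cfg)
mats <- simulate_group(cfg, truth)
profiles <- lapply(mats, function(m) fisher_z(cross_correlate(m)))
curve <- split_half_vi(profiles, k_range = 2:8, n_repetitions = 25,
                       n_replicates = 100, rng_seed = 2001)
select_optimal_k(curve)$k  # 4

group <- average_group(profiles)
parc <- kmeans_replicates(group, 4, n_replicates = 1000, rng_seed = 1)
summarize_clusters(parc, synthetic_seed_geometry(60))
```

## Known limitations

* The optimal-K rule inherits the dependence structure of overlapping
  split-half repetitions; no correction for it is applied, mirroring the
  plain paired-test reading of the procedure.
* VI needs no cluster correspondence, so `match_labels()` is used only for
  symmetry and reporting.
* No spatial contiguity constraint is imposed on clusters.
* Threshold-free cluster enhancement is out of scope; the max-statistic
  correction is the supported family-wise error control.
* Surface-based (mesh) pathways are not implemented; everything lives on
  voxel grids.
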