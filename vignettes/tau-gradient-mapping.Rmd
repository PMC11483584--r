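---
title: "Methods: whole-brain tau spot mapping and gradient consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain tau spot mapping and gradient consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauscape)
options(tauscape.quiet = TRUE)
```

# Scope and model

`tauscape` quantifies punctate tau pathology in light-sheet volumes of
cleared mouse brains and asks whether the *regional ordering* of tau
burden is conserved across animals. The pipeline is:

1. **Spot extraction** — band-pass filter the tau (AT8) channel,
   restrict to an eroded brain mask, threshold, and summarise each
   connected suprathreshold component as a spot (centroid, total
   intensity, volume).
2. **Regional density** — assign spot centroids to atlas regions and
   divide summed spot intensity by region volume (per mm³).
3. **Gradient consensus** — rank regions by descending density in each
   sample; the consensus is the longest sequence of regions whose
   relative order is identical in every sample (a longest common
   subsequence of the per-sample rankings). Its significance is read
   off an empirical permutation null.
4. **Consensus graph** — regions adjacent within consensus sequences
   become weighted edges, normalised to a fixed total, laid out with a
   force-directed algorithm.
5. **PET evaluation** — time-activity curves, SUV and SUVR summarise
   in vivo tracer uptake; voxel F-scores against expert annotation
   masks evaluate detection accuracy.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `target_pitch_um` | 8.3 | µm | standard isotropic voxel pitch; inputs are trilinearly resampled to it |
| `sigma_small_vox` | 0.83 | voxels | Gaussian scale of the band-pass (FWHM ≈ 16 µm at 8.3 µm pitch) |
| `mean_extent_um` | 83 | µm | box (mean) filter extent of the band-pass; 10 voxels, forced odd to 11 |
| `mask_threshold_factor` | 1.5 | — | brain mask threshold, × global mean intensity |
| `erosion_iterations` | 10 | — | 6-connected erosions refining the mask (border counts as background) |
| `spot_threshold_factor` | 2.0 | — | spot threshold, × mean raw intensity *outside* the eroded mask |
| `connectivity` | 6 | — | component connectivity (6 or 26) |
| SUVR window | [45, 60] | min | closed window of frame mid-times for the scalar SUVR |
| annotation ROI edge | 423 | µm | 51 voxels at standard pitch |
| graph `weight_total` | 250 | — | normalised sum of consensus-graph edge weights |
| null | n = 47, k = 3, 10,000 reps, α = 0.05 | — | permutation scheme for the consensus threshold |

The voxel-centre convention is `coord_um = (index − 0.5) · pitch`
throughout; spot centroids are intensity-weighted and reported in
(z, y, x) micrometres.

# The consensus statistic

Given per-sample descending-density orderings of the same region set,
a sequence is *order-conserved* if its regions appear in the same
relative order in every sample. `max_consensus()` finds the longest
such sequence by dynamic programming on the DAG of region pairs sorted
by sample-1 position — `O(k·n²)` — and `enumerate_sequences()` lists
all maximal ones by depth-first search with longest-path pruning. Both
are verified in the test suite against exhaustive subset enumeration
for n ≤ 7.

`permutation_null()` replays the statistic on independent uniform
permutations. For n = 47 regions and k = 3 samples (the scale of a
medium-region atlas grouping across a small cohort), 10,000 replicates
give
P(length ≥ 8) ≈ 0.027 and an α = 0.05 threshold length of 8:

```{r null, eval = FALSE}
nd <- permutation_null(n_regions = 47, k_samples = 3,
                       n_perm = 10000, alpha = 0.05, seed = 1)
nd$p_at[7:9]    # ~0.20, ~0.027, ~0.002
nd$threshold_length  # 8
```

The tail probability is the raw proportion of replicates at or above
the length — no continuity correction — and the threshold is the
smallest length whose tail falls strictly below α.

One subtlety found during testing: the intuitive claim that the
statistic is invariant under applying *the same permutation to every
sample's ranking positions* is false (counterexamples exist at n = 12).
What does hold, and what the tests assert, is invariance under
relabelling of region identities and under permuting the order of the
samples.

# Synthetic data: realism and limits

`make_toy_atlas()` builds an ellipsoidal "brain" (background label 0
outside) partitioned into layered boxes or nested shells, with exact
voxel-count volumes. `make_tau_volume()` plants Gaussian blobs on a
two-level background (brain ≈ 20, outside ≈ 2, additive Gaussian
noise) and records a ground-truth mask as the 2σ ball of each blob.

Two constraints keep the synthetic scenes inside the regime the
published recipe assumes:

* **Blob mass must stay a small fraction of total image intensity.**
  The mask threshold is 1.5× the *global* mean; in real whole brains
  spots occupy a negligible volume fraction, so they barely move that
  mean. In a 64³ scene, planting too many or too bright blobs raises
  the threshold to within ~2 noise SD of the brain background, and the
  10 erosions then amplify random sub-threshold holes into cavities
  that can destroy the mask. Scenes in the tests and analysis scripts
  use ≤ 20 calibrated blobs so the threshold stays ≥ 4 SD below the
  brain background.
* **Blobs must sit deep inside the mask.** Ten erosions remove a
  10-voxel rim; planted centres are kept within 0.55 of the
  normalised ellipsoid radius.

**Amplitude calibration.** For the detection F-score to be meaningful,
a planted blob's suprathreshold footprint should match its 2σ truth
ball. For a Gaussian blob of scale σ_b filtered by a Gaussian of scale
σ_g, the filtered peak is the raw amplitude times
`(σ_b²/(σ_b²+σ_g²))^{3/2}`, and the footprint radius at threshold T is
`σ_c · sqrt(2 ln(peak/T))` with σ_c² = σ_b² + σ_g². Setting the
filtered peak to `e² · T` makes that radius ≈ 2σ_b.
`calibrate_spot_amplitude()` solves this analytically after measuring
T on a spotless pre-pass; the resulting F on the standard 20-blob
scene is ≈ 0.99. The approximation needs σ_b large enough that the
blob is well resolved (σ_b ≥ ~1.5 voxels) and small enough that the
83 µm mean filter removes little of the blob itself; the defaults use
σ_b = 1.6.

Limits: the backgrounds are piecewise-constant (no vasculature,
autofluorescence gradients, or stripe artefacts), noise is white
Gaussian rather than mixed Poisson–Gaussian, and blobs are isotropic —
so synthetic F-scores are upper bounds on real-data performance.

# Numerical choices

* **Separable filtering** with reflective (symmetric) boundaries; the
  mean kernel extent 83 µm / 8.3 µm = 10 is forced odd (11) so the
  filter is centred. Verified against dense brute-force convolution.
* **Component labelling** is delegated to `igraph` components over a
  shifted-index adjacency; verified against a BFS flood-fill oracle on
  200 random grids under both connectivities.
* **Erosion** uses the 6-connected cross element, with the array
  border treated as background (one layer peeled per pass).
* **Resampling** is trilinear; resampling at the native pitch is an
  exact identity.
* **Ranking ties** in regional density are broken by region id, with a
  warning and an infinitesimal perturbation of stored densities so the
  strictly-decreasing invariant of `ranking_set` holds.
* **Graph layout** (`layout_graph()`) seeds R's RNG and uses igraph's
  Fruchterman–Reingold; identical seeds give identical layouts.
* **I/O**: NRRD (raw little-endian, minimal NRRD0004 subset) is the
  lossless float format; TIFF is restricted to 16-bit unsigned
  integers because the available TIFF writer clamps floating point to
  [0, 1].

# Problem sizes and runtime

64³ end-to-end extraction runs in seconds; the full 10,000-replicate
null at n = 47, k = 3 takes ~3 s. The DP is quadratic in the number of
ranked regions, so hundreds of regions remain interactive.

# Limitations

* The atlas is a toy geometry; real CCF label volumes can be supplied
  via `read_atlas()` but registration is out of scope.
* Spot assignment uses the centroid voxel only; spots straddling a
  region boundary are attributed to a single region.
* The permutation null assumes exchangeable, independent rankings;
  shared segmentation artefacts across samples would inflate apparent
  consensus.
* The consensus graph records adjacency within maximal sequences only;
  sub-maximal but biologically meaningful orderings below the
  significance threshold are not represented.
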