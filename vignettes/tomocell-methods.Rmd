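---
title: "Quantifying mesoscale neuroanatomy in microCT volumes with tomocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesoscale neuroanatomy in microCT volumes with tomocell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Synchrotron X-ray microtomography (microCT) images millimetre-scale blocks
of stained, plastic-embedded brain tissue at roughly micron, isotropic
resolution without sectioning. In such volumes cell bodies appear as
bright, quasi-spherical blobs (interiors are typically ~4.5 dB brighter
than their immediate surround), blood vessels as brighter tubes, and
myelinated axons as thin bright cylinders, all on a background with slow
brightness drift. `tomocell` turns such volumes into quantitative
mesoscale maps: per-voxel class probabilities, cell centroids and sizes,
vessel and axon segmentations, densities and distance statistics.

This vignette documents the models and algorithms, the parameters that
matter, the numerical choices, and what the synthetic phantom used for
validation does and does not emulate.

## Pipeline overview

1. **Voxel classification** (`compute_features()`, `train_classifier()`,
   `predict_probabilities()`): multi-scale image features feed a random
   forest that returns per-voxel probabilities
   $P = \{P_{cell}, P_{vessel}, P_{bg}\}$ summing to 1.
2. **Vessel / axon segmentation** (`segment_vessels()`,
   `segment_axons()`): threshold the class probability map, apply ball
   morphology, label connected components, drop small ones.
3. **Cell detection** (`detect_cells()`): greedy matching pursuit —
   correlate $P_{cell}$ with a unit-sum spherical template by FFT,
   repeatedly accept the global correlation maximum as a centroid and
   zero the map around it, until the best remaining correlation falls
   below a stopping threshold.
4. **Hyperparameter search** (`grid_search()`): score detections by
   object-level $f_1$ (cells) or voxelwise $f_2$ (vessels) against a
   densely annotated volume, over a grid of template size and threshold.
5. **Spatial statistics** (`estimate_density()`,
   `cell_to_cell_distances()`, `cell_to_vessel_distances()`): kNN
   density estimation over a 3D grid plus nearest-neighbour distance
   distributions.

`run_pipeline()` chains these stages from one YAML/list configuration;
`inst/scripts/tomocell-cli.R` exposes them as shell subcommands.

## Voxel classification

Absolute intensity drifts across a millimetre-scale sample, so raw
intensity is **excluded** from the default feature set (it can be
re-enabled with `include_intensity = TRUE` for flat-fielded data). At
each Gaussian scale $\sigma$ the features are:

* gradient-of-Gaussian magnitude — edge strength;
* difference of Gaussians, $G_\sigma - G_{1.6\sigma}$ — blob response
  (1.6 is the standard scale-space ratio);
* the three eigenvalues (sorted) of the structure tensor, i.e. the
  outer product of Gaussian gradients smoothed at $2\sigma$ — these
  separate blob-like (three comparable eigenvalues) from tube-like (two
  dominant) and plate-like (one dominant) neighbourhoods, which is what
  distinguishes somata from vessels independently of brightness.

Default scales are 0.65, 1.3, 2.6 and 5.2 um (1–8 voxels at the default
0.65 um voxel size), spanning nucleus-edge to soma scale: 20 features.
All filtering is separable with reflected boundaries, implemented in
compiled code because the installed R image stacks operate slicewise
(2D) only. The classifier is a probability random forest
(`ranger`, 100 trees by default, seed required; class order fixed as
cell, vessel, background, axon so model files are portable). Models are
saved with an embedded feature manifest and refuse to predict against
mismatched features.

## Cell detection as matching pursuit

The spherical template of diameter $d$ voxels contains every voxel
offset within Euclidean distance $d/2$ of the center, weighted $1/n$:
its correlation with $P_{cell}$ at a voxel is the *mean cell
probability over the ball*, so scores live in $[0, 1]$ and the stopping
threshold is interpretable as a mean probability. The correlation is
computed once by 3D FFT (zero-padded, so boundaries see zeros); after
each accepted detection the probability map is zeroed over a ball
(default: the template's own diameter) and the correlation is updated
by exact local subtraction — bitwise-equivalent to recomputing the full
correlation, which the test suite verifies against a brute-force oracle.

Numerical choices:

* **Ties** at the maximum (within $10^{-9}$, which also absorbs FFT
  round-off) are broken by the smallest $(z, y, x)$ index —
  deterministic and order-independent.
* **Stopping**: `stop_threshold` default 0.47 and template diameter 18
  voxels (11.7 um) reflect the operating point found by grid search on
  densely annotated cortex; both are exposed. With templates smaller
  than a cell the correlation has a plateau of exact ties and the
  reported centroid is the plateau's lexicographic corner — template
  size should be chosen near the true soma diameter.
* **Edges**: detections within a template radius of a volume face are
  flagged `edge`; evaluation can exclude them, and block merging
  recomputes the flag globally.
* Greedy scores are provably non-increasing (zeroing only removes
  probability mass), which the suite asserts.

Cell size is estimated per centroid by growing the template one voxel
at a time and taking the diameter just before the largest forward drop
in correlation $c(d) - c(d+1)$: while the template stays inscribed in
the cell the correlation is flat, and it decays sharply once the
template outgrows the body. A flat profile (no drop above $10^{-12}$)
returns `d_min` with `degenerate = TRUE`; windows truncated by the
volume boundary are renormalized and flagged.

## Vessel and axon segmentation

Vessels: binarize $P_{vessel} \ge$ threshold (default 0.47), dilate
with a Euclidean ball (default radius 8 voxels, the tuned value),
label 26-connected components, remove components below
`min_component_vox`, renumber by decreasing size. Axons: keep
$P_{axon} \ge 0.3$ — thresholding *discards* sub-threshold voxels; the
opposite reading would segment background — then apply a morphological
opening with a ball of radius 4 voxels ("size 4" is read as a radius;
the alternative, a diameter, would erase the thin axons the recipe is
for), then label components. Morphology is exact Euclidean-ball
morphology built on a squared distance transform, so dilation by
radius $r$ is precisely the set of voxels within distance $r$.
Connectivity (6/18/26) is configurable; 26 is the default for 3D
object continuity. `vascular_fraction()` is the nonzero-voxel
percentage of a mask.

## kNN density estimation

For detected centroids $V$ ($N$ cells), the score at a grid-bin center
$v$ is $k / (N \rho_k(v, V))$ with $\rho_k$ the **squared** distance to
the $k$-th nearest centroid; scores are normalized into a probability
mass function $p$ over bins and converted to densities
$p_d(v) = p(v) N / \mathrm{Vol} \times 10^9$ cells/mm^3 (bin volume
$\mathrm{Vol}$ in um^3). Two identities hold exactly by construction
and are asserted in the tests: $\sum_v p(v) = 1$ and
$\sum_v p_d(v) \mathrm{Vol} \times 10^{-9} = N$.

Choices and caveats:

* $k = 5$ by default; $k$ is the estimator's only smoothing parameter
  and is documented as free — small $k$ is noisier, large $k$ blurs
  layer boundaries.
* Bin volume defaults to 8.44 um^3 (side ~2.04 um, about one cell per
  bin); the side length is the configurable primitive.
* $\rho_k$ is clamped below at (bin side / 2)^2 so a bin center
  coinciding with a centroid cannot absorb all mass.
* Because $\rho_k$ enters as a squared distance (not cubed), relative
  bin mass scales sublinearly with local point density
  (about $n^{2/3}$); the normalized field is a sharp, bounded contrast
  map of cell density rather than an unbiased 3D density estimate, and
  the test suite checks the estimator's own scaling. For uniform
  points the grid-mean of $p_d$ still recovers the true density, which
  is tested at 10^4 points within 15%.

Distance statistics are centroid-to-centroid (nearest neighbour) and
centroid-to-nearest-vessel-voxel via the exact distance transform,
with centroids snapped to voxel centers; sub-voxel surface distances
are out of scope.

## Evaluation machinery

* $f_\beta = (1 + \beta^2) p r / (\beta^2 p + r)$ with the convention
  0 when the denominator vanishes; $\beta = 1$ for cells, $\beta = 2$
  (recall-weighted) for vessel voxels, where it tracks visual quality
  better.
* **Centroid matching** is globally-closest-first: repeatedly accept
  the closest remaining (detected, truth) pair within 10 um and remove
  both. This is deterministic, invariant to input order, and each
  centroid is used at most once. Centroids within an edge margin of
  the volume boundary can be dropped from both sets, since boundary
  objects are ambiguous for human and machine alike.
* **SNR** per sampled cell is $20 \log_{10}(s_i / n_i)$ from an
  interior marker and a marker just outside the membrane.
* **Effective resolution**: average the 2D power spectra of a series
  of transverse (xy) and vertical (xz) planes from a tissue region and
  a background region, radially average both, fit a second-order
  polynomial to the log signal spectrum (over 0.05 1/um to Nyquist by
  default; the low-frequency end is excluded because it is dominated
  by object structure), and report the half-period $1/(2f_c)$ at the
  lowest frequency where the fitted signal power falls to five times
  the noise power — the Rose detectability criterion. The crossing is
  located by linear interpolation between frequency bins.

## Block-wise processing

Volumes larger than memory are tiled by disjoint cores
(`plan_blocks()`), each read with a pad of context (at least the
template diameter for detection; the default pad is twice it). Each
padded block is processed independently; `merge_detections()` then
walks blocks in lexicographic order, keeps a detection only if its
centroid lies in its own block's core (a deterministic ownership rule),
and drops any detection within 10 um of one already accepted. With
sufficient padding the merged result equals the unblocked run exactly,
which is asserted on phantoms.

## The synthetic phantom

`generate_phantom()` emulates the statistical appearance of stained
cortex in microCT — the features the algorithms actually exploit:

* non-overlapping quasi-spherical cells, diameters
  $\mathcal{N}(12, 2^2)$ um truncated at 6 um, optional brighter
  nucleus at 0.4 x diameter;
* tortuous vessels (swept spheres along a drifting random walk, radii
  2–5 um) and thin axon cylinders (radius 1 um), both brighter than
  cells;
* a smooth multiplicative brightness field (Gaussian-filtered noise,
  default amplitude 8%, correlation length 20 um) emulating
  reconstruction-scale brightness drift;
* additive Gaussian noise (SD 0.04 on the [0, 1] scale);
* cell/background contrast calibrated so the *measured* interior/
  exterior SNR (same marker protocol as `compute_snr()`) hits 4.6 dB
  within 0.3 dB — the contrast level reported for stained neocortex.
  Calibration iterates on the cell intensity gain, not the noise
  scale: the SNR protocol is a ratio of regional means, which
  zero-mean noise does not move.

Everything is a pure function of the `phantom_spec()` arguments and the
seed. Phantoms at the
package's test scale are 128^3 voxels (83 um cubes at 0.65 um voxels,
comparable to typical densely annotated subvolumes) with 30 cells;
blocking tests use 120^3. What the phantom does **not** emulate:
reconstruction physics (ring artifacts, beam hardening, phase-contrast
fringes), anisotropic or lognormal cell shapes, touching cells, and
vessel radius variation along a tube. Passing the phantom suite
therefore demonstrates algorithmic correctness and calibrated-contrast
performance, not robustness to scanner artifacts; on real data the
classifier must be retrained from manual scribbles.

With that caveat, the end-to-end behaviour mirrors the intended use:
train on one annotated phantom, grid-search the detector, apply to a
held-out phantom. The tuned operating point lands on template 18 /
threshold 0.47 and held-out precision/recall clear 0.85/0.80 in the
acceptance tests; `scripts/acceptance.R` recomputes these numbers from
scratch.

## Degenerate inputs and errors

Constant volumes map to 0 under `to_uint8()` (no contrast to stretch);
probability maps must lie in [0, 1] and sum to 1 within 1e-6;
single-class annotations, empty vessel masks, $k > N$, empty distance
lists and resolution bands without a Rose crossing all raise immediate
errors rather than returning silent defaults. TIFF stacks with
inconsistent slice shapes and centroid CSVs with non-numeric
coordinates are rejected at read time. HDF5 volumes are not read
directly; convert to multi-page TIFF first.
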