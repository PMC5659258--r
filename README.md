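# tomocell

Quantifying mesoscale neuroanatomy — cell bodies, blood vessels,
myelinated axons — in 3D X-ray microtomography (microCT) image volumes.

Synchrotron microCT images millimetre-scale blocks of stained,
plastic-embedded brain tissue at ~1 um isotropic resolution without
sectioning. Cell somata appear as bright quasi-spherical blobs (~4.5 dB
above their surround), vessels as brighter tubes, myelinated axons as
thin bright cylinders. `tomocell` is an R package for anatomists and
image-analysis researchers who want to turn such volumes into
quantitative maps: it classifies voxels, detects and sizes cells,
segments vessels and axons, and computes densities and spatial
statistics, with an evaluation suite and a synthetic phantom generator
so every step can be validated without beamline data.

## The methods in brief

* **Voxel classification.** Multi-scale features (gradient-of-Gaussian
  magnitude, difference of Gaussians, structure-tensor eigenvalues; raw
  intensity excluded by default because brightness drifts across large
  samples) feed a random forest that returns per-voxel probabilities
  *P* = {*P*<sub>cell</sub>, *P*<sub>vessel</sub>, *P*<sub>bg</sub>},
  summing to 1.
* **Cell detection by greedy matching pursuit.** The cell probability
  map is correlated (3D FFT) with a unit-sum spherical template of
  diameter ≈ one soma (default 18 voxels = 11.7 um at 0.65 um voxels);
  the global maximum becomes the next centroid, the map is zeroed over
  a ball around it, and the loop repeats until the best remaining
  correlation — a mean probability in [0, 1] — drops below a stopping
  threshold (default 0.47). Growing the template at a fixed centroid
  until the correlation drops sharply estimates each cell's diameter.
* **Vessel / axon segmentation.** Threshold the class probability map,
  apply exact Euclidean-ball morphology (dilation for vessels; opening
  for axons), label 26-connected components, drop small ones.
* **Spatial statistics.** kNN density estimation on a 3D grid:
  score ∝ *k* / (*N* · ρ<sub>k</sub>(v)), with ρ<sub>k</sub> the squared
  distance to the *k*-th nearest centroid, normalized to a pmf *p* and
  converted to densities *p*<sub>d</sub> = *p* · *N* / Vol × 10⁹
  cells/mm³; plus cell-to-cell and cell-to-vessel distance
  distributions.
* **Evaluation.** f<sub>β</sub> scores, globally-closest-first centroid
  matching at 10 um, per-cell SNR in dB, hyperparameter grid search,
  and effective-resolution estimation from radially averaged power
  spectra via the Rose criterion (signal = 5 × noise; resolution =
  half-period 1/(2f)).
* **Scale.** Volumes larger than memory are processed in padded blocks
  whose merged detections provably equal the unblocked run.

## Worked example

Generate a synthetic cortex phantom, train the classifier on sparse
annotations, detect cells, and evaluate against the known ground truth:

```r
library(tomocell)

ph  <- generate_phantom(phantom_spec(seed = 1))      # 128^3, 30 cells, 4.6 dB
ann <- sample_annotations(ph, n_per_class = 2000, seed = 1)
clf <- train_classifier(compute_features(ph$intensity), ann,
                        n_trees = 100, seed = 1)
pm  <- predict_probabilities(clf, ph$intensity)

det <- detect_cells(pm, detection_params(cell_size_vox = 18,
                                         stop_threshold = 0.47))
det <- estimate_cell_sizes(pm, det)
match_centroids(det, as.matrix(ph$cells[, c("x_um", "y_um", "z_um")]),
                max_dist_um = 10)
```

```
<match_result> 28 matches of 29 detected / 30 truth: (p, r) = (0.966, 0.933)
```

At the default operating point (template 18 voxels, threshold 0.47) the
detector recovers 28 of the 30 phantom cells with one false positive —
precision 0.966, recall 0.933 at the 10 um matching radius. Detected
centroids are reported in um with per-cell correlation scores and
diameter estimates (here averaging 12.8 um against a true mean of
12 um); `write_centroids()` saves them as CSV. Continuing,

```r
seg <- segment_vessels(pm, threshold = 0.47, dilation_radius_vox = 2,
                       min_component_vox = 200)
vascular_fraction(seg)
#> [1] 2.753878
mean(cell_to_vessel_distances(det, seg))
#> [1] 17.91335
```

gives the vessel volume fraction (percent) and the mean distance from
each cell to its nearest vessel voxel in um.

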