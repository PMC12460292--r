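---
title: "Estimating tree disc volumes from TLS point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tree disc volumes from TLS point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disctls)
```

## The problem

Terrestrial laser scanning (TLS) can measure the volume of a tree stem disc —
a ~5 cm cross-sectional slice cut from a trunk — without touching it, by
reconstructing a closed surface from the scanned point cloud and integrating
the enclosed volume. The validation unit is the disc because its true volume
can be measured independently by water displacement. Two obstacles make this
non-trivial:

1. **The bottom face is never scanned.** A disc rests on the ground during
   scanning, so its base is occluded; a surface reconstruction run on the raw
   cloud has a large hole at the ground contact and no defined volume.
2. **The reported volume must come from a watertight surface.** The
   divergence-theorem volume is only meaningful on a closed, consistently
   oriented triangle mesh.

`disctls` implements the full chain — bottom repair, normal estimation with
global orientation, Poisson-type surface reconstruction, divergence-theorem
volume — plus the measurement-agreement statistics used to validate TLS
volumes against water-displacement references, and a synthetic scan generator
with analytically known volume that serves as the package's test substrate.

## Bottom repair by planar projection

`fill_bottom()` duplicates every point of the cloud onto the horizontal plane
through the global minimum Z (`detect_lowest()`), keeping X and Y unchanged,
and merges the projection with the original cloud. The result is a dense
filled base plane that gives the reconstruction a coherent boundary at the
ground contact.

Design points:

* **All points are projected, not just the rim.** The base therefore has
  roughly the density of the whole cloud; the reconstruction's density
  weighting (below) makes this harmless, and a dense base plane yields a
  much more stable indicator function than a sparse rim ring.
* **Duplicate policy.** A literal union duplicates any point already lying
  at the minimum Z. By default projected points that coincide exactly with
  an original point (`dedupe_tol = 0`) are dropped; `dedupe_tol = NULL`
  keeps the literal both-copies union, and positive tolerances drop
  projected points within that distance of an original. Coincident point
  pairs destabilise neighbourhood operations, which is why exact dropping is
  the default.
* **The fill plane is horizontal.** No plane is fitted to the ground; the
  transform sets Z to a constant. Tilted discs are the user's (or the
  generator's) responsibility.

## Normal estimation and orientation

`estimate_normals()` fits, per point, the quadratic patch
$z = ax^2 + by^2 + cxy + dx + ey + f$ by least squares over the point and its
$k$ nearest neighbours (default $k = 6$, making the 6-unknown fit use 7
points), in a local PCA frame whose least-variance axis is the local z — a
height-function model is invalid for steep surfaces in the global frame. The
surface normal is $(-d, -e, 1)$ at the origin of the frame, normalised and
rotated back. Degenerate neighbourhoods (rank-deficient designs) fall back to
the covariance (PCA) normal and are flagged. A plain covariance path
(`method = "covariance"`, the classic $k = 8$ variant) is also available.

With exactly $k = 6$ the fit interpolates and is noise-sensitive: under 1 mm
ranging noise the default produces normals tens of degrees off, which costs
about one percentage point of end-to-end volume accuracy relative to
$k = 16$. The default follows the six-neighbour convention; `k` is the one
knob worth raising on noisy scans, and the package's own accuracy experiments
(the bark sweep below) use $k = 16$.

Sign consistency is enforced by `orient_normals_mst()`: a minimum spanning
tree of the k-nearest-neighbour graph with edge weights
$1 - |n_i \cdot n_j|$, breadth-first sign propagation from the highest point
of each component. One subtlety is genuinely unsolvable by propagation: at
the 90° crease between the disc wall and its filled base, adjacent normals
are orthogonal and carry no sign information, so a whole region (typically
the filled base) can come out inverted while being internally consistent. We
therefore apply the outward convention *regionally* rather than once
globally: a point is flipped when its neighbourhood-averaged outwardness
score $(p - c)\cdot n$ (with $c$ the cloud centroid) is negative. For solids
that are star-shaped about their centroid — any stem disc, including rough
bark — this rule is exact; deeply concave objects are outside the package's
scope and are the known limitation of this step.

## Surface reconstruction

`reconstruct_surface()` follows the indicator-function approach: the
oriented normals are splatted onto a regular grid as a vector field $V$ and
the Poisson equation $\Delta\chi = \nabla\cdot V$ is solved spectrally
(3-D FFT), giving a smoothed indicator whose zero level set is the surface.
Marching tetrahedra (six tetrahedra per grid cube, a decomposition whose
face diagonals match between neighbouring cubes) extract a closed,
consistently oriented triangle mesh wherever the level set stays inside the
grid. Numerical choices that matter:

* **Density weighting.** Each point's normal is weighted by its local
  surface area (squared mean distance to its 8 nearest neighbours, capped at
  9× the median). Without this the filled base — about twice as dense as
  the faces — forms a dipole layer of different strength and the far field
  no longer settles on a single outside level.
* **Grid.** `octree_depth` $d$ divides the longest bounding-box axis into
  $2^d$ voxels (default 8 ≈ 1–2 mm at disc scale, the order of the
  scanner's ranging error; the minimum accepted depth is 4). A margin of
  12% of the longest axis is kept empty on every side: the spectral solve
  is periodic and the indicator's far field must decay below the isovalue
  before it wraps — for thin discs the z-axis wrap is the binding
  constraint.
* **Smoothing.** The source is low-passed with a Gaussian of width
  max(1.5 voxels, the median point spacing), bridging the gaps between
  discrete samples.
* **Isovalue.** The *median* of $\chi$ over the sample points. The mean is
  skewed by crease samples, where the indicator jump is attenuated, and that
  skew shifts the whole level set outward by a fraction of a voxel — about
  +2% volume on a disc. The median is insensitive to it.
* **Cleanup.** Optionally trim the lowest-support vertices and re-close the
  boundary loops (`density_trim_quantile`, default 0: a full-grid spectral
  solve does not produce the unsupported bubbles that octree solvers are
  trimmed for), keep the largest connected component (removes small ringing
  bubbles), drop zero-area faces, and flip all windings once if the signed
  volume is negative (the flip is recorded in the report).

The operation **fails, with open-edge diagnostics, if the cleaned mesh is
not watertight** — a volume is never computed from an open surface. This is
not a theoretical case: running the reconstruction on an occluded disc
*without* `fill_bottom()` leaves the indicator open at the base, the level
set runs into the grid boundary, and the result is rejected. That behaviour
is the package's demonstration of why the bottom repair exists; batch runs
(`run_pipeline()`) exclude such discs and itemise the reason, mirroring how
defective samples are excluded in field campaigns.

## Volume

`divergence_volume()` computes
$V = \tfrac13 \sum_i A_i (p_i \cdot n_i)$
over the faces of a watertight mesh, with per-face areas $A_i$, centroids
$p_i$ and unit normals $n_i$ taken from the winding order. For a closed
surface this equals the signed-tetrahedron sum $\sum \det(v_0,v_1,v_2)/6$
algebraically, is independent of the coordinate origin, and scales with the
cube of the length unit; the test suite asserts all three properties. The
public value is the absolute value after a single global orientation check;
the raw signed value and the per-face decomposition
(`per_face_contributions()`) are exposed for audit. Volumes are reported in
cm³; geometry is carried in the input unit throughout and converted only at
this reporting boundary.

## The synthetic disc generator

No scan data ship with the package; `generate_disc()` produces the study
conditions instead:

* **Geometry.** An elliptical prism (defaults: circular, r = 15 cm,
  height 5 cm — discs are cut to 5 ± 0.5 cm) with radial bark roughness
  $r(\theta) = r_e(\theta) + \delta(\theta)$, where $\delta$ is a smooth
  periodic Gaussian field (squared-exponential spectrum, default 15°
  correlation) with standard deviation `bark_amplitude`. Ridges run
  vertically, as longitudinal bark fissures do, so the true volume is the
  polygon area of the realized profile times the height
  (`true_profile_volume()`, 3600-gon; doubling the resolution moves the
  value by well under 0.01%).
* **Acquisition.** Points are sampled on the wall and faces at
  `density` ≥ 1000 points/dm² (the scanning floor), wall azimuths are
  filtered by a three-station visibility model (stations at 45°, 135°, 270°
  — northeast, southeast, west — each covering ±100°, so the default layout
  sees the full wall, as multi-station layouts are designed to), isotropic
  Gaussian noise of 0.1 cm (the ±1 mm ranging-error class) is added, the
  occluded bottom face is omitted, and the cloud is cropped at the ground
  plane z = 0 — the programmatic analog of separating the disc from the
  ground returns. Without that crop the minimum-Z plane would sit at the
  extreme of ~10⁴ unbounded Gaussian noise draws, ~2.5 mm below the true
  base, an artifact of synthetic noise rather than of the method.
* **Bark-sensor coupling.** Geometric roughness alone does not degrade the
  pipeline: at 1000 points/dm² the centimetre-scale ridges are fully
  resolved. What degrades real scans of rough bark is the sensor physics,
  and the generator models the three mechanisms: diffuse scattering on
  steep ridge flanks inflates the ranging noise (multiplier $1 + 4s$ with
  $s$ the local profile slope), deep grooves shadow the beam (dropout
  probability growing with slope and relative groove depth, capped at 0.8),
  and multiple reflections inside a groove lengthen the measured range,
  displacing affected returns inward by a cavity-scale amount. The
  coefficients are illustrative — no quantitative per-species roughness
  measurements exist to calibrate against — and were chosen once so that a
  1 cm amplitude produces sub-percent-to-percent extra error with an
  underestimation tendency, the scale and sign reported for rough-bark
  species. A smooth disc is entirely unaffected.

What the generator does **not** emulate: beam divergence and footprint,
multiple returns, registration error between stations, moisture and
reflectance variation of the cut faces, and non-prismatic disc shapes (bark
that differs between top and bottom). Passing the synthetic suite therefore
shows that the geometry chain is correct and that the statistics behave as
designed under controlled violations; it does not certify field accuracy.

`generate_paired_dataset()` complements this with a pure-statistics
generator: per-species reference volumes (defaults mirror a four-species
campaign, n = 69/25/12/17, species means 146.78/205.99/148.62/236.68 cm³,
spread 40% of the mean), three replicate measurements per disc
(`replicate_sd` = 2 cm³ around the truth), and TLS estimates = truth + bias
+ noise (default noise 25 cm³, the scale of the observed spread of
differences in a campaign of this kind; bias 0, injected explicitly in
experiments).

## Agreement statistics

`build_report()` assembles, overall and per species (species with a single
sample are skipped with a warning):

* R², RMSE, RE, Bias and rRMSE, with y = estimated, x = observed. rRMSE is
  RMSE divided by the mean *observed* volume × 100 — the convention under
  which published per-species values reproduce exactly from the printed
  RMSE and species means.
* Bland–Altman mean difference, sd of differences (sample, n−1 denominator)
  and 95% limits of agreement $\bar d \pm 1.96s$. The difference direction
  defaults to estimated − observed, under which a negative mean difference
  reads as TLS underestimating the reference; the convention is recorded in
  the report and configurable, since published figure captions are not
  always consistent about it.
* Lin's concordance correlation $\rho_c = 2\rho\sigma_x\sigma_y /
  (\sigma_x^2 + \sigma_y^2 + (\mu_x-\mu_y)^2)$ with population (n)
  variance denominators by default — the convention under which the
  canonical estimator is defined; sample denominators are available.
* Gauge repeatability (GRR%): a one-factor (parts) random-effects
  decomposition of the replicate reference measurements — the only
  replicated measurements in the design — with mean-square weights for
  unbalanced layouts, negative components truncated at zero, and no
  operator factor. Note the moment estimator's finite-sample upward bias
  with few parts (about +2 points at 10 parts × 3 repeats).
* Kruskal–Wallis H across species on the error variable (the paired
  difference per the declared direction), with mid-ranks and the tie
  correction on by default, and all pairwise Mann–Whitney tests (exact null
  distribution when $n_1+n_2 \le 12$ without ties, otherwise the normal
  approximation with tie-adjusted variance and continuity correction). Raw
  p values are primary; Holm-adjusted values are reported alongside. α =
  0.05 throughout.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run: the end-to-end accuracy check
on ten discs at the default depth 8; the bark sweep over amplitudes
{0, 0.2, 0.5, 1} cm × ten seeds at depth 7 with $k = 16$ normals (paired
seeds across amplitudes, so the comparison is common-random-number); 2000
null replicates for the Kruskal–Wallis type-I rate; and 123-sample paired
datasets for bias recovery and the species-bias power check. These sizes
give Monte-Carlo errors comfortably below the asserted tolerances while
keeping a full run in minutes on one core.

## Known limitations

* The outward-orientation rule assumes the solid is star-shaped about its
  centroid; deeply concave shapes can be mis-oriented regionally.
* The spectral solver works on a full regular grid: memory grows with the
  bounding-box volume, so very anisotropic or very large scenes should be
  cropped first. `octree_depth` above 8 is rarely affordable.
* Volumes on open meshes are refused rather than repaired; aggressive hole
  filling is limited to loops created by the optional density trim.
* The agreement suite treats replicate reference measurements as the only
  repeatability information; operator and setup effects are not separable
  from this design.
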