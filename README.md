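# disctls

Volume estimation for tree stem discs from terrestrial laser scanning (TLS)
point clouds, with the statistics to validate those volumes against
water-displacement reference measurements.

A stem disc — a ~5 cm cross-sectional slice cut from a trunk — is the natural
unit for checking how well TLS measures wood volume, because its true volume
can be measured by submersion. Two things stand between a raw scan and a
volume: the disc rests on the ground, so its bottom face is missing from the
cloud, and a volume is only defined on a *watertight* surface. `disctls`
implements the full chain for forest-mensuration and remote-sensing
researchers:

1. **Bottom repair** (`fill_bottom`): every point is duplicated onto the
   plane through the global minimum Z, `z_min = min_i z_i`, keeping X/Y
   unchanged — `P_complete = P_original ∪ {(x_i, y_i, z_min)}` — which gives
   the reconstruction a coherent base where the ground occluded the scan.
2. **Normals** (`estimate_normals`, `orient_normals_mst`): per point, a
   least-squares quadratic patch `z = ax² + by² + cxy + dx + ey + f` over
   the k nearest neighbours in a local PCA frame; the normal is
   `(-d, -e, 1)` normalised. Signs are made globally consistent by minimum
   spanning tree propagation plus an outward (away-from-centroid) rule.
3. **Surface reconstruction** (`reconstruct_surface`): the oriented normals
   become a vector field V on a regular grid and the Poisson equation
   `Δχ = ∇·V` is solved by FFT; marching tetrahedra extract the isosurface
   as a closed triangle mesh. Non-watertight results are refused with
   diagnostics, never silently integrated.
4. **Volume** (`divergence_volume`): the divergence theorem,
   `V = (1/3) Σ A_i (p_i · n_i)` over mesh faces, reported in cm³, with a
   per-face audit trail.
5. **Validation statistics** (`build_report`): R², RMSE, RE, Bias, rRMSE,
   Bland–Altman limits of agreement `d̄ ± 1.96s`, Lin's concordance
   correlation, gauge repeatability (GRR%) from replicate reference
   measurements, Kruskal–Wallis across species and pairwise Mann–Whitney
   tests with Holm adjustment.
6. **Synthetic scans** (`generate_disc`, `generate_paired_dataset`): discs
   with analytically known volume — elliptical profile, vertical-ridge bark
   roughness with sensor coupling (scatter noise, shadow dropouts,
   multi-path), three-station visibility, bottom occlusion, ranging noise —
   so every stage is testable without field data.

## Worked example

Simulate a scanned disc with known volume, run the pipeline, and compare:

```r
library(disctls)

disc <- generate_disc(disc_spec(radius_a = 15, height = 5,
                                density = 1000, seed = 7))
disc
#> synthetic_disc: 11741 points, true volume 3534.29 cm3 (seed 7)

filled <- fill_bottom(disc$cloud)
filled
#> filled_cloud: 11741 original + 11740 projected = 23481 points (z_min = 0.000400872 cm)

oriented <- orient_normals_mst(estimate_normals(filled$complete, k = 16))
mesh <- reconstruct_surface(oriented)
vol <- divergence_volume(mesh)
sprintf("estimated volume: %.1f cm3 (truth %.1f, error %+.2f%%)",
        as.numeric(vol), disc$true_volume,
        100 * (as.numeric(vol) / disc$true_volume - 1))
#> "estimated volume: 3544.5 cm3 (truth 3534.3, error +0.29%)"
```

The disc is a true cylinder (π·15²·5 = 3534.29 cm³); the pipeline recovers
it to 0.3% despite the missing bottom, 1 mm ranging noise and the
three-station acquisition. Omitting `fill_bottom` makes `reconstruct_surface`
fail with an open-edge diagnostic — the motivating defect, caught rather
than integrated.

Validating a paired campaign (here simulated: four species, n = 123, zero
injected bias):

```r
samples <- generate_paired_dataset(seed = 1)
build_report(samples)
#> Agreement report (n = 123; diff = est_minus_obs, ccc variances = population)
#>   R^2 = 0.8885  RMSE = 25.21 cm3  RE = 0.02136  Bias = 0.2732 cm3  rRMSE = 13.96%
#>   Bland-Altman: mean diff = 0.2732, s = 25.31, LoA [-49.34, 49.89] cm3
#>   CCC = 0.9433  GRR = 0.07823%
#>   ...
#>   Kruskal-Wallis: H = 0.8784, p = 0.831
```

With no injected species bias the Kruskal–Wallis test is (correctly) silent;
injecting a per-species bias in `generate_paired_dataset` makes it fire —
the test suite measures both the type-I rate and this power.

A thin command-line wrapper over the same functions ships in
`inst/cli/disctls.R` (subcommands `simulate`, `fill`, `normals`,
`reconstruct`, `volume`, `validate`, `pipeline`), and `run_pipeline()`
drives the whole chain from a YAML or list config, excluding and itemising
discs that fail reconstruction.

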