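# cbctrec

Sparse-view cone-beam CT (CBCT) reconstruction in R. The package targets the
dose-reduction setting where a circular-trajectory CBCT scan is acquired
from very few view angles (tens instead of hundreds), so the linear system

    y = A x

(`x` voxel attenuation, `y` detector line integrals, `a_ij` the length of
ray `i` inside voxel `j`) is heavily underdetermined and plain algebraic
reconstruction is dominated by streak artifacts. It is written for
researchers in iterative CT reconstruction who want a complete, matrix-free,
reproducible reference implementation of the guided-image-filtering fusion
of SART with total p-variation (TpV) minimization, together with the
standard baselines it is compared against.

## What is implemented

* **Projector** — Siddon ray-driven forward projection `A x` and matched
  back projection `A^T y` for circular cone-beam geometries, compiled,
  never materializing `A`; exact chord lengths, adjoint by construction.
* **SART** — simultaneous algebraic reconstruction with per-view-angle
  update subsets, relaxation `lambda = 1` decaying by `lambda_red = 0.99`
  per pass, nonnegativity clamp.
* **TpV** — reconstruction under the isotropic `l_p` quasi-norm of the
  image gradient (`p = 0.9`), solved by alternating direction minimization:
  generalized p-shrinkage `s(t) = max(t - beta^(p-2) t^(p-1), 0)` on
  gradient magnitudes, an FFT-diagonalized linearized x-subproblem, exact
  projection of the data residual onto `||e||^2 <= eps`, and multiplier
  ascent.
* **Baselines** — SART-TV (`lambda_TV = 15`) and ASD-POCS
  (`alpha = 0.002`), both as SART passes alternating with backtracked
  steepest descent on smoothed TV.
* **TpV-GIF** — the headline method: a TpV reconstruction serves as the
  initial guidance image; each of `N` outer iterations runs one SART pass,
  blends the guidance `I_guide = I_init (N-n)/N + f_sart n/N`, and
  edge-preserving-filters the SART result under that guidance (guided image
  filter, window radius 4, regularization 0.0016, slice by slice).
* **Phantom + simulation** — parametric ellipsoid phantoms (built-in 3D
  Shepp-Logan-style head), Siddon-simulated projections, optional seeded
  Poisson transmission noise.
* **Evaluation + IO** — RMSE / PSNR / SSIM, profile curves, difference
  maps; MetaImage MHD/RAW and NIfTI volumes, multi-page float TIFF
  projection stacks with YAML geometry sidecars, YAML run configs; an
  end-to-end comparison harness and a small CLI
  (`inst/cli/cbctrec.R`: `simulate`, `reconstruct`, `evaluate`, `compare`).

## Worked example

Simulate a 32-view scan of the built-in 64^3 head phantom at the clinical
distances (source-detector 1040 mm, source-origin 570 mm) and reconstruct
it with the fused method:

```r
library(cbctrec)

geom <- cone_beam_geometry(1040, 570, n_views = 32,
                           detector_shape = c(128, 128),
                           detector_pixel = c(1.6272, 1.6272))
grid <- volume_grid(c(64, 64, 64), c(1, 1, 1))
sim  <- simulate_projections(simulation_config(grid, geom))

fit <- ct_reconstruct(sim$projections, grid, method = "tpv-gif")
print(fit)
#> CBCT reconstruction (tpv-gif)
#>   volume: 64 x 64 x 64 voxels, values in [0, 1.146]
#>   views: 32, detector 128 x 128
#>   runtime: 180.2 s

metrics_report(fit$volume, sim$ground_truth)
#> RMSE 0.0135938   PSNR 37.3332 dB   SSIM 0.997366   (l = 1)
```

The RMSE is on the phantom's unit attenuation scale (so ~1.4% of the
dynamic range), PSNR is in dB against peak 1, and SSIM compares the global
luminance/contrast/structure statistics of the two volumes. For the full
five-method study:

```r
cfg <- run_config(geom, grid)
res <- compare_algorithms(cfg, out_dir = "report")
res$metrics
#>   algorithm       rmse     psnr      ssim
#> 1      sart 0.02217175 33.08400 0.9931702
#> 2  asd-pocs 0.02105366 33.53345 0.9938435
#> 3   sart-tv 0.07177112 22.88101 0.9122607
#> 4       tpv 0.01443797 36.80988 0.9971330
#> 5   tpv-gif 0.01359382 37.33317 0.9973657
```

The fused method wins on all three metrics, TpV is second, and the
over-smoothing SART-TV trails — the qualitative ordering this method family
was designed to demonstrate on sparse-view data. `report/` receives the
per-method volumes (MHD), difference maps, central profile curves (CSV) and
a `run_log.yaml` that makes the run bit-reproducible.

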