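# meniscusdti

Zonal parcellation, diffusion tensor metrics and deterministic
tractography for diffusion MRI of the knee meniscus.

## What problem this solves

The meniscus is a C-shaped fibrocartilage pad whose load-bearing capacity
comes from circumferential collagen bundles tied together by radial
fibers.  Diffusion MRI sees that architecture: water diffuses fastest
along the fibers, so the principal eigenvector of the per-voxel diffusion
tensor tracks the local fiber direction.  Quantifying how diffusion
properties vary across the tissue requires dividing it into its standard
sub-regions — the vascular zones of Cooper's classification (White-White
inner third, Red-White middle third, Red-Red outer third) and the
anterior/body/posterior parts — yet neither division is visible as image
contrast.  This package provides, for researchers working on meniscal
microstructure and degeneration:

* **automatic parcellation** of any binary meniscus mask into 3 zones ×
  3 parts = 9 regions, using a fitted rotation frame (PCA plane + circle
  fit with midline refinement) and an angular-sweep radial trisection;
* **voxelwise DTI fitting** (`ln S = ln S0 − b gᵀDg`, weighted linear
  least squares) with FA / MD / AD / RD and colour-FA maps, where
  FA = √(3/2)·‖λ − MD‖/‖λ‖, MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2;
* **deterministic streamline tractography** along the interpolated
  principal eigenvector with the 45° turning-angle stopping rule;
* **region-to-region connectivity** matrices and heatmaps from the tracts;
* **zonal statistics** (volume fractions, mean ± sd tables, one-way
  ANOVA with F = (SSB/df_B)/(SSW/df_W));
* a **synthetic phantom generator** — crescent masks, zone-dependent
  fibrous tensor fields, Stejskal–Tanner signal synthesis
  (b = γ²G²δ²(Δ − δ/3)) and Rician noise — emulating a 125 µm, b = 1000
  s/mm², 81-direction + 8 b0 protocol, so the whole chain is testable
  with known ground truth.

## Worked example

Simulate a half-annulus phantom with the zone eigenvalue presets, fit the
tensor, parcellate, and summarise:

```r
library(meniscusdti)

spec   <- phantom_spec(grid_shape = c(64, 64, 24), voxel_size = 1,
                       inner_radius = 10, outer_radius = 25, height = 8,
                       seed = 7)
scheme <- generate_direction_scheme(81, 8, 1000, seed = 7)
ph     <- simulate_phantom(spec, scheme)

tensors <- fit_dti(ph$dwi, scheme, ph$mask)
maps    <- compute_scalar_maps(tensors)
frame   <- fit_rotation_frame(ph$mask, spec$voxel_size)
zones   <- radial_segmentation(ph$mask, frame)
zonal_summary(maps, zones)[, c("zone", "volume_pct", "FA_mean", "MD_mean",
                               "AD_mean", "RD_mean")]
#>   zone volume_pct FA_mean  MD_mean AD_mean  RD_mean
#> 1  W-W       24.1  0.0926 0.001057 0.00117 0.001000
#> 2  R-W       33.5  0.1628 0.000915 0.00109 0.000828
#> 3  R-R       42.4  0.1948 0.000790 0.00097 0.000700
```

Reading the table: the zone volume fractions reproduce the analytic
annulus-area ratios of an even radial trisection (23.8 / 33.3 / 42.9%
within voxelisation error); the fitted AD and RD means equal the phantom's
per-zone eigenvalue presets (this run is noise-free, so recovery is exact
to numerical precision); FA rises from the inner to the outer zone while
MD falls — the zonal anisotropy trend the pipeline is designed to detect.

The full chain in one call, with manifest, heatmap and all artifacts:

```r
cfg <- run_config(phantom = phantom_spec(seed = 1), out_dir = "run1",
                  seed = 1)
run_pipeline(cfg)
```

or from the shell via the installed launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/meniscus-dti.R", package="meniscusdti"))')" \
  run-all --out run1 --seed 1
```

## Layout

* `R/` — acquisition schemes, phantom, NIfTI I/O, tensor fit, parcellation,
  tracking, streamline I/O, connectivity, statistics, pipeline, CLI.
* `src/` — Rcpp/RcppArmadillo cores (batch 3×3 eigendecomposition,
  streamline propagation).
* `vignettes/meniscus-dti-methods.Rmd` — the methods notes: model
  assumptions, parameter defaults and their rationale, what the phantom
  does and does not emulate, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance suites.
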