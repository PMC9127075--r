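---
title: "Methods: zonal parcellation, DTI metrics and tractography for meniscus dMRI"
author: "meniscusdti authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zonal parcellation, DTI metrics and tractography for meniscus dMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meniscusdti)
```

## The problem

The knee meniscus is a crescent-shaped fibrocartilage pad whose mechanical
competence rests on a predominantly circumferential collagen network, with
localized radial "tie" fibers.  Diffusion MRI can probe that architecture
non-invasively: water diffuses preferentially along collagen bundles, so the
principal axis of the local diffusion tensor tracks the fiber direction, and
streamline tractography reconstructs the three-dimensional network.
Quantitative comparison across the tissue requires splitting the meniscus
into its standard sub-regions: the three vascular zones of Cooper's
classification — White-White (inner third, avascular), Red-White (middle
third), Red-Red (outer third, vascularised) — and the anterior, body and
posterior parts.  Neither division is visible as image contrast; both are
purely geometric, which is what this package automates.

`meniscusdti` implements the full chain — acquisition-scheme handling,
voxelwise tensor estimation, automatic parcellation, deterministic
tractography, connectivity summarisation — together with a synthetic
phantom generator that produces crescent geometries with known ground
truth, so every stage is testable at desk scale without scanner data.

## Signal model and tensor estimation

The single-tensor model relates the diffusion-weighted signal in a voxel to
the symmetric positive-definite tensor $D$ (mm$^2$/s):

$$ S(b, \mathbf{g}) = S_0 \, e^{-b\, \mathbf{g}^\mathsf{T} D \mathbf{g}}, $$

with $b$ the diffusion weighting (s/mm$^2$) and $\mathbf{g}$ the unit
encoding direction.  For rectangular gradient pulses the b-value follows the
Stejskal–Tanner relation $b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$;
`stejskal_tanner_b()` evaluates it and `stejskal_tanner_G()` inverts it for
the gradient amplitude.  The emulated protocol uses $b = 1000$ s/mm$^2$,
81 directions on a half sphere and 8 b0 volumes; with $\delta = 4.5$ ms and
$\Delta = 5.5$ ms the amplitude needed for $b = 1000$ is about 0.42 T/m,
comfortably below the 0.6 T/m system maximum the protocol assumes.

`fit_dti()` linearises the model, $\ln S = \ln S_0 - b\,\mathbf{g}^\mathsf{T}
D \mathbf{g}$, and solves the 7-parameter design per voxel.  The default is
the standard two-pass weighted least squares (weights = squared predicted
signal), which counteracts the heteroscedasticity introduced by the log
transform at low SNR; plain OLS (`"lls"`) is exact on noise-free data and
kept for validation.  Numerical choices:

* multiple b0 volumes are averaged into one baseline measurement;
* signals are floored at $10^{-6} S_0$ before the log (QC-flagged), so
  noise-nulled voxels are retained rather than dropped;
* eigenvalues are sorted descending; negative eigenvalues (possible under
  noise) are clamped to zero for metric computation and QC-flagged.

Scalar maps follow the standard definitions: MD = trace/3, AD = $\lambda_1$,
RD = $(\lambda_2 + \lambda_3)/2$, FA = $\sqrt{3/2}\,\|\lambda - \mathrm{MD}\|
/ \|\lambda\|$, and the colour-FA map encodes $|\mathbf{e}_1|$ scaled by FA.
The identity MD = (AD + 2RD)/3 holds voxelwise by construction and is
asserted in the tests.  The principal eigenvector sign is canonicalised
(non-negative x component, ties broken by +y then +z) so colour maps are
bit-reproducible; eigenvector sign is physically meaningless, so this is
pure bookkeeping.

## Gradient scheme generation

The protocol only requires directions "uniform on the half sphere".  We
place $n$ axes by minimising the antipodally symmetric electrostatic energy
$\sum_{i<j} 1/\|\mathbf{g}_i-\mathbf{g}_j\| +
1/\|\mathbf{g}_i+\mathbf{g}_j\|$ with projected gradient descent from a
seeded random start (backtracking line search, so the energy trace is
non-increasing — a tested invariant; at most 1000 iterations).  Any
similarly uniform scheme would serve; the tests therefore assert relative
quality (the optimised scheme beats the best of many random schemes in
minimum crossing angle) rather than a specific point set.  When reading
gradient tables, b-values below 10 s/mm$^2$ are treated as b0, tolerating
scanner-exported near-zero values.

## Automatic parcellation

Both segmentations are defined in polar coordinates about a rotation frame
that must be estimated from the mask alone, since no anatomical landmark
defines it.  `fit_rotation_frame()` proceeds as:

1. **Dominant plane** — principal axes of the in-mask voxel coordinate
   covariance; the third axis is the rotation normal.
2. **Centre** — an algebraic (Kåsa) circle fit to the projected
   coordinates, then refined by re-fitting to the arc's *midline* (the
   per-angular-bin midpoint of the radial extent), because the plain
   algebraic fit on a *filled* thick arc is biased along the symmetry axis
   by several voxels.  Bins clipped by the arc's end faces are excluded.
   The midline of a uniform-thickness C-shape is a true circle, so the
   iteration converges to the geometric centre; on analytic half-annulus
   masks the residual error is under 0.15 voxel.
3. **Zero axis** — the direction of the circular mean of the voxels' polar
   angles, which centres the mask's angular extent on 0°.  For a full ring
   this is undefined; the frame is then flagged `ambiguous` but still
   returned.

**Radial (zonal) segmentation.**  The reference procedure rotates the mask
in 0.5° steps, trisects each 2D central-plane cross-section along its
radial length, and reassembles the slices.  We implement the exact limit of
that sweep without resampling: each voxel is assigned to the angular wedge
containing its polar angle, and each wedge's radial interval
$[r_\min, r_\max]$ is split into `n_zones` equal-length bins (half-open;
boundary voxels go to the lower bin).  Two sampling corrections are needed
because a 0.5° wedge is far thinner than one voxel at these radii:

* a wedge's radial bounds are computed from every voxel whose angular
  footprint ($\approx$ voxel size / radius) overlaps the wedge — precisely
  the voxels a 2D cross-section at that angle would pass through — while
  each voxel is still *labelled* exactly once, by its centre angle, so the
  partition property is preserved;
* the extreme over the handful of voxels crossing one wedge underestimates
  the true radial extent by a fraction of a voxel, so a running min/max
  over a ±2.5° window de-biases the bounds (`bounds_window`, settable to 0).

With these corrections the trisection of an analytic half-annulus (inner
radius 10, outer 25) reproduces the exact area fractions
23.8% / 33.3% / 42.9% to within half a percentage point at 128³.
Wedges with fewer than 10 contributing voxels borrow interpolated bounds
from their neighbours.  Zone codes run inner→outer W-W, R-W, R-R, matching
Cooper's assignment of the outer third as Red-Red.

**Rotational segmentation** splits by polar angle: body =
[−`body_span`/2, +`body_span`/2) about the zero axis (default 60°, and
deliberately adjustable — no ground truth fixes it), anterior below,
posterior above.  `combine_parcellations()` crosses the two partitions into
9 regions with codes grouped by part and ordered inner→outer within each
part; that code order is also the heatmap's label order.

Open questions resolved here: how overlapping 2D sections of the rotate-
and-slice sweep are reconciled in 3D is moot under voxel binning (each
voxel has one angle); and "length in the radial direction" is measured on
each wedge's own cross-section (per-wedge bounds), not globally, so a
tapering horn is trisected locally as the figure-level description implies.

## Deterministic tractography

`track_streamlines()` seeds every in-mask voxel (optionally strided or
jittered) and integrates both ways along the principal eigenvector with
fixed-step Euler steps (default step 0.5 × voxel).  At each step the six
tensor components are interpolated trilinearly and the eigenvector is
recomputed at the interpolated point — interpolating the *tensor* rather
than the eigenvector field avoids sign-flip artifacts, and sign continuity
is enforced by flipping the eigenvector to keep a positive dot product with
the previous step.  A direction terminates when the next point would leave
the mask, its FA drops below `fa_threshold` (default 0.05 — deliberately
low because the tissue's own FA is only 0.1–0.3), the turning angle between
successive steps exceeds `angle_threshold` (default 45°, the one stopping
rule the reference analysis states), or the length bound is reached.

Fixed-step Euler drifts outward on circular fibers by about
$\pi h/2$ per half-turn ($h$ = step), i.e. a constant ~0.8 voxel at the
default step; the geometric oracle in the tests (tracked radius within 5%
of seed radius on an analytic circumferential annulus) bounds exactly this
error and fixes the smallest usable phantom radius.  Streamlines serialise
to TrackVis-style `.trk` or MRtrix-style `.tck` containers.

## Connectivity

`connection_matrix()` builds the region × region count matrix.  The
reference analysis does not define "connection strength", so both obvious
conventions are implemented: `endpoint` (default; each streamline
increments the cell of its endpoint-label pair, so diagonal + upper
triangle sums to the streamline count) and `passthrough` (each visited
label pair counted once per streamline — appropriate because the zones are
thin and most tracts traverse several regions).  Endpoints just outside the
labels snap to the nearest label within one voxel (tracks can overshoot by
under one step); unresolvable streamlines are dropped and counted.
Optional volume normalisation divides cell $(i,j)$ by $\sqrt{V_i V_j}$,
useful because the outer zone is several times larger than the inner.
The matrix is always symmetric and non-negative; permuting label codes
permutes rows and columns identically (tested properties).

## The phantom: what it emulates, what it does not

`phantom_spec()` states the synthetic world once:

* **geometry** — a half-annulus (default arc 180°) slab; radii/height in
  mm on a 0.125 mm grid by default, matching the emulated acquisition's
  resolution.  An optional linear radial taper approximates the wedge
  cross-section of the real tissue; the default is untapered so analytic
  volume checks stay exact.
* **fibers** — circumferential tangents everywhere (`"radial"` and
  `"mixed"` with a configurable radial wedge are available, the latter
  reproducing the coexistence of both families).  Orientation dispersion
  is off by default (`jitter_sd = 0`) because no quantitative dispersion
  value is established for this tissue.
* **diffusivities** — per-zone eigenvalue presets
  (`meniscus_zone_eigenvalues()`): $\lambda_1$ = the zonal axial
  diffusivity and $\lambda_2 = \lambda_3$ = the radial diffusivity of the
  reported zonal summaries (only axial/radial summaries are available, so
  the two minor eigenvalues are set equal).  Anisotropy therefore rises
  inner→outer (FA 0.09 → 0.19) while MD falls — the zonal trend the
  analysis is meant to detect.
* **noise** — Rician, $\sqrt{(S+n_1)^2+n_2^2}$, as magnitude MRI requires;
  SNR is defined as $S_0/\sigma$ on b0.  The default is noise-free
  (`snr = Inf`) so accuracy tests are exact; noisy tests state their SNR
  explicitly (e.g. 20).  One seed governs all stochastic steps through
  per-step substreams.

A green test on this phantom establishes that the *chain* is correct:
geometry-faithful parcellation, exact tensor recovery, drift-bounded
tracking.  It does not establish fidelity to real menisci — the phantom has
no partial-volume boundary fading, no T2/T1 weighting, no registration
error (volumes are aligned by construction), no compressed-sensing
artifacts, and an idealised fiber field.  Claims about real tissue rest on
the acquisition, not on these tests.

## Statistics

`zonal_summary()` reports per-label volume fraction and mean ± sd (sample
sd) of each metric in the layout of the standard zonal table.
`one_way_anova()` is the classical fixed-effects F test; the primary unit
of analysis is the per-specimen per-zone mean (5 specimens per group in the
emulated design).  A pooled voxelwise mode exists but is flagged
anti-conservative: voxels within a zone are spatially correlated, so its
p-values are optimistic.  No multiple-testing correction is applied (none
is reported in the emulated design).  Degenerate input (all observations
identical) defines F = 0, p = 1.

## Reproducibility

`run_pipeline()` fans a single global seed into per-stage substreams,
writes every artifact (NIfTI volumes, bval/bvec, `.trk` tracts, CSV/JSON
tables) plus a manifest with parameters and MD5 checksums of all data
artifacts; the PNG heatmap is rendered but excluded from checksums because
raster encoders are not guaranteed byte-stable across libpng builds.
Re-running a config reproduces identical checksums — a tested acceptance
criterion.  Every default the emulated protocol leaves unreported is marked
`"unreported-in-paper"` in the manifest.

## Known limitations

* The NIfTI reader/writer is deliberately minimal: uncompressed single-file
  NIfTI-1, axis-aligned diagonal sform only.  Oblique acquisitions must be
  resampled upstream.
* The tensor is the only orientation model; crossing fibers within a voxel
  (radial tie fibers interdigitating with circumferential bundles) collapse
  to a single axis, and the b-matrix is not rotated for oblique gradients.
* Euler integration's radial drift makes very tight curvature (radius below
  about 8 steps) unreliable; use a smaller step there.
* The rotation frame assumes a roughly planar C-shape; a strongly buckled
  meniscus would need a curved central surface, which is out of scope.
* WLS refits voxels independently in R; at very large masks (millions of
  voxels) the fit is the slowest stage.
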