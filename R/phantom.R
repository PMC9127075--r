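#' Table of per-zone diffusion tensor eigenvalue presets
#'
#' Zone-wise (lambda1, lambda2, lambda3) presets in mm^2/s for the three
#' vascular zones of Cooper's classification, ordered inner to outer:
#' White-White, Red-White, Red-Red.  lambda1 is the reported zonal axial
#' diffusivity and lambda2 = lambda3 the radial diffusivity, so anisotropy
#' rises from the inner to the outer zone while mean diffusivity falls.
#'
#' @return 3 x 3 numeric matrix, rows `W-W`, `R-W`, `R-R`, columns
#'   `lambda1..3` (mm^2/s).
#' @export
meniscus_zone_eigenvalues <- function() {
  m <- rbind(
    "W-W" = c(1.17, 1.00, 1.00),
    "R-W" = c(1.09, 0.83, 0.83),
    "R-R" = c(0.97, 0.70, 0.70)
  ) * 1e-3
  colnames(m) <- c("lambda1", "lambda2", "lambda3")
  m
}

#' Specification of a synthetic crescent meniscus phantom
#'
#' Describes a C-shaped (partial-annulus) solid on a regular voxel grid
#' together with the fibrous tensor field and acquisition noise used to
#' synthesise diffusion-weighted volumes from it.
#'
#' @param grid_shape integer length-3 voxel counts per axis.
#' @param voxel_size isotropic voxel edge length, mm.
#' @param center world coordinates (mm) of the annulus centre; default is
#'   the grid centre.
#' @param inner_radius,outer_radius annulus radii, mm (0 < inner < outer).
#' @param arc_span angular extent in degrees (180 = half annulus), centred
#'   on the +x axis from `center`.
#' @param height slab thickness along z, mm.
#' @param zone_eigenvalues matrix of per-zone (lambda1,lambda2,lambda3) in
#'   mm^2/s, inner zone first; default [meniscus_zone_eigenvalues()].
#' @param fiber_pattern `"circumferential"`, `"radial"`, or `"mixed"`
#'   (circumferential with radial fibers inside the wedge given by
#'   `radial_wedge`).
#' @param radial_wedge for `"mixed"`: `c(center_deg, half_width_deg)` of the
#'   radial-fiber wedge. Default `c(0, 15)`.
#' @param taper linear radial taper of the slab height, 0 (none) to 1 (the
#'   outer edge has zero height).
#' @param jitter_sd optional fiber-orientation angular jitter (degrees,
#'   in-plane, Gaussian sd). Default 0; the magnitude of real fiber
#'   dispersion is not established for this tissue.
#' @param S0 baseline (b0) signal, arbitrary units.
#' @param snr signal-to-noise ratio S0/sigma on b0; `Inf` = noise-free.
#' @param seed RNG seed governing all stochastic steps of the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 32), voxel_size = 0.125,
                         center = NULL, inner_radius = 2, outer_radius = 5,
                         arc_span = 180, height = 2,
                         zone_eigenvalues = meniscus_zone_eigenvalues(),
                         fiber_pattern = c("circumferential", "radial", "mixed"),
                         radial_wedge = c(0, 15), taper = 0, jitter_sd = 0,
                         S0 = 100, snr = Inf, seed = 42) {
  fiber_pattern <- match.arg(fiber_pattern)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stop("grid_shape must be three positive integers")
  if (is.null(center))
    center <- (grid_shape - 1) / 2 * voxel_size
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop("phantom spec error: need 0 < inner_radius < outer_radius")
  if (!(arc_span > 0 && arc_span <= 360))
    stop("phantom spec error: arc_span must be in (0, 360]")
  ze <- as.matrix(zone_eigenvalues)
  if (ncol(ze) != 3L) stop("zone_eigenvalues must have three columns")
  if (any(ze <= 0) || any(ze[, 1] < ze[, 2]) || any(ze[, 2] < ze[, 3]))
    stop("phantom spec error: need lambda1 >= lambda2 >= lambda3 > 0 per zone")
  structure(list(
    grid_shape = grid_shape, voxel_size = voxel_size, center = center,
    inner_radius = inner_radius, outer_radius = outer_radius,
    arc_span = arc_span, height = height, zone_eigenvalues = ze,
    fiber_pattern = fiber_pattern, radial_wedge = radial_wedge,
    taper = taper, jitter_sd = jitter_sd, S0 = S0, snr = snr, seed = seed
  ), class = "phantom_spec")
}

# World coordinates (mm) of all voxel centres, n x 3, in grid storage order.
voxel_coordinates <- function(grid_shape, voxel_size, origin = c(0, 0, 0)) {
  ax <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - 1) * voxel_size +
                 origin[k])
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Generate the binary crescent mask of a phantom
#'
#' A voxel is inside iff its centre lies within `[inner_radius,
#' outer_radius]` radially, inside the arc span angularly, and inside the
#' (optionally radially tapered) height slab.  Deterministic; voxel-centre
#' point sampling with no partial-volume anti-aliasing.
#'
#' @param spec a [phantom_spec()].
#' @return integer 3D array (1 inside, 0 outside).
#' @export
make_crescent_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- (spec$grid_shape - 1) * spec$voxel_size
  if (any(spec$center[1:2] - spec$outer_radius < -spec$voxel_size / 2) ||
      any(spec$center[1:2] + spec$outer_radius > ext[1:2] + spec$voxel_size / 2))
    stop("phantom spec error: outer radius does not fit inside the grid")
  co <- voxel_coordinates(spec$grid_shape, spec$voxel_size)
  dx <- co[, 1] - spec$center[1]
  dy <- co[, 2] - spec$center[2]
  dz <- co[, 3] - spec$center[3]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) * 180 / pi
  hloc <- spec$height *
    (1 - spec$taper * pmax(pmin((r - spec$inner_radius) /
      (spec$outer_radius - spec$inner_radius), 1), 0))
  inside <- r >= spec$inner_radius & r <= spec$outer_radius &
    theta >= -spec$arc_span / 2 & theta < spec$arc_span / 2 &
    abs(dz) <= hloc / 2
  array(as.integer(inside), dim = spec$grid_shape)
}

# Analytic ground-truth zone labels (equal thirds of [inner, outer] radius).
# Independent of the parcellation module; used for parameter-recovery tests.
crescent_zone_truth <- function(mask, spec, n_zones = nrow(spec$zone_eigenvalues)) {
  co <- voxel_coordinates(spec$grid_shape, spec$voxel_size)
  r <- sqrt((co[, 1] - spec$center[1])^2 + (co[, 2] - spec$center[2])^2)
  width <- (spec$outer_radius - spec$inner_radius) / n_zones
  z <- pmin(pmax(floor((r - spec$inner_radius) / width), 0), n_zones - 1) + 1
  lab <- array(0L, dim = spec$grid_shape)
  lab[mask == 1L] <- as.integer(z[mask == 1L])
  lab
}

#' Build the zone-dependent fibrous tensor field of a phantom
#'
#' At each in-mask voxel the principal eigenvector follows the fiber
#' pattern: the local circumferential tangent, the outward radial unit
#' vector, or circumferential with radial fibers inside a configurable
#' wedge (`"mixed"`).  Eigenvalues come from the voxel's zone; the tensor is
#' assembled as `R diag(lambda) R^T` so every constructed tensor has exactly
#' the zone eigenvalues.
#'
#' @param mask integer/logical 3D array.
#' @param spec a [phantom_spec()].
#' @param zone_labels optional integer 3D array of zone codes (1 = inner);
#'   if `NULL`, analytic equal-thirds radial zones are used when the spec
#'   has several zones.
#' @return object of class `tensor_field`: list with `comp` (4D array,
#'   sixth-dim order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz, mm^2/s), `valid` mask,
#'   `voxel_size`, `origin`, and `zone_labels`.
#' @export
make_tensor_field <- function(mask, spec, zone_labels = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (sum(mask) == 0) stop("mask is empty")
  if (is.null(zone_labels))
    zone_labels <- crescent_zone_truth(mask, spec)
  idx <- which(mask == 1L)
  co <- voxel_coordinates(spec$grid_shape, spec$voxel_size)[idx, , drop = FALSE]
  dx <- co[, 1] - spec$center[1]
  dy <- co[, 2] - spec$center[2]
  r <- sqrt(dx^2 + dy^2)
  deg <- atan2(dy, dx) * 180 / pi
  bad <- r < 1e-9
  if (any(bad)) {
    warning(sum(bad), " voxel(s) at zero radius excluded from the tensor field")
    keep <- !bad
    idx <- idx[keep]; dx <- dx[keep]; dy <- dy[keep]
    r <- r[keep]; deg <- deg[keep]
  }
  ur <- cbind(dx / r, dy / r, 0)           # outward radial
  ut <- cbind(-dy / r, dx / r, 0)          # circumferential tangent
  radial_here <- switch(spec$fiber_pattern,
    circumferential = rep(FALSE, length(r)),
    radial = rep(TRUE, length(r)),
    mixed = {
      dd <- (deg - spec$radial_wedge[1] + 180) %% 360 - 180
      abs(dd) <= spec$radial_wedge[2]
    })
  e1 <- ifelse(radial_here, 1, 0) * ur + ifelse(radial_here, 0, 1) * ut
  e2 <- ifelse(radial_here, 1, 0) * ut + ifelse(radial_here, 0, 1) * ur
  if (spec$jitter_sd > 0) {
    ang <- with_seed(spec$seed + 1L, rnorm(length(r), 0, spec$jitter_sd)) * pi / 180
    ca <- cos(ang); sa <- sin(ang)
    e1n <- cbind(ca * e1[, 1] - sa * e1[, 2], sa * e1[, 1] + ca * e1[, 2], 0)
    e2n <- cbind(ca * e2[, 1] - sa * e2[, 2], sa * e2[, 1] + ca * e2[, 2], 0)
    e1 <- e1n; e2 <- e2n
  }
  zl <- zone_labels[idx]
  zl[zl < 1 | zl > nrow(spec$zone_eigenvalues)] <- 1L
  lam <- spec$zone_eigenvalues[zl, , drop = FALSE]
  # D = l1 e1 e1' + l2 e2 e2' + l3 e3 e3', e3 = z-hat
  comp <- array(0, dim = c(spec$grid_shape, 6))
  n <- prod(spec$grid_shape)
  put <- function(k, v) comp[idx + (k - 1) * n] <<- v
  put(1, lam[, 1] * e1[, 1]^2       + lam[, 2] * e2[, 1]^2)            # Dxx
  put(2, lam[, 1] * e1[, 1] * e1[, 2] + lam[, 2] * e2[, 1] * e2[, 2])  # Dxy
  put(3, 0)                                                            # Dxz
  put(4, lam[, 1] * e1[, 2]^2       + lam[, 2] * e2[, 2]^2)            # Dyy
  put(5, 0)                                                            # Dyz
  put(6, lam[, 3])                                                     # Dzz
  valid <- array(0L, dim = spec$grid_shape)
  valid[idx] <- 1L
  structure(list(comp = comp, valid = valid, voxel_size = spec$voxel_size,
                 origin = c(0, 0, 0), zone_labels = zone_labels),
            class = "tensor_field")
}

#' Synthesise a diffusion-weighted 4D volume from a tensor field
#'
#' Noise-free signal per volume and voxel by the single-tensor forward model
#' `S = S0 exp(-b g' D g)`; voxels outside the valid mask are zero.  Rician
#' noise is then applied when `spec$snr` is finite, with
#' `sigma = S0 / snr`.
#'
#' @param tensors a `tensor_field` from [make_tensor_field()].
#' @param scheme a [gradient_scheme()].
#' @param spec the [phantom_spec()] providing `S0`, `snr` and `seed`.
#' @return 4D numeric array `c(grid, n_volumes)`.
#' @export
synthesize_dwi <- function(tensors, scheme, spec) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(scheme, "gradient_scheme"))
  d <- dim(tensors$comp)[1:3]
  n <- prod(d)
  idx <- which(tensors$valid == 1L)
  cm <- sapply(1:6, function(k) tensors$comp[idx + (k - 1) * n])
  if (length(idx) == 1L) cm <- matrix(cm, nrow = 1)
  nvol <- length(scheme$b_values)
  dwi <- array(0, dim = c(d, nvol))
  for (v in seq_len(nvol)) {
    g <- scheme$directions[, v]
    b <- scheme$b_values[v]
    q <- if (b == 0) 0 else
      cm[, 1] * g[1]^2 + cm[, 4] * g[2]^2 + cm[, 6] * g[3]^2 +
      2 * (cm[, 2] * g[1] * g[2] + cm[, 3] * g[1] * g[3] +
           cm[, 5] * g[2] * g[3])
    dwi[idx + (v - 1) * n] <- spec$S0 * exp(-b * q)
  }
  if (is.finite(spec$snr))
    dwi <- add_rician_noise(dwi, sigma = spec$S0 / spec$snr,
                            seed = spec$seed + 2L)
  dwi
}

#' Add Rician noise to a magnitude image
#'
#' Each value v becomes `sqrt((v + n1)^2 + n2^2)` with independent zero-mean
#' Gaussian(sigma) draws n1, n2 — the standard magnitude-MRI noise model.
#' Reproducible for a fixed seed.
#'
#' @param volume numeric array.
#' @param sigma Gaussian noise scale (same units as the signal); 0 is the
#'   identity.
#' @param seed RNG seed.
#' @return array of the same shape.
#' @export
add_rician_noise <- function(volume, sigma, seed = 1) {
  if (sigma < 0) stop("domain error: sigma must be non-negative")
  if (sigma == 0) return(volume)
  n <- length(volume)
  with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    out <- sqrt((volume + n1)^2 + n2^2)
    if (!is.null(dim(volume))) dim(out) <- dim(volume)
    out
  })
}

#' Generate and (optionally) write a complete phantom dataset
#'
#' Convenience wrapper: mask, analytic ground-truth zone labels, tensor
#' field, gradient scheme and noisy DWI for one phantom spec.  When
#' `out_dir` is given, writes `dwi.nii`, `mask.nii`, `zone_truth.nii`,
#' `dwi.bval`, `dwi.bvec` there.
#'
#' @param spec a [phantom_spec()].
#' @param scheme optional [gradient_scheme()]; default is the 81-direction +
#'   8 b0, b = 1000 s/mm^2 protocol scheme.
#' @param out_dir optional output directory.
#' @return list with `mask`, `zone_truth`, `tensors`, `scheme`, `dwi`,
#'   `spec`.
#' @export
simulate_phantom <- function(spec = phantom_spec(), scheme = NULL,
                             out_dir = NULL) {
  if (is.null(scheme))
    scheme <- generate_direction_scheme(81, 8, 1000, seed = spec$seed)
  mask <- make_crescent_mask(spec)
  zt <- crescent_zone_truth(mask, spec)
  tf <- make_tensor_field(mask, spec, zone_labels = zt)
  dwi <- synthesize_dwi(tf, scheme, spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    vs <- rep(spec$voxel_size, 3)
    write_nifti(dwi, file.path(out_dir, "dwi.nii"), vs, datatype = "float32")
    write_nifti(mask, file.path(out_dir, "mask.nii"), vs, datatype = "uint8")
    write_nifti(zt, file.path(out_dir, "zone_truth.nii"), vs,
                datatype = "int16")
    write_gradient_table(scheme, file.path(out_dir, "dwi.bval"),
                         file.path(out_dir, "dwi.bvec"))
  }
  list(mask = mask, zone_truth = zt, tensors = tf, scheme = scheme,
       dwi = dwi, spec = spec)
}
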