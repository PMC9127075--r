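#' Fit the rotation frame of a C-shaped mask
#'
#' The zonal and rotational parcellations are defined in polar coordinates
#' about a rotation centre.  Neither the centre nor the 0-degree "central
#' plane" is observable directly from a mask, so they are estimated:
#' * dominant plane: first two principal axes of the in-mask voxel
#'   coordinate covariance; the rotation axis (`normal`) is the third.
#' * centre: algebraic least-squares circle fit (Kasa) to the in-mask
#'   coordinates projected onto that plane.
#' * zero axis: the in-plane direction of the circular mean of voxel polar
#'   angles about the centre, so the mask's angular extent is centred on 0.
#'
#' For a full ring the zero axis is arbitrary; it is still reported but the
#' frame is flagged `ambiguous`.
#'
#' @param mask integer/logical 3D array.
#' @param voxel_size voxel edge length(s), mm.
#' @param origin world coordinate of the first voxel centre, mm.
#' @return object of class `rotation_frame`: `center` (mm, 3D), `normal`,
#'   `zero_axis`, `y_axis` (= normal x zero_axis), `angle_range` (degrees,
#'   observed), `radius` (fitted circle radius), `ambiguous` flag.
#' @export
fit_rotation_frame <- function(mask, voxel_size = 1, origin = c(0, 0, 0)) {
  idx <- which(mask != 0L)
  if (length(idx) < 3L) stop("mask is empty or degenerate to a point")
  d <- dim(mask)
  vs <- rep(voxel_size, length.out = 3)
  co <- arrayInd(idx, d)
  co <- sweep(sweep(co - 1, 2, vs, "*"), 2, origin, "+")
  mu <- colMeans(co)
  cc <- sweep(co, 2, mu)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * ev$values[1])
    stop("degenerate-geometry error: in-mask voxels are collinear")
  p1 <- ev$vectors[, 1]; p2 <- ev$vectors[, 2]; nrml <- ev$vectors[, 3]
  # canonicalise the normal's sign (largest-magnitude component positive)
  k <- which.max(abs(nrml))
  if (nrml[k] < 0) nrml <- -nrml
  u <- cc %*% p1
  v <- cc %*% p2
  kasa <- function(u, v) {
    # algebraic circle fit: minimise ||[2u 2v 1] c(a,b,c) - (u^2+v^2)||
    A <- cbind(2 * u, 2 * v, 1)
    sol <- solve(crossprod(A), crossprod(A, u^2 + v^2))
    c(sol[1], sol[2], sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
  }
  sol <- kasa(u, v)
  # The plain fit on a *filled* thick arc is biased along the symmetry axis
  # (the radial spread trades against the angular asymmetry).  Refine by
  # re-fitting to the arc's midline: per angular bin, the midpoint of the
  # radial extent.  The midline of a uniform-thickness C-shape is a true
  # circular arc, so this converges to the geometric centre.
  for (it in 1:10) {
    du <- u - sol[1]; dv <- v - sol[2]
    ang <- atan2(dv, du)
    bin <- floor(ang / (5 * pi / 180))
    rr <- sqrt(du^2 + dv^2)
    rmid <- tapply(rr, bin, function(x) (min(x) + max(x)) / 2)
    thick <- tapply(rr, bin, function(x) max(x) - min(x))
    amid <- tapply(ang, bin, mean)
    # drop bins clipped by the arc's end faces: the two extreme bins per
    # end, and any bin whose radial thickness is abnormally small
    nb <- length(rmid)
    keep <- thick >= 0.8 * median(thick)
    if (nb > 6) keep[c(1, 2, nb - 1, nb)] <- FALSE
    if (sum(keep) < 3) keep[] <- TRUE
    new_sol <- kasa(sol[1] + rmid[keep] * cos(amid[keep]),
                    sol[2] + rmid[keep] * sin(amid[keep]))
    shift <- sqrt(sum((new_sol[1:2] - sol[1:2])^2))
    sol <- new_sol
    if (shift < 1e-6) break
  }
  center <- mu + sol[1] * p1 + sol[2] * p2
  radius <- sol[3]
  # zero axis from the circular mean of polar angles about the centre
  du <- u - sol[1]; dv <- v - sol[2]
  ang <- atan2(dv, du)
  mang <- atan2(mean(sin(ang)), mean(cos(ang)))
  zero_axis <- cos(mang) * p1 + sin(mang) * p2
  zero_axis <- zero_axis / sqrt(sum(zero_axis^2))
  y_axis <- c(nrml[2] * zero_axis[3] - nrml[3] * zero_axis[2],
              nrml[3] * zero_axis[1] - nrml[1] * zero_axis[3],
              nrml[1] * zero_axis[2] - nrml[2] * zero_axis[1])
  rel <- (ang - mang + pi) %% (2 * pi) - pi
  rng <- range(rel) * 180 / pi
  ambiguous <- diff(range(rel)) > 2 * pi * 0.995 ||
    sqrt(mean(sin(ang))^2 + mean(cos(ang))^2) < 0.05
  structure(list(center = as.numeric(center), normal = as.numeric(nrml),
                 zero_axis = as.numeric(zero_axis), y_axis = y_axis,
                 angle_range = rng, radius = radius, ambiguous = ambiguous,
                 voxel_size = vs, origin = origin),
            class = "rotation_frame")
}

# Polar coordinates (angle degrees, radius mm) of in-mask voxels in a frame.
frame_polar <- function(mask, frame) {
  idx <- which(mask != 0L)
  co <- arrayInd(idx, dim(mask))
  co <- sweep(sweep(co - 1, 2, frame$voxel_size, "*"), 2, frame$origin, "+")
  rel <- sweep(co, 2, frame$center)
  x <- rel %*% frame$zero_axis
  y <- rel %*% frame$y_axis
  list(idx = idx, phi = as.numeric(atan2(y, x)) * 180 / pi,
       r = as.numeric(sqrt(x^2 + y^2)))
}

new_parcellation <- function(labels, table) {
  structure(list(labels = labels, table = table), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", sum(x$labels != 0L), "voxels,",
      nrow(x$table), "labels\n")
  print(x$table)
  invisible(x)
}

#' Radial (zonal) segmentation of a C-shaped mask
#'
#' Implements the angular-sweep trisection: each in-mask voxel is assigned
#' to the angular wedge of width `step` degrees containing its polar angle
#' about the fitted rotation centre; within each wedge, the radial extent
#' `[r_min, r_max]` of the wedge's own voxels is divided into `n_zones`
#' equal-length intervals.  Innermost interval = White-White, middle =
#' Red-White, outermost = Red-Red (Cooper's classification, whose Red-Red
#' zone is the outer, vascularised third).  Assigning voxels to the wedge
#' containing their polar angle is the exact limit of rotating the mask in
#' `step`-degree increments and slicing at the central plane, without
#' resampling artifacts.
#'
#' @param mask integer/logical 3D array.
#' @param frame a [fit_rotation_frame()] result (fitted from `mask` if
#'   `NULL`).
#' @param step wedge width, degrees (default 0.5).
#' @param n_zones number of radial zones (default 3).
#' @param min_wedge_voxels wedges with fewer voxels than this take their
#'   radial bounds interpolated from neighbouring non-sparse wedges
#'   (default 10).
#' @param bounds_window half-width (degrees) of the running-extreme window
#'   used to de-bias each wedge's radial bounds (default 2.5; 0 disables).
#' @return a `parcellation`: integer label volume (1 = innermost zone) plus
#'   a label table mapping codes to zone names.
#' @export
radial_segmentation <- function(mask, frame = NULL, step = 0.5, n_zones = 3,
                                min_wedge_voxels = 10, bounds_window = 2.5) {
  if (step <= 0) stop("parameter error: step must be positive")
  if (n_zones < 1) stop("parameter error: n_zones must be >= 1")
  if (is.null(frame)) frame <- fit_rotation_frame(mask)
  pol <- frame_polar(mask, frame)
  phi0 <- min(pol$phi)
  nw <- max(1L, as.integer(ceiling((max(pol$phi) - phi0) / step + 1e-9)))
  w <- pmin(pmax(floor((pol$phi - phi0) / step), 0), nw - 1) + 1L
  # Radial bounds per wedge.  A wedge `step` degrees wide is much thinner
  # than one voxel at these radii, so a wedge's bounds are computed from
  # every voxel whose angular footprint (about voxel_size / r radians)
  # overlaps the wedge — the voxels a 2D cross-section at that angle would
  # pass through.  Each voxel is still *labelled* once, by its centre angle.
  vox <- frame$voxel_size[1]
  half_fp <- (vox / pmax(pol$r, vox)) * (180 / pi) / 2
  lo <- pmin(pmax(floor((pol$phi - half_fp - phi0) / step), 0), nw - 1)
  hi <- pmin(pmax(floor((pol$phi + half_fp - phi0) / step), 0), nw - 1)
  counts <- hi - lo + 1L
  wexp <- sequence(counts) - 1L + rep(lo, counts) + 1L
  rexp <- rep(pol$r, counts)
  cnt <- tabulate(wexp, nbins = nw)
  rmin <- rep(NA_real_, nw); rmax <- rep(NA_real_, nw)
  agg_min <- tapply(rexp, wexp, min)
  agg_max <- tapply(rexp, wexp, max)
  iw <- as.integer(names(agg_min))
  rmin[iw] <- agg_min; rmax[iw] <- agg_max
  # the extreme of the handful of voxels crossing one thin wedge
  # underestimates the true radial extent by a fraction of a voxel; a
  # running extreme over a small angular window removes that bias while
  # still tracking slow variation of the cross-section
  n_off <- max(0L, as.integer(round(bounds_window / step)))
  if (n_off > 0L && nw > 1L) {
    rmin_s <- rmin; rmax_s <- rmax
    for (o in seq(-n_off, n_off)) {
      if (o == 0) next
      src <- seq_len(nw) + o
      ok <- src >= 1L & src <= nw
      rmin_s[ok] <- pmin(rmin_s[ok], rmin[src[ok]], na.rm = TRUE)
      rmax_s[ok] <- pmax(rmax_s[ok], rmax[src[ok]], na.rm = TRUE)
    }
    rmin <- rmin_s; rmax <- rmax_s
  }
  sparse <- cnt < min_wedge_voxels
  if (any(sparse) && any(!sparse)) {
    ok <- which(!sparse)
    rmin[sparse] <- approx(ok, rmin[ok], xout = which(sparse), rule = 2)$y
    rmax[sparse] <- approx(ok, rmax[ok], xout = which(sparse), rule = 2)$y
    message(sum(sparse & cnt > 0),
            " sparse wedge(s) borrowed radial bounds from neighbours")
  }
  width <- (rmax[w] - rmin[w]) / n_zones
  z <- ifelse(width > 0,
              pmin(pmax(floor((pol$r - rmin[w]) / width), 0), n_zones - 1),
              0) + 1L
  labels <- array(0L, dim = dim(mask))
  labels[pol$idx] <- as.integer(z)
  zone_names <- if (n_zones == 3) c("W-W", "R-W", "R-R")
                else paste0("zone", seq_len(n_zones))
  new_parcellation(labels, data.frame(
    code = seq_len(n_zones), zone = zone_names, part = NA_character_,
    stringsAsFactors = FALSE))
}

#' Rotational (anterior/body/posterior) segmentation
#'
#' Splits the mask by polar angle about the rotation centre: `body` covers
#' the central `body_span` degrees (`[-body_span/2, +body_span/2)` about
#' the zero axis), `anterior` the angles below, `posterior` the angles
#' above.  The span is adjustable; no anatomical ground truth fixes it.
#'
#' @param mask integer/logical 3D array.
#' @param frame a [fit_rotation_frame()] result (fitted if `NULL`).
#' @param body_span central angular width of the body part, degrees
#'   (default 60).
#' @return a `parcellation` with labels 1 = anterior, 2 = body,
#'   3 = posterior.
#' @export
rotational_segmentation <- function(mask, frame = NULL, body_span = 60) {
  if (body_span <= 0) stop("parameter error: body_span must be positive")
  if (is.null(frame)) frame <- fit_rotation_frame(mask)
  pol <- frame_polar(mask, frame)
  part <- ifelse(pol$phi < -body_span / 2, 1L,
                 ifelse(pol$phi < body_span / 2, 2L, 3L))
  labels <- array(0L, dim = dim(mask))
  labels[pol$idx] <- part
  new_parcellation(labels, data.frame(
    code = 1:3, zone = NA_character_,
    part = c("anterior", "body", "posterior"), stringsAsFactors = FALSE))
}

#' Combine zonal and rotational parcellations into 9 regions
#'
#' Each (part, zone) pair becomes one label with code
#' `n_zones * (part - 1) + zone`, so codes are grouped by part (anterior,
#' body, posterior) and ordered inner to outer zone within each part.
#'
#' @param zones `parcellation` from [radial_segmentation()].
#' @param parts `parcellation` from [rotational_segmentation()].
#' @return a combined `parcellation` whose label table carries both names.
#' @export
combine_parcellations <- function(zones, parts) {
  stopifnot(inherits(zones, "parcellation"), inherits(parts, "parcellation"))
  if (!identical(dim(zones$labels), dim(parts$labels)) ||
      !identical(zones$labels != 0L, parts$labels != 0L))
    stop("support mismatch: the two parcellations label different voxels")
  nz <- nrow(zones$table)
  labels <- array(0L, dim = dim(zones$labels))
  on <- zones$labels != 0L
  labels[on] <- nz * (parts$labels[on] - 1L) + zones$labels[on]
  tab <- expand.grid(zone_code = seq_len(nz),
                     part_code = seq_len(nrow(parts$table)),
                     KEEP.OUT.ATTRS = FALSE)
  new_parcellation(labels, data.frame(
    code = nz * (tab$part_code - 1L) + tab$zone_code,
    zone = zones$table$zone[tab$zone_code],
    part = parts$table$part[tab$part_code],
    stringsAsFactors = FALSE))
}

#' Write a parcellation as NIfTI labels plus a JSON label table
#'
#' @param parcellation a `parcellation`.
#' @param path output `.nii` path; the label table goes to the sidecar
#'   `<path without .nii>_labels.json`.
#' @param voxel_size,origin grid geometry, mm.
#' @return invisibly, the two paths.
#' @export
write_parcellation <- function(parcellation, path, voxel_size = 1,
                               origin = c(0, 0, 0)) {
  stopifnot(inherits(parcellation, "parcellation"))
  write_nifti(parcellation$labels, path, rep(voxel_size, length.out = 3),
              origin, datatype = "int16")
  side <- sub("\\.nii$", "", path)
  side <- paste0(side, "_labels.json")
  jsonlite::write_json(parcellation$table, side, dataframe = "rows",
                       na = "null", auto_unbox = FALSE)
  invisible(c(path, side))
}
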