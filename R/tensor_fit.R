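#' Voxelwise diffusion tensor estimation
#'
#' Fits the single-tensor model `ln S = ln S0 - b g' D g` per in-mask voxel
#' by linear least squares on the 7-parameter design (six unique tensor
#' components plus ln S0).  The default `"wls"` estimator is the standard
#' two-pass weighted fit: an ordinary least-squares pass, then a re-fit with
#' per-measurement weights equal to the squared predicted signal, which
#' counteracts the log-transform noise bias at low SNR.  Multiple b0
#' volumes are averaged into a single baseline measurement before fitting.
#' Non-positive or tiny signals are floored at `signal_floor * S0` before
#' the log (QC-flagged).
#'
#' @param dwi 4D array `c(grid, n_volumes)`.
#' @param scheme matching [gradient_scheme()].
#' @param mask integer/logical 3D array of voxels to fit.
#' @param method `"wls"` (default) or `"lls"`.
#' @param signal_floor fraction of the voxel's S0 used as the signal floor
#'   before the log (default 1e-6).
#' @return a `tensor_field`: `comp` (4D, sixth-dim order Dxx, Dxy, Dxz,
#'   Dyy, Dyz, Dzz), `valid`, `voxel_size`, `origin`, `s0` (3D array of
#'   fitted baseline), and `qc` (integer 3D array; bit 1 = signal floored,
#'   bit 2 = singular design / invalid voxel).
#' @export
fit_dti <- function(dwi, scheme, mask, method = c("wls", "lls"),
                    signal_floor = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "gradient_scheme"))
  d4 <- dim(dwi)
  if (length(d4) != 4L) stop("dwi must be a 4D array")
  if (d4[4] != length(scheme$b_values))
    stop("dwi volume count does not match the gradient scheme")
  d <- d4[1:3]
  b0 <- scheme$b0_mask
  if (sum(b0) < 1L) stop("insufficient-scheme error: need at least one b0 volume")
  gd <- scheme$directions[, !b0, drop = FALSE]
  bv <- scheme$b_values[!b0]
  # >= 6 distinct, non-collinear directions: rank of the quadratic-form design
  Xq <- t(apply(rbind(gd, bv), 2, function(col) {
    g <- col[1:3]; b <- col[4]
    -b * c(g[1]^2, g[2]^2, g[3]^2, 2 * g[1] * g[2], 2 * g[1] * g[3],
           2 * g[2] * g[3])
  }))
  if (ncol(gd) < 6L || qr(Xq)$rank < 6L)
    stop("insufficient-scheme error: need >= 6 distinct non-collinear directions")
  n <- prod(d)
  idx <- which(mask != 0L)
  nvox <- length(idx)
  # measurement matrix: averaged b0 first, then each DW volume
  S <- matrix(0, nvox, 1 + ncol(gd))
  b0idx <- which(b0)
  Sb0 <- 0
  for (v in b0idx) Sb0 <- Sb0 + dwi[idx + (v - 1) * n]
  S[, 1] <- Sb0 / length(b0idx)
  for (j in seq_len(ncol(gd)))
    S[, 1 + j] <- dwi[idx + (which(!b0)[j] - 1) * n]
  X <- cbind(rbind(0, Xq), 1)   # columns: Dxx..Dyz order above, ln S0
  s0_est <- pmax(S[, 1], .Machine$double.eps)
  floorv <- signal_floor * s0_est
  floored <- S < floorv
  Sf <- pmax(S, floorv)
  Y <- log(t(Sf))               # nmeas x nvox
  XtXinv_Xt <- solve(crossprod(X), t(X))
  beta <- XtXinv_Xt %*% Y       # 7 x nvox
  if (method == "wls") {
    for (k in seq_len(nvox)) {
      w <- exp(X %*% beta[, k])^2          # squared predicted signal
      Xw <- X * as.numeric(w)
      fit <- tryCatch(solve(crossprod(X, Xw), crossprod(Xw, Y[, k])),
                      error = function(e) NULL)
      if (!is.null(fit)) beta[, k] <- fit
    }
  }
  comp <- array(0, dim = c(d, 6))
  # beta rows: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, lnS0 -> storage order
  ord <- c(1, 4, 5, 2, 6, 3)    # storage slot k takes beta row ord[k]
  for (k in 1:6) comp[idx + (k - 1) * n] <- beta[ord[k], ]
  s0 <- array(0, dim = d)
  s0[idx] <- exp(beta[7, ])
  valid <- array(0L, dim = d)
  valid[idx] <- 1L
  qc <- array(0L, dim = d)
  qc[idx] <- as.integer(rowSums(floored) > 0)
  structure(list(comp = comp, valid = valid, voxel_size = 1, origin = c(0, 0, 0),
                 s0 = s0, qc = qc, zone_labels = NULL),
            class = "tensor_field")
}

#' Scalar diffusion maps from a tensor field
#'
#' Per-voxel eigen-decomposition (eigenvalues sorted descending) and the
#' standard rotation-invariant summaries: FA, MD (trace/3), AD (largest
#' eigenvalue), RD (mean of the two smaller), plus the direction-encoded
#' colour-FA map (|e1| components scaled by FA).  Negative eigenvalues are
#' clamped to zero for the metric computation and QC-flagged.  The principal
#' eigenvector sign is canonicalised to have a non-negative x component
#' (ties broken by +y, then +z) so colour maps are reproducible.
#'
#' @param tensors a `tensor_field`.
#' @return object of class `scalar_maps`: 3D arrays `FA`, `MD`, `AD`, `RD`,
#'   4D `colorFA` (3 channels), 4D `e1` (principal eigenvector), `qc`
#'   (integer; bit 1 = negative-eigenvalue clamp), and `valid`.
#' @export
compute_scalar_maps <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_field"))
  d <- dim(tensors$comp)[1:3]
  n <- prod(d)
  idx <- which(tensors$valid == 1L)
  cm <- sapply(1:6, function(k) tensors$comp[idx + (k - 1) * n])
  if (length(idx) == 1L) cm <- matrix(cm, nrow = 1)
  eg <- eig3_batch(cm)
  lam <- eg$values
  neg <- rowSums(lam < 0) > 0
  lamc <- pmax(lam, 0)
  # metrics from the clamped set so MD = (AD + 2 RD)/3 holds voxelwise
  mdc <- rowMeans(lamc)
  num <- sqrt(rowSums((lamc - mdc)^2))
  den <- sqrt(rowSums(lamc^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  e1 <- eg$vectors[, 1:3, drop = FALSE]
  # canonical sign: non-negative dot with +x (ties: +y, then +z)
  flip <- e1[, 1] < 0 |
    (e1[, 1] == 0 & (e1[, 2] < 0 | (e1[, 2] == 0 & e1[, 3] < 0)))
  e1[flip, ] <- -e1[flip, , drop = FALSE]
  mk <- function(v) { a <- array(NA_real_, dim = d); a[idx] <- v; a }
  colorFA <- array(0, dim = c(d, 3))
  e1arr <- array(0, dim = c(d, 3))
  for (k in 1:3) {
    colorFA[idx + (k - 1) * n] <- abs(e1[, k]) * fa
    e1arr[idx + (k - 1) * n] <- e1[, k]
  }
  qc <- array(0L, dim = d)
  qc[idx] <- as.integer(neg)
  structure(list(FA = mk(fa), MD = mk(mdc), AD = mk(lamc[, 1]),
                 RD = mk(rowMeans(lamc[, 2:3, drop = FALSE])),
                 colorFA = colorFA, e1 = e1arr, qc = qc,
                 valid = tensors$valid), class = "scalar_maps")
}

#' Write scalar maps as NIfTI files
#'
#' FA/MD/AD/RD as separate 3D volumes, colour-FA as one 3-channel 4D volume
#' and QC flags as an integer volume, into `out_dir`.
#'
#' @param maps a `scalar_maps`.
#' @param out_dir output directory (created if needed).
#' @param voxel_size voxel edge length(s), mm.
#' @return invisibly, the written paths.
#' @export
write_scalar_maps <- function(maps, out_dir, voxel_size = 1) {
  stopifnot(inherits(maps, "scalar_maps"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- rep(voxel_size, length.out = 3)
  paths <- character(0)
  for (nm in c("FA", "MD", "AD", "RD")) {
    p <- file.path(out_dir, paste0(tolower(nm), ".nii"))
    img <- maps[[nm]]
    img[is.na(img)] <- 0
    write_nifti(img, p, vs, datatype = "float32")
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "color_fa.nii")
  write_nifti(maps$colorFA, p, vs, datatype = "float32")
  paths <- c(paths, p)
  p <- file.path(out_dir, "qc.nii")
  write_nifti(maps$qc, p, vs, datatype = "int16")
  invisible(c(paths, p))
}
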