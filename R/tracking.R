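#' Parameters for deterministic streamline tracking
#'
#' @param angle_threshold maximum turning angle between successive steps,
#'   degrees; propagation stops when exceeded (default 45).
#' @param step_size integration step, mm; default `0.5 * voxel_size`.
#' @param fa_threshold stopping FA (default 0.05 — deliberately low: the
#'   tissue itself has FA of order 0.1-0.3).
#' @param seeds_per_voxel seeds placed per in-mask voxel; the first is the
#'   voxel centre, further ones are uniformly jittered inside the voxel
#'   (default 1).
#' @param min_length,max_length streamline length bounds, mm.
#' @param voxel_size isotropic voxel edge length, mm (used for the step
#'   default and world-coordinate output).
#' @param rng_seed seed for the seed-jitter RNG.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(angle_threshold = 45, step_size = NULL,
                            fa_threshold = 0.05, seeds_per_voxel = 1,
                            min_length = 0, max_length = Inf,
                            voxel_size = 1, rng_seed = 1) {
  if (is.null(step_size)) step_size <- 0.5 * voxel_size
  if (!(angle_threshold > 0 && angle_threshold < 90))
    stop("parameter error: angle_threshold must be in (0, 90) degrees")
  if (step_size <= 0) stop("parameter error: step_size must be positive")
  if (!(fa_threshold >= 0 && fa_threshold < 1))
    stop("parameter error: fa_threshold must be in [0, 1)")
  if (seeds_per_voxel < 1) stop("parameter error: seeds_per_voxel must be >= 1")
  structure(list(angle_threshold = angle_threshold, step_size = step_size,
                 fa_threshold = fa_threshold,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 min_length = min_length, max_length = max_length,
                 voxel_size = voxel_size, rng_seed = rng_seed),
            class = "tracking_params")
}

#' Deterministic streamline tractography along the principal eigenvector
#'
#' Seeds every in-mask voxel and propagates bidirectionally by fixed-step
#' Euler integration along the principal eigenvector of the trilinearly
#' interpolated tensor, with sign continuity (the eigenvector is flipped to
#' keep a positive dot product with the previous step).  A direction stops
#' when the next point leaves the mask, its FA falls below
#' `fa_threshold`, the turning angle exceeds `angle_threshold`, or the
#' length bound is reached.  Deterministic for a fixed seed.
#'
#' @param tensors a `tensor_field`.
#' @param scalarmaps optional `scalar_maps` supplying the FA stopping map
#'   (computed from `tensors` if `NULL`).
#' @param mask integer/logical 3D array of the tracking domain (default:
#'   the tensor field's valid mask).
#' @param params a [tracking_params()].
#' @param seed_stride keep every `seed_stride`-th in-mask voxel as a seed
#'   (1 = all voxels); a deterministic density control for large masks.
#' @return object of class `streamline_set`: `streamlines` (list of
#'   n_points x 3 matrices, world mm), `seed_index`, `seed_points` (world
#'   mm coordinates of each retained streamline's seed), `voxel_size`,
#'   `origin`, `params`.
#' @export
track_streamlines <- function(tensors, scalarmaps = NULL, mask = NULL,
                              params = tracking_params(), seed_stride = 1) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(params, "tracking_params"))
  if (is.null(mask)) mask <- tensors$valid
  d <- dim(tensors$comp)[1:3]
  idx <- which(mask != 0L)
  if (length(idx) == 0L)
    return(structure(list(streamlines = list(), seed_index = integer(0),
                          seed_points = matrix(0, 0, 3),
                          voxel_size = params$voxel_size, origin = c(0, 0, 0),
                          params = params), class = "streamline_set"))
  if (is.null(scalarmaps)) scalarmaps <- compute_scalar_maps(tensors)
  fa <- scalarmaps$FA
  fa[is.na(fa)] <- 0
  if (seed_stride > 1) idx <- idx[seq(1, length(idx), by = seed_stride)]
  seeds <- arrayInd(idx, d) - 1          # 0-based voxel centres
  if (params$seeds_per_voxel > 1) {
    extra <- with_seed(params$rng_seed, {
      do.call(rbind, lapply(seq_len(params$seeds_per_voxel - 1L), function(i)
        seeds + matrix(runif(length(seeds), -0.5, 0.5), nrow(seeds), 3)))
    })
    seeds <- rbind(seeds, extra)
  }
  step_vox <- params$step_size / params$voxel_size
  max_steps <- if (is.finite(params$max_length))
    max(1L, as.integer(floor(params$max_length / params$step_size / 2)))
  else 100000L
  min_points <- max(2L, as.integer(ceiling(params$min_length /
                                             params$step_size)) + 1L)
  res <- track_core(as.numeric(tensors$comp), as.integer(mask),
                    as.numeric(fa), as.integer(d),
                    seeds, step_vox, params$angle_threshold,
                    params$fa_threshold, max_steps, min_points)
  world <- lapply(res$streamlines, function(m) m * params$voxel_size)
  structure(list(streamlines = world, seed_index = res$seed_index,
                 seed_points = seeds[res$seed_index, , drop = FALSE] *
                   params$voxel_size,
                 voxel_size = params$voxel_size, origin = c(0, 0, 0),
                 params = params), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, 1L)
  cat(sprintf("<streamline_set> %d streamlines, %d points total\n",
              length(np), sum(np)))
  invisible(x)
}

#' Streamline lengths in mm
#' @param set a `streamline_set`.
#' @return numeric vector of polyline arc lengths.
#' @export
streamline_lengths <- function(set) {
  vapply(set$streamlines, function(m) {
    if (nrow(m) < 2) return(0)
    sum(sqrt(rowSums(diff(m)^2)))
  }, 1.0)
}
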