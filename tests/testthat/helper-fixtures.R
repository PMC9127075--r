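# Shared fixtures, built in code and memoised per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small crescent phantom (48^3-ish grid), noise-free, modest scheme.
small_phantom <- function() cached("small_phantom", {
  spec <- phantom_spec(grid_shape = c(48, 48, 16), voxel_size = 1,
                       inner_radius = 8, outer_radius = 20, height = 6,
                       seed = 11)
  scheme <- generate_direction_scheme(30, 2, 1000, seed = 3)
  simulate_phantom(spec, scheme)
})

# The same geometry fitted: tensors + scalar maps (noise-free, lls exact).
small_fit <- function() cached("small_fit", {
  ph <- small_phantom()
  tensors <- fit_dti(ph$dwi, ph$scheme, ph$mask, method = "lls")
  list(ph = ph, tensors = tensors, maps = compute_scalar_maps(tensors))
})

# Analytic half-annulus mask, radii 10/25, for parcellation oracles.
annulus_10_25 <- function() cached("annulus_10_25", {
  spec <- phantom_spec(grid_shape = c(128, 128, 64), voxel_size = 1,
                       inner_radius = 10, outer_radius = 25, height = 10)
  mask <- make_crescent_mask(spec)
  list(spec = spec, mask = mask, frame = fit_rotation_frame(mask, 1))
})

# A uniform-tensor box field with principal axis along +x.
box_field <- function(d = c(20, 20, 20), lam = c(1.5, 0.3, 0.3) * 1e-3,
                      axis = 1) {
  comp <- array(0, dim = c(d, 6))
  slot <- c(1, 4, 6)  # diagonal component indices: Dxx, Dyy, Dzz
  comp[, , , slot[axis]] <- lam[1]
  rest <- setdiff(1:3, axis)
  comp[, , , slot[rest[1]]] <- lam[2]
  comp[, , , slot[rest[2]]] <- lam[3]
  mask <- array(1L, dim = d)
  structure(list(comp = comp, valid = mask, voxel_size = 1,
                 origin = c(0, 0, 0)), class = "tensor_field")
}

# Tensor field directly from an eigenvalue triple + eigenvector basis.
tensor_from_eigen <- function(lam, R) {
  D <- R %*% diag(lam) %*% t(R)
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# Single-voxel tensor field wrapper for scalar-map unit tests.
one_voxel_field <- function(comp6) {
  comp <- array(0, dim = c(1, 1, 1, 6))
  comp[1, 1, 1, ] <- comp6
  structure(list(comp = comp, valid = array(1L, dim = c(1, 1, 1)),
                 voxel_size = 1, origin = c(0, 0, 0)),
            class = "tensor_field")
}

# Rotate a 3D or 4D array by 90 degrees in the xy plane (exact grid op).
rot90_xy <- function(a) {
  d <- dim(a)
  perm <- if (length(d) == 3) c(2, 1, 3) else c(2, 1, 3, 4)
  b <- aperm(a, perm)
  idx <- rev(seq_len(dim(b)[1]))
  if (length(d) == 3) b[idx, , , drop = FALSE] else b[idx, , , , drop = FALSE]
}
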