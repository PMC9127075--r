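#' Gradient scheme: per-volume b-values and encoding directions
#'
#' Container for a single-shell diffusion acquisition: one b-value and one
#' unit encoding direction per acquired volume, with b0 (non-diffusion
#' weighted) volumes flagged.  Directions are stored in the image coordinate
#' frame, one column per volume.
#'
#' @param b_values numeric vector of b-values (s/mm^2), one per volume.
#' @param directions 3 x n numeric matrix of encoding directions (unit norm
#'   for diffusion-weighted volumes, zero for b0 volumes).
#' @param b0_threshold b-values below this (s/mm^2) are flagged as b0;
#'   tolerates scanner-exported near-zero b-values. Default 10.
#' @return An object of class `gradient_scheme` with fields `b_values`,
#'   `directions`, `b0_mask`.
#' @export
gradient_scheme <- function(b_values, directions, b0_threshold = 10) {
  b_values <- as.numeric(b_values)
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L || ncol(directions) != length(b_values))
    stop("directions must be a 3 x n matrix matching length(b_values)")
  if (any(b_values < 0)) stop("b_values must be non-negative")
  b0 <- b_values < b0_threshold
  if (any(!b0)) {
    nrm <- sqrt(colSums(directions[, !b0, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("diffusion-weighted directions must have unit norm (within 1e-6)")
  }
  structure(
    list(b_values = b_values, directions = directions, b0_mask = b0),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf(
    "<gradient_scheme> %d volumes: %d diffusion-weighted (b = %s s/mm^2), %d b0\n",
    length(x$b_values), sum(!x$b0_mask),
    paste(unique(x$b_values[!x$b0_mask]), collapse = ", "), sum(x$b0_mask)))
  invisible(x)
}

#' @export
format.gradient_scheme <- function(x, ...) {
  sprintf("gradient_scheme(%d dirs + %d b0)", sum(!x$b0_mask), sum(x$b0_mask))
}

# Antipodally-symmetric electrostatic energy of a direction set.
# P: 3 x n matrix of unit vectors. E = sum_{i<j} 1/|gi-gj| + 1/|gi+gj|.
antipodal_energy <- function(P) {
  n <- ncol(P)
  if (n < 2) return(0)
  G <- crossprod(P)
  dm <- sqrt(pmax(2 - 2 * G, 0))
  dp <- sqrt(pmax(2 + 2 * G, 0))
  up <- upper.tri(G)
  sum(1 / dm[up]) + sum(1 / dp[up])
}

# Repulsive force (negative energy gradient) on each point, 3 x n.
antipodal_force <- function(P) {
  n <- ncol(P)
  Fm <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    d <- P[, i] - P
    s <- P[, i] + P
    dn <- sqrt(colSums(d^2)); sn <- sqrt(colSums(s^2))
    dn[i] <- Inf                      # skip self term of the difference part
    dn[dn < 1e-12] <- Inf; sn[sn < 1e-12] <- Inf
    Fm[, i] <- rowSums(sweep(d, 2, dn^3, "/")) + rowSums(sweep(s, 2, sn^3, "/"))
  }
  Fm
}

#' Minimum pairwise antipodal crossing angle of a direction set (degrees)
#'
#' The smallest angle between any two encoding axes, treating g and -g as the
#' same axis.  A uniformity figure of merit: larger is better.
#'
#' @param directions 3 x n matrix of unit direction vectors, or a
#'   `gradient_scheme` (b0 columns are ignored).
#' @return angle in degrees.
#' @export
min_crossing_angle <- function(directions) {
  if (inherits(directions, "gradient_scheme"))
    directions <- directions$directions[, !directions$b0_mask, drop = FALSE]
  P <- as.matrix(directions)
  if (ncol(P) < 2) return(90)
  G <- abs(crossprod(P))
  G[G > 1] <- 1
  min(acos(G[upper.tri(G)])) * 180 / pi
}

#' Generate a uniform half-sphere diffusion encoding scheme
#'
#' Places `n_dirs` unit vectors on the half sphere by minimising the
#' antipodally-symmetric electrostatic energy (sum over pairs of
#' 1/|gi-gj| + 1/|gi+gj|) with projected gradient descent from a seeded
#' random start.  `n_b0` zero-weighted entries are prepended.  Deterministic
#' for a fixed seed.
#'
#' @param n_dirs number of diffusion-weighted directions (>= 1).
#' @param n_b0 number of b0 volumes to prepend.
#' @param b_value shell b-value in s/mm^2.
#' @param seed RNG seed for the random initialisation.
#' @param max_iter maximum optimiser iterations (default 1000).
#' @param tol relative energy-decrease convergence tolerance.
#' @return A [gradient_scheme()].  The optimiser's energy trace is attached
#'   as attribute `"energy_trace"` (non-increasing by construction).
#' @export
generate_direction_scheme <- function(n_dirs, n_b0 = 0, b_value = 1000,
                                      seed = 1, max_iter = 1000, tol = 1e-12) {
  n_dirs <- as.integer(n_dirs); n_b0 <- as.integer(n_b0)
  if (n_dirs < 1 && b_value > 0)
    stop("invalid scheme: n_dirs must be >= 1 when b_value > 0")
  if (n_b0 < 0) stop("n_b0 must be non-negative")
  P <- with_seed(seed, {
    M <- matrix(rnorm(3 * n_dirs), 3, n_dirs)
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  })
  trace <- antipodal_energy(P)
  if (n_dirs >= 2) {
    eta <- 0.01
    e_cur <- trace[1]
    for (it in seq_len(max_iter)) {
      Fm <- antipodal_force(P)
      # project force onto the tangent space of the sphere at each point
      Ft <- Fm - sweep(P, 2, colSums(Fm * P), "*")
      accepted <- FALSE
      for (bt in 1:30) {
        Q <- P + eta * Ft
        Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
        e_new <- antipodal_energy(Q)
        if (e_new <= e_cur) { accepted <- TRUE; break }
        eta <- eta / 2
      }
      if (!accepted) break
      rel <- (e_cur - e_new) / abs(e_cur)
      P <- Q; e_cur <- e_new
      trace <- c(trace, e_cur)
      eta <- eta * 1.2
      if (rel < tol) break
    }
  }
  # canonical half-sphere representative: z > 0 (ties: x > 0, then y > 0)
  for (j in seq_len(ncol(P))) {
    v <- P[, j]
    flip <- v[3] < 0 ||
      (abs(v[3]) < 1e-12 && (v[1] < 0 || (abs(v[1]) < 1e-12 && v[2] < 0)))
    if (flip) P[, j] <- -v
  }
  bvals <- c(rep(0, n_b0), rep(b_value, n_dirs))
  dirs <- cbind(matrix(0, 3, n_b0), P)
  sch <- gradient_scheme(bvals, dirs)
  attr(sch, "energy_trace") <- trace
  sch
}

#' Stejskal-Tanner b-value from gradient timing parameters
#'
#' Computes b = gamma^2 G^2 delta^2 (Delta - delta/3) for rectangular
#' diffusion gradients and converts from SI (s/m^2) to s/mm^2.
#'
#' @param G gradient amplitude, T/m.
#' @param delta diffusion gradient duration, s.
#' @param Delta gradient separation (leading-edge to leading-edge), s.
#' @param gamma gyromagnetic ratio, rad s^-1 T^-1; default is the proton
#'   value 2.6752218744e8.
#' @return b-value in s/mm^2.
#' @export
stejskal_tanner_b <- function(G, delta, Delta, gamma = 2.6752218744e8) {
  if (any(c(G, delta, Delta, gamma) < 0))
    stop("domain error: all Stejskal-Tanner arguments must be non-negative")
  if (Delta < delta / 3)
    stop("domain error: Delta must be >= delta/3")
  gamma^2 * G^2 * delta^2 * (Delta - delta / 3) / 1e6
}

#' Gradient amplitude required for a target b-value
#'
#' Inverts the Stejskal-Tanner relation for G.
#'
#' @param b target b-value, s/mm^2.
#' @inheritParams stejskal_tanner_b
#' @return gradient amplitude in T/m.
#' @export
stejskal_tanner_G <- function(b, delta, Delta, gamma = 2.6752218744e8) {
  if (any(c(b, delta, Delta, gamma) < 0))
    stop("domain error: all Stejskal-Tanner arguments must be non-negative")
  if (Delta < delta / 3)
    stop("domain error: Delta must be >= delta/3")
  sqrt(b * 1e6 / (gamma^2 * delta^2 * (Delta - delta / 3)))
}

#' Write a gradient scheme as FSL-dialect bval/bvec text files
#'
#' One whitespace-separated row of b-values; three rows of direction
#' components; one column per volume.
#'
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(formatC(scheme$b_values, format = "g", digits = 9),
                   collapse = " "), bval_path)
  lns <- apply(scheme$directions, 1, function(r)
    paste(formatC(r, format = "g", digits = 9), collapse = " "))
  writeLines(lns, bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read FSL-dialect bval/bvec files into a gradient scheme
#'
#' @param bval_path,bvec_path input file paths.
#' @param b0_threshold b-values below this are flagged as b0 (default 10).
#' @return a [gradient_scheme()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, b0_threshold = 10) {
  parse_rows <- function(path) {
    lns <- readLines(path)
    lns <- lns[nzchar(trimws(lns))]
    lapply(lns, function(l) as.numeric(strsplit(trimws(l), "[ \t]+")[[1]]))
  }
  bv <- parse_rows(bval_path)
  if (length(bv) != 1L) stop("format error: bval file must have one row")
  gv <- parse_rows(bvec_path)
  if (length(gv) != 3L) stop("format error: bvec file must have three rows")
  ncols <- vapply(gv, length, 1L)
  if (length(unique(ncols)) != 1L || ncols[1] != length(bv[[1]]))
    stop("format error: column-count mismatch between bval and bvec files")
  gradient_scheme(bv[[1]], do.call(rbind, gv), b0_threshold = b0_threshold)
}
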