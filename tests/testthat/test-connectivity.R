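# Hand-built parcellation: 9 cubes along x in a 27x3x3 grid.
toy_parcellation <- function() {
  labels <- array(0L, dim = c(27, 3, 3))
  for (k in 1:9) labels[(3 * k - 2):(3 * k), 2, 2] <- k
  tab <- expand.grid(zone = c("W-W", "R-W", "R-R"),
                     part = c("anterior", "body", "posterior"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(labels = labels,
                 table = data.frame(code = 1:9, zone = tab$zone,
                                    part = tab$part)),
            class = "parcellation")
}

toy_set <- function(...) {
  structure(list(streamlines = list(...), seed_index = seq_along(list(...)),
                 voxel_size = 1, origin = c(0, 0, 0), params = NULL),
            class = "streamline_set")
}

test_that("endpoint mode counts the endpoint-pair cell", {
  parc <- toy_parcellation()
  # streamline from region 1 (x~1) to region 5 (x~13), 0-based world coords
  sl <- cbind(seq(1, 13, by = 0.5), 1, 1)
  cm <- connection_matrix(toy_set(sl), parc, mode = "endpoint")
  M <- cm$matrix
  expect_equal(M[1, 5], 1)
  expect_equal(M[5, 1], 1)
  expect_equal(sum(M), 2)
  # wholly inside region 3: only the diagonal cell
  sl3 <- cbind(seq(6.2, 7.8, by = 0.4), 1, 1)
  M3 <- connection_matrix(toy_set(sl3), parc)$matrix
  expect_equal(M3[3, 3], 1)
  expect_equal(sum(M3), 1)
})

test_that("passthrough mode counts each visited pair once", {
  parc <- toy_parcellation()
  sl <- cbind(seq(1, 13, by = 0.25), 1, 1)   # visits regions 1..5
  M <- connection_matrix(toy_set(sl), parc, mode = "passthrough")$matrix
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(M[i, j], 1)
    expect_equal(M[j, i], 1)
  }
  expect_equal(sum(M[1:5, 1:5]), 2 * choose(5, 2))
})

test_that("connection matrices are symmetric, non-negative and monotone", {
  parc <- toy_parcellation()
  s1 <- cbind(seq(1, 7, by = 0.5), 1, 1)
  s2 <- cbind(seq(10, 22, by = 0.5), 1, 1)
  Ma <- connection_matrix(toy_set(s1), parc)$matrix
  Mb <- connection_matrix(toy_set(s1, s2), parc)$matrix
  expect_true(all(Ma >= 0))
  expect_identical(Ma, t(Ma))
  expect_identical(Mb, t(Mb))
  expect_true(all(Mb >= Ma))
  # endpoint-pair count (diagonal + one triangle) equals the streamline count
  expect_equal(sum(diag(Mb)) + sum(Mb[upper.tri(Mb)]), 2)
})

test_that("permuting label codes permutes the matrix rows/columns", {
  parc <- toy_parcellation()
  perm <- c(3, 1, 2, 5, 4, 9, 8, 7, 6)
  labels2 <- parc$labels
  labels2[parc$labels != 0L] <- perm[parc$labels[parc$labels != 0L]]
  parc2 <- structure(list(labels = labels2,
                          table = data.frame(code = 1:9,
                                             zone = parc$table$zone[order(perm)],
                                             part = parc$table$part[order(perm)])),
                     class = "parcellation")
  s1 <- cbind(seq(1, 13, by = 0.5), 1, 1)
  M <- connection_matrix(toy_set(s1), parc)$matrix
  M2 <- connection_matrix(toy_set(s1), parc2)$matrix
  for (i in 1:9) for (j in 1:9)
    expect_equal(M2[perm[i], perm[j]], M[i, j])
})

test_that("volume normalization divides by sqrt(Vi Vj)", {
  parc <- toy_parcellation()
  s1 <- cbind(seq(1, 13, by = 0.5), 1, 1)
  raw <- connection_matrix(toy_set(s1), parc, normalization = "raw")$matrix
  nrm <- connection_matrix(toy_set(s1), parc, normalization = "volume")$matrix
  v <- vapply(1:9, function(k) sum(parc$labels == k), 1.0)
  expect_equal(nrm[1, 5], raw[1, 5] / sqrt(v[1] * v[5]))
})

test_that("endpoints just outside the labels snap within one voxel", {
  parc <- toy_parcellation()
  sl <- cbind(seq(1, 13, by = 0.5), 1, 2)   # y row 2 (0-based) is unlabelled
  cm <- connection_matrix(toy_set(sl), parc)
  expect_equal(cm$matrix[1, 5], 1)
  expect_equal(cm$n_dropped, 0)
  far <- cbind(seq(1, 13, by = 0.5), 1, 9)  # far outside: dropped
  cm2 <- connection_matrix(toy_set(far), parc)
  expect_equal(sum(cm2$matrix), 0)
  expect_equal(cm2$n_dropped, 1)
})

test_that("full-arc circumferential phantom links parts through the body", {
  spec <- phantom_spec(grid_shape = c(64, 64, 12), voxel_size = 1,
                       inner_radius = 12, outer_radius = 26, height = 5)
  m <- make_crescent_mask(spec)
  tf <- make_tensor_field(m, spec)
  fr <- fit_rotation_frame(m, 1)
  r9 <- suppressMessages(combine_parcellations(
    radial_segmentation(m, fr), rotational_segmentation(m, fr)))
  # cap track length well below the arc length so few tracks span
  # anterior -> posterior while body connections are unaffected
  tp <- tracking_params(voxel_size = 1, max_length = 20)
  ts <- track_streamlines(tf, NULL, m, tp, seed_stride = 5)
  cm <- connection_matrix(ts, r9)$matrix
  part_of <- rep(1:3, each = 3)
  agg <- matrix(0, 3, 3)
  for (i in 1:9) for (j in 1:9)
    agg[part_of[i], part_of[j]] <- agg[part_of[i], part_of[j]] + cm[i, j]
  expect_gt(agg[1, 3], 0)                  # anterior<->posterior present
  expect_gte(agg[1, 2], agg[1, 3])         # body links dominate
  expect_gte(agg[2, 3], agg[1, 3])
})

test_that("heatmap rendering writes image, exact table and sidecar", {
  parc <- toy_parcellation()
  s1 <- cbind(seq(1, 13, by = 0.5), 1, 1)
  cm <- connection_matrix(toy_set(s1), parc)
  png_path <- withr::local_tempfile(fileext = ".png")
  render_heatmap(cm, png_path)
  expect_true(file.exists(png_path))
  tab <- as.matrix(read.csv(sub("\\.png$", ".csv", png_path),
                            row.names = 1, check.names = FALSE))
  expect_equal(unname(tab), unname(cm$matrix))
  side <- jsonlite::read_json(sub("\\.png$", ".json", png_path),
                              simplifyVector = TRUE)
  expect_identical(side$labels, colnames(cm$matrix))
  # all-zero matrix renders too
  cm0 <- cm; cm0$matrix[] <- 0
  p0 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(cm0, p0)
  tab0 <- as.matrix(read.csv(sub("\\.png$", ".csv", p0), row.names = 1,
                             check.names = FALSE))
  expect_true(all(tab0 == 0))
})

test_that("empty parcellation errors", {
  parc <- toy_parcellation()
  parc$labels[] <- 0L
  expect_error(connection_matrix(toy_set(cbind(1, 1, 1)), parc),
               "empty parcellation")
})
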