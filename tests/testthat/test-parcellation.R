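test_that("rotation frame recovers the analytic centre within one voxel", {
  spec <- phantom_spec(grid_shape = c(128, 128, 128), voxel_size = 1,
                       inner_radius = 20, outer_radius = 50, height = 10)
  m <- make_crescent_mask(spec)
  fr <- fit_rotation_frame(m, 1)
  expect_lt(sqrt(sum((fr$center - spec$center)^2)), 1)
  expect_equal(abs(sum(fr$normal * c(0, 0, 1))), 1, tolerance = 1e-6)
  expect_false(fr$ambiguous)
  # orthonormality invariants
  expect_equal(sum(fr$normal * fr$zero_axis), 0, tolerance = 1e-9)
  expect_equal(sum(fr$zero_axis^2), 1, tolerance = 1e-9)
})

test_that("full ring recovers the centre but is flagged ambiguous", {
  spec <- phantom_spec(grid_shape = c(64, 64, 16), voxel_size = 1,
                       inner_radius = 10, outer_radius = 22, height = 5,
                       arc_span = 360)
  m <- make_crescent_mask(spec)
  fr <- fit_rotation_frame(m, 1)
  expect_lt(sqrt(sum((fr$center[1:2] - spec$center[1:2])^2)), 1)
  expect_true(fr$ambiguous)
})

test_that("degenerate masks are rejected", {
  m <- array(0L, dim = c(10, 10, 10))
  expect_error(fit_rotation_frame(m), "empty")
  m[3:8, 5, 5] <- 1L
  expect_error(fit_rotation_frame(m), "degenerate-geometry")
})

test_that("radial trisection matches the analytic annulus fractions", {
  ann <- annulus_10_25()
  z <- suppressMessages(radial_segmentation(ann$mask, ann$frame))
  counts <- table(z$labels[z$labels != 0L])
  frac <- 100 * counts / sum(counts)
  expected <- 100 * c(15^2 - 10^2, 20^2 - 15^2, 25^2 - 20^2) / (25^2 - 10^2)
  for (k in 1:3) expect_lt(abs(frac[k] - expected[k]), 1.5)
  # partition property
  expect_identical(z$labels != 0L, ann$mask == 1L)
  expect_equal(sum(counts), sum(ann$mask))
  # zone ordering: mean radius strictly increases W-W < R-W < R-R
  co <- arrayInd(which(ann$mask == 1L), dim(ann$mask)) - 1
  r <- sqrt((co[, 1] - ann$spec$center[1])^2 + (co[, 2] - ann$spec$center[2])^2)
  mr <- tapply(r, z$labels[z$labels != 0L], mean)
  expect_true(all(diff(mr) > 0))
  expect_identical(z$table$zone, c("W-W", "R-W", "R-R"))
})

test_that("single-zone radial segmentation is the identity labelling", {
  ph <- small_phantom()
  z1 <- suppressMessages(radial_segmentation(ph$mask, n_zones = 1))
  expect_identical(unique(z1$labels[z1$labels != 0L]), 1L)
  expect_identical(z1$labels != 0L, ph$mask == 1L)
})

test_that("rotational segmentation splits by body span", {
  ann <- annulus_10_25()
  p <- rotational_segmentation(ann$mask, ann$frame, body_span = 60)
  counts <- table(p$labels[p$labels != 0L])
  frac <- 100 * counts / sum(counts)
  expect_lt(abs(frac[2] - 100 * 60 / 180), 1.5)
  expect_identical(p$table$part, c("anterior", "body", "posterior"))
  # the voxel nearest phi = 0 is body
  pol_x <- ann$spec$center + c(20, 0, 0)
  vx <- round(pol_x) + 1
  expect_equal(p$labels[vx[1], vx[2], vx[3]], 2L)
  # exhaustive interval
  pall <- rotational_segmentation(ann$mask, ann$frame, body_span = 181)
  expect_identical(unique(pall$labels[pall$labels != 0L]), 2L)
  expect_error(rotational_segmentation(ann$mask, ann$frame, body_span = 0),
               "parameter error")
})

test_that("combined parcellation yields 9 labels partitioning the mask", {
  ann <- annulus_10_25()
  z <- suppressMessages(radial_segmentation(ann$mask, ann$frame))
  p <- rotational_segmentation(ann$mask, ann$frame)
  r9 <- combine_parcellations(z, p)
  labs <- r9$labels[r9$labels != 0L]
  expect_identical(sort(unique(labs)), 1:9)
  expect_identical(r9$labels != 0L, ann$mask == 1L)
  expect_equal(sum(table(labs)), sum(ann$mask))
  expect_equal(nrow(r9$table), 9)
  # code layout: grouped by part, zones inner->outer within each part
  expect_identical(r9$table$part[1:3], rep("anterior", 3))
  expect_identical(r9$table$zone[1:3], c("W-W", "R-W", "R-R"))
})

test_that("combining mismatched supports errors", {
  ann <- annulus_10_25()
  z <- suppressMessages(radial_segmentation(ann$mask, ann$frame))
  m2 <- ann$mask
  m2[which(m2 == 1L)[1:10]] <- 0L
  p2 <- rotational_segmentation(m2, ann$frame)
  expect_error(combine_parcellations(z, p2), "support mismatch")
})

test_that("parcellation is equivariant under exact 90-degree grid rotation", {
  ph <- small_phantom()
  m <- ph$mask
  mr <- rot90_xy(m)
  seg <- function(mm) {
    fr <- fit_rotation_frame(mm, 1)
    suppressMessages(combine_parcellations(
      radial_segmentation(mm, fr), rotational_segmentation(mm, fr)))
  }
  a <- seg(m); b <- seg(mr)
  a_rot <- rot90_xy(a$labels)
  agree <- mean(a_rot[mr == 1L] == b$labels[mr == 1L])
  expect_gte(agree, 0.995)
})

test_that("zonal FA increases outward on the zone-preset phantom", {
  fit <- small_fit()
  frame <- fit_rotation_frame(fit$ph$mask, 1)
  z <- suppressMessages(radial_segmentation(fit$ph$mask, frame))
  fa_means <- vapply(1:3, function(k) mean(fit$maps$FA[z$labels == k]), 1.0)
  expect_true(all(diff(fa_means) > 0))
})

test_that("pipeline parcellation agrees with the analytic zone truth", {
  # Dice >= 0.9 per zone against the equal-thirds analytic labels at 128-grid
  ann <- annulus_10_25()
  z <- suppressMessages(radial_segmentation(ann$mask, ann$frame))
  truth <- meniscusdti:::crescent_zone_truth(ann$mask, ann$spec)
  for (k in 1:3) {
    a <- z$labels == k
    b <- truth == k
    dice <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_gte(dice, 0.9)
  }
  # zonal metric means computed on either labelling agree within 2%
  # (maps from the analytic tensor field at the same 128-grid resolution)
  maps <- compute_scalar_maps(make_tensor_field(ann$mask, ann$spec,
                                                zone_labels = truth))
  for (k in 1:3) {
    m_truth <- mean(maps$FA[truth == k])
    m_pipe <- mean(maps$FA[z$labels == k])
    expect_lt(abs(m_pipe - m_truth) / m_truth, 0.02)
  }
})

test_that("parcellation writes labels + JSON sidecar", {
  ph <- small_phantom()
  z <- suppressMessages(radial_segmentation(ph$mask))
  p <- withr::local_tempfile(fileext = ".nii")
  write_parcellation(z, p, 1)
  back <- read_nifti(p)
  expect_identical(array(as.integer(back$data), dim = dim(z$labels)), z$labels)
  side <- jsonlite::read_json(sub("\\.nii$", "_labels.json", p),
                              simplifyVector = TRUE)
  expect_identical(side$zone, c("W-W", "R-W", "R-R"))
})
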