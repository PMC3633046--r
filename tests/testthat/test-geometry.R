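test_that("slice hulls report exact areas for simple shapes", {
  # 5x5 square of pixels: hull through pixel centers spans 4x4
  sq <- as.matrix(expand.grid(y = 1:5, x = 1:5))
  h <- slice_hull(sq)
  expect_equal(h$area_px, 16)
  expect_equal(nrow(h$hull_points), 4)
  # right triangle with legs 4: shoelace area 8
  tr <- rbind(c(1, 1), c(1, 5), c(5, 1))
  expect_equal(slice_hull(tr)$area_px, 8)
  # degenerate cases report pixel counts
  expect_equal(slice_hull(cbind(3L, 3L))$area_px, 1)
  expect_equal(slice_hull(cbind(1:4, 2L))$area_px, 4)
  # physical calibration scales the area
  expect_equal(slice_hull(sq, spacing = c(0.5, 2))$area_um2, 16)
  expect_error(slice_hull(matrix(integer(0), 0, 2)), "empty")
})

test_that("hull vertices are counter-clockwise and on the convex hull", {
  set.seed(8)
  pts <- cbind(sample(1:30, 40, TRUE), sample(1:30, 40, TRUE))
  h <- slice_hull(pts)
  p <- h$hull_points
  x <- p[, 2]; y <- p[, 1]
  expect_gt(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y), 0)  # signed CCW
  expect_true(all(apply(p, 1, function(r)
    any(pts[, 1] == r[1] & pts[, 2] == r[2]))))
})

test_that("outlier pruning removes far points but never the bulk", {
  theta <- seq(0, 2 * pi, length.out = 25)[-25]
  ring <- cbind(10 + 3 * sin(theta), 10 + 3 * cos(theta))
  spiked <- rbind(ring, c(40, 40))
  pruned <- prune_outliers(spiked, k = 2)
  expect_equal(nrow(pruned), nrow(ring))
  expect_false(any(pruned[, 1] == 40))
  pruned2 <- prune_outliers(spiked, k = 2, method = "pairwise")
  expect_false(any(pruned2[, 1] == 40))
  # clean contours are untouched; tiny sets are returned unchanged
  expect_identical(prune_outliers(ring), ring)
  two <- cbind(c(1, 100), c(1, 100))
  expect_identical(prune_outliers(two), two)
  # the per-pass removal cap holds even with many outliers
  many <- rbind(ring[1:10, ], matrix(50, 8, 2) + matrix(rnorm(16), 8))
  expect_gte(nrow(prune_outliers(many, k = 0.1)), ceiling(0.8 * 18))
})

test_that("gc_report converts voxel counts to calibrated volumes", {
  # a 4 x 5 x 6 cuboid of bright voxels
  vox <- array(0L, c(6, 9, 9))
  vox[2:5, 2:6, 3:8] <- 200L
  s <- image_stack(vox, spacing = c(0.5, 0.5, 2))
  cl <- segment_spots(s, segmentation_params(100))[[1]]
  rep <- gc_report(cl, spacing = s$spacing)
  expect_identical(rep$voxel_count, 4L * 5L * 6L)
  expect_equal(rep$volume_um3, 120 * 0.5 * 0.5 * 2)
  expect_equal(unname(rep$slice_span), c(2, 5))
  expect_equal(rep$centroid_um[["z"]], (mean(2:5) - 0.5) * 2)
  expect_equal(rep$centroid_um[["x"]], (mean(3:8) - 0.5) * 0.5)
  expect_equal(unname(rep$bbox), c(2, 5, 2, 6, 3, 8))
  expect_output(print(rep), "um\\^3")
})

test_that("lofted surfaces are closed 2-manifolds (Euler characteristic 2)", {
  ph <- small_phantom(noise_sigma = 0)
  cl <- segment_spots(ph$stack, segmentation_params(150, 10L))[[1]]
  mesh <- build_surface(cl, spacing = c(1, 1, 1.43))
  expect_s3_class(mesh, "surface_mesh")
  expect_identical(euler_characteristic(mesh), 2L)
  expect_true(all(vapply(mesh$faces, length, integer(1)) == 3L))
  # every vertex is used by some face
  expect_setequal(unique(unlist(mesh$faces)), seq_len(nrow(mesh$vertices)))
  # z range spans the cluster plus nothing else
  zs <- sort(unique(mesh$vertices[, 3]))
  expect_equal(min(zs), (min(cl$slices) - 0.5) * 1.43)
  expect_equal(max(zs), (max(cl$slices) - 0.5) * 1.43)
})

test_that("single-slice and degenerate-slice clusters still close up", {
  vox <- array(0L, c(3, 8, 8))
  vox[2, 3:6, 3:6] <- 200L          # single-slice blob
  s <- image_stack(vox)
  cl <- segment_spots(s, segmentation_params(100))[[1]]
  mesh <- build_surface(cl)
  expect_identical(euler_characteristic(mesh), 2L)
  # a column: every slice is a single pixel (degenerate hull)
  vox2 <- array(0L, c(4, 8, 8))
  vox2[, 4, 4] <- 200L
  cl2 <- segment_spots(image_stack(vox2), segmentation_params(100))[[1]]
  mesh2 <- build_surface(cl2)
  expect_identical(euler_characteristic(mesh2), 2L)
})

test_that("OFF files round-trip and satisfy the format invariants", {
  ph <- small_phantom(shape = c(8, 24, 24), noise_sigma = 0,
                      semiaxes = c(2.5, 6, 6))
  cl <- segment_spots(ph$stack, segmentation_params(150))[[1]]
  mesh <- build_surface(cl)
  p <- withr::local_tempfile(fileext = ".off")
  write_off(mesh, p)
  ln <- readLines(p)
  expect_identical(ln[1], "OFF")
  counts <- as.integer(strsplit(ln[2], " ")[[1]])
  expect_identical(counts[1], nrow(mesh$vertices))
  expect_identical(counts[2], length(mesh$faces))
  expect_identical(counts[3], n_mesh_edges(mesh))
  m2 <- read_off(p)
  expect_equal(m2$vertices, mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(m2$faces, mesh$faces)
  expect_identical(euler_characteristic(m2), 2L)
  expect_error(read_off(withr::local_tempfile(lines = "PLY")), "OFF")
})
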