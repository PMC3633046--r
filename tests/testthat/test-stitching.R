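base_stitch <- small_phantom(shape = c(4, 80, 160), noise_sigma = 4, seed = 9,
                             semiaxes = c(2, 15, 30))$stack

test_that("phase correlation recovers known integer shifts exactly", {
  for (shift in list(c(0L, 0L), c(5L, 3L), c(-6L, 2L), c(7L, -4L))) {
    tp <- make_tile_pair(base_stitch, shift = shift, overlap = 0.35,
                         noise_sigma = 2, seed = 13)
    reg <- register_pair(tp$tile_a, tp$tile_b, prior = tp$nominal,
                         window = 12L)
    expect_identical(reg$offset, tp$nominal + shift)
    expect_false(reg$low_confidence)
  }
})

test_that("registration respects the prior search window", {
  tp <- make_tile_pair(base_stitch, shift = c(3L, 2L), overlap = 0.35)
  # window too small to contain the true peak: the result stays inside it
  reg <- register_pair(tp$tile_a, tp$tile_b, prior = tp$nominal, window = 1L)
  expect_true(all(abs(reg$offset - tp$nominal) <= 1L))
  expect_error(register_pair(tp$tile_a, tp$tile_b, prior = c(0L, 200L)),
               "too small")
  flat <- image_stack(array(50L, dim(tp$tile_a$voxels)))
  reg0 <- register_pair(flat, flat, prior = c(0L, 0L), window = 4L)
  expect_s3_class(reg0, "registration_result")
  expect_output(print(reg0), "offset")
})

test_that("gain estimation matches a known exposure factor within 1%", {
  tp <- make_tile_pair(base_stitch, shift = c(0L, 0L), overlap = 0.35,
                       gain = 0.8, noise_sigma = 1, seed = 4)
  res <- stitch_tiles(list(tp$tile_a, tp$tile_b),
                      priors = rbind(c(0L, 0L), tp$nominal))
  g <- res$layout$gain[2]
  expect_lt(abs(g - 1 / 0.8) / (1 / 0.8), 0.01)
  expect_identical(res$layout$y[2], 0L)
  expect_identical(res$layout$x[2], tp$nominal[2])
})

test_that("non-overlap pixels of the mosaic equal their source tiles exactly", {
  tp <- make_tile_pair(base_stitch, shift = c(2L, -3L), overlap = 0.3)
  res <- stitch_tiles(list(tp$tile_a, tp$tile_b),
                      priors = rbind(c(0L, 0L), tp$nominal))
  off <- c(res$layout$y[2], res$layout$x[2]) - c(res$layout$y[1], res$layout$x[1])
  expect_identical(off, tp$nominal + tp$true_shift)
  m <- res$mosaic$voxels
  da <- dim(tp$tile_a$voxels)
  oy <- -min(0L, off[1])  # tile_a origin on the canvas
  # columns of tile_a left of the overlap are copied verbatim
  left <- seq_len(off[2])
  expect_identical(m[, oy + seq_len(da[2]), left],
                   tp$tile_a$voxels[, , left])
  # canvas is the bounding box of both placed tiles
  expect_identical(dim(m)[3], da[3] + off[2])
})

test_that("blending identical overlap content reproduces it unchanged", {
  tp <- make_tile_pair(base_stitch, shift = c(0L, 0L), overlap = 0.4)
  bl <- blend_mosaic(list(tp$tile_a, tp$tile_b),
                     rbind(c(0L, 0L), tp$nominal))
  d <- dim(tp$tile_a$voxels)
  expect_identical(bl$mosaic$voxels[, , seq_len(d[3])], tp$tile_a$voxels)
  expect_equal(bl$gains, c(1, 1))
  # the full mosaic equals the corresponding crop of the base stack
  w <- dim(bl$mosaic$voxels)[3]
  expect_identical(bl$mosaic$voxels, base_stitch$voxels[, seq_len(d[2]),
                                                        seq_len(w)])
})

test_that("pyramid down/up pair reconstructs exactly", {
  set.seed(21)
  m <- matrix(runif(48 * 37), 48, 37)
  u <- gcvolumes:::pyr_up(gcvolumes:::pyr_down(m), dim(m))
  expect_identical(dim(u), dim(m))
  # blending a layer with itself is the identity regardless of weights
  w <- matrix(runif(48 * 37), 48, 37)
  expect_equal(gcvolumes:::pyramid_blend(m, m, w, 3L), m)
})

test_that("a 2x2 tile grid stitches into a consistent mosaic", {
  base <- small_phantom(shape = c(3, 140, 140), noise_sigma = 3, seed = 2,
                        semiaxes = c(1.5, 25, 25))$stack
  crop <- function(ys, xs) image_stack(base$voxels[, ys, xs, drop = FALSE])
  step <- 60L
  tiles <- list(crop(1:80, 1:80), crop(1:80, step + 1:80),
                crop(step + 1:80, 1:80), crop(step + 1:80, step + 1:80))
  priors <- rbind(c(0L, 0L), c(0L, step + 2L), c(step - 1L, 0L),
                  c(step + 1L, step - 2L))
  res <- stitch_tiles(tiles, priors, window = 8L)
  expect_identical(unname(as.matrix(res$layout[, c("y", "x")])),
                   rbind(c(0L, 0L), c(0L, step), c(step, 0L), c(step, step)))
  expect_identical(dim(res$mosaic$voxels), dim(base$voxels))
})
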