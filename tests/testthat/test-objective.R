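test_that("Bhattacharyya distance has the required boundary behaviour", {
  h <- c(3, 5, 0, 2)
  expect_equal(bhattacharyya_distance(h, h), 0)
  expect_equal(bhattacharyya_distance(h, 10 * h), 0)   # scale invariance
  expect_equal(bhattacharyya_distance(c(1, 0), c(0, 1)), 1)  # disjoint
  a <- c(4, 1, 0); b <- c(1, 2, 2)
  expect_equal(bhattacharyya_distance(a, b), bhattacharyya_distance(b, a))
  d <- bhattacharyya_distance(a, b)
  expect_true(d > 0 && d < 1)
  expect_error(bhattacharyya_distance(c(1, 2), c(1, 2, 3)), "equal bin")
  expect_error(bhattacharyya_distance(c(1, -1), c(1, 1)), ">= 0")
  expect_error(bhattacharyya_distance(c(0, 0), c(1, 1)), "positive total")
})

test_that("area similarity is symmetric, bounded and has exact extremes", {
  set.seed(3)
  a <- runif(1000, 0, 500); b <- runif(1000, 0, 500)
  s1 <- area_similarity(a, b); s2 <- area_similarity(b, a)
  expect_equal(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(area_similarity(7, 7), 1)
  expect_equal(area_similarity(7, 0), 0)
  expect_equal(area_similarity(0, 7), 0)
  expect_equal(area_similarity(0, 0), 0)
  # closed form against direct evaluation
  expect_equal(s1, (abs(a + b) - abs(a - b)) / abs(a + b))
  expect_error(area_similarity(-1, 2), ">= 0")
})

test_that("identical segmentations give the closed-form objective N/(eps + beta*N)", {
  cfg <- objective_config()
  for (N in c(1L, 2L, 7L, 50L)) {
    hists <- replicate(N, uniform_hist(), simplify = FALSE)
    cl <- fake_cluster(seq_len(N), rep(10L, N), hists)
    expect_equal(cluster_objective(cl, cl, cfg), N / (cfg$epsilon + cfg$beta * N))
  }
})

test_that("vanished contours inflate the per-cluster objective", {
  cfg <- objective_config()
  hists <- replicate(4, uniform_hist(), simplify = FALSE)
  full <- fake_cluster(1:4, rep(10L, 4), hists)
  shrunk <- fake_cluster(1:3, rep(10L, 3), hists[1:3])
  stable <- cluster_objective(full, full, cfg)
  lost_one <- cluster_objective(full, shrunk, cfg)
  expect_gt(lost_one, stable)
  # a fully vanished partner: numerator e^alpha per slice, denominator eps
  gone <- cluster_objective(full, NULL, cfg)
  expect_equal(gone, 4 * exp(cfg$alpha) / cfg$epsilon)
  expect_gt(gone, lost_one)
  expect_error(cluster_objective(NULL, NULL, cfg), "empty")
})

test_that("cluster matching pairs by maximal voxel overlap", {
  ph <- small_phantom(noise_sigma = 0)
  seg_a <- segment_spots(ph$stack, segmentation_params(150, 5L))
  seg_b <- segment_spots(ph$stack, segmentation_params(151, 5L))
  pairs <- match_clusters(seg_a, seg_b)
  expect_length(pairs, length(seg_a))
  expect_false(is.null(pairs[[1]]$b))
  expect_gt(length(intersect(pairs[[1]]$a$linear_idx,
                             pairs[[1]]$b$linear_idx)), 0)
  # against an empty segmentation every cluster pairs with NULL
  seg_none <- segment_spots(ph$stack, segmentation_params(250, 5L))
  pairs0 <- match_clusters(seg_a, seg_none)
  expect_true(all(vapply(pairs0, function(p) is.null(p$b), logical(1))))
})

test_that("stack objective is low on the plateau and Inf when nothing segments", {
  ph <- small_phantom(noise_sigma = 0)
  v_stable <- stack_objective(ph$stack, 150, 5L)
  n_sl <- length(segment_spots(ph$stack, segmentation_params(150, 5L))[[1]]$slices)
  expect_equal(as.numeric(v_stable), n_sl / (1e-9 + n_sl))
  expect_identical(attr(v_stable, "n_clusters"), 1L)
  v_none <- stack_objective(ph$stack, 250, 5L)
  expect_identical(as.numeric(v_none), Inf)
  expect_identical(attr(v_none, "n_clusters"), 0L)
  # at th = 200 the plateau survives but vanishes at th + 1 -> huge value
  v_edge <- stack_objective(ph$stack, 200, 5L)
  expect_gt(as.numeric(v_edge), 1e6)
})

test_that("the segmentation cache returns the same results as direct calls", {
  ph <- small_phantom(shape = c(8, 32, 32), noise_sigma = 5, seed = 2,
                      semiaxes = c(3, 7, 7))
  cache <- new.env(parent = emptyenv())
  for (th in c(120, 150, 120)) {
    v1 <- stack_objective(ph$stack, th, 5L, cache = cache)
    v2 <- stack_objective(ph$stack, th, 5L)
    expect_identical(v1, v2)
  }
})
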