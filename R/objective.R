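#' Configuration of the threshold-selection objective
#'
#' The objective compares the segmentation of each GC at a parameter vector
#' `lambda = (th, smin)` with the segmentation at the neighbouring vector
#' `lambda' = (th + neighbor_offset, smin)`: stable, large segmentations
#' score low; segmentations whose per-slice contours shrink or vanish
#' between neighbouring thresholds score high.
#'
#' @param alpha weight on the per-slice histogram-distance term
#'   (default 0.001).
#' @param beta weight on the area-similarity sum (default 1.0).
#' @param epsilon small positive constant preventing division by zero
#'   (default 1e-9).
#' @param neighbor_offset nonzero integer increment applied to `th` to form
#'   the neighbouring parameter vector (default +1).
#' @return An object of class `objective_config`.
#' @export
objective_config <- function(alpha = 0.001, beta = 1.0, epsilon = 1e-9,
                             neighbor_offset = 1L) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  neighbor_offset <- as.integer(neighbor_offset)
  if (neighbor_offset == 0L) stop("neighbor_offset must be nonzero")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 neighbor_offset = neighbor_offset),
            class = "objective_config")
}

#' Bhattacharyya distance between two histograms
#'
#' `D = 1 - sum_k sqrt(Ha_hat(k) * Hb_hat(k))` where the hatted histograms
#' are normalized to unit sum.  `D` is symmetric, zero iff the normalized
#' histograms coincide, and bounded by 1 (disjoint support).
#'
#' @param h_a,h_b nonnegative histograms with equal bin counts and positive
#'   total mass.
#' @return A scalar in `[0, 1]`.
#' @export
bhattacharyya_distance <- function(h_a, h_b) {
  if (length(h_a) != length(h_b)) stop("histograms must have equal bin counts")
  if (any(h_a < 0) || any(h_b < 0)) stop("histogram entries must be >= 0")
  sa <- sum(h_a); sb <- sum(h_b)
  if (sa == 0 || sb == 0) stop("histograms must have positive total mass")
  bc <- sum(sqrt((h_a / sa) * (h_b / sb)))
  min(max(1 - bc, 0), 1)
}

#' Area similarity of two per-slice segmentation areas
#'
#' `A = (|a + a'| - |a - a'|) / |a + a'|`: a symmetric score that equals 1
#' iff the areas are equal and 0 iff exactly one of them has vanished.  The
#' doubly-degenerate case `a = a' = 0` is defined as 0 (the slice carries no
#' region under either parameter setting).
#'
#' @param a,a_prime nonnegative areas (vectorized).
#' @return Values in `[0, 1]`.
#' @export
area_similarity <- function(a, a_prime) {
  if (any(a < 0) || any(a_prime < 0)) stop("areas must be >= 0")
  s <- abs(a + a_prime)
  out <- ifelse(s == 0, 0, (s - abs(a - a_prime)) / s)
  as.numeric(out)
}

#' Objective value for one matched cluster pair
#'
#' Sums `exp(alpha * D_n)` over the slices where at least one of the two
#' segmentations has a region, and divides by `epsilon + beta * sum_n A_n`.
#' On a slice where one side has vanished, `A_n = 0` and the histogram
#' distance is taken as 1 (total dissimilarity), so vanishing contours
#' inflate the numerator while contributing nothing to the denominator —
#' the penalty that drives threshold selection.  Slices empty on both sides
#' are skipped.
#'
#' @param cluster_a `spot_cluster` at `lambda` (may be `NULL` if the cluster
#'   only exists at `lambda'`).
#' @param cluster_b `spot_cluster` at `lambda'` (may be `NULL`).
#' @param config an [objective_config()].
#' @return Scalar objective value `L_j`.
#' @export
cluster_objective <- function(cluster_a, cluster_b, config = objective_config()) {
  if (is.null(cluster_a) && is.null(cluster_b))
    stop("empty cluster pair: no slices at either parameter setting")
  sl_a <- if (is.null(cluster_a)) integer(0) else cluster_a$slices
  sl_b <- if (is.null(cluster_b)) integer(0) else cluster_b$slices
  slices <- sort(union(sl_a, sl_b))
  num <- 0; den <- 0
  for (n in slices) {
    key <- as.character(n)
    aa <- if (n %in% sl_a) cluster_a$slice_areas[[key]] else 0
    ab <- if (n %in% sl_b) cluster_b$slice_areas[[key]] else 0
    if (aa == 0 && ab == 0) next
    D <- if (aa > 0 && ab > 0)
      bhattacharyya_distance(cluster_a$slice_hists[[key]],
                             cluster_b$slice_hists[[key]])
    else 1
    num <- num + exp(config$alpha * D)
    den <- den + area_similarity(aa, ab)
  }
  num / (config$epsilon + config$beta * den)
}

#' Match clusters of two segmentations of the same stack
#'
#' Greedy maximal-voxel-overlap matching: repeatedly pairs the two clusters
#' with the largest remaining overlap.  Clusters of `seg_a` with no overlap
#' partner are paired with `NULL` (an empty segmentation, all areas zero),
#' which drives their area similarity to 0 on every slice.
#'
#' @param seg_a,seg_b cluster lists from [segment_spots()] on the same
#'   stack.
#' @return A list of `list(a = , b = )` pairs, one per cluster of `seg_a`.
#' @export
match_clusters <- function(seg_a, seg_b) {
  na <- length(seg_a); nb <- length(seg_b)
  if (na == 0L) return(list())
  if (nb == 0L) return(lapply(seg_a, function(a) list(a = a, b = NULL)))
  dims <- attr(seg_b, "dims")
  blab <- integer(prod(dims))
  for (j in seq_len(nb)) blab[seg_b[[j]]$linear_idx] <- j
  ov <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    hit <- blab[seg_a[[i]]$linear_idx]
    hit <- hit[hit > 0L]
    if (length(hit)) {
      tt <- tabulate(hit, nb)
      ov[i, ] <- tt
    }
  }
  pairs <- vector("list", na)
  assigned_b <- rep(FALSE, nb)
  assigned_a <- rep(FALSE, na)
  repeat {
    m <- max(ov)
    if (m <= 0) break
    w <- which(ov == m, arr.ind = TRUE)[1, ]
    i <- w[1]; j <- w[2]
    pairs[[i]] <- list(a = seg_a[[i]], b = seg_b[[j]])
    assigned_a[i] <- TRUE; assigned_b[j] <- TRUE
    ov[i, ] <- -1; ov[, j] <- -1
  }
  for (i in which(!assigned_a)) pairs[[i]] <- list(a = seg_a[[i]], b = NULL)
  pairs
}

#' Total objective of a stack at one parameter vector
#'
#' Segments the stack at `lambda = (th, smin)` and at the neighbouring
#' vector `(th + neighbor_offset, smin)`, matches the clusters, and sums the
#' per-cluster objectives.  Returns `Inf` (with a reason attribute) when no
#' cluster is found at `lambda`.
#'
#' @param stack an [image_stack()].
#' @param th,smin parameter vector under evaluation.
#' @param config an [objective_config()].
#' @param connectivity passed to [segment_spots()].
#' @param cache optional environment used to memoize segmentations across
#'   calls (used by [optimize_params()] and [sweep_objective()]).
#' @return Scalar total objective with attribute `n_clusters`.
#' @export
stack_objective <- function(stack, th, smin, config = objective_config(),
                            connectivity = 26L, cache = NULL) {
  seg_a <- cached_segment(stack, th, smin, connectivity, cache)
  if (length(seg_a) == 0L) {
    out <- Inf
    attr(out, "n_clusters") <- 0L
    attr(out, "reason") <- "no cluster at lambda"
    return(out)
  }
  seg_b <- cached_segment(stack, th + config$neighbor_offset, smin,
                          connectivity, cache)
  pairs <- match_clusters(seg_a, seg_b)
  total <- sum(vapply(pairs, function(p)
    cluster_objective(p$a, p$b, config), numeric(1)))
  attr(total, "n_clusters") <- length(seg_a)
  total
}

cached_segment <- function(stack, th, smin, connectivity, cache) {
  if (is.null(cache))
    return(segment_spots(stack, segmentation_params(th, smin), connectivity))
  key <- sprintf("s:%g:%d:%d", th, smin, connectivity)
  if (!is.null(cache[[key]])) return(cache[[key]])
  lkey <- sprintf("l:%g:%d", th, connectivity)
  labels <- cache[[lkey]]
  if (is.null(labels)) {
    labels <- label_components_cpp(stack$voxels, dim(stack$voxels), th,
                                   as.integer(connectivity))
    cache_put(cache, lkey, labels, max_items = 64L, prefix = "l:")
  }
  seg <- clusters_from_labels(labels, stack, as.integer(smin))
  cache_put(cache, key, seg, max_items = 256L, prefix = "s:")
  seg
}

cache_put <- function(cache, key, value, max_items, prefix) {
  keys <- grep(prefix, ls(cache), fixed = TRUE, value = TRUE)
  if (length(keys) >= max_items) rm(list = keys[1], envir = cache)
  assign(key, value, envir = cache)
}
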