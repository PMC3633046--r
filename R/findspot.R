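#' Segmentation parameters
#'
#' @param th global intensity threshold; a voxel enters a cluster iff its
#'   intensity is `>= th` (inclusive, so `th` is the minimum admitted
#'   intensity).
#' @param smin minimum cluster size: a cut on the total 3D voxel count of a
#'   contiguous cluster, not on per-slice areas.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(th, smin = 1L) {
  th <- as.numeric(th); smin <- as.integer(smin)
  if (length(th) != 1L || !is.finite(th) || th < 0) stop("th must be >= 0")
  if (length(smin) != 1L || is.na(smin) || smin < 1L) stop("smin must be >= 1")
  structure(list(th = th, smin = smin), class = "segmentation_params")
}

#' Number of histogram bins used for per-slice region histograms
#'
#' 64 bins spanning the dtype range keep the Bhattacharyya distance stable
#' on small regions.
#' @keywords internal
GC_HIST_BINS <- 64L

region_histogram <- function(values, maxval, nbins = GC_HIST_BINS) {
  bin <- pmin(floor(values * (nbins / (maxval + 1))), nbins - 1L) + 1L
  tabulate(bin, nbins)
}

#' Extract contiguous bright 3D clusters (spot finding)
#'
#' Labels every maximal connected component of `{voxels >= th}` (default
#' 26-neighbourhood, i.e. clustering in all xyz directions including
#' diagonals), discards components smaller than `smin` voxels, and
#' decomposes each surviving cluster into its per-slice regions, areas and
#' intensity histograms.  Clusters are returned largest first, ties broken
#' by the lexicographically smallest member voxel `(z, y, x)`.
#'
#' @param stack an [image_stack()].
#' @param params a [segmentation_params()].
#' @param connectivity 26 (default) or 6.
#' @return A list of `spot_cluster` objects.  Each has `index`, `voxels`
#'   (n x 3 integer matrix of `(z, y, x)`, sorted), `linear_idx`, `size`,
#'   `slices`, `slice_areas` (named by slice), `slice_regions` (named list
#'   of `(y, x)` matrices) and `slice_hists` (named list of length-64 count
#'   vectors).  The list carries the stack dimensions and `maxval` as
#'   attributes.
#' @export
segment_spots <- function(stack, params, connectivity = 26L) {
  validate_stack(stack)
  stopifnot(inherits(params, "segmentation_params"))
  labels <- label_components_cpp(stack$voxels, dim(stack$voxels),
                                 params$th, as.integer(connectivity))
  clusters_from_labels(labels, stack, params$smin)
}

# shared by segment_spots and by the label-cache path in the optimizer
clusters_from_labels <- function(labels, stack, smin) {
  d <- dim(labels)
  maxval <- max_intensity(stack)
  idx <- which(labels > 0L)
  out <- list()
  if (length(idx)) {
    labs <- labels[idx]
    sizes <- tabulate(labs)
    keep <- which(sizes >= smin)
    if (length(keep)) {
      groups <- split(idx, labs)[as.character(keep)]
      # deterministic order: largest first, ties by the lexicographically
      # smallest member voxel in (z, y, x)
      keys <- t(vapply(groups, function(g) {
        co <- arrayInd(g, d)
        o <- order(co[, 1], co[, 2], co[, 3])[1]
        co[o, ]
      }, integer(3)))
      sz <- lengths(groups)
      ord <- order(-sz, keys[, 1], keys[, 2], keys[, 3])
      groups <- groups[ord]
      out <- vector("list", length(groups))
      for (j in seq_along(groups)) {
        g <- sort(groups[[j]])
        co <- arrayInd(g, d)
        colnames(co) <- c("z", "y", "x")
        oz <- order(co[, 1], co[, 2], co[, 3])
        co <- co[oz, , drop = FALSE]
        g <- g[oz]
        vals <- stack$voxels[g]
        sl <- split(seq_len(nrow(co)), co[, 1])
        slices <- as.integer(names(sl))
        regions <- lapply(sl, function(rr) co[rr, c("y", "x"), drop = FALSE])
        hists <- lapply(sl, function(rr) region_histogram(vals[rr], maxval))
        areas <- vapply(sl, length, integer(1))
        out[[j]] <- structure(
          list(index = j, voxels = co, linear_idx = g, size = nrow(co),
               slices = slices, slice_areas = areas,
               slice_regions = regions, slice_hists = hists),
          class = "spot_cluster")
      }
    }
  }
  attr(out, "dims") <- d
  attr(out, "maxval") <- maxval
  out
}

#' @export
print.spot_cluster <- function(x, ...) {
  cat(sprintf("<spot_cluster #%d> %d voxels, slices %d..%d\n",
              x$index, x$size, min(x$slices), max(x$slices)))
  invisible(x)
}

#' Fraction of above-threshold pixels in an annular region
#'
#' Diagnostic for whether a segmentation border has strayed outside the dark
#' halo that surrounds a GC: counts the pixels of `outer \ inner` on one
#' slice whose intensity is `>= th` (`N_f`) against the total annulus size
#' (`N_t`).  A well-placed border has a small fraction, because the halo is
#' darker than the threshold.
#'
#' @param stack an [image_stack()].
#' @param inner,outer two-column `(y, x)` pixel matrices with
#'   `inner` a subset of `outer`.
#' @param th intensity threshold.
#' @param slice z index of the slice the regions live on.
#' @return A list with `N_f`, `N_t` and `fraction` (`0` when `N_t == 0`).
#' @export
halo_fraction <- function(stack, inner, outer, th, slice) {
  validate_stack(stack)
  inner <- as_region(inner); outer <- as_region(outer)
  ki <- region_key(inner); ko <- region_key(outer)
  if (!all(ki %in% ko)) stop("`inner` must be a subset of `outer`")
  ann <- outer[!(ko %in% ki), , drop = FALSE]
  N_t <- nrow(ann)
  if (N_t == 0L) return(list(N_f = 0L, N_t = 0L, fraction = 0))
  vals <- stack$voxels[cbind(slice, ann[, 1], ann[, 2])]
  N_f <- sum(vals >= th)
  list(N_f = N_f, N_t = N_t, fraction = N_f / N_t)
}

as_region <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop("a slice region must be a 2-column (y, x) matrix")
  storage.mode(m) <- "integer"
  m
}

region_key <- function(m) paste(m[, 1], m[, 2], sep = ",")
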