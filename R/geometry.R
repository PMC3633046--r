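#' Convex hull of a per-slice segmentation region
#'
#' @param region two-column `(y, x)` matrix of pixel coordinates (non-empty).
#' @param spacing optional `(dx, dy)` pixel calibration in micrometres used
#'   for `area_um2`.
#' @return A list of class `slice_contour` with `hull_points` (ordered
#'   `(y, x)` polygon vertices, counter-clockwise), `area_px` (shoelace
#'   polygon area of the hull through the pixel centers; degenerate
#'   collinear/single-pixel regions report their pixel count instead) and
#'   `area_um2`.
#' @export
slice_hull <- function(region, spacing = c(1, 1)) {
  region <- as_region(region)
  if (nrow(region) == 0L) stop("empty region has no hull")
  pts <- unique(region)
  if (nrow(pts) == 1L) {
    hull <- pts
  } else {
    h <- grDevices::chull(pts[, 2], pts[, 1])  # (x, y) args
    hull <- pts[h, , drop = FALSE]
    hull <- orient_ccw(hull)
  }
  a <- polygon_area(hull)
  area_px <- if (a == 0) nrow(pts) else a
  structure(list(hull_points = hull, area_px = area_px,
                 area_um2 = area_px * spacing[1] * spacing[2]),
            class = "slice_contour")
}

# shoelace area of an (y, x) polygon
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 2]; y <- p[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

orient_ccw <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(p)
  x <- p[, 2]; y <- p[, 1]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s < 0) p[n:1, , drop = FALSE] else p
}

#' Remove outlier contour points
#'
#' Points much farther out than the bulk of the contour (staining artifacts
#' near a GC) distort hulls and volumes.  The default heuristic computes
#' every point's distance to the geometric center and drops those exceeding
#' `mean + k * sd` of the center distances.  The `"pairwise"` variant flags
#' a point when its mean distance to all other points exceeds `mean + k *
#' sd` of all pairwise distances.  At most 20% of the points are removed in
#' one pass; sets of fewer than 3 points are returned unchanged.
#'
#' @param points two-column `(y, x)` coordinate matrix.
#' @param k sigma multiplier (default 2).
#' @param method `"center"` (default) or `"pairwise"`.
#' @param max_remove_frac cap on the fraction removed per pass.
#' @return The filtered point matrix.
#' @export
prune_outliers <- function(points, k = 2, method = c("center", "pairwise"),
                           max_remove_frac = 0.2) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) return(points)
  if (method == "center") {
    ctr <- colMeans(points)
    d <- sqrt(rowSums(sweep(points, 2, ctr)^2))
    cut <- mean(d) + k * sd(d)
    score <- d
  } else {
    dm <- as.matrix(stats::dist(points))
    all_d <- dm[upper.tri(dm)]
    cut <- mean(all_d) + k * sd(all_d)
    score <- rowSums(dm) / (n - 1)
  }
  out <- which(score > cut)
  limit <- floor(max_remove_frac * n)
  if (length(out) > limit)
    out <- out[order(score[out], decreasing = TRUE)][seq_len(limit)]
  if (length(out) == 0L) return(points)
  points[-out, , drop = FALSE]
}

#' Quantitative report for one segmented cluster
#'
#' @param cluster a `spot_cluster` from [segment_spots()].
#' @param spacing `(dx, dy, dz)` voxel calibration in micrometres.
#' @return A list of class `gc_report` with `gc_index`, `voxel_count`,
#'   `volume_um3` (`voxel_count * dx * dy * dz`), `slice_span`
#'   (first and last z), `slice_areas_px`, `bbox` (named z/y/x min/max) and
#'   `centroid_um` (voxel centers at `(index - 0.5) * spacing`).
#' @export
gc_report <- function(cluster, spacing = c(1, 1, 1.43)) {
  stopifnot(inherits(cluster, "spot_cluster"))
  co <- cluster$voxels
  vol <- cluster$size * prod(spacing)
  centroid <- c(x = (mean(co[, "x"]) - 0.5) * spacing[1],
                y = (mean(co[, "y"]) - 0.5) * spacing[2],
                z = (mean(co[, "z"]) - 0.5) * spacing[3])
  bbox <- c(z_min = min(co[, "z"]), z_max = max(co[, "z"]),
            y_min = min(co[, "y"]), y_max = max(co[, "y"]),
            x_min = min(co[, "x"]), x_max = max(co[, "x"]))
  structure(list(gc_index = cluster$index, voxel_count = cluster$size,
                 volume_um3 = vol,
                 slice_span = c(first = min(cluster$slices),
                                last = max(cluster$slices)),
                 slice_areas_px = cluster$slice_areas,
                 bbox = bbox, centroid_um = centroid),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  cat(sprintf("<gc_report #%d> %d voxels = %.2f um^3, slices %d..%d\n",
              x$gc_index, x$voxel_count, x$volume_um3,
              x$slice_span["first"], x$slice_span["last"]))
  invisible(x)
}

report_row <- function(rep) {
  data.frame(gc_id = rep$gc_index, voxels = rep$voxel_count,
             volume_um3 = rep$volume_um3,
             z_first = rep$slice_span[["first"]],
             z_last = rep$slice_span[["last"]],
             bbox_y_min = rep$bbox[["y_min"]], bbox_y_max = rep$bbox[["y_max"]],
             bbox_x_min = rep$bbox[["x_min"]], bbox_x_max = rep$bbox[["x_max"]],
             centroid_x_um = rep$centroid_um[["x"]],
             centroid_y_um = rep$centroid_um[["y"]],
             centroid_z_um = rep$centroid_um[["z"]])
}

#' Build a closed polygon surface for a cluster by lofting slice hulls
#'
#' Consecutive per-slice convex hulls are stitched into triangulated side
#' walls, with triangle-fan caps closing the first and last slices; a
#' single-slice cluster becomes a flat prism of thickness `dz`.  Vertices
#' are voxel centers in micrometres (`(index - 0.5) * spacing`).  Slices
#' whose hull is degenerate (one pixel, or collinear pixels) are represented
#' by the corner ring of their pixel bounding boxes so that the loft stays
#' a closed 2-manifold.
#'
#' @param cluster a `spot_cluster`.
#' @param spacing `(dx, dy, dz)` calibration in micrometres.
#' @return A list of class `surface_mesh` with `vertices` (n x 3 matrix of
#'   `(x, y, z)` um) and `faces` (list of 1-based vertex-index triangles).
#' @export
build_surface <- function(cluster, spacing = c(1, 1, 1.43)) {
  stopifnot(inherits(cluster, "spot_cluster"))
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  rings <- lapply(cluster$slices, function(n) {
    reg <- cluster$slice_regions[[as.character(n)]]
    ring <- ring_points(reg)
    cbind(x = (ring[, 2] - 0.5) * dx, y = (ring[, 1] - 0.5) * dy,
          z = (n - 0.5) * dz)
  })
  if (length(rings) == 1L) {
    top <- rings[[1]]; bot <- rings[[1]]
    bot[, 3] <- bot[, 3] - dz / 2
    top[, 3] <- top[, 3] + dz / 2
    rings <- list(bot, top)
  }
  verts <- do.call(rbind, rings)
  offs <- cumsum(c(0L, vapply(rings, nrow, integer(1))))
  faces <- list()
  for (i in seq_len(length(rings) - 1L)) {
    faces <- c(faces, zip_rings(rings[[i]], rings[[i + 1]],
                                offs[i], offs[i + 1]))
  }
  faces <- c(faces, ring_cap(rings[[1]], offs[1], reverse = TRUE),
             ring_cap(rings[[length(rings)]], offs[length(rings)],
                      reverse = FALSE))
  structure(list(vertices = verts, faces = faces), class = "surface_mesh")
}

# CCW ring of representative boundary points for a slice region; degenerate
# regions fall back to the half-pixel corner ring of their bounding box
ring_points <- function(reg) {
  pts <- unique(as_region(reg))
  if (nrow(pts) >= 3L) {
    h <- grDevices::chull(pts[, 2], pts[, 1])
    hull <- orient_ccw(pts[h, , drop = FALSE])
    if (polygon_area(hull) > 0) return(hull)
  }
  ymin <- min(pts[, 1]) - 0.5; ymax <- max(pts[, 1]) + 0.5
  xmin <- min(pts[, 2]) - 0.5; xmax <- max(pts[, 2]) + 0.5
  cbind(c(ymin, ymin, ymax, ymax), c(xmin, xmax, xmax, xmin))
}

# triangulate the wall between two CCW rings by merging on polar angle
zip_rings <- function(r1, r2, off1, off2) {
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 == 1L) {
    return(lapply(seq_len(n2), function(j)
      c(off1 + 1L, off2 + j, off2 + (j %% n2) + 1L)))
  }
  if (n2 == 1L) {
    return(lapply(seq_len(n1), function(i)
      c(off2 + 1L, off1 + (i %% n1) + 1L, off1 + i)))
  }
  # parameterize each ring by angle about its own centroid (equals its
  # cyclic hull order for convex rings)
  ang <- function(r) {
    ctr <- colMeans(r[, 1:2, drop = FALSE])
    atan2(r[, 2] - ctr[2], r[, 1] - ctr[1])
  }
  a1 <- ang(r1); a2 <- ang(r2)
  o1 <- order(a1); o2 <- order(a2)
  s1 <- a1[o1]; s2 <- a2[o2]
  faces <- vector("list", n1 + n2)
  i <- 1L; j <- 1L; c1 <- 0L; c2 <- 0L; f <- 0L
  nxt <- function(s, k, n, c) if (c >= n - 1L) Inf else s[k %% n + 1L]
  while (c1 < n1 || c2 < n2) {
    adv1 <- if (c1 >= n1) FALSE
            else if (c2 >= n2) TRUE
            else nxt(s1, i, n1, c1) <= nxt(s2, j, n2, c2)
    f <- f + 1L
    if (adv1) {
      i2 <- i %% n1 + 1L
      faces[[f]] <- c(off1 + o1[i], off2 + o2[j], off1 + o1[i2])
      i <- i2; c1 <- c1 + 1L
    } else {
      j2 <- j %% n2 + 1L
      faces[[f]] <- c(off1 + o1[i], off2 + o2[j], off2 + o2[j2])
      j <- j2; c2 <- c2 + 1L
    }
  }
  faces[seq_len(f)]
}

ring_cap <- function(ring, off, reverse = FALSE) {
  n <- nrow(ring)
  if (n < 3L) return(list())
  idx <- lapply(2:(n - 1L), function(i) {
    tri <- c(off + 1L, off + i, off + i + 1L)
    if (reverse) rev(tri) else tri
  })
  idx
}
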