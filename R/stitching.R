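#' Register an overlapping tile pair by Fourier phase correlation
#'
#' Computes the normalized cross-power spectrum of one representative
#' z-slice of each tile (by default the slice of `tile_a` with maximal
#' variance) and returns the integer translation of `tile_b`'s origin in
#' `tile_a`'s pixel frame at the correlation peak, searched within
#' `prior +/- window`.  Registration is per-stack — the offset of the
#' representative slice is applied to all slices, consistent with a rigid
#' stage translation — and integer-pixel only.
#'
#' @param tile_a,tile_b two [image_stack()] tiles with equal z-dimension.
#' @param prior `(dy, dx)` expected offset (e.g. from stage positions).
#' @param window scalar or `(wy, wx)`: search half-width around the prior.
#' @param z optional z-slice index used for registration.
#' @param peak_floor peak scores below this value flag the result as low
#'   confidence.
#' @return A list of class `registration_result` with `offset` (integer
#'   `(dy, dx)`), `peak_score` in `[0, 1]` and `low_confidence`.
#' @export
register_pair <- function(tile_a, tile_b, prior = c(0L, 0L), window = 32L,
                          z = NULL, peak_floor = 0.05) {
  validate_stack(tile_a); validate_stack(tile_b)
  da <- dim(tile_a$voxels); db <- dim(tile_b$voxels)
  if (da[1] != db[1]) stop("tiles must share the z dimension")
  prior <- as.integer(round(prior))
  if (length(window) == 1L) window <- c(window, window)
  # expected overlap given the prior must be usable
  ov_y <- min(da[2], prior[1] + db[2], da[2] - prior[1], db[2])
  ov_x <- min(da[3], prior[2] + db[3], da[3] - prior[2], db[3])
  need_y <- min(16L, da[2], db[2])
  need_x <- min(16L, da[3], db[3])
  if (ov_y < need_y || ov_x < need_x)
    stop("overlap region implied by the prior is too small to register")
  if (is.null(z)) {
    v <- vapply(seq_len(da[1]), function(n) var(as.numeric(tile_a$voxels[n, , ])),
                numeric(1))
    z <- which.max(v)
  }
  ny <- max(da[2], db[2]); nx <- max(da[3], db[3])
  a <- matrix(0, ny, nx); b <- matrix(0, ny, nx)
  a[seq_len(da[2]), seq_len(da[3])] <- tile_a$voxels[z, , ]
  b[seq_len(db[2]), seq_len(db[3])] <- tile_b$voxels[z, , ]
  r <- phase_corr_surface(a, b)
  dys <- seq(prior[1] - window[1], prior[1] + window[1])
  dxs <- seq(prior[2] - window[2], prior[2] + window[2])
  iy <- (dys %% ny) + 1L
  ix <- (dxs %% nx) + 1L
  sub <- r[iy, ix, drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  offset <- c(dys[w[1]], dxs[w[2]])
  score <- max(min(max(sub), 1), 0)
  structure(list(offset = as.integer(offset), peak_score = score,
                 low_confidence = score < peak_floor),
            class = "registration_result")
}

# inverse-FFT of the normalized cross-power spectrum; peak at index o+1
# (modulo dims) when b's content equals a's translated by o
phase_corr_surface <- function(a, b) {
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  cp <- cp / pmax(Mod(cp), 1e-12)
  Re(stats::fft(cp, inverse = TRUE)) / length(cp)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> offset (dy, dx) = (%d, %d), peak %.3f%s\n",
              x$offset[1], x$offset[2], x$peak_score,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Register and assemble a set of overlapping tiles into a mosaic
#'
#' Tile positions start from the stage-position priors; each tile after the
#' first is refined by phase correlation against the already-placed tile
#' with which it shares the largest prior overlap.  When the correlation
#' peak falls below the confidence floor the prior is kept as a fallback
#' (with a warning).  The refined layout is then blended with
#' [blend_mosaic()].
#'
#' @param tiles list of [image_stack()] tiles sharing spacing and z-dim.
#' @param priors n x 2 integer matrix of `(dy, dx)` tile origins relative to
#'   tile 1 (stage positions in pixels).
#' @param window search half-width passed to [register_pair()].
#' @param peak_floor confidence floor for accepting a registration.
#' @return A list with `mosaic` (an [image_stack()]) and `layout`, a
#'   data.frame with columns tile, y, x, gain, peak_score.
#' @export
stitch_tiles <- function(tiles, priors, window = 16L, peak_floor = 0.05) {
  n <- length(tiles)
  if (n < 2L) stop("stitching requires at least 2 tiles")
  priors <- matrix(as.integer(round(priors)), ncol = 2)
  if (nrow(priors) != n) stop("need one (dy, dx) prior per tile")
  pos <- priors
  peaks <- rep(NA_real_, n)
  for (k in 2:n) {
    # reference: placed tile with largest prior overlap
    best_ref <- 1L; best_ov <- -Inf
    dk <- dim(tiles[[k]]$voxels)
    for (r in 1:(k - 1)) {
      dr <- dim(tiles[[r]]$voxels)
      rel <- priors[k, ] - pos[r, ]
      ovy <- min(dr[2], rel[1] + dk[2]) - max(0, rel[1])
      ovx <- min(dr[3], rel[2] + dk[3]) - max(0, rel[2])
      ov <- max(ovy, 0) * max(ovx, 0)
      if (ov > best_ov) { best_ov <- ov; best_ref <- r }
    }
    rel_prior <- priors[k, ] - pos[best_ref, ]
    reg <- tryCatch(
      register_pair(tiles[[best_ref]], tiles[[k]], prior = rel_prior,
                    window = window, peak_floor = peak_floor),
      error = function(e) NULL)
    if (is.null(reg) || reg$low_confidence) {
      warning(sprintf("tile %d: registration confidence below floor; using stage prior", k))
      pos[k, ] <- pos[best_ref, ] + rel_prior
      peaks[k] <- if (is.null(reg)) NA_real_ else reg$peak_score
    } else {
      pos[k, ] <- pos[best_ref, ] + reg$offset
      peaks[k] <- reg$peak_score
    }
  }
  bl <- blend_mosaic(tiles, pos)
  layout <- data.frame(tile = seq_len(n), y = pos[, 1], x = pos[, 2],
                       gain = bl$gains, peak_score = peaks)
  list(mosaic = bl$mosaic, layout = layout)
}

#' Blend placed tiles into a single mosaic stack
#'
#' Tiles are placed at integer positions; each tile after the first is
#' pre-scaled by a single multiplicative gain factor (the ratio of overlap
#' means against the already-built canvas, matching exposure differences).
#' Overlap regions are blended with a multiresolution (Laplacian-style)
#' pyramid whose depth is `floor(log2(overlap width))` capped at 4, with a
#' linear feather fallback for overlaps narrower than 16 px.  Pixels
#' covered by a single tile equal their (gain-scaled) source exactly.
#'
#' @param tiles list of [image_stack()] tiles.
#' @param positions n x 2 integer matrix of `(dy, dx)` tile origins
#'   (relative to any common frame).
#' @return A list with `mosaic` (an [image_stack()]) and `gains`.
#' @export
blend_mosaic <- function(tiles, positions) {
  n <- length(tiles)
  stopifnot(n >= 1L)
  positions <- matrix(as.integer(round(positions)), ncol = 2)
  nz <- dim(tiles[[1]]$voxels)[1]
  for (t in tiles) if (dim(t$voxels)[1] != nz)
    stop("all tiles must share the z dimension")
  positions[, 1] <- positions[, 1] - min(positions[, 1])
  positions[, 2] <- positions[, 2] - min(positions[, 2])
  ny <- max(vapply(seq_len(n), function(k)
    positions[k, 1] + dim(tiles[[k]]$voxels)[2], integer(1)))
  nx <- max(vapply(seq_len(n), function(k)
    positions[k, 2] + dim(tiles[[k]]$voxels)[3], integer(1)))
  canvas <- array(0, dim = c(nz, ny, nx))
  filled <- matrix(FALSE, ny, nx)
  gains <- rep(1, n)
  for (k in seq_len(n)) {
    d <- dim(tiles[[k]]$voxels)
    ys <- positions[k, 1] + seq_len(d[2])
    xs <- positions[k, 2] + seq_len(d[3])
    tile <- tiles[[k]]$voxels
    ov_mask <- filled[ys, xs, drop = FALSE]
    if (k > 1L && any(ov_mask)) {
      ov3 <- rep(ov_mask, each = nz)  # recycle mask over z
      m_canvas <- mean(canvas[, ys, xs][ov3])
      m_tile <- mean(tile[ov3])
      if (m_tile > 0) gains[k] <- m_canvas / m_tile
    }
    tile <- tile * gains[k]
    if (!any(ov_mask)) {
      canvas[, ys, xs] <- tile
    } else {
      blended <- blend_overlap(canvas[, ys, xs, drop = FALSE], tile,
                               ov_mask, filled, ys, xs)
      # overlap pixels take the blend; fresh pixels take the tile exactly
      out <- canvas[, ys, xs, drop = FALSE]
      for (zz in seq_len(nz)) {
        sl <- out[zz, , ]
        tl <- tile[zz, , ]
        bl <- blended[zz, , ]
        sl[!ov_mask] <- tl[!ov_mask]
        sl[ov_mask] <- bl[ov_mask]
        out[zz, , ] <- sl
      }
      canvas[, ys, xs] <- out
    }
    filled[ys, xs] <- TRUE
  }
  maxv <- max_intensity(tiles[[1]])
  vox <- array(as.integer(pmin(pmax(round(canvas), 0), maxv)),
               dim = dim(canvas))
  list(mosaic = image_stack(vox, spacing = tiles[[1]]$spacing,
                            bits = tiles[[1]]$bits),
       gains = gains)
}

# blend canvas patch A against tile patch B over the overlap mask; weights
# feather from the overlap geometry (distance into tile vs into canvas)
blend_overlap <- function(A, B, ov_mask, filled, ys, xs) {
  nz <- dim(A)[1]
  tile_mask <- matrix(TRUE, nrow(ov_mask), ncol(ov_mask))
  canvas_mask <- filled[ys, xs, drop = FALSE]
  d_tile <- chamfer_interior_cpp(tile_mask)
  d_canvas <- chamfer_interior_cpp(canvas_mask)
  wB <- d_tile / pmax(d_tile + d_canvas, 1e-12)
  wB[!canvas_mask] <- 1
  ov_w <- sum(apply(ov_mask, 2, any))
  ov_h <- sum(apply(ov_mask, 1, any))
  depth <- if (min(ov_w, ov_h) < 16L) 0L
           else min(4L, floor(log2(min(ov_w, ov_h))))
  out <- A
  for (zz in seq_len(nz)) {
    a <- A[zz, , ]; b <- B[zz, , ]
    # where only one source exists, make both layers agree so the pyramid
    # cannot bleed undefined content into the overlap
    a[!canvas_mask] <- b[!canvas_mask]
    out[zz, , ] <- if (depth == 0L) (1 - wB) * a + wB * b
                   else pyramid_blend(a, b, wB, depth)
  }
  out
}

pyr_down <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% 2L) { m <- rbind(m, m[nr, ]); nr <- nr + 1L }
  if (nc %% 2L) { m <- cbind(m, m[, nc]); nc <- nc + 1L }
  (m[seq(1, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(1, nc, 2), drop = FALSE] +
   m[seq(1, nr, 2), seq(2, nc, 2), drop = FALSE] +
   m[seq(2, nr, 2), seq(2, nc, 2), drop = FALSE]) / 4
}

pyr_up <- function(m, dims) {
  u <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2),
         drop = FALSE]
  u[seq_len(dims[1]), seq_len(dims[2]), drop = FALSE]
}

# Laplacian-pyramid blend; exactly reconstructing (nearest-neighbour
# up/down pair), so identical inputs come back unchanged
pyramid_blend <- function(a, b, w, depth) {
  GA <- list(a); GB <- list(b); GW <- list(w)
  for (l in seq_len(depth)) {
    GA[[l + 1]] <- pyr_down(GA[[l]])
    GB[[l + 1]] <- pyr_down(GB[[l]])
    GW[[l + 1]] <- pyr_down(GW[[l]])
  }
  top <- (1 - GW[[depth + 1]]) * GA[[depth + 1]] + GW[[depth + 1]] * GB[[depth + 1]]
  out <- top
  for (l in depth:1) {
    dims <- dim(GA[[l]])
    LA <- GA[[l]] - pyr_up(GA[[l + 1]], dims)
    LB <- GB[[l]] - pyr_up(GB[[l + 1]], dims)
    out <- (1 - GW[[l]]) * LA + GW[[l]] * LB + pyr_up(out, dims)
  }
  out
}
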