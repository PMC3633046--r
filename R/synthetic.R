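#' Describe one synthetic germinal center
#'
#' @param center numeric `(z, y, x)` center in voxel coordinates.
#' @param semiaxes numeric `(az, ay, ax)` ellipsoid semi-axes in voxels
#'   (each >= 1).
#' @param plateau plateau intensity of the fluorescent interior.
#' @return A list used inside [phantom_spec()].
#' @export
gc_blob <- function(center, semiaxes, plateau = 200) {
  stopifnot(length(center) == 3L, length(semiaxes) == 3L)
  if (any(semiaxes < 1)) stop("semi-axes must be >= 1 voxel")
  list(center = as.numeric(center), semiaxes = as.numeric(semiaxes),
       plateau = as.numeric(plateau))
}

#' Specification of a germinal-center phantom
#'
#' The phantom emulates the canonical stained-GC morphology: a bright,
#' homogeneous ellipsoidal plateau of labelled B cells, surrounded by a dark
#' ring of unlabelled follicular/T-zone cells (the halo), embedded in
#' moderately bright tissue background, with additive Gaussian read noise
#' clipped to the dtype range.  Intensities must satisfy
#' `plateau > background > halo >= 0`.
#'
#' @param shape integer `(nz, ny, nx)` stack dimensions.
#' @param gcs list of [gc_blob()] objects; the blobs (including halos) must
#'   be pairwise disjoint and inside the stack.
#' @param halo_intensity intensity of the dark ring (default 10).
#' @param halo_thickness ring thickness in voxels added to each semi-axis
#'   (default 3).
#' @param background tissue background intensity (default 80).
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (default 5).
#' @param bits bit depth of the generated stack.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, gcs, halo_intensity = 10, halo_thickness = 3,
                         background = 80, noise_sigma = 5, bits = 8L,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, is.list(gcs), length(gcs) >= 1L)
  plateaus <- vapply(gcs, function(g) g$plateau, numeric(1))
  if (!(all(plateaus > background) && background > halo_intensity &&
        halo_intensity >= 0))
    stop("need plateau > background > halo_intensity >= 0")
  structure(list(shape = as.integer(shape), gcs = gcs,
                 halo_intensity = halo_intensity,
                 halo_thickness = halo_thickness,
                 background = background, noise_sigma = noise_sigma,
                 bits = as.integer(bits), seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical mask of voxel centers inside the ellipsoid (implicit equation),
# evaluated on the full grid
ellipsoid_mask <- function(shape, center, semiaxes) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  fz <- ((seq_len(nz) - center[1]) / semiaxes[1])^2
  fy <- ((seq_len(ny) - center[2]) / semiaxes[2])^2
  fx <- ((seq_len(nx) - center[3]) / semiaxes[3])^2
  q <- outer(outer(fz, fy, `+`), fx, `+`)
  q <= 1
}

#' Generate a germinal-center phantom with ground truth
#'
#' Voxels start at the background intensity, are overwritten by the halo
#' ring and then the ellipsoid plateau of each GC, and finally receive
#' zero-mean Gaussian noise clipped to the dtype range.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` (an [image_stack()]), and `truth`, a
#'   list with `labels` (3D integer array, 0 = background, j = voxels of GC
#'   j) and `true_volumes_vox` (analytic ellipsoid volumes `4/3*pi*az*ay*ax`
#'   in voxel units).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  vox <- array(spec$background, dim = shape)
  labels <- array(0L, dim = shape)
  painted <- array(FALSE, dim = shape)
  for (j in seq_along(spec$gcs)) {
    g <- spec$gcs[[j]]
    halo <- ellipsoid_mask(shape, g$center, g$semiaxes + spec$halo_thickness)
    core <- ellipsoid_mask(shape, g$center, g$semiaxes)
    if (any(painted & halo))
      stop("overlapping GCs (including halos) are not allowed")
    painted <- painted | halo
    vox[halo & !core] <- spec$halo_intensity
    vox[core] <- g$plateau
    labels[core] <- j
  }
  if (spec$noise_sigma > 0) {
    vox <- with_seed(spec$seed, {
      vox + rnorm(length(vox), mean = 0, sd = spec$noise_sigma)
    })
  }
  maxv <- bitwShiftL(1L, spec$bits) - 1L
  vox <- array(pmin(pmax(round(vox), 0), maxv), dim = shape)
  true_vols <- vapply(spec$gcs, function(g) 4 / 3 * pi * prod(g$semiaxes),
                      numeric(1))
  list(stack = image_stack(vox, bits = spec$bits),
       truth = list(labels = labels, true_volumes_vox = true_vols))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cut a pair of overlapping tiles out of a base stack
#'
#' Produces two same-size crops of `base` that share an overlap strip along
#' x.  The second tile's crop window is the nominal side-by-side position
#' displaced by `shift = (dy, dx)`, its intensities are multiplied by `gain`,
#' and independent Gaussian noise is added.  This is the standard fixture
#' for testing registration and blending: the true offset of tile B relative
#' to tile A is `nominal + shift`.
#'
#' @param base an [image_stack()] wide enough for two tiles plus margins.
#' @param shift integer `(dy, dx)` displacement from the nominal layout.
#' @param overlap nominal overlap fraction of the tile width, in (0, 1).
#' @param gain multiplicative exposure factor applied to tile B.
#' @param noise_sigma additive Gaussian noise sd applied to tile B.
#' @param seed RNG seed for the noise.
#' @return A list with `tile_a`, `tile_b` (both [image_stack()]),
#'   `true_shift = shift`, and `nominal`, the nominal `(dy, dx)` offset of
#'   tile B in tile A's frame (so the true full offset is
#'   `nominal + true_shift`).
#' @export
make_tile_pair <- function(base, shift = c(0L, 0L), overlap = 0.3, gain = 1,
                           noise_sigma = 0, seed = 1L) {
  validate_stack(base)
  if (overlap <= 0 || overlap >= 1) stop("overlap must be in (0, 1)")
  shift <- as.integer(round(shift))
  d <- dim(base$voxels)
  nz <- d[1]
  w <- as.integer(d[3] %/% 2)
  ov <- as.integer(round(overlap * w))
  if (abs(shift[2]) >= ov)
    stop("overlap region too small for the requested x shift")
  s <- w - ov  # nominal x offset of tile B
  h <- d[2] - abs(shift[1])
  if (h < 8L) stop("base stack too short in y for the requested y shift")
  xb <- s + 1L + shift[2]
  if (xb < 1L || xb + w - 1L > d[3])
    stop("base stack too narrow for the requested layout")
  ya <- if (shift[1] >= 0) 1L else 1L - shift[1]
  yb <- ya + shift[1]
  a <- base$voxels[, ya:(ya + h - 1L), 1:w, drop = FALSE]
  b <- base$voxels[, yb:(yb + h - 1L), xb:(xb + w - 1L), drop = FALSE]
  b <- b * gain
  if (noise_sigma > 0)
    b <- with_seed(seed, b + rnorm(length(b), sd = noise_sigma))
  maxv <- max_intensity(base)
  b <- array(pmin(pmax(round(b), 0), maxv), dim = dim(b))
  list(tile_a = image_stack(a, spacing = base$spacing, bits = base$bits),
       tile_b = image_stack(b, spacing = base$spacing, bits = base$bits),
       true_shift = shift,
       nominal = c(0L, s))
}
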