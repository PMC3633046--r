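#' Calibrated single-channel image stack
#'
#' The basic container of the package: a 3D array of integer intensities in
#' `(z, y, x)` order together with the physical voxel calibration.  A voxel
#' at index `(z, y, x)` (1-based) spans a physical box of size
#' `(dz, dy, dx)` micrometres; all downstream areas and volumes use this
#' convention.
#'
#' @param voxels 3D integer array with dimensions `c(nz, ny, nx)`.
#' @param spacing numeric length-3 vector `c(dx, dy, dz)` in micrometres per
#'   voxel; all components must be strictly positive.  The default z-step of
#'   1.43 um matches a typical confocal acquisition of lymph-node sections.
#' @param channel optional channel label.
#' @param bits bit depth, 8 or 16; intensities must lie in `[0, 2^bits - 1]`.
#' @param origin optional `(x0, y0)` stage position in micrometres, used as a
#'   stitching prior.
#'
#' @return An object of class `image_stack`: a list with elements `voxels`,
#'   `spacing`, `channel`, `bits`, `origin`.
#' @export
image_stack <- function(voxels, spacing = c(1, 1, 1.43), channel = "ch0",
                        bits = 8L, origin = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (z, y, x)")
  storage.mode(voxels) <- "integer"
  stk <- structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         channel = as.character(channel), bits = as.integer(bits),
         origin = origin),
    class = "image_stack")
  validate_stack(stk)
  stk
}

validate_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (any(d < 1L)) stop("all stack dimensions must be >= 1")
  if (length(stack$spacing) != 3L || any(!is.finite(stack$spacing)) ||
      any(stack$spacing <= 0))
    stop("spacing must be three strictly positive numbers (dx, dy, dz)")
  if (!stack$bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  rng <- range(stack$voxels)
  if (rng[1] < 0L || rng[2] > max_intensity(stack))
    stop("intensities must lie in [0, 2^bits - 1]")
  invisible(stack)
}

max_intensity <- function(stack) bitwShiftL(1L, stack$bits) - 1L

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d x %d (z,y,x), %d-bit, channel %s\n",
    d[1], d[2], d[3], x$bits, x$channel))
  cat(sprintf("  spacing (dx,dy,dz): %g x %g x %g um; intensity range %d..%d\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read one channel of a multi-page TIFF z-stack
#'
#' Pages are interpreted as z-slices.  For interleaved multichannel files,
#' page `p` (1-based) belongs to channel `((p - 1) %% n_channels) + 1` and
#' slice `((p - 1) %/% n_channels) + 1`.  Vendor metadata beyond plain page
#' sequences (e.g. OME-XML) is not parsed; calibration comes from the
#' `spacing` argument.
#'
#' @param path path to an 8- or 16-bit grayscale multi-page TIFF.
#' @param channel 1-based channel index to extract.
#' @param n_channels number of interleaved channels in the file.
#' @param spacing,origin passed to [image_stack()].
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel = 1L, n_channels = 1L,
                       spacing = c(1, 1, 1.43), origin = NULL) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) ||
      !file.exists(path))
    stop("cannot read TIFF: file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("unreadable or corrupt TIFF: ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  n_channels <- as.integer(n_channels)
  channel <- as.integer(channel)
  if (n_channels < 1L) stop("n_channels must be >= 1")
  if (channel < 1L || channel > n_channels)
    stop(sprintf("channel %d out of range (file has %d channels)",
                 channel, n_channels))
  if (length(pages) %% n_channels != 0L)
    stop("page count is not a multiple of n_channels")
  sel <- seq(channel, length(pages), by = n_channels)
  slices <- pages[sel]
  if (any(vapply(slices, function(m) length(dim(m)) != 2L, logical(1))))
    stop("only single-sample (grayscale) TIFF pages are supported")
  bits <- attr(slices[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- if (max(unlist(slices)) > 255) 16L else 8L
  nz <- length(slices)
  ny <- nrow(slices[[1]])
  nx <- ncol(slices[[1]])
  vox <- array(0L, dim = c(nz, ny, nx))
  for (n in seq_len(nz)) vox[n, , ] <- as.integer(slices[[n]])
  image_stack(vox, spacing = spacing, channel = sprintf("ch%d", channel - 1L),
              bits = as.integer(bits), origin = origin)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Round trip through [read_stack()] reproduces the voxels bit-exactly for
#' both 8- and 16-bit stacks.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  validate_stack(stack)
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("invalid output path")
  maxv <- max_intensity(stack)
  nz <- dim(stack$voxels)[1]
  pages <- lapply(seq_len(nz), function(n) stack$voxels[n, , ] / maxv)
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bits,
                    compression = "none"),
    error = function(e) stop("cannot write TIFF: ", conditionMessage(e)))
  invisible(path)
}

#' Write a cluster label volume as a 16-bit TIFF (0 = background)
#'
#' @param labels 3D integer array of cluster labels, dim `c(nz, ny, nx)`.
#' @param path output path.
#' @param spacing voxel calibration recorded on the intermediate stack.
#' @export
write_labels <- function(labels, path, spacing = c(1, 1, 1.43)) {
  stk <- image_stack(labels, spacing = spacing, channel = "labels",
                     bits = 16L)
  write_stack(stk, path)
}
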