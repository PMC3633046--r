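# Independent brute-force oracles and fixture builders used across tests.

# Pure-R BFS flood fill over {vox >= th}; deliberately independent of the
# package's C++ labelling (different language, different traversal).
bf_label <- function(vox, th, connectivity = 26) {
  d <- dim(vox)
  nb <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dz == 0 & nb$dy == 0 & nb$dx == 0), ]
  if (connectivity == 6)
    nb <- nb[abs(nb$dz) + abs(nb$dy) + abs(nb$dx) == 1, ]
  lab <- array(0L, d)
  cur <- 0L
  fg <- which(vox >= th)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      co <- arrayInd(i, d)
      for (r in seq_len(nrow(nb))) {
        z <- co[1] + nb$dz[r]; y <- co[2] + nb$dy[r]; x <- co[3] + nb$dx[r]
        if (z < 1 || z > d[1] || y < 1 || y > d[2] || x < 1 || x > d[3]) next
        j <- z + d[1] * ((y - 1) + d[2] * (x - 1))
        if (lab[j] == 0L && vox[j] >= th) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# canonical partition of foreground voxels: sorted list of sorted index sets
partition_of <- function(lab, smin = 1L) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  groups <- split(idx, lab[idx])
  groups <- groups[lengths(groups) >= smin]
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, numeric(1), 1))]
}

partition_of_clusters <- function(seg) {
  groups <- lapply(seg, function(cl) sort(cl$linear_idx))
  groups[order(vapply(groups, `[`, numeric(1), 1))]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

segmentation_mask <- function(seg, dims) {
  m <- array(FALSE, dims)
  for (cl in seg) m[cl$linear_idx] <- TRUE
  m
}

# a small spot_cluster-shaped object built by hand for objective tests
fake_cluster <- function(slices, areas, hists) {
  names(areas) <- as.character(slices)
  names(hists) <- as.character(slices)
  structure(list(index = 1L, voxels = NULL, linear_idx = integer(0),
                 size = sum(areas), slices = as.integer(slices),
                 slice_areas = areas, slice_regions = NULL,
                 slice_hists = hists),
            class = "spot_cluster")
}

uniform_hist <- function(mass = 10, nbins = 64L) {
  h <- numeric(nbins)
  h[1:4] <- mass
  h
}

# the standard test phantom: one GC with the canonical intensities
small_phantom <- function(shape = c(16, 64, 64), noise_sigma = 5, seed = 1L,
                          semiaxes = c(5, 12, 12)) {
  make_phantom(phantom_spec(
    shape = shape,
    gcs = list(gc_blob(center = shape / 2, semiaxes = semiaxes,
                       plateau = 200)),
    halo_intensity = 10, background = 80,
    noise_sigma = noise_sigma, seed = seed))
}
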