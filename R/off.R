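#' Write a polygon surface in OFF (Geomview Object File Format)
#'
#' Standard layout: an `OFF` header line, a `V F E` counts line, `V` vertex
#' coordinate lines, then `F` face lines each starting with its vertex
#' count followed by 0-based vertex indices.
#'
#' @param mesh a `surface_mesh` from [build_surface()].
#' @param path output path.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0L || length(mesh$faces) == 0L)
    stop("cannot write an empty mesh")
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("invalid output path")
  nv <- nrow(mesh$vertices)
  nf <- length(mesh$faces)
  ne <- n_mesh_edges(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nv, nf, ne), con)
  writeLines(sprintf("%.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(vapply(mesh$faces, function(f)
    paste(c(length(f), f - 1L), collapse = " "), character(1)), con)
  invisible(path)
}

#' Read an OFF polygon surface
#'
#' @param path path to an OFF file.
#' @return A `surface_mesh` (vertices in file order, 1-based face indices).
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (trimws(ln[1]) != "OFF") stop("not an OFF file: missing header")
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  verts <- t(vapply(ln[2 + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3]), numeric(3)))
  rownames(verts) <- NULL
  colnames(verts) <- c("x", "y", "z")
  faces <- lapply(ln[2 + nv + seq_len(nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    v[1 + seq_len(v[1])] + 1L
  })
  structure(list(vertices = verts, faces = faces), class = "surface_mesh")
}

# number of distinct undirected edges in a face list
n_mesh_edges <- function(mesh) {
  e <- do.call(rbind, lapply(mesh$faces, function(f) {
    cbind(f, c(f[-1], f[1]))
  }))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  length(unique(key))
}

#' Euler characteristic of a surface mesh (V - E + F)
#'
#' Equals 2 for a watertight genus-0 surface.
#' @param mesh a `surface_mesh`.
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - n_mesh_edges(mesh) + length(mesh$faces)
}
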