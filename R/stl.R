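# Binary STL export/import (little-endian, 80-byte header).

#' Export a cell design as a binary STL mesh
#'
#' Builds the watertight mesh of the printed solid with
#' [design_mesh()] and writes a little-endian binary STL. A
#' non-watertight mesh is a hard failure (it would not slice).
#'
#' @param design A [cell_design()] (or a prebuilt `cell_mesh`).
#' @param path Output file path.
#' @param facet_count Target facet count (>= 64), passed to
#'   [design_mesh()].
#' @return Invisibly, the written mesh.
#' @export
export_stl <- function(design, path, facet_count = 5000) {
  mesh <- if (inherits(design, "cell_mesh")) design else design_mesh(design, facet_count)
  if (!mesh_is_watertight(mesh)) {
    stop("refusing to export a non-watertight mesh")
  }
  write_stl_binary(mesh, path)
  invisible(mesh)
}

#' Read/write binary STL
#'
#' Minimal binary STL I/O: 80-byte header, uint32 facet count, then per
#' facet a float32 normal, three float32 vertices and a uint16
#' attribute. `read_stl()` returns the triangle soup as a `cell_mesh`
#' (vertices are not merged, which is sufficient for volume and
#' round-trip checks).
#'
#' @param mesh A `cell_mesh`.
#' @param path File path.
#' @return `read_stl()`: a `cell_mesh`.
#' @export
write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("nmrcell binary STL", width = -80))
  writeBin(header[1:80], con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # interleave: per facet 12 float32 then the uint16 attribute
  block <- cbind(nrm, a, b, c3)  # n x 12
  fl <- writeBin(as.numeric(t(block)), raw(), size = 4, endian = "little")
  rec <- rbind(matrix(fl, nrow = 48), matrix(as.raw(0), nrow = 2, ncol = n))
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' @rdname write_stl_binary
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rest <- readBin(con, "raw", n * 50)
  # each 50-byte record: 12 float32 + uint16
  rec <- matrix(rest, nrow = 50)
  fl <- readBin(as.raw(rec[1:48, ]), "numeric", n * 12, size = 4,
                endian = "little")
  m <- matrix(fl, ncol = 12, byrow = TRUE)
  verts <- matrix(0, nrow = 3 * n, ncol = 3)
  verts[seq(1, 3 * n, 3), ] <- m[, 4:6, drop = FALSE]
  verts[seq(2, 3 * n, 3), ] <- m[, 7:9, drop = FALSE]
  verts[seq(3, 3 * n, 3), ] <- m[, 10:12, drop = FALSE]
  faces <- matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)
  new_mesh(verts, faces)
}
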