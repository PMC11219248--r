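# Minimal ASCII PLY / STL mesh I/O (units mm).  Only the subset needed for
# triangle surface meshes is supported.

#' Write a mesh as ASCII PLY
#'
#' @param mesh A [femur_mesh()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    sprintf("comment side %s units mm", mesh$side),
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#'
#' @param path File path.
#' @param side Side label; if `NULL`, recovered from the comment line written
#'   by [write_ply()] (default `"right"` when absent).
#' @return A [femur_mesh()].
#' @export
read_ply <- function(path, side = NULL) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated")
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header))) {
    stop("only ascii PLY is supported")
  }
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  if (is.null(side)) {
    cm <- grep("^comment side ", header, value = TRUE)
    side <- if (length(cm)) strsplit(cm[1], " ")[[1]][3] else "right"
  }
  body <- lines[(end + 1L):length(lines)]
  verts <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = body[nv + seq_len(nf)], quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle faces are supported")
  femur_mesh(verts, fl[, 2:4] + 1L, side)
}

#' Write a mesh as ASCII STL
#'
#' STL stores no connectivity or side metadata; prefer PLY for round trips.
#'
#' @param mesh A [femur_mesh()].
#' @param path Output file path.
#' @param name Solid name written in the header.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "femur") {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  body <- sprintf(paste0(
    "facet normal %.6e %.6e %.6e\n outer loop\n",
    "  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n  vertex %.6e %.6e %.6e\n",
    " endloop\nendfacet"),
    n[, 1], n[, 2], n[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
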