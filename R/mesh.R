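#' Triangulated surface mesh
#'
#' Container for the triangulated geometry on which all per-vertex
#' computation runs: a flattened 2-D cortical patch (`kind = "flat"`,
#' z-coordinates all zero), a common spherical registration surface
#' (`kind = "sphere"`, every vertex at `radius_mm` from the origin), or a
#' generic folded surface (`kind = "folded"`).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param kind one of `"flat"`, `"sphere"`, `"folded"`.
#' @param radius_mm sphere radius in mm; required when `kind = "sphere"`
#'   (the common-surface convention is 100 mm).
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `kind`, `radius_mm`.
#' @export
surface_mesh <- function(vertices, faces, kind = c("flat", "sphere", "folded"),
                         radius_mm = NULL) {
  kind <- match.arg(kind)
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex indices")
  n <- nrow(vertices)
  if (n < 3L) stop("a mesh needs at least 3 vertices")
  if (any(faces < 1L) || any(faces > n)) {
    stop("faces index vertices outside 1..", n)
  }
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3])) {
    stop("degenerate faces (repeated vertex within a triangle)")
  }
  if (kind == "flat" && any(abs(vertices[, 3]) > 1e-9)) {
    stop("flat meshes must have all z-coordinates equal to 0")
  }
  if (kind == "sphere") {
    if (is.null(radius_mm)) stop("radius_mm is required for kind = 'sphere'")
    r <- sqrt(rowSums(vertices^2))
    if (any(abs(r - radius_mm) > 1e-6 * radius_mm)) {
      stop("sphere vertices must lie within 1e-6*radius of the sphere")
    }
  } else if (is.null(radius_mm)) {
    radius_mm <- NA_real_
  }
  structure(list(vertices = vertices, faces = faces, kind = kind,
                 radius_mm = radius_mm),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh: %d vertices, %d faces, kind=%s%s>\n",
              nrow(x$vertices), nrow(x$faces), x$kind,
              if (x$kind == "sphere") sprintf(", radius=%g mm", x$radius_mm)
              else ""))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

#' Per-face triangle areas
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of face areas in mm^2 (one per face), computed as
#'   half the norm of the edge cross product.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh surface area
#'
#' @param mesh a [surface_mesh()].
#' @return total surface area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Vertex adjacency (1-ring neighbourhoods)
#'
#' @param mesh a [surface_mesh()].
#' @return list of integer vectors; element `i` holds the sorted vertex
#'   indices sharing an edge with vertex `i`.
#' @export
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  to <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  adj <- split(to, from)
  out <- vector("list", n_vertices(mesh))
  for (nm in names(adj)) out[[as.integer(nm)]] <- sort(unique(adj[[nm]]))
  idx <- vapply(out, is.null, logical(1))
  out[idx] <- list(integer(0))
  out
}

# Connected components of a vertex subset under mesh adjacency.
# Returns a list of integer vectors (each one component).
vertex_components <- function(adjacency, subset) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(list())
  in_set <- logical(length(adjacency))
  in_set[subset] <- TRUE
  visited <- logical(length(adjacency))
  comps <- list()
  for (s in subset) {
    if (visited[s]) next
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[in_set[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read and write meshes as ASCII PLY
#'
#' Meshes round trip losslessly through ASCII PLY; the `kind` flag and sphere
#' radius are stored as `comment somatomap` header lines so the file remains
#' readable by any PLY tool.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `read_mesh_ply` returns a [surface_mesh()]; `write_mesh_ply`
#'   returns `path` invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- n_vertices(mesh)
  m <- nrow(mesh$faces)
  header <- c(
    "ply",
    "format ascii 1.0",
    sprintf("comment somatomap kind=%s", mesh$kind),
    if (!is.na(mesh$radius_mm))
      sprintf("comment somatomap radius_mm=%s", fmt_num(mesh$radius_mm)),
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", m),
    "property list uchar int vertex_indices",
    "end_header")
  vlines <- apply(mesh$vertices, 1L, function(r) paste(fmt_num(r), collapse = " "))
  # file indices are 0-based (PLY convention)
  flines <- apply(mesh$faces - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' @rdname write_mesh_ply
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop("malformed PLY at line 1: expected 'ply' magic in ", path)
  }
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop("malformed PLY: no end_header in ", path)
  header <- trimws(lines[seq_len(hdr_end)])
  kind <- "folded"
  radius <- NULL
  nv <- nf <- NA_integer_
  for (i in seq_along(header)) {
    h <- header[[i]]
    if (startsWith(h, "comment somatomap kind=")) {
      kind <- sub("comment somatomap kind=", "", h)
    } else if (startsWith(h, "comment somatomap radius_mm=")) {
      radius <- as.numeric(sub("comment somatomap radius_mm=", "", h))
    } else if (startsWith(h, "element vertex ")) {
      nv <- as.integer(sub("element vertex ", "", h))
    } else if (startsWith(h, "element face ")) {
      nf <- as.integer(sub("element face ", "", h))
    }
  }
  if (is.na(nv) || is.na(nf)) stop("malformed PLY: missing element counts in ", path)
  body <- lines[-seq_len(hdr_end)]
  if (length(body) < nv + nf) stop("malformed PLY: truncated body in ", path)
  vert <- matrix(NA_real_, nv, 3L)
  for (i in seq_len(nv)) {
    xs <- suppressWarnings(as.numeric(strsplit(trimws(body[[i]]), "\\s+")[[1]]))
    if (length(xs) < 3L || anyNA(xs[1:3])) {
      stop("malformed PLY at line ", hdr_end + i, ": bad vertex row")
    }
    vert[i, ] <- xs[1:3]
  }
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    xs <- suppressWarnings(as.integer(strsplit(trimws(body[[nv + i]]), "\\s+")[[1]]))
    if (length(xs) < 1L || is.na(xs[1])) {
      stop("malformed PLY at line ", hdr_end + nv + i, ": bad face row")
    }
    if (xs[1] != 3L) {
      stop("unsupported format: non-triangular face (", xs[1],
           " vertices) at line ", hdr_end + nv + i)
    }
    faces[i, ] <- xs[2:4] + 1L
  }
  surface_mesh(vert, faces, kind = kind, radius_mm = radius)
}
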