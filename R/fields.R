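#' Per-vertex data field
#'
#' One value per mesh vertex: a scalar (e.g. F-ratio), an angle in radians in
#' `[0, 2*pi)` (e.g. response phase), a complex response coefficient, or a
#' 2-D vector (e.g. a phase gradient; flat meshes only).
#'
#' @param values numeric vector (scalar/angle), complex vector, or n x 2
#'   numeric matrix (`kind = "vector2d"`).
#' @param kind one of `"scalar"`, `"angle"`, `"complex"`, `"vector2d"`.
#' @param mesh optional [surface_mesh()] the field lives on; when supplied the
#'   vertex count is validated (and must be flat for `vector2d`).
#' @return object of class `vertex_field` with elements `values`, `kind`,
#'   `n_vertices`.
#' @export
vertex_field <- function(values, kind = c("scalar", "angle", "complex", "vector2d"),
                         mesh = NULL) {
  kind <- match.arg(kind)
  if (kind == "vector2d") {
    values <- as.matrix(values)
    if (ncol(values) != 2L) stop("vector2d fields need an n x 2 matrix")
    n <- nrow(values)
  } else {
    if (kind == "complex") values <- as.complex(values) else values <- as.numeric(values)
    n <- length(values)
  }
  if (kind == "angle") {
    ok <- is.na(values) | (values >= 0 & values < 2 * pi)
    if (!all(ok)) stop("angle fields must lie in [0, 2*pi)")
  }
  if (!is.null(mesh)) {
    if (n != n_vertices(mesh)) {
      stop("field has ", n, " values but mesh has ", n_vertices(mesh), " vertices")
    }
    if (kind == "vector2d" && mesh$kind != "flat") {
      stop("vector2d fields are only defined on flat meshes")
    }
  }
  structure(list(values = values, kind = kind, n_vertices = n),
            class = "vertex_field")
}

#' @export
print.vertex_field <- function(x, ...) {
  cat(sprintf("<vertex_field: %d vertices, kind=%s>\n", x$n_vertices, x$kind))
  invisible(x)
}

#' Read and write per-vertex fields as CSV
#'
#' The file has a `# somatomap field kind=<kind>` first line, then a header
#' and one row per vertex with a 0-based `vertex_index` column. Complex
#' fields are stored as `re`,`im` columns and 2-D vector fields as `gx`,`gy`;
#' values are written with 17 significant digits so round trips are exact.
#'
#' @param field a [vertex_field()].
#' @param path file path.
#' @param mesh optional mesh used to validate the vertex count on read.
#' @return `read_field_csv` returns a [vertex_field()]; `write_field_csv`
#'   returns `path` invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "vertex_field"))
  idx <- seq_len(field$n_vertices) - 1L
  df <- switch(field$kind,
    scalar = data.frame(vertex_index = idx, value = field$values),
    angle = data.frame(vertex_index = idx, value = field$values),
    complex = data.frame(vertex_index = idx, re = Re(field$values),
                         im = Im(field$values)),
    vector2d = data.frame(vertex_index = idx, gx = field$values[, 1],
                          gy = field$values[, 2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# somatomap field kind=%s", field$kind), con)
  writeLines(paste(names(df), collapse = ","), con)
  num <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(format(df[i, 1]),
            fmt_num(as.numeric(df[i, -1, drop = FALSE]))), collapse = ",")
  }, character(1))
  writeLines(num, con)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path, mesh = NULL) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# somatomap field kind=", first)) {
    stop("not a somatomap field CSV (missing kind header): ", path)
  }
  kind <- sub("^# somatomap field kind=", "", first)
  df <- utils::read.csv(path, skip = 1L)
  values <- switch(kind,
    scalar = df$value,
    angle = df$value,
    complex = complex(real = df$re, imaginary = df$im),
    vector2d = cbind(gx = df$gx, gy = df$gy),
    stop("unknown field kind '", kind, "' in ", path))
  vertex_field(values, kind = kind, mesh = mesh)
}

#' Region-of-interest label
#'
#' A set of mesh vertices, e.g. the hand-map ROI cut from all vertices with a
#' significant periodic response. A label can be explicitly flagged `missing`
#' to represent hemispheres where no significant map was found; downstream
#' measures propagate the flag instead of failing.
#'
#' @param vertex_indices integer vector of 1-based vertex indices (unique).
#' @param mesh optional mesh to validate indices against.
#' @param missing logical; `TRUE` marks an absent map (indices must be empty).
#' @return object of class `roi_label` with `vertex_indices` and `missing`.
#' @export
roi_label <- function(vertex_indices = integer(0), mesh = NULL, missing = FALSE) {
  vertex_indices <- as.integer(vertex_indices)
  if (anyDuplicated(vertex_indices)) stop("duplicate vertex indices in label")
  if (any(vertex_indices < 1L)) stop("vertex indices must be >= 1")
  if (!is.null(mesh) && length(vertex_indices) &&
        max(vertex_indices) > n_vertices(mesh)) {
    stop("label indexes vertex ", max(vertex_indices),
         " but mesh has only ", n_vertices(mesh), " vertices")
  }
  if (missing && length(vertex_indices)) {
    stop("a missing label cannot carry vertex indices")
  }
  if (!missing && !length(vertex_indices)) {
    stop("empty label: pass missing = TRUE for an explicitly absent map")
  }
  structure(list(vertex_indices = sort(vertex_indices), missing = missing),
            class = "roi_label")
}

#' @export
print.roi_label <- function(x, ...) {
  if (x$missing) cat("<roi_label: missing map>\n")
  else cat(sprintf("<roi_label: %d vertices>\n", length(x$vertex_indices)))
  invisible(x)
}

#' Read and write ROI labels
#'
#' ASCII format mirroring FreeSurfer label files: a `#!` comment line
#' (carrying the missing-map flag), a count line, then one 0-based vertex
#' index per line.
#'
#' @param label an [roi_label()].
#' @param path file path.
#' @param mesh optional mesh used to validate indices on read.
#' @return `read_label` returns an [roi_label()]; `write_label` returns
#'   `path` invisibly.
#' @export
write_label <- function(label, path) {
  stopifnot(inherits(label, "roi_label"))
  lines <- c(sprintf("#!ascii label, somatomap roi (missing=%d)",
                     as.integer(label$missing)),
             as.character(length(label$vertex_indices)),
             as.character(label$vertex_indices - 1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_label
#' @export
read_label <- function(path, mesh = NULL) {
  lines <- trimws(readLines(path))
  if (!length(lines) || !startsWith(lines[[1]], "#!")) {
    stop("malformed label file (missing #! header): ", path)
  }
  missing <- grepl("missing=1", lines[[1]], fixed = TRUE)
  count <- as.integer(lines[[2]])
  idx <- as.integer(lines[-(1:2)])
  idx <- idx[!is.na(idx)]
  if (length(idx) != count) {
    stop("label count line says ", count, " but file has ", length(idx), " indices")
  }
  roi_label(idx + 1L, mesh = mesh, missing = missing)
}
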