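#' ROI surface area
#'
#' Surface area of a map ROI: the summed area of faces whose three vertices
#' all belong to the ROI. A missing ROI propagates as `NA`.
#'
#' @param mesh a [surface_mesh()].
#' @param roi an [roi_label()].
#' @return area in mm^2 (`NA` for a missing map).
#' @export
roi_area <- function(mesh, roi) {
  stopifnot(inherits(roi, "roi_label"))
  if (roi$missing) return(NA_real_)
  if (length(roi$vertex_indices) && max(roi$vertex_indices) > n_vertices(mesh)) {
    stop("ROI references vertices beyond this mesh")
  }
  inr <- logical(n_vertices(mesh))
  inr[roi$vertex_indices] <- TRUE
  f <- mesh$faces
  keep <- inr[f[, 1]] & inr[f[, 2]] & inr[f[, 3]]
  sum(face_areas(mesh)[keep])
}

#' Spherical centroid of a map ROI
#'
#' Centroid of the ROI on the common spherical surface: the (by default
#' area-weighted) mean of the ROI vertex positions, renormalized to unit
#' length. Vertex weights are one third of the summed areas of adjacent
#' faces, the usual barycentric lumping.
#'
#' @param mesh a [surface_mesh()] with `kind = "sphere"`.
#' @param roi an [roi_label()].
#' @param weighted logical; `FALSE` uses the unweighted vertex mean.
#' @return object of class `spherical_centroid`: `direction` (unit
#'   3-vector), `radius_mm`. `NA` direction for a missing map.
#' @export
spherical_centroid <- function(mesh, roi, weighted = TRUE) {
  stopifnot(inherits(roi, "roi_label"))
  if (mesh$kind != "sphere") stop("centroids are defined on spherical meshes")
  if (roi$missing) {
    return(structure(list(direction = rep(NA_real_, 3),
                          radius_mm = mesh$radius_mm, missing = TRUE),
                     class = "spherical_centroid"))
  }
  idx <- roi$vertex_indices
  if (max(idx) > n_vertices(mesh)) stop("ROI references vertices beyond this mesh")
  w <- if (weighted) {
    fa <- face_areas(mesh)
    vw <- numeric(n_vertices(mesh))
    for (k in 1:3) {
      acc <- tapply(fa, mesh$faces[, k], sum)
      vw[as.integer(names(acc))] <- vw[as.integer(names(acc))] + acc / 3
    }
    vw[idx]
  } else rep(1, length(idx))
  m <- colSums(mesh$vertices[idx, , drop = FALSE] * w) / sum(w)
  nrm <- sqrt(sum(m^2))
  if (nrm < 1e-9 * mesh$radius_mm) {
    stop("degenerate centroid: ROI mean vector has near-zero norm")
  }
  structure(list(direction = m / nrm, radius_mm = mesh$radius_mm,
                 missing = FALSE),
            class = "spherical_centroid")
}

as_direction_matrix <- function(x) {
  if (inherits(x, "fisher_sample")) return(x$directions)
  if (is.list(x) && !is.matrix(x) && !is.data.frame(x)) {
    x <- do.call(rbind, lapply(x, function(d) {
      if (inherits(d, "spherical_centroid")) d$direction else as.numeric(d)
    }))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("directions must be n x 3")
  x[stats::complete.cases(x), , drop = FALSE]
}

#' Resultant length of a directional sample
#'
#' Norm of the vector sum of unit direction vectors; `R = n` for perfectly
#' aligned samples, near 0 for balanced/dispersed ones.
#'
#' @param directions n x 3 matrix of unit vectors, a [sample_fisher()]
#'   result, or a list of [spherical_centroid()]s.
#' @return `R >= 0`.
#' @export
resultant_length <- function(directions) {
  d <- as_direction_matrix(directions)
  sqrt(sum(colSums(d)^2))
}

#' Watson F test for equal mean direction of two spherical samples
#'
#' Two-sample directional comparison based on the Fisher distribution on
#' the sphere: with group resultant lengths `R1`, `R2` and pooled resultant
#' `R`,
#' `F = (N - 2) * (R1 + R2 - R) / (N - R1 - R2)` with `N = N1 + N2`,
#' referred to the F distribution with df (2, 2(N-2)). Larger F means more
#' different group mean directions. A Bayes factor for the contrast is
#' attached via [bf_from_f()].
#'
#' @param group1,group2 directional samples (see [resultant_length()] for
#'   accepted forms); at least 2 observations each.
#' @param bf_p0 the H1 calibration tail level passed to [bf_from_f()].
#' @return object of class `watson_f`: `N1, N2, R1, R2, R, F, df, p, BF10`.
#' @export
watson_f_test <- function(group1, group2, bf_p0 = 0.05) {
  d1 <- as_direction_matrix(group1)
  d2 <- as_direction_matrix(group2)
  n1 <- nrow(d1); n2 <- nrow(d2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  r1 <- resultant_length(d1)
  r2 <- resultant_length(d2)
  r <- resultant_length(rbind(d1, d2))
  n <- n1 + n2
  denom <- n - r1 - r2
  if (denom <= 1e-12) {
    stop("degenerate dispersion: all vectors identical within groups")
  }
  f <- (n - 2) * (r1 + r2 - r) / denom
  f <- max(f, 0)
  df <- c(2, 2 * (n - 2))
  structure(list(N1 = n1, N2 = n2, R1 = r1, R2 = r2, R = r, F = f, df = df,
                 p = f_to_p(f, df[1], df[2]),
                 BF10 = bf_from_f(f, df[1], df[2], p0 = bf_p0)),
            class = "watson_f")
}

#' @export
print.watson_f <- function(x, ...) {
  cat(sprintf("Watson F test: F(%d,%d) = %.4g, p = %.4g, BF10 = %.4g\n",
              x$df[1], x$df[2], x$F, x$p, x$BF10))
  invisible(x)
}

#' Upper-tail probability of the F distribution
#'
#' Exact survival function of the central F distribution; for `df1 = 2`
#' this equals the closed form `(1 + 2*F/df2)^(-df2/2)`.
#'
#' @param f observed F statistic (>= 0).
#' @param df1,df2 degrees of freedom.
#' @return `P(F(df1, df2) >= f)`.
#' @export
f_to_p <- function(f, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be positive")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

#' Bayes factor from an F statistic
#'
#' Converts an F statistic into an evidence ratio `BF10` for the presence of
#' an effect against the point null. The default calibration is a
#' likelihood-ratio Bayes factor that pins the alternative at the critical
#' effect size of a tail test at level `p0`: the null likelihood is the
#' central F density at the observed statistic and the alternative
#' likelihood is the noncentral F density with noncentrality
#' `ncp = df1 * qf(1 - p0, df1, df2)`. By the monotone-likelihood-ratio
#' property of the noncentral F family, `BF10` is increasing in F at fixed
#' df. The reciprocal identity `BF10 = 1 / BF01` holds exactly.
#'
#' @param f observed F statistic (>= 0).
#' @param df1,df2 degrees of freedom (> 0).
#' @param p0 tail level fixing the H1 calibration point (default 0.05).
#' @return `BF10` (> 0).
#' @export
bf_from_f <- function(f, df1, df2, p0 = 0.05) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be positive")
  if (any(f < 0)) stop("F must be >= 0")
  ncp <- df1 * stats::qf(1 - p0, df1, df2)
  l1 <- stats::df(f, df1, df2, ncp = ncp)
  l0 <- stats::df(f, df1, df2)
  l1 / l0
}

#' Geodesic distance between points on the common sphere
#'
#' Great-circle distance `radius * acos(a . b)` between two unit direction
#' vectors, e.g. a map centroid and a reference point in the concavity of
#' the central sulcus.
#'
#' @param a,b unit 3-vectors or [spherical_centroid()]s.
#' @param radius_mm sphere radius (defaults to 100 mm or the centroid's).
#' @return distance in mm (`NA` if either point is missing).
#' @export
geodesic_distance <- function(a, b, radius_mm = NULL) {
  get_dir <- function(x) if (inherits(x, "spherical_centroid")) x$direction else {
    x <- as.numeric(x); x / sqrt(sum(x^2))
  }
  if (is.null(radius_mm)) {
    radius_mm <- if (inherits(a, "spherical_centroid")) a$radius_mm else 100
  }
  va <- get_dir(a); vb <- get_dir(b)
  if (anyNA(va) || anyNA(vb)) return(NA_real_)
  radius_mm * acos(min(1, max(-1, sum(va * vb))))
}
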