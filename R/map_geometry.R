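#' Nearest-neighbour smoothing of complex surface data
#'
#' Gentle smoothing of per-vertex complex response values: each step
#' replaces every value by the uniform mean over the vertex and its 1-ring
#' neighbours. The operation is linear and preserves constant fields. When
#' `steps` is `NULL` the step count is chosen so the accumulated kernel
#' width approximates `kernel_mm` FWHM at the patch's edge-length
#' resolution (at least one step), and is reported via an attribute.
#'
#' @param mesh a [surface_mesh()].
#' @param values complex (or numeric) vector, one value per vertex.
#' @param steps number of averaging iterations (>= 0), or `NULL` to derive
#'   from `kernel_mm`.
#' @param kernel_mm target FWHM in mm used when `steps` is `NULL`.
#' @return smoothed vector, with attribute `steps`.
#' @export
smooth_complex <- function(mesh, values, steps = NULL, kernel_mm = 1.5) {
  if (length(values) != n_vertices(mesh)) {
    stop("values length does not match mesh vertex count")
  }
  adj <- mesh_adjacency(mesh)
  if (is.null(steps)) {
    # per-step per-axis kernel variance of uniform {self + 1-ring} averaging
    v <- mesh$vertices
    s2 <- mean(vapply(seq_along(adj), function(i) {
      nb <- adj[[i]]
      if (!length(nb)) return(0)
      d2 <- rowSums((v[nb, , drop = FALSE] -
                       matrix(v[i, ], length(nb), 3, byrow = TRUE))^2)
      sum(d2) / (2 * (length(nb) + 1))
    }, numeric(1)))
    steps <- max(1L, round((kernel_mm / (2 * sqrt(2 * log(2))))^2 / s2))
  }
  if (steps < 0) stop("steps must be >= 0")
  out <- values
  for (s in seq_len(steps)) {
    out <- vapply(seq_along(adj), function(i) {
      mean(out[c(i, adj[[i]])])
    }, out[1])
  }
  attr(out, "steps") <- steps
  out
}

#' Plane-fit phase gradients on a flat patch
#'
#' Per ROI vertex, computes the 2-D spatial gradient of the phase angle by
#' least-squares fitting a plane through the neighbouring phase values,
#' taking care to circularly subtract the angular data: neighbour phase
#' differences relative to the centre vertex are wrapped to `(-pi, pi]`
#' before the fit, so the gradient is invariant to where the phase wraps.
#' When an ROI is given, only in-ROI neighbours enter the fit (vertices
#' outside the map carry no meaningful phase), and vertices with fewer than
#' 3 usable non-collinear neighbours are flagged undefined. Gradient
#' magnitudes are normalized to a maximum of 1 within the ROI.
#'
#' @param patch a flat [surface_mesh()].
#' @param phase numeric vector of phases (radians), one per vertex, or a
#'   `phase_map`.
#' @param roi an [roi_label()]; defaults to all vertices.
#' @param neighbourhood ring order of the fitted neighbourhood (1 = 1-ring).
#' @return object of class `gradient_field`: `gradient` (n x 2, rad/mm, `NA`
#'   where undefined), `direction` (`[0, 2*pi)`), `magnitude`,
#'   `norm_magnitude`, `vertices` (ROI indices with defined gradients).
#' @export
phase_gradient <- function(patch, phase, roi = NULL, neighbourhood = 1L) {
  if (patch$kind != "flat") stop("phase gradients are defined on flat patches")
  if (inherits(phase, "phase_map")) phase <- phase$phase
  if (length(phase) != n_vertices(patch)) {
    stop("phase length does not match mesh vertex count")
  }
  idx <- if (is.null(roi)) seq_len(n_vertices(patch)) else {
    if (roi$missing) integer(0) else roi$vertex_indices
  }
  adj <- mesh_adjacency(patch)
  if (neighbourhood > 1L) {
    for (k in seq_len(neighbourhood - 1L)) {
      adj <- lapply(seq_along(adj), function(i) {
        setdiff(sort(unique(c(adj[[i]], unlist(adj[adj[[i]]])))), i)
      })
    }
  }
  n <- n_vertices(patch)
  in_roi <- logical(n)
  in_roi[idx] <- TRUE
  grad <- matrix(NA_real_, n, 2)
  for (i in idx) {
    nb <- adj[[i]]
    nb <- nb[in_roi[nb]]
    if (length(nb) < 3L) next
    dx <- patch$vertices[nb, 1] - patch$vertices[i, 1]
    dy <- patch$vertices[nb, 2] - patch$vertices[i, 2]
    dphi <- (phase[nb] - phase[i] + pi) %% (2 * pi) - pi  # wrap to (-pi, pi]
    X <- cbind(dx, dy)
    XtX <- crossprod(X)
    if (abs(det(XtX)) < 1e-12) next  # collinear neighbourhood
    grad[i, ] <- solve(XtX, crossprod(X, dphi))
  }
  ok <- which(!is.na(grad[, 1]))
  mag <- sqrt(rowSums(grad^2))
  mx <- if (length(ok)) max(mag[ok]) else NA_real_
  structure(list(
    gradient = grad,
    direction = (atan2(grad[, 2], grad[, 1])) %% (2 * pi),
    magnitude = mag,
    norm_magnitude = if (!is.na(mx) && mx > 0) mag / mx else mag,
    vertices = intersect(idx, ok)),
    class = "gradient_field")
}

#' Circular variance of a set of angles
#'
#' `1 - |mean of unit phasors|`; 0 for perfectly aligned angles, 1 for
#' maximally dispersed ones. Used as the per-ROI summary of map-gradient
#' variability.
#'
#' @param angles radians (NAs dropped).
#' @return value in `[0, 1]`.
#' @export
circular_variance <- function(angles) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) return(NA_real_)
  1 - Mod(mean(exp(1i * angles)))
}

circular_mean <- function(angles) {
  angles <- angles[!is.na(angles)]
  Arg(mean(exp(1i * angles))) %% (2 * pi)
}

# Maximum-likelihood concentration estimate for the von Mises distribution
# from the mean resultant length (standard piecewise approximation).
vm_kappa <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Harrison-Kanji two-factor ANOVA for circular data
#'
#' Two-way ANOVA for angular responses under the high-concentration
#' decomposition of Harrison & Kanji (1988), as implemented in standard
#' circular-statistics toolboxes: resultant-based sums of squares for the
#' two main effects, their interaction and the residual, with F statistics
#' scaled by the `1 + 3/(8*kappa)` correction and referred to the F
#' distribution. `kappa` is estimated from the mean within-cell resultant
#' length (so that real factor effects do not masquerade as dispersion); a
#' warning is issued in the low-concentration regime (`kappa < 2`) where
#' the approximation loses power.
#'
#' @param angles angular responses, radians.
#' @param factor1,factor2 crossed factors (e.g. side within subjects and
#'   group between subjects); every cell needs >= 2 observations.
#' @return object of class `harrison_kanji`: a data frame `table` with one
#'   row per effect (`F`, `df1`, `df2`, `p`, `pes` partial eta^2) and the
#'   concentration estimate `kappa`.
#' @export
harrison_kanji <- function(angles, factor1, factor2) {
  f1 <- factor(factor1); f2 <- factor(factor2)
  ok <- !is.na(angles) & !is.na(f1) & !is.na(f2)
  angles <- angles[ok]; f1 <- droplevels(f1[ok]); f2 <- droplevels(f2[ok])
  p <- nlevels(f1); q <- nlevels(f2)
  if (p < 2 || q < 2) stop("both factors need at least 2 levels")
  n_cell <- table(f1, f2)
  if (any(n_cell < 2)) stop("every factor cell needs >= 2 observations")
  n <- length(angles)
  z <- exp(1i * angles)
  R_tot <- Mod(sum(z))
  R_cell <- tapply(z, list(f1, f2), function(v) Mod(sum(v)))
  kappa <- vm_kappa(min(sum(R_cell) / n, 1 - 1e-12))
  if (kappa < 2) {
    warning("low concentration (kappa = ", signif(kappa, 3),
            "): high-kappa Harrison-Kanji approximation is low-powered here")
  }
  R_r <- tapply(z, f1, function(v) Mod(sum(v)))
  R_c <- tapply(z, f2, function(v) Mod(sum(v)))
  n_r <- tabulate(f1, p); n_c <- tabulate(f2, q)
  ss_1 <- sum(R_r^2 / n_r) - R_tot^2 / n
  ss_2 <- sum(R_c^2 / n_c) - R_tot^2 / n
  ss_res <- n - sum(R_cell^2 / n_cell)
  ss_tot <- n - R_tot^2 / n
  ss_int <- ss_tot - ss_1 - ss_2 - ss_res
  df1_ <- p - 1; df2_ <- q - 1; dfi <- df1_ * df2_; dfr <- n - p * q
  beta <- 1 + 3 / (8 * kappa)
  eff <- function(ss, df) {
    f <- beta * (ss / df) / (ss_res / dfr)
    f <- max(f, 0)
    c(F = f, df1 = df, df2 = dfr, p = f_to_p(f, df, dfr),
      pes = max(0, ss) / (max(0, ss) + ss_res))
  }
  tab <- rbind(factor1 = eff(ss_1, df1_), factor2 = eff(ss_2, df2_),
               interaction = eff(ss_int, dfi))
  structure(list(table = as.data.frame(tab), kappa = kappa, n = n),
            class = "harrison_kanji")
}

#' @export
print.harrison_kanji <- function(x, ...) {
  cat(sprintf("Harrison-Kanji circular ANOVA (kappa = %.3g, n = %d)\n",
              x$kappa, x$n))
  print(round(x$table, 4))
  invisible(x)
}

#' Circular-linear correlation
#'
#' Correlation between an angular and a linear variable via the sine and
#' cosine components (Zar's r_cl): with `r_xc = cor(x, cos theta)`,
#' `r_xs = cor(x, sin theta)` and `r_cs = cor(cos theta, sin theta)`,
#' `r_cl = sqrt((r_xc^2 + r_xs^2 - 2 r_xc r_xs r_cs) / (1 - r_cs^2))`.
#' Significance uses the statistic `n * r_cl^2`, referred to the chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param angles radians.
#' @param x linear covariate (non-constant), same length.
#' @return list `r_cl`, `statistic` (`n * r_cl^2`), `p`, `n`.
#' @export
circ_linear_correlation <- function(angles, x) {
  ok <- !is.na(angles) & !is.na(x)
  angles <- angles[ok]; x <- x[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (stats::sd(x) == 0) stop("undefined correlation: linear variable is constant")
  rxc <- stats::cor(x, cos(angles))
  rxs <- stats::cor(x, sin(angles))
  rcs <- stats::cor(cos(angles), sin(angles))
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  r_cl <- sqrt(max(0, min(1, r2)))
  stat <- n * r_cl^2
  list(r_cl = r_cl, statistic = stat,
       p = stats::pchisq(stat, df = 2, lower.tail = FALSE), n = n)
}

#' Map gradient variances to angles for circular ANOVA
#'
#' The per-ROI summary of map-gradient variability is a circular variance in
#' `[0, 1]`, a linear quantity; the Harrison-Kanji test takes angular data.
#' The default analysis pathway feeds per-subject mean gradient directions
#' to [harrison_kanji()]; this helper supports the alternative, literal
#' pathway in which the variances themselves are wrapped onto the circle as
#' `2*pi*v` before testing. Both pathways are exposed because the choice is
#' genuinely ambiguous; see the package vignette.
#'
#' @param variances circular variances in `[0, 1]`.
#' @return angles in `[0, 2*pi)`.
#' @export
variance_to_angle <- function(variances) {
  if (any(variances < 0 | variances > 1, na.rm = TRUE)) {
    stop("circular variances must lie in [0, 1]")
  }
  (2 * pi * variances) %% (2 * pi)
}
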