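#' Regular flat triangulated patch
#'
#' Builds an `nx` x `ny` grid of vertices with the given spacing in the z=0
#' plane, each grid square split into two triangles. Stand-in for a
#' flattened 2-D cortical surface patch.
#'
#' @param nx,ny number of vertices along x and y (>= 2).
#' @param spacing_mm grid spacing, mm (> 0).
#' @return a flat [surface_mesh()] with total area
#'   `(nx-1)*(ny-1)*spacing_mm^2`.
#' @export
make_flat_patch <- function(nx, ny, spacing_mm = 1) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  xy <- expand.grid(x = seq_len(nx) - 1L, y = seq_len(ny) - 1L)
  vertices <- cbind(xy$x * spacing_mm, xy$y * spacing_mm, 0)
  vid <- function(i, j) (j - 1L) * nx + i  # i along x, j along y
  faces <- matrix(0L, 2L * (nx - 1L) * (ny - 1L), 3L)
  k <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      a <- vid(i, j); b <- vid(i + 1L, j)
      c_ <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
      faces[k, ] <- c(a, b, d); faces[k + 1L, ] <- c(a, d, c_)
      k <- k + 2L
    }
  }
  surface_mesh(vertices, faces, kind = "flat")
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected onto
#' the sphere of radius `radius_mm`; stand-in for the average spherical
#' cortical surface (radius convention 100 mm).
#'
#' @param subdivisions nonnegative integer; 0 gives the icosahedron
#'   (12 vertices / 20 faces); each level quadruples the face count.
#' @param radius_mm sphere radius in mm.
#' @return a [surface_mesh()] with `kind = "sphere"`.
#' @export
make_sphere_mesh <- function(subdivisions = 3, radius_mm = 100) {
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      id <- nv + length(newv) + 1L
      newv[[length(newv) + 1L]] <<- (v[a, ] + v[b, ]) / 2
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c_, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  surface_mesh(v, f, kind = "sphere", radius_mm = radius_mm)
}

#' Ground-truth somatotopic phase map on a flat patch
#'
#' Lays a rectangular "hand map" band across the centre of a flat patch. The
#' true response phase increases linearly along `gradient_direction_rad`
#' across the band, spanning the stimulated segment of the cycle (d2 at the
#' leading edge through d5 at the trailing edge); vertices outside the band
#' are non-responsive with amplitude zero. This emulates the orderly spatial
#' gradient of digit preference from index to little finger seen in the S1
#' fingertip map.
#'
#' @param patch a flat [surface_mesh()].
#' @param protocol a [stim_protocol()]; sets the stimulated cycle fraction
#'   and the hemodynamic delay offset folded into the true phases.
#' @param gradient_direction_rad direction of phase increase in the plane
#'   (0 = +x), radians.
#' @param band_length_mm extent of the map along the gradient (phase axis).
#' @param band_width_mm extent perpendicular to the gradient.
#' @param amplitude response amplitude of the responsive band, percent signal.
#' @return object of class `ground_truth_map`: `true_phase` (radians in
#'   `[0, 2*pi)`, per vertex), `responsive_mask` (logical), `amplitude`
#'   (numeric per vertex), plus the generating parameters.
#' @export
ground_truth_phase_map <- function(patch, protocol = stim_protocol(),
                                   gradient_direction_rad = 0,
                                   band_length_mm = 20, band_width_mm = 10,
                                   amplitude = 1) {
  if (patch$kind != "flat") stop("ground-truth maps are built on flat patches")
  v <- patch$vertices
  ctr <- c(mean(range(v[, 1])), mean(range(v[, 2])))
  u <- c(cos(gradient_direction_rad), sin(gradient_direction_rad))
  w <- c(-u[2], u[1])
  du <- (v[, 1] - ctr[1]) * u[1] + (v[, 2] - ctr[2]) * u[2]
  dw <- (v[, 1] - ctr[1]) * w[1] + (v[, 2] - ctr[2]) * w[2]
  ext_u <- diff(range(du)); ext_w <- diff(range(dw))
  if (band_length_mm > ext_u + 1e-9 || band_width_mm > ext_w + 1e-9) {
    stop("band (", band_length_mm, " x ", band_width_mm,
         " mm) exceeds patch extent along the requested direction")
  }
  inside <- abs(du) <= band_length_mm / 2 + 1e-9 &
    abs(dw) <= band_width_mm / 2 + 1e-9
  # phase spans the stimulated segment of the cycle, offset by the
  # hemodynamic delay so downstream finger binning lands on d2..d5
  frac <- (du + band_length_mm / 2) / band_length_mm  # 0..1 along gradient
  span <- 2 * pi * protocol$stim_fraction
  phase <- (protocol$delay_offset_rad + frac * span * 0.999) %% (2 * pi)
  phase[!inside] <- 0
  amp <- ifelse(inside, amplitude, 0)
  structure(list(true_phase = phase, responsive_mask = inside,
                 amplitude = amp, patch = patch, protocol = protocol,
                 gradient_direction_rad = gradient_direction_rad,
                 band_length_mm = band_length_mm,
                 band_width_mm = band_width_mm),
            class = "ground_truth_map")
}

#' Simulate phase-encoded BOLD runs
#'
#' Forward model of the traveling-wave experiment: at each vertex
#' `signal(t) = amplitude * cos(2*pi*f_stim*t - true_phase) +
#' drift_slope * t + N(0, noise_sd)`, sampled on the TR grid of each run.
#' The stimulation clock starts at the first post-dummy volume (the dummy
#' volumes are acquired before it and discarded downstream). Hemodynamics
#' enter only as the constant phase offset already folded into the
#' ground-truth phases.
#'
#' @param truth a [ground_truth_phase_map()].
#' @param protocol a [stim_protocol()].
#' @param noise_sd white-noise SD, percent signal (>= 0).
#' @param drift_slope linear drift, percent signal per second.
#' @param seed RNG seed; simulations are reproducible given
#'   `(seed, parameters)`.
#' @return object of class `bold_runs`: `runs` is a list of
#'   vertices x volumes_per_run matrices.
#' @export
simulate_bold <- function(truth, protocol = truth$protocol, noise_sd = 0.5,
                          drift_slope = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nv <- length(truth$true_phase)
  t_s <- (seq_len(protocol$volumes_per_run) - 1 - protocol$dummy_volumes) *
    protocol$tr_s
  clean <- truth$amplitude *
    cos(sweep(outer(rep(1, nv), 2 * pi * protocol$stim_freq_hz * t_s),
              1, truth$true_phase, "-"))
  set.seed(seed)
  runs <- lapply(seq_len(protocol$n_runs), function(r) {
    clean + rep(drift_slope * t_s, each = nv) +
      matrix(stats::rnorm(nv * length(t_s), sd = noise_sd), nv)
  })
  structure(list(runs = runs, protocol = protocol, noise_sd = noise_sd,
                 drift_slope = drift_slope, seed = seed),
            class = "bold_runs")
}

#' Sample unit vectors from the Fisher distribution on the sphere
#'
#' Draws i.i.d. directions from the Fisher density
#' `f(x) ~ exp(kappa * mu.x)` via the closed-form inverse CDF of the
#' colatitude about `mu` — `cos(theta) = 1 + log(u + (1-u)*exp(-2*kappa)) /
#' kappa` for uniform `u` — and a uniform longitude, then rotates the frame
#' so the pole is `mu`. `kappa = 0` gives the uniform distribution on the
#' sphere.
#'
#' @param mu mean direction, length-3 vector (normalized with a warning if
#'   not unit length).
#' @param kappa concentration, >= 0.
#' @param n number of samples.
#' @param seed RNG seed.
#' @return object of class `fisher_sample`: `directions` (n x 3, unit rows),
#'   `mu`, `kappa`.
#' @export
sample_fisher <- function(mu, kappa, n, seed = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  mu <- as.numeric(mu)
  nrm <- sqrt(sum(mu^2))
  if (nrm == 0) stop("mu must be a nonzero 3-vector")
  if (abs(nrm - 1) > 1e-9) {
    warning("mu is not unit length; normalizing")
  }
  mu <- mu / nrm
  set.seed(seed)
  u <- stats::runif(n)
  if (kappa == 0) {
    w <- 2 * u - 1
  } else {
    # numerically safe form of 1 + log(u + (1-u) e^{-2k})/k
    w <- 1 + (log(u + (1 - u) * exp(-2 * kappa))) / kappa
    w <- pmin(1, pmax(-1, w))
  }
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(phi), s * sin(phi), w)
  # orthonormal frame with e3 = mu
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  dirs <- local %*% rbind(e1, e2, mu)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  structure(list(directions = dirs, mu = mu, kappa = kappa),
            class = "fisher_sample")
}

#' Synthetic clinical table
#'
#' Generates a cohort with the schema of the packaged study table: control
#' ages and patient ages from a common normal distribution, Edinburgh
#' laterality scores from a right-dominant clipped normal, log-normal
#' pressure pain thresholds with a configurable affected-hand deficit
#' (in log-SD units), 0-10 pain ratings for patients, and log-normal disease
#' durations. Patients are split between left- and right-hand CRPS.
#'
#' @param n_controls,n_patients group sizes (>= 2 each).
#' @param effect_config named list overriding any of: `age_mean` (44),
#'   `age_sd` (12), `lat_mean` (75), `lat_sd` (40), `ppt_meanlog` (log 5),
#'   `ppt_sdlog` (0.8), `ppt_deficit_sd` (1; affected-hand log-PPT deficit in
#'   units of `ppt_sdlog`), `pain_mean` (6), `pain_sd` (2),
#'   `duration_meanlog` (log 2.5), `duration_sdlog` (1).
#' @param seed RNG seed.
#' @return a `clinical_table` data frame (validated by the same rules as
#'   [load_clinical_table()]).
#' @export
synth_clinical_table <- function(n_controls, n_patients,
                                 effect_config = list(), seed = 1) {
  if (n_controls < 2 || n_patients < 2) stop("need n >= 2 per group")
  cfg <- utils::modifyList(list(
    age_mean = 44, age_sd = 12, lat_mean = 75, lat_sd = 40,
    ppt_meanlog = log(5), ppt_sdlog = 0.8, ppt_deficit_sd = 1,
    pain_mean = 6, pain_sd = 2,
    duration_meanlog = log(2.5), duration_sdlog = 1), effect_config)
  set.seed(seed)
  n <- n_controls + n_patients
  age <- round(pmin(80, pmax(18, stats::rnorm(n, cfg$age_mean, cfg$age_sd))), 1)
  lat <- round(pmin(100, pmax(-100, stats::rnorm(n, cfg$lat_mean, cfg$lat_sd))), 1)
  gender <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.8, 0.2))
  n_left <- floor(n_patients / 2)
  group <- c(rep("control", n_controls), rep("left-CRPS", n_left),
             rep("right-CRPS", n_patients - n_left))
  is_pat <- group != "control"
  affected_left <- group == "left-CRPS"
  logL <- stats::rnorm(n, cfg$ppt_meanlog, cfg$ppt_sdlog)
  logR <- stats::rnorm(n, cfg$ppt_meanlog, cfg$ppt_sdlog)
  deficit <- cfg$ppt_deficit_sd * cfg$ppt_sdlog
  logL[is_pat & affected_left] <- logL[is_pat & affected_left] - deficit
  logR[is_pat & !affected_left] <- logR[is_pat & !affected_left] - deficit
  pain <- function() {
    x <- numeric(n)
    x[is_pat] <- round(pmin(10, pmax(0, stats::rnorm(sum(is_pat),
                                                     cfg$pain_mean, cfg$pain_sd))))
    x
  }
  dur <- rep(NA_real_, n)
  dur[is_pat] <- round(stats::rlnorm(sum(is_pat), cfg$duration_meanlog,
                                     cfg$duration_sdlog), 1)
  df <- data.frame(
    id = c(paste0("C", seq_len(n_controls)), paste0("P", seq_len(n_patients))),
    group = factor(group, levels = c("control", "left-CRPS", "right-CRPS")),
    age_yr = age, gender = gender, crps_duration_yr = dur,
    pain_scan = pain(), pain_2d = pain(), pain_7d = pain(),
    ppt_left = round(exp(logL), 3), ppt_right = round(exp(logR), 3),
    laterality = lat, disability_score = NA_real_,
    stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}
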