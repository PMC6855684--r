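#' Preprocess BOLD runs for Fourier analysis
#'
#' Per run: drop the initial dummy volumes, remove a least-squares linear
#' trend (intercept and slope) from every vertex time series, then raw-average
#' the runs sample-wise. Run averaging precedes the Fourier transform.
#'
#' The trend is estimated jointly with the stimulus-frequency quadrature
#' pair (whose fitted components are kept, not removed), so detrending is
#' unbiased at the stimulus frequency: a noiseless periodic response passes
#' through unchanged and its phase is recovered exactly downstream.
#'
#' @param bold_runs a [simulate_bold()] result, or a list of
#'   vertices x volumes matrices.
#' @param protocol a [stim_protocol()].
#' @return vertices x `protocol$n_kept` matrix of detrended, run-averaged
#'   signal.
#' @export
preprocess_runs <- function(bold_runs, protocol = stim_protocol()) {
  runs <- if (inherits(bold_runs, "bold_runs")) bold_runs$runs else bold_runs
  if (length(runs) != protocol$n_runs) {
    stop("expected ", protocol$n_runs, " runs, got ", length(runs))
  }
  keep <- (protocol$dummy_volumes + 1L):protocol$volumes_per_run
  n_t <- length(keep)
  tc <- seq_len(n_t) - (n_t + 1) / 2      # centred time index
  wt <- 2 * pi * protocol$stim_bin * (seq_len(n_t) - 1) / n_t
  X <- cbind(1, tc, cos(wt), sin(wt))    # trend + protected quadrature pair
  XtX_inv <- solve(crossprod(X))
  acc <- NULL
  for (r in runs) {
    r <- as.matrix(r)
    if (ncol(r) != protocol$volumes_per_run) {
      stop("run has ", ncol(r), " volumes; protocol expects ",
           protocol$volumes_per_run)
    }
    y <- r[, keep, drop = FALSE]
    beta <- XtX_inv %*% crossprod(X, t(y))     # 4 x vertices
    detr <- y - t(X[, 1:2] %*% beta[1:2, , drop = FALSE])
    acc <- if (is.null(acc)) detr else acc + detr
  }
  acc / length(runs)
}

#' Fourier phase map
#'
#' Computes, per vertex, the discrete Fourier coefficient of the detrended
#' average time series at the stimulus frequency (bin `protocol$stim_bin`),
#' giving a complex response with amplitude and phase; and an F-ratio
#' comparing power at the stimulus bin to the mean power over noise
#' frequencies. Noise frequencies are all bins up to Nyquist excluding bins
#' below 0.005 Hz (movement-dominated), the stimulus bin, and its harmonics;
#' each retained complex bin contributes two degrees of freedom, so with K
#' noise bins the F-ratio is referred to F(2, 2K).
#'
#' Phase is reported for the convention `signal = A*cos(2*pi*f*t - phase)`
#' with the clock at zero on the first retained sample, so a noiseless
#' cosine is recovered exactly.
#'
#' @param series vertices x n_kept matrix (or a single time-series vector)
#'   from [preprocess_runs()].
#' @param protocol a [stim_protocol()].
#' @return object of class `phase_map`: `complex_coef` (amplitude-scaled,
#'   `Arg` = phase), `amplitude`, `phase` in `[0, 2*pi)`, `f_ratio`, `df`
#'   (c(2, 2K)), `p_uncorrected`, `noise_bins`. All-zero series get
#'   amplitude 0 and p = 1.
#' @export
fourier_phase_map <- function(series, protocol = stim_protocol()) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1L)
  n_t <- ncol(series)
  if (n_t != protocol$n_kept) {
    stop("series length ", n_t, " does not match protocol (", protocol$n_kept, ")")
  }
  nyq <- n_t %/% 2L
  sbin <- protocol$stim_bin
  freq_hz <- seq_len(nyq) / (n_t * protocol$tr_s)
  low <- which(freq_hz < 0.005)
  harmonics <- seq(2L * sbin, nyq, by = sbin)
  noise_bins <- setdiff(seq_len(nyq), c(low, sbin, harmonics))
  K <- length(noise_bins)
  X <- t(stats::mvfft(t(series)))        # vertices x n_t
  coef_raw <- X[, sbin + 1L]
  complex_coef <- (2 / n_t) * Conj(coef_raw)
  amplitude <- Mod(complex_coef)
  phase <- Arg(complex_coef) %% (2 * pi)
  p_stim <- Mod(coef_raw)^2
  p_noise <- rowMeans(Mod(X[, noise_bins + 1L, drop = FALSE])^2)
  f_ratio <- ifelse(p_noise > 0, p_stim / p_noise, 0)
  p_unc <- ifelse(p_noise > 0,
                  stats::pf(f_ratio, 2, 2 * K, lower.tail = FALSE), 1)
  zero <- p_noise == 0 & p_stim == 0
  phase[zero] <- 0
  structure(list(complex_coef = complex_coef, amplitude = amplitude,
                 phase = phase, f_ratio = f_ratio, df = c(2, 2 * K),
                 p_uncorrected = p_unc, noise_bins = noise_bins,
                 protocol = protocol),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map: %d vertices, df=(%d,%d), %d vertices p<0.05>\n",
              length(x$phase), x$df[1], x$df[2], sum(x$p_uncorrected < 0.05)))
  invisible(x)
}

# k nearest-neighbour averaging steps as a dense operator (vertex + 1-ring,
# uniform weights). Used by the cluster-correction null and smooth_complex.
smoothing_operator <- function(mesh, steps) {
  n <- n_vertices(mesh)
  if (steps == 0L) return(diag(n))
  adj <- mesh_adjacency(mesh)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- c(i, adj[[i]])
    A[i, nb] <- 1 / length(nb)
  }
  out <- A
  if (steps > 1L) for (s in seq_len(steps - 1L)) out <- out %*% A
  out
}

#' Surface-based cluster correction
#'
#' Thresholds the uncorrected vertexwise p-values at `cluster_forming_p`,
#' finds connected components in mesh adjacency, and scores each component
#' by its surface area (the summed area of faces whose three vertices are
#' all suprathreshold). Family-wise significance is assessed against a
#' Monte-Carlo null: `n_null` maps of i.i.d. Gaussian noise are smoothed
#' with `smoothing_steps` nearest-neighbour iterations, standardized, and
#' thresholded at the matching Gaussian quantile; the maximum cluster area
#' of each null map forms the null distribution, and each observed cluster
#' gets `corrected_p = (1 + #null >= area) / (n_null + 1)`.
#'
#' @param pmap a [fourier_phase_map()] result (or any list with
#'   `p_uncorrected`).
#' @param mesh the [surface_mesh()] the map lives on.
#' @param cluster_forming_p vertexwise threshold forming clusters.
#' @param alpha family-wise level for retaining clusters.
#' @param n_null number of Monte-Carlo null maps.
#' @param smoothing_steps nearest-neighbour smoothing iterations applied to
#'   the null noise (match the smoothing applied to the data; 0 for none).
#' @param seed RNG seed for the null maps.
#' @return object of class `cluster_correction`: `clusters` (list of
#'   `vertices`, `area_mm2`, `corrected_p`), `significant` (the subset with
#'   `corrected_p < alpha`), `null_max_areas`, `missing` (`TRUE` when no
#'   vertex survives the cluster-forming threshold), and an [roi_label()]
#'   `roi` pooling the significant clusters.
#' @export
cluster_correct <- function(pmap, mesh, cluster_forming_p = 0.01, alpha = 0.01,
                            n_null = 1000, smoothing_steps = 0, seed = 1) {
  p <- pmap$p_uncorrected
  if (length(p) != n_vertices(mesh)) {
    stop("phase map and mesh disagree on vertex count")
  }
  adj <- mesh_adjacency(mesh)
  fa <- face_areas(mesh)
  cluster_areas <- function(supra) {
    comps <- vertex_components(adj, which(supra))
    if (!length(comps)) return(list(comps = list(), areas = numeric(0)))
    all_in <- supra[mesh$faces[, 1]] & supra[mesh$faces[, 2]] &
      supra[mesh$faces[, 3]]
    areas <- vapply(comps, function(cc) {
      inc <- logical(length(supra)); inc[cc] <- TRUE
      sum(fa[all_in & inc[mesh$faces[, 1]]])
    }, numeric(1))
    list(comps = comps, areas = areas)
  }
  obs <- cluster_areas(p < cluster_forming_p)
  # Monte-Carlo null: smoothed standardized Gaussian maps at the same quantile
  n <- n_vertices(mesh)
  A <- smoothing_operator(mesh, smoothing_steps)
  sd_v <- sqrt(rowSums(A^2))
  thr <- stats::qnorm(1 - cluster_forming_p)
  set.seed(seed)
  Z <- A %*% matrix(stats::rnorm(n * n_null), n) / sd_v
  null_max <- vapply(seq_len(n_null), function(j) {
    ca <- cluster_areas(Z[, j] > thr)
    if (length(ca$areas)) max(ca$areas) else 0
  }, numeric(1))
  if (!length(obs$comps)) {
    return(structure(list(clusters = list(), significant = list(),
                          null_max_areas = null_max, missing = TRUE,
                          roi = roi_label(missing = TRUE),
                          cluster_forming_p = cluster_forming_p,
                          alpha = alpha),
                     class = "cluster_correction"))
  }
  clusters <- lapply(seq_along(obs$comps), function(i) {
    a <- obs$areas[[i]]
    list(vertices = obs$comps[[i]], area_mm2 = a,
         corrected_p = (1 + sum(null_max >= a)) / (n_null + 1))
  })
  sig <- Filter(function(cl) cl$corrected_p < alpha, clusters)
  roi_idx <- sort(unique(unlist(lapply(sig, `[[`, "vertices"))))
  roi <- if (length(roi_idx)) roi_label(roi_idx, mesh = mesh)
  else roi_label(missing = TRUE)
  structure(list(clusters = clusters, significant = sig,
                 null_max_areas = null_max, missing = FALSE, roi = roi,
                 cluster_forming_p = cluster_forming_p, alpha = alpha),
            class = "cluster_correction")
}

#' @export
print.cluster_correction <- function(x, ...) {
  if (x$missing) cat("<cluster_correction: missing map (no suprathreshold vertices)>\n")
  else cat(sprintf("<cluster_correction: %d clusters, %d significant at alpha=%g>\n",
                   length(x$clusters), length(x$significant), x$alpha))
  invisible(x)
}

#' Convert response phase to finger preference
#'
#' Subtracts the hemodynamic delay offset, expresses the phase as a cycle
#' fraction, and maps the stimulated fraction of the cycle to the four
#' fingers in stimulation order (d2, d3, d4, d5); phases falling in the rest
#' segment are labelled `rest` (these are the phases truncated from map
#' displays).
#'
#' @param pmap a [fourier_phase_map()] result, or a numeric vector of phases.
#' @param protocol a [stim_protocol()].
#' @return factor with levels `d2, d3, d4, d5, rest`, one per vertex.
#' @export
phase_to_finger <- function(pmap, protocol = stim_protocol()) {
  phase <- if (inherits(pmap, "phase_map")) pmap$phase else as.numeric(pmap)
  frac <- ((phase - protocol$delay_offset_rad) / (2 * pi)) %% 1
  labs <- c("d2", "d3", "d4", "d5")
  bin_w <- protocol$stim_fraction / protocol$n_fingers
  idx <- ifelse(frac < protocol$stim_fraction,
                pmin(protocol$n_fingers, floor(frac / bin_w) + 1),
                protocol$n_fingers + 1)
  factor(c(labs, "rest")[idx], levels = c(labs, "rest"))
}

#' Cross-subject vector average of phase maps
#'
#' Averages complex phase maps across subjects vertex-by-vertex after
#' normalizing each subject's response to unit amplitude (zero responses
#' stay zero and are excluded from the per-vertex count), so subjects with
#' strong amplitudes are not over-represented. The group amplitude is the
#' mean resultant length of the subject phase vectors (1 = perfect phase
#' agreement), and a coherence-style cross-subject F-ratio
#' `F = (n-1) * A^2 / (1 - A^2)` with df (2, 2(n-1)) is attached for
#' display thresholding.
#'
#' @param maps list (length >= 2) of [fourier_phase_map()] results on a
#'   common mesh, or a vertices x subjects complex matrix.
#' @return object of class `phase_map` with `amplitude` in `[0, 1]`,
#'   plus `n_subjects` per vertex.
#' @export
cross_subject_average <- function(maps) {
  M <- if (is.matrix(maps)) maps else {
    if (length(maps) < 2L) stop("need at least 2 maps")
    nv <- length(maps[[1]]$complex_coef)
    ok <- vapply(maps, function(m) length(m$complex_coef) == nv, logical(1))
    if (!all(ok)) stop("maps live on meshes with different vertex counts")
    vapply(maps, `[[`, complex(nv), "complex_coef")
  }
  amp <- Mod(M)
  U <- M
  U[amp > 0] <- M[amp > 0] / amp[amp > 0]
  n_sub <- rowSums(amp > 0)
  avg <- rowSums(U) / ncol(M)
  g_amp <- Mod(avg)
  g_phase <- ifelse(g_amp > 0, Arg(avg) %% (2 * pi), 0)
  a2 <- pmin(g_amp^2, 1 - 1e-12)
  f_ratio <- ifelse(n_sub > 1, (n_sub - 1) * a2 / (1 - a2), 0)
  p <- ifelse(n_sub > 1,
              stats::pf(f_ratio, 2, 2 * (pmax(n_sub, 2) - 1), lower.tail = FALSE),
              1)
  structure(list(complex_coef = avg, amplitude = g_amp, phase = g_phase,
                 f_ratio = f_ratio, df = c(2, 2 * (max(n_sub) - 1)),
                 p_uncorrected = p, n_subjects = n_sub),
            class = "phase_map")
}
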