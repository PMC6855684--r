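pr <- stim_protocol()

make_runs <- function(fun) {
  # four identical runs built from a per-volume function of time (seconds,
  # clock zero at the first post-dummy volume)
  t_s <- (seq_len(pr$volumes_per_run) - 1 - pr$dummy_volumes) * pr$tr_s
  lapply(1:4, function(r) matrix(fun(t_s), nrow = 1))
}

test_that("preprocessing removes constants and linear trends", {
  expect_equal(max(abs(preprocess_runs(make_runs(function(t) rep(5, length(t))), pr))),
               0)
  expect_equal(max(abs(preprocess_runs(make_runs(function(t) 0.3 * t - 2), pr))),
               0, tolerance = 1e-12)
  # cosine + ramp: detrended series matches the regression-residual oracle
  f <- pr$stim_freq_hz
  runs <- make_runs(function(t) cos(2 * pi * f * t - 1) + 0.05 * t)
  out <- preprocess_runs(runs, pr)[1, ]
  t_s <- (seq_len(pr$n_kept) - 1) * pr$tr_s
  pure <- cos(2 * pi * f * t_s - 1)
  expect_gt(cor(out, pure), 0.999)
  expect_error(preprocess_runs(runs[1:2], pr), "expected 4 runs")
  bad <- runs; bad[[1]] <- bad[[1]][, 1:100, drop = FALSE]
  expect_error(preprocess_runs(bad, pr), "volumes")
})

test_that("the stimulus-bin DFT recovers amplitude and phase of a pure response", {
  t_s <- (seq_len(pr$n_kept) - 1) * pr$tr_s
  s <- 2 * cos(2 * pi * pr$stim_freq_hz * t_s - pi / 2)
  pm <- fourier_phase_map(s, pr)
  expect_equal(pm$phase, pi / 2, tolerance = 1e-12)
  expect_equal(pm$amplitude, 2, tolerance = 1e-12)
  expect_lt(pm$p_uncorrected, 1e-100)
  # sign flip shifts phase by exactly pi
  pm2 <- fourier_phase_map(-s, pr)
  expect_equal((pm2$phase - pm$phase) %% (2 * pi), pi, tolerance = 1e-12)
  # all-zero series is flagged, not a division error
  pm0 <- fourier_phase_map(rep(0, pr$n_kept), pr)
  expect_equal(pm0$amplitude, 0)
  expect_equal(pm0$p_uncorrected, 1)
})

test_that("noise frequency set excludes low bins, stimulus bin and harmonics", {
  pm <- fourier_phase_map(rnorm(pr$n_kept), pr)
  expect_false(any(c(1, 12, 24, 36, 48, 60, 72, 84) %in% pm$noise_bins))
  expect_identical(length(pm$noise_bins), 82L)
  expect_identical(pm$df, c(2, 164))
})

test_that("F-ratio p-values are calibrated on white noise and scale invariant", {
  set.seed(42)
  Y <- matrix(rnorm(5000 * pr$n_kept), 5000)
  pm <- fourier_phase_map(Y, pr)
  expect_lt(abs(mean(pm$p_uncorrected < 0.05) - 0.05), 0.01)
  pm_scaled <- fourier_phase_map(3.7 * Y[1:50, ], pr)
  expect_equal(pm_scaled$f_ratio, pm$f_ratio[1:50], tolerance = 1e-12)
})

test_that("Parseval holds for detrended series", {
  pr2 <- pr
  set.seed(1)
  gt <- ground_truth_phase_map(make_flat_patch(5, 5, 2), pr2,
                               band_length_mm = 4, band_width_mm = 4)
  ts <- preprocess_runs(simulate_bold(gt, pr2, noise_sd = 1, seed = 2), pr2)
  X <- t(stats::mvfft(t(ts)))
  lhs <- rowSums(ts^2)
  rhs <- rowSums(Mod(X)^2) / ncol(ts)
  expect_lt(max(abs(lhs - rhs) / rhs), 1e-9)
})

test_that("phase recovery degrades gracefully with noise and is unbiased", {
  patch <- make_flat_patch(10, 10, 1)
  gt <- ground_truth_phase_map(patch, pr, band_length_mm = 6, band_width_mm = 4)
  on <- gt$responsive_mask
  # noiseless limit: exact recovery
  pm0 <- fourier_phase_map(preprocess_runs(simulate_bold(gt, pr, 0, seed = 1), pr), pr)
  expect_lt(max(abs(Arg(exp(1i * (pm0$phase - gt$true_phase)))[on])), 1e-9)
  # noise_sd = 0.5, amplitude 1: RMSE below a quarter finger bin,
  # oracle = the direct DFT at the stimulus bin is this very estimator, so
  # the bound is the CRLB-scale tolerance 2*pi/24
  errs <- c()
  for (seed in 1:20) {
    pm <- fourier_phase_map(preprocess_runs(simulate_bold(gt, pr, 0.5, seed = seed), pr), pr)
    errs <- c(errs, Arg(exp(1i * (pm$phase - gt$true_phase)))[on])
  }
  expect_lt(sqrt(mean(errs^2)), 2 * pi / 24)
  # unbiasedness: mean circular error near zero
  expect_lt(abs(mean(errs)), 0.02)
  # convergence as noise shrinks
  rmse_at <- function(sd) {
    pm <- fourier_phase_map(preprocess_runs(simulate_bold(gt, pr, sd, seed = 99), pr), pr)
    sqrt(mean(Arg(exp(1i * (pm$phase - gt$true_phase)))[on]^2))
  }
  r <- vapply(c(0.5, 0.1, 0.01), rmse_at, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("cluster correction recovers a strong map and flags empty maps", {
  patch <- make_flat_patch(21, 21, 1)
  gt <- ground_truth_phase_map(patch, pr, band_length_mm = 12, band_width_mm = 8)
  pm <- fourier_phase_map(preprocess_runs(simulate_bold(gt, pr, 0.05, seed = 5), pr), pr)
  cc <- cluster_correct(pm, patch, n_null = 499, seed = 6)
  expect_false(cc$missing)
  expect_identical(length(cc$significant), 1L)
  truth_area <- roi_area(patch, roi_label(which(gt$responsive_mask), mesh = patch))
  expect_gte(cc$significant[[1]]$area_mm2, 0.95 * truth_area)
  expect_true(all(cc$significant[[1]]$corrected_p >= 1 / 500))

  flat <- list(p_uncorrected = rep(1, nrow(patch$vertices)))
  cc0 <- cluster_correct(flat, patch, n_null = 99, seed = 1)
  expect_true(cc0$missing)
  expect_true(cc0$roi$missing)
  # missing maps propagate without failure downstream
  expect_true(is.na(roi_area(patch, cc0$roi)))
})

test_that("phase-to-finger binning follows the stimulation order", {
  d <- pr$delay_offset_rad
  expect_identical(as.character(phase_to_finger((d + 0.1 * 2 * pi) %% (2 * pi), pr)), "d2")
  expect_identical(as.character(phase_to_finger((d + 0.25 * 2 * pi) %% (2 * pi), pr)), "d3")
  expect_identical(as.character(phase_to_finger((d + 0.79 * 2 * pi) %% (2 * pi), pr)), "d5")
  expect_identical(as.character(phase_to_finger((d + 0.9 * 2 * pi) %% (2 * pi), pr)), "rest")
})

test_that("cross-subject vector averaging behaves like a Rayleigh walk", {
  nv <- 5000; ns <- 17
  # identical phases: unit amplitude, same phase
  M <- matrix(rep(3 * exp(1i * 1.2), nv * 2), nv)
  avg <- cross_subject_average(M)
  expect_equal(avg$amplitude, rep(1, nv))
  expect_equal(avg$phase, rep(1.2, nv))
  # opposite phases cancel
  M2 <- cbind(rep(exp(1i * 0.4), 4), rep(exp(1i * (0.4 + pi)), 4))
  expect_equal(cross_subject_average(M2)$amplitude, rep(0, 4))
  # random phases: mean amplitude follows the sqrt(pi)/2/sqrt(n) law
  set.seed(8)
  M3 <- matrix(exp(1i * runif(nv * ns, 0, 2 * pi)), nv)
  a <- cross_subject_average(M3)$amplitude
  expect_lt(abs(mean(a) / (sqrt(pi) / 2 / sqrt(ns)) - 1), 0.15)
  expect_error(cross_subject_average(list()), "at least 2")
})
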