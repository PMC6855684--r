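test_that("nearest-neighbour smoothing is local, linear and mass-preserving", {
  patch <- make_flat_patch(15, 15, 1)
  n <- nrow(patch$vertices)
  const <- rep(2 - 1i, n)
  expect_equal(smooth_complex(patch, const, steps = 3), const,
               ignore_attr = TRUE)
  # impulse spreads to exactly the k-ring after k steps
  adj <- mesh_adjacency(patch)
  centre <- which(patch$vertices[, 1] == 7 & patch$vertices[, 2] == 7)
  imp <- rep(0 + 0i, n); imp[centre] <- 1
  reach <- centre
  for (k in 1:3) {
    sm <- smooth_complex(patch, imp, steps = k)
    reach <- sort(unique(c(reach, unlist(adj[reach]))))
    expect_identical(which(Mod(sm) > 0), reach)
  }
  # interior averaging is doubly stochastic: total mass conserved while the
  # impulse stays away from the boundary
  sm3 <- smooth_complex(patch, imp, steps = 3)
  expect_equal(sum(sm3), 1 + 0i, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(smooth_complex(patch, imp, steps = -1), ">= 0")
  # kernel-derived step count is reported
  auto <- smooth_complex(patch, imp, kernel_mm = 1.5)
  expect_gte(attr(auto, "steps"), 1L)
})

test_that("plane-fit gradients are exact on affine phase fields", {
  patch <- make_flat_patch(12, 10, 1)
  ph <- (0.3 * patch$vertices[, 1]) %% (2 * pi)
  gf <- phase_gradient(patch, ph)
  expect_lt(max(abs(gf$gradient[gf$vertices, 1] - 0.3)), 1e-12)
  expect_lt(max(abs(gf$gradient[gf$vertices, 2])), 1e-12)
  expect_lt(max(abs(Arg(exp(1i * gf$direction[gf$vertices])))), 1e-9)
  expect_equal(max(gf$norm_magnitude[gf$vertices]), 1)
  # random affine fields recovered at machine precision
  set.seed(41)
  for (i in 1:5) {
    g <- runif(2, -0.4, 0.4)
    ph2 <- (g[1] * patch$vertices[, 1] + g[2] * patch$vertices[, 2]) %% (2 * pi)
    gf2 <- phase_gradient(patch, ph2)
    expect_lt(max(abs(sweep(gf2$gradient[gf2$vertices, ], 2, g))), 1e-10)
  }
})

test_that("circular subtraction makes gradients wrap invariant", {
  patch <- make_flat_patch(12, 10, 1)
  ph <- (0.3 * patch$vertices[, 1]) %% (2 * pi)
  gf <- phase_gradient(patch, ph)
  # shift so the ramp crosses the 0/2pi wrap in the middle of the patch
  ph_shift <- (ph + 2 * pi - 0.3 * 5.5) %% (2 * pi)
  gf_shift <- phase_gradient(patch, ph_shift)
  expect_equal(gf_shift$gradient[gf_shift$vertices, ],
               gf$gradient[gf$vertices, ], tolerance = 1e-10)
})

test_that("radial phase fields give radial gradient directions", {
  patch <- make_flat_patch(21, 21, 1)
  ctr <- c(10, 10)
  r <- sqrt((patch$vertices[, 1] - ctr[1])^2 + (patch$vertices[, 2] - ctr[2])^2)
  ph <- (0.2 * r) %% (2 * pi)
  gf <- phase_gradient(patch, ph)
  interior <- gf$vertices[r[gf$vertices] > 2 &
                            patch$vertices[gf$vertices, 1] %in% 2:18 &
                            patch$vertices[gf$vertices, 2] %in% 2:18]
  outward <- atan2(patch$vertices[interior, 2] - ctr[2],
                   patch$vertices[interior, 1] - ctr[1]) %% (2 * pi)
  err <- abs(Arg(exp(1i * (gf$direction[interior] - outward))))
  expect_lt(max(err), 0.05)
})

test_that("circular variance has its analytic values and symmetries", {
  expect_equal(circular_variance(rep(1.3, 10)), 0)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2)
  set.seed(43)
  a <- runif(50, 0, 2 * pi)
  for (rot in runif(3, 0, 2 * pi)) {
    expect_equal(circular_variance((a + rot) %% (2 * pi)),
                 circular_variance(a), tolerance = 1e-12)
  }
})

test_that("gradient variability tracks phase noise in the synthetic map", {
  pr <- stim_protocol()
  patch <- make_flat_patch(25, 25, 1)
  gt <- ground_truth_phase_map(patch, pr, band_length_mm = 16, band_width_mm = 10)
  roi <- roi_label(which(gt$responsive_mask), mesh = patch)
  set.seed(44)
  cv_at <- function(noise) {
    ph <- (gt$true_phase + rnorm(length(gt$true_phase), 0, noise)) %% (2 * pi)
    gf <- phase_gradient(patch, ph, roi)
    circular_variance(gf$direction[gf$vertices])
  }
  cv <- vapply(c(0, 0.4, 1.2), cv_at, numeric(1))
  expect_lt(cv[1], 0.05)
  expect_true(all(diff(cv) > 0))
})

test_that("Harrison-Kanji main effects swap with their factor labels", {
  set.seed(45)
  ang <- rvm(60, mu = 1, kappa = 5)
  f1 <- rep(c("L", "R"), 30)
  f2 <- rep(c("ctrl", "pat"), each = 30)
  hk12 <- harrison_kanji(ang, f1, f2)
  hk21 <- harrison_kanji(ang, f2, f1)
  expect_equal(hk12$table["factor1", ], hk21$table["factor2", ],
               ignore_attr = TRUE)
  expect_equal(hk12$table["factor2", ], hk21$table["factor1", ],
               ignore_attr = TRUE)
  expect_equal(hk12$table["interaction", "F"], hk21$table["interaction", "F"])
  expect_error(harrison_kanji(ang[1:3], f1[c(1, 2, 1)], f2[c(1, 1, 1)]),
               "levels|cell")
  expect_warning(harrison_kanji(runif(40, 0, 2 * pi), rep(c("a", "b"), 20),
                                rep(c("x", "y"), each = 20)),
                 "low concentration")
})

test_that("circular-linear correlation is exact for in-span signals", {
  set.seed(46)
  th <- runif(200, 0, 2 * pi)
  expect_equal(circ_linear_correlation(th, cos(th))$r_cl, 1, tolerance = 1e-9)
  expect_equal(circ_linear_correlation(th, sin(th + 1))$r_cl, 1, tolerance = 1e-9)
  # invariant to rotation of the angle and affine maps of the covariate
  x <- rnorm(200) + 0.8 * cos(th)
  base <- circ_linear_correlation(th, x)
  rot <- circ_linear_correlation((th + 1.1) %% (2 * pi), x)
  aff <- circ_linear_correlation(th, 3 * x - 7)
  expect_equal(rot$r_cl, base$r_cl, tolerance = 1e-9)
  expect_equal(aff$r_cl, base$r_cl, tolerance = 1e-12)
  expect_error(circ_linear_correlation(th, rep(1, 200)), "constant")
  expect_error(circ_linear_correlation(th[1:3], x[1:3]), "at least 4")
})

test_that("variance-to-angle mapping validates its domain", {
  expect_equal(variance_to_angle(c(0, 0.25, 1)), c(0, pi / 2, 0))
  expect_error(variance_to_angle(1.2), "\\[0, 1\\]")
})
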