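test_that("affected-side pooling flips right-CRPS and is an involution", {
  pooled <- pool_by_affected_side(left = c(1, 1, 1), right = c(2, 2, 2),
                                  group = c("control", "left-CRPS", "right-CRPS"))
  expect_equal(pooled$affected, c(1, 1, 2))
  expect_equal(pooled$unaffected, c(2, 2, 1))
  expect_identical(as.character(pooled$group), c("control", "CRPS", "CRPS"))
  # flipping twice restores the left/right assignment
  again <- pool_by_affected_side(pooled$affected, pooled$unaffected,
                                 group = c("control", "left-CRPS", "right-CRPS"))
  expect_equal(again$affected, c(1, 1, 1))
  expect_equal(again$unaffected, c(2, 2, 2))
  expect_error(pool_by_affected_side(1, 2, "patient"), "unknown group")
})

test_that("pooled-variance t tests reproduce the cohort demographics", {
  t1 <- somatomap_table1()
  ctrl <- t1$group == "control"
  expect_equal(round(mean(t1$age_yr[ctrl]), 1), 44.9)
  expect_equal(round(mean(t1$laterality[ctrl]), 1), 73.6)
  expect_equal(round(mean(t1$laterality[!ctrl]), 1), 61.6)
  age <- ttest(t1$age_yr[ctrl], t1$age_yr[!ctrl])
  expect_equal(age$df, 33)
  expect_equal(round(age$t, 2), 0.19)
  lat <- ttest(t1$laterality[ctrl], t1$laterality[!ctrl])
  expect_equal(round(lat$t, 2), 0.65)
  same <- ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("JZS Bayes factors match a fine-grid quadrature oracle", {
  # oracle: trapezoid rule under the substitution delta = scale * tan(u)
  jzs_oracle <- function(t, n1, n2, scale = sqrt(2) / 2) {
    nu <- n1 + n2 - 2
    neff <- n1 * n2 / (n1 + n2)
    u <- seq(-pi / 2 + 1e-7, pi / 2 - 1e-7, length.out = 4001)
    delta <- scale * tan(u)
    integrand <- suppressWarnings(
      dt(t, nu, ncp = delta * sqrt(neff)) * dcauchy(delta, scale = scale) *
        scale / cos(u)^2)
    marg <- sum((integrand[-1] + integrand[-length(u)]) / 2 * diff(u))
    marg / dt(t, nu)
  }
  for (t in c(0, 0.5, 1, 2, 3)) {
    for (n in c(10, 17, 35)) {
      expect_equal(jzs_bf_ttest(t, n, n + 1), jzs_oracle(t, n, n + 1),
                   tolerance = 5e-4)
    }
  }
  # BF at t = 0 shrinks with growing n
  bfs <- vapply(c(10, 20, 40), function(n) jzs_bf_ttest(0, n, n), numeric(1))
  expect_true(all(bfs < 1))
  expect_true(all(diff(bfs) < 0))
  expect_error(jzs_bf_ttest(1, 1, 10), "exceed 1")
})

test_that("JZS Bayes factors reproduce the cohort values", {
  t1 <- somatomap_table1()
  ctrl <- t1$group == "control"
  t_age <- ttest(t1$age_yr[ctrl], t1$age_yr[!ctrl])$t
  t_lat <- ttest(t1$laterality[ctrl], t1$laterality[!ctrl])$t
  expect_lt(abs(jzs_bf_ttest(t_age, 17, 18) - 0.329), 0.002)
  expect_lt(abs(jzs_bf_ttest(t_lat, 17, 18) - 0.384), 0.002)
})

test_that("the mixed ANOVA handles missing sides and degenerate data", {
  set.seed(51)
  pooled <- pool_by_affected_side(rnorm(24), rnorm(24),
                                  rep(c("control", "right-CRPS"), each = 12))
  pooled$affected[c(2, 15)] <- NA
  fit <- mixed_anova_2x2(pooled)
  expect_identical(fit$n_used, 22L)
  expect_identical(fit$n_dropped, 2L)
  expect_identical(rownames(fit$table), c("group", "side", "side:group"))
  expect_true(all(fit$table$p >= 0 & fit$table$p <= 1))
  # constant response: no variance anywhere, F undefined/zero
  const <- pool_by_affected_side(rep(1, 8), rep(1, 8),
                                 rep(c("control", "left-CRPS"), each = 4))
  tab <- mixed_anova_2x2(const)$table
  expect_true(all(is.na(tab$F) | tab$F == 0))
  few <- pool_by_affected_side(1:3, 1:3, c("control", "control", "left-CRPS"))
  expect_error(mixed_anova_2x2(few), "2 complete subjects")
})

test_that("group-effect p-values are calibrated under label permutation", {
  set.seed(52)
  base <- data.frame(l = rnorm(20), r = rnorm(20))
  groups <- rep(c("control", "left-CRPS"), each = 10)
  p <- vapply(1:200, function(i) {
    g <- sample(groups)
    mixed_anova_2x2(pool_by_affected_side(base$l, base$r, g))$table["group", "p"]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.04)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("normality pipeline log-transforms only what needs it", {
  set.seed(53)
  x <- rnorm(50)
  res <- normality_log_pipeline(x)
  expect_false(res$transformed)
  expect_equal(res$values, x)
  n_fixed <- 0
  for (i in 1:100) {
    y <- rlnorm(40, sdlog = 1.2)
    r <- normality_log_pipeline(y)
    if (r$transformed && r$p_log >= 0.05) n_fixed <- n_fixed + 1
  }
  expect_gt(n_fixed / 100, 0.85)
  z <- c(rlnorm(30, sdlog = 1.5), -1)
  expect_error(normality_log_pipeline(z), "nonpositive")
})

test_that("Fisher-z comparison matches the printed contrast and is antisymmetric", {
  eq <- fisher_z_compare(0.3, 20, 0.3, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_equal(round(fisher_z_compare(0.40, 15, 0.20, 16)$z, 2), 0.55)
  a <- fisher_z_compare(0.7, 12, -0.1, 30)
  b <- fisher_z_compare(-0.1, 30, 0.7, 12)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_error(fisher_z_compare(0.5, 3, 0.2, 10), "exceed 3")
})

test_that("Benjamini-Hochberg criticals follow the step-up rule", {
  crit <- bh_critical_values(c(0.2, 0.01, 0.04, 0.9, 0.5, 0.03))$critical
  expect_equal(sort(crit), (1:6) * 0.05 / 6)
  expect_equal(round(sort(crit), 3), c(0.008, 0.017, 0.025, 0.033, 0.042, 0.05))
  expect_equal(bh_critical_values(0.2)$critical, 0.05)
  expect_false(any(bh_critical_values(rep(1, 5))$pass))
  # step-up: every test below its critical in rank order passes
  res <- bh_critical_values(c(0.001, 0.012, 0.9))
  expect_identical(res$pass, c(TRUE, TRUE, FALSE))
  # BH rejects at least whatever Bonferroni rejects
  set.seed(54)
  for (i in 1:20) {
    p <- runif(8)^2
    res <- bh_critical_values(p, q = 0.05)
    expect_true(all(res$pass[p <= 0.05 / 8]))
  }
})

test_that("the pressure-pain severity score is a normalized deficit", {
  expect_equal(pp_severity(5, 5), 0)
  expect_equal(pp_severity(0, 8), 1)
  expect_equal(round(pp_severity(1.9, 12.2), 4), 0.7305)
  expect_equal(pp_severity(2, 6, normalized = FALSE), 4)
  expect_error(pp_severity(0, 0), "both PPTs are zero")
})
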