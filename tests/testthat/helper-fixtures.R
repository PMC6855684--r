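# Shared fixtures and independent oracles used across test files.

# unit square split into two triangles, z = 0
square_mesh <- function() {
  surface_mesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
    faces = rbind(c(1, 2, 3), c(1, 3, 4)),
    kind = "flat")
}

# five-vertex spherical cap: a ring of 4 vertices symmetric about +z plus
# the pole, all on the unit sphere
cap_mesh <- function() {
  a <- 0.6; b <- 0.8
  surface_mesh(
    vertices = rbind(c(a, 0, b), c(0, a, b), c(-a, 0, b), c(0, -a, b),
                     c(0, 0, 1)),
    faces = rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5)),
    kind = "sphere", radius_mm = 1)
}

# independent triangle-area oracle: explicit per-face cross-product loop
brute_force_area <- function(mesh, vertex_subset = seq_len(nrow(mesh$vertices))) {
  inr <- seq_len(nrow(mesh$vertices)) %in% vertex_subset
  total <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    if (!all(inr[f])) next
    p <- mesh$vertices[f[1], ]; q <- mesh$vertices[f[2], ]; r <- mesh$vertices[f[3], ]
    cr <- c((q - p)[2] * (r - p)[3] - (q - p)[3] * (r - p)[2],
            (q - p)[3] * (r - p)[1] - (q - p)[1] * (r - p)[3],
            (q - p)[1] * (r - p)[2] - (q - p)[2] * (r - p)[1])
    total <- total + 0.5 * sqrt(sum(cr^2))
  }
  total
}

# von Mises sampler (Best & Fisher 1979 rejection); independent of the
# package, used to drive the circular-ANOVA calibration tests
rvm <- function(n, mu = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# uniform random 3-D rotation matrix (QR with positive diagonal, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
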