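# Shared fixtures and independent oracles, built in code.

# random rotation matrix (uniform via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))
}

# exact boundary points of an ellipsoid: per-axis extremes plus octant points,
# mapped through centre/axes/lengths
ellipsoid_surface_points <- function(center, axes, lengths, n_extra = 0L) {
  u <- rbind(diag(3L), -diag(3L),
             as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3))
  if (n_extra > 0L) {
    v <- matrix(rnorm(3L * n_extra), ncol = 3L)
    u <- rbind(u, v / sqrt(rowSums(v^2)))
  }
  sweep(u %*% diag(lengths) %*% t(axes), 2L, center, "+")
}

# brute-force closest-surface-point oracle: scalar per-face loop
closest_surface_point_oracle <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  best <- list(distance = Inf)
  for (i in seq_len(nrow(f))) {
    r <- closest_point_on_triangle(p, v[f[i, 1L], ], v[f[i, 2L], ], v[f[i, 3L], ])
    if (r$distance < best$distance)
      best <- list(point = r$point, face_index = i, distance = r$distance)
  }
  best
}

# dense barycentric-grid oracle for the closest point on one triangle
triangle_distance_grid_oracle <- function(p, a, b, c, n = 120L) {
  s <- seq(0, 1, length.out = n)
  g <- expand.grid(u = s, v = s)
  g <- g[g$u + g$v <= 1, ]
  q <- outer(1 - g$u - g$v, a) + outer(g$u, b) + outer(g$v, c)
  min(sqrt(rowSums((q - matrix(p, nrow(q), 3L, byrow = TRUE))^2)))
}

# exact two-sided Mann-Whitney p by enumeration over all labelings
mann_whitney_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) # tie-free data
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2L, function(k) u_of(pooled[k], pooled[-k]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# truncated-normal mean by numerical integration (independent of the
# generator's inverse-CDF sampling)
truncnorm_mean_quadrature <- function(mu, sd, lower) {
  z <- stats::integrate(function(x) x * stats::dnorm(x, mu, sd), lower, Inf)$value
  z / (1 - stats::pnorm(lower, mu, sd))
}

# small digitized ball mask for hull/depth tests
ball_mask <- function(radius_um, spacing = c(1, 1, 1), pad_um = 2) {
  ext <- 2 * (radius_um + pad_um)
  dims <- floor(ext / spacing) + 1L
  ctr <- rep(radius_um + pad_um, 3L)
  zs <- (seq_len(dims[1L]) - 1L) * spacing[1L]
  ys <- (seq_len(dims[2L]) - 1L) * spacing[2L]
  xs <- (seq_len(dims[3L]) - 1L) * spacing[3L]
  mask <- array(FALSE, dims)
  for (iz in seq_len(dims[1L])) {
    r2 <- outer((ys - ctr[2L])^2, (xs - ctr[1L])^2, "+") + (zs[iz] - ctr[3L])^2
    mask[iz, , ] <- r2 <= radius_um^2
  }
  list(grid = binary_grid(mask, spacing), center = ctr)
}

# fine spherical hull matching a phantom's centre and radius
sphere_hull_for <- function(gt, n = 4000L) {
  u <- matrix(rnorm(3L * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2)) * gt$radius
  convex_hull_mesh(sweep(u, 2L, gt$center, "+"))
}
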