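test_that("phantom generation is bit-reproducible for a fixed seed", {
  spec <- phantom_spec(n_nuclei = 25, spheroid_radius = 30, seed = 71)
  gt1 <- generate_ground_truth(spec)
  gt2 <- generate_ground_truth(spec)
  expect_identical(gt1, gt2)

  v1 <- render_volume(gt1)
  v2 <- render_volume(gt2)
  expect_identical(v1$intensities, v2$intensities)

  e1 <- generate_mitosis_events(100, seed = 72)
  e2 <- generate_mitosis_events(100, seed = 72)
  expect_identical(e1, e2)

  a1 <- sample_annotations(gt1$nuclei[[1L]], 8, 0.1, seed = 73)
  a2 <- sample_annotations(gt1$nuclei[[1L]], 8, 0.1, seed = 73)
  expect_identical(a1$points, a2$points)

  # a different seed actually changes the draw
  expect_false(identical(generate_ground_truth(phantom_spec(n_nuclei = 25,
    spheroid_radius = 30, seed = 74))$nuclei[[1L]]$center,
    gt1$nuclei[[1L]]$center))
})

test_that("orientation modes construct the intended true angles", {
  tang <- generate_ground_truth(phantom_spec(n_nuclei = 40, spheroid_radius = 40,
                                             orientation_mode = "tangential",
                                             orientation_noise_deg = 0, seed = 75))
  expect_equal(unname(true_orientation_angles(tang)), rep(90, 40),
               tolerance = 1e-6)

  rad <- generate_ground_truth(phantom_spec(n_nuclei = 40, spheroid_radius = 40,
                                            orientation_mode = "radial",
                                            orientation_noise_deg = 0, seed = 76))
  expect_equal(unname(true_orientation_angles(rad)), rep(0, 40),
               tolerance = 1e-6)

  noisy <- generate_ground_truth(phantom_spec(n_nuclei = 300, spheroid_radius = 100,
                                              orientation_mode = "tangential",
                                              orientation_noise_deg = 10, seed = 77))
  ang <- true_orientation_angles(noisy)
  expect_gt(median(ang), 80)
  expect_gt(sd(ang), 2)  # the noise is really applied
})

test_that("nuclei are placed inside the spheroid without overlap", {
  gt <- generate_ground_truth(phantom_spec(n_nuclei = 60, spheroid_radius = 50,
                                           seed = 78))
  ctr <- t(vapply(gt$nuclei, function(e) e$center, numeric(3L)))
  L1 <- vapply(gt$nuclei, function(e) e$lengths[1L], numeric(1L))
  rr <- sqrt(rowSums(sweep(ctr, 2L, gt$center)^2))
  expect_true(all(rr + L1 <= gt$radius + 1e-9))
  dd <- as.matrix(dist(ctr))
  need <- outer(L1, L1, "+")
  diag(dd) <- Inf
  expect_true(all(dd >= need - 1e-9 | !is.finite(dd)))

  expect_error(generate_ground_truth(phantom_spec(n_nuclei = 500,
                                                  spheroid_radius = 15,
                                                  seed = 79)),
               "could not place|too large")
})

test_that("noiseless annotations lie on the surface and round-trip the fit", {
  set.seed(80)
  for (i in 1:10) {
    e <- ellipsoid(runif(3, -20, 20), random_rotation(),
                   sort(runif(3, 2, 8), decreasing = TRUE))
    ann <- sample_annotations(e, 8, jitter_sd = 0, seed = 80 + i)
    M <- e$axes %*% diag(1 / e$lengths^2) %*% t(e$axes)
    resid <- apply(ann$points, 1L, function(p)
      drop(t(p - e$center) %*% M %*% (p - e$center)) - 1)
    expect_lt(max(abs(resid)), 1e-9)
    expect_setequal(unique(ann$view), c("xy", "yz", "xz"))

    f <- fit_ellipsoid(ann)
    expect_equal(f$center, e$center, tolerance = 1e-6)
    expect_equal(f$lengths, e$lengths, tolerance = 1e-6)
  }
})

test_that("rendered clean phantom recovers the analytic sphere via the pipeline", {
  spec <- phantom_spec(n_nuclei = 15, spheroid_radius = 30,
                       read_noise_sd = 0, poisson_scaling = 0,
                       attenuation_per_um = 0, seed = 81)
  gt <- generate_ground_truth(spec)
  vol <- render_volume(gt)
  hull <- extract_convex_hull(binarize(denoise(vol, 2)))
  rad <- sqrt(rowSums(sweep(hull$vertices, 2L, gt$center)^2))
  expect_lt(max(abs(rad - 30)), sqrt(sum(spec$spacing^2)))
})

test_that("depth attenuation makes intensity decrease into the spheroid", {
  spec <- phantom_spec(n_nuclei = 1, spheroid_radius = 30,
                       read_noise_sd = 0, poisson_scaling = 0,
                       attenuation_per_um = 0.01, psf_sigma_um = 0, seed = 82)
  gt <- generate_ground_truth(spec)
  vol <- render_volume(gt)
  # cytoplasm intensity profile along a diameter through the centre
  ctr_idx <- round(gt$center / rev(spec$spacing)) + 1L  # (x, y, z) -> indices
  prof <- vol$intensities[ctr_idx[3L], ctr_idx[2L], ]
  xs <- (seq_along(prof) - 1L) * spec$spacing[3L]
  depth <- 30 - abs(xs - gt$center[1L])
  sel <- depth > 2 & depth < 28
  expect_lt(cor(depth[sel], prof[sel]), -0.95)
})

test_that("a capped phantom yields a visibly non-spherical hull", {
  spec <- phantom_spec(n_nuclei = 10, spheroid_radius = 30, shape = "capped",
                       read_noise_sd = 0, poisson_scaling = 0,
                       attenuation_per_um = 0, seed = 83)
  gt <- generate_ground_truth(spec)
  hull <- extract_convex_hull(binarize(denoise(render_volume(gt), 2)))
  zmax <- max(hull$vertices[, 3L]) - gt$center[3L]
  xmax <- max(hull$vertices[, 1L]) - gt$center[1L]
  expect_lt(zmax, 0.7 * 30)   # flattened pole
  expect_gt(xmax, 0.95 * 30)  # full radius elsewhere
})
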