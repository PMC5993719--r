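test_that("Gaussian denoising: identity at sigma 0, flat fields preserved", {
  set.seed(11)
  g <- voxel_grid(array(runif(6 * 7 * 8), c(6, 7, 8)), c(1, 0.5, 0.5))
  expect_identical(denoise(g, 0)$intensities, g$intensities)
  expect_error(denoise(g, -1), "non-negative")

  # constant field is preserved wherever the kernel does not reach the border
  flat <- voxel_grid(array(3.5, c(17, 17, 17)), c(1, 1, 1))
  sm <- denoise(flat, 1)          # kernel radius 4
  interior <- sm$intensities[6:12, 6:12, 6:12]
  expect_equal(interior, array(3.5, c(7, 7, 7)), tolerance = 1e-9)
})

test_that("separable Gaussian matches direct dense convolution", {
  set.seed(12)
  d <- c(7L, 8L, 9L)
  spacing <- c(1, 0.8, 0.6)
  arr <- array(0, d)
  arr[4, 4, 5] <- 10
  arr <- arr + array(runif(prod(d)), d)
  sigma <- 0.9

  # direct truncated-kernel convolution with zero padding
  ks <- lapply(1:3, function(ax) {
    s <- sigma / spacing[ax]
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2)); k / sum(k)
  })
  direct <- array(0, d)
  for (iz in 1:d[1]) for (iy in 1:d[2]) for (ix in 1:d[3]) {
    acc <- 0
    for (a in seq_along(ks[[1]])) for (b in seq_along(ks[[2]])) for (cc in seq_along(ks[[3]])) {
      z <- iz + a - 1L - (length(ks[[1]]) - 1L) / 2 - 1L + 1L
      y <- iy + b - 1L - (length(ks[[2]]) - 1L) / 2 - 1L + 1L
      x <- ix + cc - 1L - (length(ks[[3]]) - 1L) / 2 - 1L + 1L
      if (z >= 1 && z <= d[1] && y >= 1 && y <= d[2] && x >= 1 && x <= d[3])
        acc <- acc + arr[z, y, x] * ks[[1]][a] * ks[[2]][b] * ks[[3]][cc]
    }
    direct[iz, iy, ix] <- acc
  }
  sm <- denoise(voxel_grid(arr, spacing), sigma)
  expect_equal(sm$intensities, direct, tolerance = 1e-12)
  # symmetric response around an interior impulse, total mass conserved
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  blur <- denoise(voxel_grid(imp, c(1, 1, 1)), 0.8)$intensities
  expect_equal(blur, blur[9:1, , ], tolerance = 1e-12)
  expect_equal(blur, blur[, 9:1, ], tolerance = 1e-12)
  expect_equal(sum(blur), 1, tolerance = 1e-9)
})

test_that("thresholding separates a two-valued image; foreground is strict", {
  set.seed(13)
  arr <- array(10, c(10, 10, 10))
  fg <- array(runif(1000) < 0.3, c(10, 10, 10))
  arr[fg] <- 200
  g <- voxel_grid(arr, c(1, 1, 1))

  bo <- binarize(g, "otsu")
  expect_identical(bo$mask, fg)
  thr <- attr(bo, "threshold")
  expect_gt(thr, 10); expect_lte(thr, 200)

  bf <- binarize(g, "fixed", level = 100)
  expect_identical(bf$mask, fg)
  # strictly-greater-than convention
  expect_false(any(binarize(g, "fixed", level = 200,
                            min_foreground_fraction = 0)$mask))
  expect_error(binarize(voxel_grid(array(5, c(4, 4, 4)), c(1, 1, 1)), "otsu"),
               "flat")
  expect_error(binarize(g, "fixed"), "level")
})

test_that("hull of a digitized ball sits at the analytic radius", {
  bm <- ball_mask(50, spacing = c(1, 1, 1))
  mesh <- extract_convex_hull(bm$grid)
  rad <- sqrt(rowSums(sweep(mesh$vertices, 2L, bm$center)^2))
  vox_diag <- sqrt(3)
  expect_true(all(rad <= 50 + 1e-9))
  expect_true(all(rad >= 50 - vox_diag))

  # anisotropic spacing is honoured: same in physical um
  bma <- ball_mask(20, spacing = c(1, 0.65, 0.65))
  mesha <- extract_convex_hull(bma$grid)
  rada <- sqrt(rowSums(sweep(mesha$vertices, 2L, bma$center)^2))
  expect_true(all(rada <= 20 + 1e-9))
  expect_true(all(rada >= 20 - sqrt(sum(c(1, 0.65, 0.65)^2))))
})

test_that("hull extraction needs enough non-degenerate foreground", {
  m <- array(FALSE, c(5, 5, 5)); m[2, 2, 2] <- TRUE; m[2, 3, 2] <- TRUE
  expect_error(extract_convex_hull(binary_grid(m, c(1, 1, 1))), "fewer than 4")
  flat <- array(FALSE, c(5, 5, 5)); flat[3, , ] <- TRUE
  expect_error(extract_convex_hull(binary_grid(flat, c(1, 1, 1))), "coplanar")
})

test_that("largest-component cleanup drops disconnected specks", {
  bm <- ball_mask(6, spacing = c(1, 1, 1), pad_um = 6)
  m <- bm$grid$mask
  m[1, 1, 1] <- TRUE  # far-corner speck would distort the hull
  dirty <- binary_grid(m, c(1, 1, 1))
  mesh <- extract_convex_hull(dirty, keep_largest_component = TRUE)
  rad <- sqrt(rowSums(sweep(mesh$vertices, 2L, bm$center)^2))
  expect_true(all(rad <= 6 + 1e-9))
})

test_that("depth below the surface matches the analytic sphere and is 1-Lipschitz", {
  bm <- ball_mask(40, spacing = c(1, 1, 1))
  mesh <- extract_convex_hull(bm$grid)
  vox_diag <- sqrt(3)

  expect_equal(depth_from_surface(mesh$vertices[1L, ], mesh), 0)
  expect_equal(depth_from_surface(bm$center, mesh), 40, tolerance = vox_diag / 40)
  p40 <- bm$center + c(25, 0, 0)  # radius 25 in a radius-40 ball
  expect_equal(depth_from_surface(p40, mesh), 15, tolerance = vox_diag / 15)

  set.seed(14)
  for (i in 1:15) {
    p <- bm$center + runif(3, -30, 30)
    q <- p + rnorm(3)
    expect_lte(abs(depth_from_surface(p, mesh) - depth_from_surface(q, mesh)),
               sqrt(sum((p - q)^2)) + 1e-9)
  }
})

test_that("TIFF stack writing and reading round-trip integer intensities", {
  set.seed(15)
  arr <- array(sample(0:4095, 4 * 6 * 5, replace = TRUE), c(4, 6, 5))
  g <- voxel_grid(arr, c(1, 0.65, 0.65))
  path <- tempfile(fileext = ".tif")
  write_stack(g, path)
  back <- read_stack(path, spacing = g$spacing)
  expect_equal(dim(back$intensities), dim(arr))
  expect_equal(back$intensities, arr, ignore_attr = TRUE)
})

test_that("hull summary JSON reports counts, volume and centroid", {
  mesh <- convex_hull_mesh(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  path <- tempfile(fileext = ".json")
  s <- write_hull_summary(mesh, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_vertices, 8L)
  expect_equal(j$volume_um3, 1)
  expect_equal(unlist(j$centroid_um), rep(0.5, 3))
})
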