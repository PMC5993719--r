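# Ground-truthed synthetic spheroid phantoms.
#
# The phantom emulates the acquisition this pipeline was designed for: a
# ball-shaped spheroid imaged with a 1 um z-step and anisotropic xy pixels,
# containing ellipsoidal nuclei of controlled aspect ratio and orientation
# relative to the surface, plus time-lapse mitosis event tables with
# controlled phase-duration distributions. Every stage is deterministic for
# a fixed seed.

#' Phantom specification
#'
#' Defaults describe the study conditions the package targets: a 650 um
#' diameter spheroid (radius 325 um), nuclei with a median aspect ratio of
#' 1.83 (log-normal elongation), L3 around 3 um, tangentially oriented long
#' axes, 1 um z-step with 0.65 um xy pixels, and a moderate mixed
#' Poisson/Gaussian noise model with depth attenuation.
#'
#' @param n_nuclei number of nuclei to place.
#' @param spheroid_radius spheroid radius in um.
#' @param shape `"ball"` (free-growing spheroid) or `"capped"` (ball with one
#'   flattened side, exercising non-spherical hulls as a rough confined
#'   geometry; not a gel-mechanics model).
#' @param aspect_ratio_meanlog,aspect_ratio_sdlog parameters of the
#'   log-normal elongation AR = 1 + Lognormal(meanlog, sdlog); the defaults
#'   give a median aspect ratio of 1.83.
#' @param orientation_mode `"tangential"`, `"radial"` or `"isotropic"` long
#'   axis relative to the local surface.
#' @param orientation_noise_deg Gaussian angular perturbation of the drawn
#'   axis, degrees.
#' @param nucleus_l3_um shortest semi-axis L3 in um.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param intensity named vector with `background`, `cytoplasm`, `nucleus`
#'   mean grey levels.
#' @param read_noise_sd Gaussian read-noise standard deviation (grey levels).
#' @param poisson_scaling photons per grey level for the Poisson shot-noise
#'   component; 0 disables shot noise.
#' @param attenuation_per_um exponential signal attenuation per um of depth.
#' @param psf_sigma_um Gaussian PSF width applied to the rendered volume.
#' @param seed integer seed; all phantom stages derive their randomness from
#'   it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_nuclei,
                         spheroid_radius = 325,
                         shape = c("ball", "capped"),
                         aspect_ratio_meanlog = log(0.83),
                         aspect_ratio_sdlog = 0.4,
                         orientation_mode = c("tangential", "radial", "isotropic"),
                         orientation_noise_deg = 10,
                         nucleus_l3_um = 3,
                         spacing = c(1, 0.65, 0.65),
                         intensity = c(background = 10, cytoplasm = 40,
                                       nucleus = 200),
                         read_noise_sd = 2,
                         poisson_scaling = 1,
                         attenuation_per_um = 0.002,
                         psf_sigma_um = 1,
                         seed = 1L) {
  shape <- match.arg(shape)
  orientation_mode <- match.arg(orientation_mode)
  if (spheroid_radius <= 0) stop("spheroid_radius must be positive")
  if (n_nuclei < 1L) stop("n_nuclei must be at least 1")
  if (orientation_noise_deg < 0 || read_noise_sd < 0 ||
      poisson_scaling < 0 || attenuation_per_um < 0 || psf_sigma_um < 0)
    stop("noise parameters must be non-negative")
  if (!all(c("background", "cytoplasm", "nucleus") %in% names(intensity)))
    stop("intensity needs background, cytoplasm and nucleus entries")
  structure(list(n_nuclei = as.integer(n_nuclei),
                 spheroid_radius = spheroid_radius,
                 shape = shape,
                 aspect_ratio_meanlog = aspect_ratio_meanlog,
                 aspect_ratio_sdlog = aspect_ratio_sdlog,
                 orientation_mode = orientation_mode,
                 orientation_noise_deg = orientation_noise_deg,
                 nucleus_l3_um = nucleus_l3_um,
                 spacing = as.numeric(spacing),
                 intensity = intensity,
                 read_noise_sd = read_noise_sd,
                 poisson_scaling = poisson_scaling,
                 attenuation_per_um = attenuation_per_um,
                 psf_sigma_um = psf_sigma_um,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

random_unit_vector <- function() {
  v <- stats::rnorm(3L)
  while (vnorm(v) < 1e-12) v <- stats::rnorm(3L)
  v / vnorm(v)
}

# random unit vector orthogonal to d
random_perpendicular <- function(d) {
  v <- random_unit_vector()
  w <- v - sum(v * d) * d
  while (vnorm(w) < 1e-9) {
    v <- random_unit_vector()
    w <- v - sum(v * d) * d
  }
  w / vnorm(w)
}

# rotate v by angle_rad about unit axis k (Rodrigues)
rotate_about <- function(v, k, angle_rad) {
  v * cos(angle_rad) +
    c(k[2L] * v[3L] - k[3L] * v[2L],
      k[3L] * v[1L] - k[1L] * v[3L],
      k[1L] * v[2L] - k[2L] * v[1L]) * sin(angle_rad) +
    k * sum(k * v) * (1 - cos(angle_rad))
}

# draw an axis for one nucleus given its outward radial direction
draw_oriented_axis <- function(mode, radial, noise_deg) {
  d <- switch(mode,
              isotropic = random_unit_vector(),
              radial = radial,
              tangential = random_perpendicular(radial))
  if (mode != "isotropic" && noise_deg > 0) {
    d <- rotate_about(d, random_perpendicular(d),
                      stats::rnorm(1L) * noise_deg * pi / 180)
  }
  d
}

# orthonormal frame with first column d; second column chosen quasi-radial
# when possible so tangential nuclei get a radial-ish short axis
complete_frame <- function(d, hint) {
  h <- hint - sum(hint * d) * d
  if (vnorm(h) < 1e-6) h <- random_perpendicular(d) else h <- h / vnorm(h)
  e3 <- c(d[2L] * h[3L] - d[3L] * h[2L],
          d[3L] * h[1L] - d[1L] * h[3L],
          d[1L] * h[2L] - d[2L] * h[1L])
  cbind(d, h, e3 / vnorm(e3))
}

#' Generate ground-truth nuclei for a phantom spheroid
#'
#' Nucleus centres are sampled uniformly in the spheroid, rejected when two
#' centres come closer than the sum of the nuclei's L1 (no overlap), and each
#' long axis is drawn in the requested orientation mode, then perturbed by
#' the orientation noise. Deterministic for a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return Object of class `phantom_truth`: the spec, the spheroid `center`
#'   (um, in the rendered frame) and `radius`, and `nuclei`, a named list of
#'   [ellipsoid()] objects.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$n_nuclei
  R <- spec$spheroid_radius
  c0 <- rep(R + 8, 3L)  # spheroid centre in the rendered coordinate frame

  ar <- 1 + stats::rlnorm(n, spec$aspect_ratio_meanlog, spec$aspect_ratio_sdlog)
  L3 <- rep(spec$nucleus_l3_um, n)
  L1 <- ar * L3
  L2 <- L3 * ar^stats::runif(n, 0.3, 0.7)

  centers <- matrix(NA_real_, n, 3L)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 500L * n
  while (placed < n) {
    if ((attempts <- attempts + 1L) > max_attempts)
      stop(sprintf("could not place %d non-overlapping nuclei in a radius-%g spheroid",
                   n, R))
    rmax <- R - L1[placed + 1L] - 1
    if (rmax <= 0) stop("nuclei are too large for the spheroid radius")
    cand <- random_unit_vector() * rmax * stats::runif(1L)^(1 / 3)
    if (spec$shape == "capped" && cand[3L] > 0.6 * R) next
    ok <- TRUE
    if (placed > 0L) {
      dd <- sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 3L, byrow = TRUE))^2))
      ok <- all(dd >= L1[seq_len(placed)] + L1[placed + 1L])
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }

  nuclei <- vector("list", n)
  for (i in seq_len(n)) {
    rad <- centers[i, ]
    radial <- if (vnorm(rad) < 1e-9) c(0, 0, 1) else rad / vnorm(rad)
    e1 <- draw_oriented_axis(spec$orientation_mode, radial,
                             spec$orientation_noise_deg)
    frame <- complete_frame(e1, radial)
    nuclei[[i]] <- ellipsoid(c0 + centers[i, ], frame, c(L1[i], L2[i], L3[i]))
  }
  names(nuclei) <- sprintf("n%03d", seq_len(n))
  structure(list(spec = spec, center = c0, radius = R, nuclei = nuclei),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d nuclei in a radius-%g um %s spheroid (%s orientation)\n",
              length(x$nuclei), x$radius, x$spec$shape,
              x$spec$orientation_mode))
  invisible(x)
}

#' True long-axis angles of phantom nuclei to the spheroid surface normal
#'
#' For the spherical phantom the outward normal at the closest surface point
#' is the radial direction, so the true angle is the angle between e1 and the
#' centre-to-nucleus vector.
#'
#' @param gt a `phantom_truth` object.
#' @return Numeric vector of angles in degrees in \[0, 90\].
#' @export
true_orientation_angles <- function(gt) {
  stopifnot(inherits(gt, "phantom_truth"))
  vapply(gt$nuclei, function(e) {
    r <- e$center - gt$center
    if (vnorm(r) < 1e-9) r <- c(0, 0, 1)
    angle_to_normal(e$axes[, 1L], r)
  }, numeric(1L))
}

#' True depths of phantom nuclei below the spheroid surface
#'
#' @param gt a `phantom_truth` object.
#' @return Numeric vector, `radius - |centre offset|`, in um.
#' @export
true_depths <- function(gt) {
  stopifnot(inherits(gt, "phantom_truth"))
  vapply(gt$nuclei, function(e) gt$radius - vnorm(e$center - gt$center),
         numeric(1L))
}

#' Sample boundary-point annotations from a true ellipsoid
#'
#' Emulates the manual tri-view clicking: points are sampled on the
#' intersection ellipses of the ellipsoid surface with the three coordinate
#' planes through its centre (the xy, yz and xz views of a central plane),
#' with optional isotropic Gaussian jitter.
#'
#' @param e an [ellipsoid()].
#' @param points_per_view points per view (>= 3).
#' @param jitter_sd isotropic jitter standard deviation, um.
#' @param seed optional seed for reproducible sampling.
#' @return An [annotation_set()].
#' @export
sample_annotations <- function(e, points_per_view = 8L, jitter_sd = 0,
                               seed = NULL) {
  stopifnot(inherits(e, "ellipsoid"))
  if (points_per_view < 3L) stop("need at least 3 points per view")
  if (!is.null(seed)) set.seed(seed)
  M <- e$axes %*% diag(1 / e$lengths^2) %*% t(e$axes)
  views <- list(xy = c(1L, 2L), yz = c(2L, 3L), xz = c(1L, 3L))
  pts <- NULL
  tags <- NULL
  for (v in names(views)) {
    ij <- views[[v]]
    B <- M[ij, ij]
    eg <- eigen(B, symmetric = TRUE)
    theta <- stats::runif(1L, 0, 2 * pi) +
      2 * pi * (seq_len(points_per_view) - 1L) / points_per_view
    uv <- cbind(cos(theta) / sqrt(eg$values[1L]),
                sin(theta) / sqrt(eg$values[2L])) %*% t(eg$vectors)
    p <- matrix(e$center, points_per_view, 3L, byrow = TRUE)
    p[, ij] <- p[, ij] + uv
    pts <- rbind(pts, p)
    tags <- c(tags, rep(v, points_per_view))
  }
  if (jitter_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd), nrow(pts), 3L)
  annotation_set("phantom", pts, tags)
}

#' Render a phantom spheroid as a fluorescence z-stack
#'
#' Voxels inside a nucleus take the nucleus grey level, the rest of the
#' spheroid the cytoplasm level, outside the background level. Fluorescence
#' is attenuated as `exp(-attenuation x depth)`, the volume is blurred with
#' a Gaussian PSF, and Poisson shot noise plus Gaussian read noise are added.
#' Deterministic for a fixed spec seed.
#'
#' @param gt a `phantom_truth` object from [generate_ground_truth()].
#' @param grid_dim optional explicit grid dimension `(nz, ny, nx)`; an error
#'   is raised if the spheroid does not fit. By default the grid is sized to
#'   the spheroid plus an 8 um margin.
#' @return A [voxel_grid()].
#' @export
render_volume <- function(gt, grid_dim = NULL) {
  stopifnot(inherits(gt, "phantom_truth"))
  spec <- gt$spec
  sp <- spec$spacing
  extent <- 2 * (gt$radius + 8)
  if (is.null(grid_dim))
    grid_dim <- c(floor(extent / sp[1L]) + 1L,
                  floor(extent / sp[2L]) + 1L,
                  floor(extent / sp[3L]) + 1L)
  phys_max <- (grid_dim - 1L) * sp  # (z, y, x)
  if (gt$center[3L] + gt$radius > phys_max[1L] ||
      gt$center[2L] + gt$radius > phys_max[2L] ||
      gt$center[1L] + gt$radius > phys_max[3L] ||
      any(gt$center - gt$radius < 0))
    stop("spheroid exceeds the voxel grid")

  bg <- spec$intensity[["background"]]
  cyto <- spec$intensity[["cytoplasm"]]
  nuc <- spec$intensity[["nucleus"]]
  xs <- (seq_len(grid_dim[3L]) - 1L) * sp[3L]
  ys <- (seq_len(grid_dim[2L]) - 1L) * sp[2L]
  c0 <- gt$center
  R <- gt$radius

  # per-nucleus quadratic forms and world-axis bounding half-extents
  nM <- lapply(gt$nuclei, function(e)
    e$axes %*% diag(1 / e$lengths^2) %*% t(e$axes))
  nC <- t(vapply(gt$nuclei, function(e) e$center, numeric(3L)))
  nH <- t(vapply(gt$nuclei, function(e)
    sqrt(colSums((e$lengths * t(e$axes))^2)), numeric(3L)))

  dy2 <- (ys - c0[2L])^2
  dx2 <- (xs - c0[1L])^2
  arr <- array(0, grid_dim)
  for (iz in seq_len(grid_dim[1L])) {
    z <- (iz - 1L) * sp[1L]
    r2 <- outer(dy2, dx2, "+") + (z - c0[3L])^2
    inside <- r2 <= R^2
    if (spec$shape == "capped")
      inside <- inside & (z - c0[3L] <= 0.6 * R)
    fluor <- matrix(bg, grid_dim[2L], grid_dim[3L])
    fluor[inside] <- cyto
    hit <- which(abs(nC[, 3L] - z) <= nH[, 3L])
    for (k in hit) {
      jy <- which(abs(ys - nC[k, 2L]) <= nH[k, 2L])
      jx <- which(abs(xs - nC[k, 1L]) <= nH[k, 1L])
      if (length(jy) == 0L || length(jx) == 0L) next
      M <- nM[[k]]
      ddx <- xs[jx] - nC[k, 1L]
      ddy <- ys[jy] - nC[k, 2L]
      ddz <- z - nC[k, 3L]
      q <- outer(M[2L, 2L] * ddy^2 + 2 * M[2L, 3L] * ddy * ddz,
                 M[1L, 1L] * ddx^2 + 2 * M[1L, 3L] * ddx * ddz, "+") +
        2 * M[1L, 2L] * outer(ddy, ddx) + M[3L, 3L] * ddz^2
      sub <- fluor[jy, jx, drop = FALSE]
      sub[q <= 1] <- nuc
      fluor[jy, jx] <- sub
    }
    depth <- pmax(0, R - sqrt(r2))
    arr[iz, , ] <- bg + (fluor - bg) * exp(-spec$attenuation_per_um * depth)
  }

  grid <- voxel_grid(arr, sp)
  if (spec$psf_sigma_um > 0) grid <- denoise(grid, spec$psf_sigma_um)
  arr <- grid$intensities

  set.seed(spec$seed + 1000003L)
  if (spec$poisson_scaling > 0) {
    lam <- pmax(arr, 0) * spec$poisson_scaling
    arr <- array(stats::rpois(length(lam), lam) / spec$poisson_scaling,
                 dim(arr))
  }
  if (spec$read_noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, spec$read_noise_sd)
  voxel_grid(arr, sp)
}

#' Generate metaphase-plate tracks with known division-axis orientation
#'
#' Each cell gets a flattened plate ellipsoid whose shortest axis (the
#' division axis) is drawn in the spec's orientation mode, plus two earlier
#' decoy plates with a perpendicular axis and an anaphase frame, so that the
#' last-plate-before-anaphase selection rule is exercised.
#'
#' @param spec a [phantom_spec()]; `n_nuclei` is the number of cells.
#' @param plate_lengths plate semi-axes (L1, L2, L3) in um; flattened along
#'   L3 (the division axis).
#' @return List with `tracks` (list of [plate_track()]), `true_angles`
#'   (degrees) and `center`/`radius` of the spheroid.
#' @export
generate_division_plates <- function(spec, plate_lengths = c(4, 3.6, 1.2)) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 2000003L)
  n <- spec$n_nuclei
  R <- spec$spheroid_radius
  c0 <- rep(R + 8, 3L)
  tracks <- vector("list", n)
  true_angles <- numeric(n)
  for (i in seq_len(n)) {
    cen <- random_unit_vector() * (R - plate_lengths[1L] - 1) *
      stats::runif(1L)^(1 / 3)
    radial <- if (vnorm(cen) < 1e-9) c(0, 0, 1) else cen / vnorm(cen)
    d <- draw_oriented_axis(spec$orientation_mode, radial,
                            spec$orientation_noise_deg)
    frame <- complete_frame(d, radial)          # columns: d, perp, perp
    axes <- frame[, c(2L, 3L, 1L)]              # shortest axis e3 = d
    plate <- ellipsoid(c0 + cen, axes, plate_lengths)
    decoy <- ellipsoid(c0 + cen, frame, plate_lengths)  # axis rotated 90 deg
    tracks[[i]] <- plate_track(sprintf("c%03d", i), frames = c(1L, 2L, 3L),
                               plates = list(decoy, decoy, plate),
                               anaphase_frame = 4L)
    true_angles[i] <- angle_to_normal(d, radial)
  }
  list(tracks = tracks, true_angles = true_angles, center = c0, radius = R)
}

#' Generate a simulated mitosis event table
#'
#' Phase durations are drawn from normal distributions truncated below at
#' `min_duration_min` and discretized to the frame interval. Condensation
#' times are uniform over the recording (extended one mean prometaphase
#' before its start), so a realistic fraction of events is censored at both
#' ends: condensation before the first frame, or plate/anaphase after the
#' last.
#'
#' @param n number of cells.
#' @param prometaphase_mean,prometaphase_sd prometaphase duration
#'   distribution, minutes.
#' @param metaphase_mean,metaphase_sd metaphase duration distribution,
#'   minutes.
#' @param frame_interval_min minutes per frame.
#' @param recording_length_frames number of recorded frames.
#' @param min_duration_min lower truncation of both duration distributions.
#' @param seed integer seed.
#' @return A [mitosis_events()] data frame with extra ground-truth columns
#'   `true_prometaphase_min` and `true_metaphase_min` (continuous, before
#'   frame discretization).
#' @export
generate_mitosis_events <- function(n,
                                    prometaphase_mean = 14.4,
                                    prometaphase_sd = 7.6,
                                    metaphase_mean = 13,
                                    metaphase_sd = 5,
                                    frame_interval_min = 4,
                                    recording_length_frames = 60L,
                                    min_duration_min = 4,
                                    seed = 1L) {
  if (n < 1L || prometaphase_mean <= 0 || prometaphase_sd < 0 ||
      metaphase_mean <= 0 || metaphase_sd < 0 || frame_interval_min <= 0)
    stop("cohort parameters must be positive (sd may be 0)")
  set.seed(as.integer(seed))
  rtrunc <- function(n, mu, sd) {
    if (sd == 0) return(rep(mu, n))   # degenerate distribution
    lo <- stats::pnorm(min_duration_min, mu, sd)
    stats::qnorm(stats::runif(n, lo, 1), mu, sd)
  }
  pro <- rtrunc(n, prometaphase_mean, prometaphase_sd)
  met <- rtrunc(n, metaphase_mean, metaphase_sd)

  pre <- ceiling(prometaphase_mean / frame_interval_min)
  cond_real <- sample(seq.int(-pre, recording_length_frames - 1L), n,
                      replace = TRUE)
  met_frame <- cond_real + round(pro / frame_interval_min)
  ana_frame <- met_frame + round(met / frame_interval_min)
  last <- recording_length_frames - 1L

  censored <- cond_real < 0L
  met_obs <- met_frame >= 0L & met_frame <= last
  ana_obs <- met_obs & ana_frame <= last

  ev <- mitosis_events(cell_id = sprintf("m%04d", seq_len(n)),
                       condensation_frame = pmax(cond_real, 0L),
                       metaphase_frame = ifelse(met_obs, met_frame, NA),
                       anaphase_frame = ifelse(ana_obs, ana_frame, NA),
                       condensation_censored = censored,
                       last_frame = last)
  ev$true_prometaphase_min <- pro
  ev$true_metaphase_min <- met
  ev
}
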