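# Spheroid envelope extraction from a fluorescence z-stack:
# Gaussian denoise -> threshold -> convex hull of the 3D binary image,
# triangulated, plus depth-below-surface queries.

#' 3D intensity grid with physical voxel spacing
#'
#' @param intensities 3D numeric array indexed `[z, y, x]`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um (z-step first, matching
#'   the acquisition axis order).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, spacing = c(1, 0.65, 0.65)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array [z, y, x]")
  if (any(dim(intensities) < 1L)) stop("intensities must be non-empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx) in um")
  structure(list(intensities = intensities, spacing = spacing),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_grid: %d x %d x %d voxels (z, y, x), spacing %.3g/%.3g/%.3g um\n",
              d[1L], d[2L], d[3L],
              x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  cat(sprintf("  physical extent: %.1f x %.1f x %.1f um, intensity range [%.3g, %.3g]\n",
              (d[1L] - 1L) * x$spacing[1L], (d[2L] - 1L) * x$spacing[2L],
              (d[3L] - 1L) * x$spacing[3L],
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary mask aligned with a voxel grid
#'
#' @param mask 3D logical array `[z, y, x]`.
#' @param spacing voxel spacing `(dz, dy, dx)` in um.
#' @return An object of class `binary_grid`.
#' @export
binary_grid <- function(mask, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("mask must be a 3D logical array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values")
  structure(list(mask = mask, spacing = spacing), class = "binary_grid")
}

gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Sparse banded convolution matrix for a symmetric kernel (zero boundary).
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  diags <- lapply(-r:r, function(k) rep(kernel[k + r + 1L], n - abs(k)))
  Matrix::bandSparse(n, n, k = -r:r, diagonals = diags)
}

#' Gaussian denoising of a z-stack
#'
#' Separable Gaussian convolution with one physical width `sigma_um`; the
#' per-axis sigma in voxels is `sigma_um / spacing` so anisotropic stacks are
#' smoothed isotropically in physical space. Outside the stack the image is
#' treated as zero. `sigma_um = 0` is the identity.
#'
#' @param grid a [voxel_grid()].
#' @param sigma_um Gaussian standard deviation in um (default 2).
#' @return A denoised [voxel_grid()].
#' @export
denoise <- function(grid, sigma_um = 2) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(sigma_um) || sigma_um < 0)
    stop("sigma_um must be non-negative")
  if (sigma_um == 0) return(grid)

  arr <- grid$intensities
  d <- dim(arr)
  sig <- sigma_um / grid$spacing   # voxels per axis (z, y, x)

  # axis 1 (z): fastest-varying index, convolve columns directly
  if (sig[1L] > 0) {
    K <- conv_band_matrix(d[1L], gaussian_kernel(sig[1L]))
    dim(arr) <- c(d[1L], d[2L] * d[3L])
    arr <- as.matrix(K %*% arr)
    dim(arr) <- d
  }
  # axis 2 (y): per x-slice right-multiplication
  if (sig[2L] > 0) {
    tK <- Matrix::t(conv_band_matrix(d[2L], gaussian_kernel(sig[2L])))
    for (i in seq_len(d[3L]))
      arr[, , i] <- as.matrix(arr[, , i] %*% tK)
  }
  # axis 3 (x): collapse (z, y) and right-multiply
  if (sig[3L] > 0) {
    tK <- Matrix::t(conv_band_matrix(d[3L], gaussian_kernel(sig[3L])))
    dim(arr) <- c(d[1L] * d[2L], d[3L])
    arr <- as.matrix(arr %*% tK)
    dim(arr) <- d
  }
  voxel_grid(arr, grid$spacing)
}

#' Otsu threshold of a 3D intensity array
#'
#' Maximizes between-class variance over a 256-bin histogram of the whole
#' volume. Returns the threshold level (upper edge of the background class).
#'
#' @param x numeric array or vector of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold level on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("intensities must be finite")
  if (rng[1L] == rng[2L])
    stop("flat image: Otsu threshold undefined (no bimodality)")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  w <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(w)
  mu_t <- sum(w * mids)
  mu0 <- cumsum(w * mids)
  valid <- w0 > 0 & w0 < 1
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!valid] <- -Inf
  edges[which.max(between) + 1L]
}

#' Threshold a z-stack into a 3D binary image
#'
#' Foreground is strictly greater than the threshold. The Otsu level is
#' computed on the full 3D histogram (256 bins).
#'
#' @param grid a [voxel_grid()].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level threshold level, required for `method = "fixed"`.
#' @param min_foreground_fraction emit a warning when the foreground fraction
#'   falls below this (uneven staining can preclude envelope extraction).
#' @return A [binary_grid()].
#' @export
binarize <- function(grid, method = c("otsu", "fixed"), level = NULL,
                     min_foreground_fraction = 0.01) {
  stopifnot(inherits(grid, "voxel_grid"))
  method <- match.arg(method)
  thr <- if (method == "otsu") otsu_threshold(grid$intensities)
         else {
           if (is.null(level)) stop("method = 'fixed' requires a level")
           level
         }
  mask <- grid$intensities > thr
  frac <- mean(mask)
  if (frac < min_foreground_fraction)
    warning(sprintf("foreground fraction %.2g%% is very low; envelope extraction may fail",
                    100 * frac))
  out <- binary_grid(mask, grid$spacing)
  attr(out, "threshold") <- thr
  out
}

# Physical (x, y, z) um coordinates of voxel centers flagged TRUE, thinned to
# the 6-connectivity boundary of the foreground (interior voxels cannot be
# hull vertices).
foreground_boundary_coords <- function(bg) {
  m <- bg$mask
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, src) acc & src
  # a voxel is interior if all 6 neighbours (in-volume) are foreground
  pad <- function(along, side) {
    idx <- lapply(d, seq_len)
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    if (side > 0) { idx[[along]] <- 2:d[along]; src[[along]] <- 1:(d[along] - 1L) }
    else { idx[[along]] <- 1:(d[along] - 1L); src[[along]] <- 2:d[along] }
    out[idx[[1L]], idx[[2L]], idx[[3L]]] <- m[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  for (along in 1:3) {
    interior <- shift_and(interior, pad(along, 1L))
    interior <- shift_and(interior, pad(along, -1L))
  }
  keep <- which(m & !interior, arr.ind = TRUE)
  sp <- bg$spacing
  cbind(x = (keep[, 3L] - 1) * sp[3L],
        y = (keep[, 2L] - 1) * sp[2L],
        z = (keep[, 1L] - 1) * sp[1L])
}

#' Convex hull of a 3D binary image as a triangle mesh
#'
#' The spheroid envelope: the smallest convex polyhedron containing all
#' foreground voxel centers, in physical um coordinates (anisotropic spacing
#' is applied before hulling), returned as a triangulation with outward face
#' normals.
#'
#' @param bg a [binary_grid()].
#' @param keep_largest_component drop all but the largest 6-connected
#'   foreground component first (off by default; no morphological cleanup).
#' @return A [triangle_mesh()].
#' @export
extract_convex_hull <- function(bg, keep_largest_component = FALSE) {
  stopifnot(inherits(bg, "binary_grid"))
  if (keep_largest_component && any(bg$mask)) {
    d <- dim(bg$mask)
    m <- .largest_component6(as.logical(bg$mask), as.integer(d))
    bg <- binary_grid(array(m, d), bg$spacing)
  }
  pts <- foreground_boundary_coords(bg)
  if (nrow(pts) < 4L)
    stop("fewer than 4 foreground voxels: cannot build a 3D envelope")
  convex_hull_mesh(pts)
}

#' Depth of a point below the spheroid surface
#'
#' Distance from `p` to the nearest point of the envelope mesh (um); zero on
#' the hull. Used for the 0-100 um shell selection of peripheral nuclei.
#'
#' @param p numeric length-3 point (um).
#' @param mesh a [triangle_mesh()] envelope.
#' @return Distance in um.
#' @export
depth_from_surface <- function(p, mesh) {
  closest_surface_point(mesh, p)$distance
}

#' Read a multi-page TIFF z-stack
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(dz, dy, dx)` in um; the default takes the
#'   1 um z-step of the acquisition and a typical 10x pixel size.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, spacing = c(1, 0.65, 0.65)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1L]])
  arr <- array(0, c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  voxel_grid(arr, spacing)
}

#' Write a voxel grid as a 16-bit multi-page TIFF
#'
#' Intensities are clipped to `[0, 65535]` and stored as 16-bit grey levels,
#' one page per z-plane.
#'
#' @param grid a [voxel_grid()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  arr <- pmin(pmax(round(grid$intensities), 0), 65535) / 65535
  pages <- lapply(seq_len(dim(arr)[1L]), function(i) arr[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Envelope summary as JSON
#'
#' Writes vertex count, face count, enclosed volume and centroid of a hull
#' mesh to a JSON file.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output JSON path.
#' @return The summary list, invisibly.
#' @export
write_hull_summary <- function(mesh, path) {
  s <- list(n_vertices = nrow(mesh$vertices),
            n_faces = nrow(mesh$faces),
            volume_um3 = mesh_volume(mesh),
            centroid_um = as.numeric(colMeans(mesh$vertices)))
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
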