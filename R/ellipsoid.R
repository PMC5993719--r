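# Ellipsoid fitting to manually delimited nucleus boundary points.
#
# A nucleus is modelled as an ellipsoid with centre c, orthonormal axes
# e1, e2, e3 and semi-axis lengths L1 >= L2 >= L3 (um). The fit is algebraic
# least squares on the general quadric
#   a x^2 + b y^2 + c z^2 + d xy + e xz + f yz + g x + h y + i z + j = 0
# under a unit-norm coefficient constraint (smallest right singular vector of
# the design matrix), followed by an explicit ellipsoid-validity check.

#' Construct an ellipsoid
#'
#' @param center numeric length-3 centre (um).
#' @param axes 3 x 3 matrix whose columns are orthonormal direction vectors;
#'   column i is paired with `lengths[i]`.
#' @param lengths three positive semi-axis lengths (um); reordered internally
#'   (with their axes) so that L1 >= L2 >= L3.
#' @param axis_ratio_tol if L1/L2 is below this the long axis is ill-defined
#'   (near-oblate or spherical nucleus) and the ellipsoid is flagged
#'   `orientation_reliable = FALSE`.
#' @return An object of class `ellipsoid` with elements `center`, `axes`
#'   (columns e1, e2, e3), `lengths` (L1, L2, L3) and `orientation_reliable`.
#' @export
ellipsoid <- function(center, axes, lengths, axis_ratio_tol = 1.02) {
  center <- as_point3(center)
  axes <- as.matrix(axes)
  lengths <- as.numeric(lengths)
  if (!all(dim(axes) == c(3L, 3L))) stop("axes must be a 3 x 3 matrix")
  if (length(lengths) != 3L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be three positive finite values")
  g <- crossprod(axes)
  if (max(abs(g - diag(3))) > 1e-6)
    stop("axes must be pairwise orthonormal")

  ord <- order(lengths, decreasing = TRUE)
  lengths <- lengths[ord]
  axes <- axes[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude component of each axis positive
  for (i in 1:3) {
    k <- which.max(abs(axes[, i]))
    if (axes[k, i] < 0) axes[, i] <- -axes[, i]
  }
  structure(list(center = center, axes = axes, lengths = lengths,
                 orientation_reliable = lengths[1L] / lengths[2L] >= axis_ratio_tol),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("ellipsoid: centre (%.3f, %.3f, %.3f) um\n",
              x$center[1L], x$center[2L], x$center[3L]))
  cat(sprintf("  semi-axes L1=%.3f L2=%.3f L3=%.3f um  (aspect ratio %.3f)\n",
              x$lengths[1L], x$lengths[2L], x$lengths[3L], aspect_ratio(x)))
  if (!x$orientation_reliable)
    cat("  long-axis orientation flagged unreliable (L1 ~ L2)\n")
  invisible(x)
}

#' Boundary-point annotation set for one nucleus
#'
#' Points delimited on the xy, yz and xz views of a central plane through the
#' nucleus. View tags are metadata only: all points enter one joint 3D fit.
#'
#' @param nucleus_id identifier.
#' @param points numeric n x 3 matrix of boundary points (um).
#' @param view character vector of view tags (`"xy"`, `"yz"` or `"xz"`),
#'   recycled to `nrow(points)`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(nucleus_id, points, view = "xy") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (any(!is.finite(points))) stop("annotation points must be finite")
  view <- rep_len(as.character(view), nrow(points))
  if (!all(view %in% c("xy", "yz", "xz")))
    stop("view must be one of 'xy', 'yz', 'xz'")
  structure(list(nucleus_id = nucleus_id, points = points, view = view),
            class = "annotation_set")
}

#' Read nucleus boundary annotations from CSV
#'
#' Expects columns `nucleus_id`, `view`, `x_um`, `y_um`, `z_um`.
#'
#' @param path CSV file path.
#' @return Named list of [annotation_set()] objects, one per nucleus.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nucleus_id", "view", "x_um", "y_um", "z_um")
  if (!all(need %in% names(d)))
    stop("annotation CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$nucleus_id), function(g)
    annotation_set(g$nucleus_id[1L],
                   cbind(g$x_um, g$y_um, g$z_um), g$view))
  out[order(names(out))]
}

#' Write nucleus boundary annotations to CSV
#'
#' @param annotations list of [annotation_set()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  rows <- lapply(annotations, function(a)
    data.frame(nucleus_id = a$nucleus_id, view = a$view,
               x_um = a$points[, 1L], y_um = a$points[, 2L],
               z_um = a$points[, 3L]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Fit an ellipsoid to 3D boundary points
#'
#' Algebraic least-squares quadric fit: the coefficient 10-vector minimizing
#' the sum of squared quadric residuals over the points, under a unit-norm
#' constraint, is the smallest right singular vector of the design matrix.
#' The quadric is then decomposed into centre, axes and lengths by
#' [quadric_to_ellipsoid()]. On noiseless points in general position on a
#' true ellipsoid the recovery is exact to numerical tolerance.
#'
#' @param annotation an [annotation_set()] or a plain n x 3 point matrix (um).
#' @return An [ellipsoid()].
#' @export
fit_ellipsoid <- function(annotation) {
  pts <- if (inherits(annotation, "annotation_set")) annotation$points
         else as.matrix(annotation)
  if (ncol(pts) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(pts) < 9L)
    stop("at least 9 points are needed to determine a quadric")

  ctr <- colMeans(pts)
  x0 <- sweep(pts, 2L, ctr)
  sv <- svd(x0, nu = 0L, nv = 0L)$d
  if (sv[3L] < 1e-8 * max(sv[1L], 1))
    stop("annotation points are coplanar or degenerate")

  s <- sqrt(mean(x0^2)) * sqrt(3)   # RMS radius, conditions the design matrix
  xn <- x0 / s
  x <- xn[, 1L]; y <- xn[, 2L]; z <- xn[, 3L]
  D <- cbind(x * x, y * y, z * z, x * y, x * z, y * z, x, y, z, 1)
  v <- svd(D, nu = 0L)$v[, 10L]

  e <- quadric_to_ellipsoid(v)
  ellipsoid(ctr + s * e$center, e$axes, s * e$lengths)
}

#' Decompose quadric coefficients into an ellipsoid
#'
#' Coefficients `(a, b, c, d, e, f, g, h, i, j)` of
#' `a x^2 + b y^2 + c z^2 + d xy + e xz + f yz + g x + h y + i z + j = 0`.
#' The centre solves the stationarity system of the quadric; axes and lengths
#' come from the eigendecomposition of the quadratic form normalized at the
#' centre. Raises an error if the quadric is not an ellipsoid.
#'
#' @param coeffs numeric length-10 coefficient vector.
#' @return An [ellipsoid()].
#' @export
quadric_to_ellipsoid <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != 10L) stop("coeffs must have length 10")
  A <- matrix(c(coeffs[1L], coeffs[4L] / 2, coeffs[5L] / 2,
                coeffs[4L] / 2, coeffs[2L], coeffs[6L] / 2,
                coeffs[5L] / 2, coeffs[6L] / 2, coeffs[3L]), 3L, 3L)
  b <- coeffs[7:9]
  scale <- max(abs(A))
  if (scale == 0 || abs(det(A)) < 1e-12 * scale^3)
    stop("best-fit quadric is not an ellipsoid (singular quadratic form)")
  ctr <- solve(A, -b / 2)
  k <- -(drop(ctr %*% A %*% ctr) + sum(b * ctr) + coeffs[10L])
  # (p - ctr)' A (p - ctr) = k ; need A/k positive definite
  eg <- eigen(A / k, symmetric = TRUE)
  if (any(eg$values <= 0))
    stop("best-fit quadric is not an ellipsoid (indefinite quadratic form)")
  # eigenvalues are 1/L^2, returned in decreasing order -> lengths increasing
  lengths <- rev(1 / sqrt(eg$values))
  axes <- eg$vectors[, 3:1, drop = FALSE]
  ellipsoid(ctr, axes, lengths)
}

#' Nucleus aspect ratio L1/L3
#'
#' Ratio of the longest to the shortest semi-axis: 1 for a sphere, larger for
#' more elongated nuclei.
#'
#' @param e an [ellipsoid()].
#' @return Aspect ratio (>= 1).
#' @export
aspect_ratio <- function(e) {
  stopifnot(inherits(e, "ellipsoid"))
  e$lengths[1L] / e$lengths[3L]
}

#' Is a nucleus elongated?
#'
#' A nucleus counts as elongated when its aspect ratio strictly exceeds the
#' threshold (default 1.5).
#'
#' @param e an [ellipsoid()].
#' @param threshold elongation cutoff on L1/L3.
#' @return Logical.
#' @export
is_elongated <- function(e, threshold = 1.5) {
  aspect_ratio(e) > threshold
}

#' Write fitted ellipsoids to CSV
#'
#' One row per nucleus: centre, axis components, lengths, aspect ratio, flags.
#'
#' @param ellipsoids named list of [ellipsoid()] objects (names are ids), or a
#'   list with `NULL` names in which case sequence numbers are used.
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_ellipsoids <- function(ellipsoids, path) {
  ids <- names(ellipsoids)
  if (is.null(ids)) ids <- as.character(seq_along(ellipsoids))
  rows <- mapply(function(e, id) {
    data.frame(nucleus_id = id,
               cx = e$center[1L], cy = e$center[2L], cz = e$center[3L],
               e1x = e$axes[1L, 1L], e1y = e$axes[2L, 1L], e1z = e$axes[3L, 1L],
               e2x = e$axes[1L, 2L], e2y = e$axes[2L, 2L], e2z = e$axes[3L, 2L],
               e3x = e$axes[1L, 3L], e3y = e$axes[2L, 3L], e3z = e$axes[3L, 3L],
               L1 = e$lengths[1L], L2 = e$lengths[2L], L3 = e$lengths[3L],
               aspect_ratio = aspect_ratio(e),
               orientation_reliable = e$orientation_reliable)
  }, ellipsoids, ids, SIMPLIFY = FALSE)
  d <- do.call(rbind, rows)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Read ellipsoids from a CSV written by [write_ellipsoids()]
#'
#' @param path CSV file path.
#' @return Named list of [ellipsoid()] objects.
#' @export
read_ellipsoids <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    ellipsoid(c(d$cx[i], d$cy[i], d$cz[i]),
              cbind(c(d$e1x[i], d$e1y[i], d$e1z[i]),
                    c(d$e2x[i], d$e2y[i], d$e2z[i]),
                    c(d$e3x[i], d$e3y[i], d$e3z[i])),
              c(d$L1[i], d$L2[i], d$L3[i])))
  names(out) <- d$nucleus_id
  out
}
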