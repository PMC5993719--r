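#' @useDynLib spheroidgeom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All geometry runs in physical micrometre coordinates; voxel-to-um conversion
# happens at I/O, never inside these operations.

as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("a 3D point must have three finite components")
  p
}

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10)
    stop(sprintf("zero-length %s has no direction", what))
  v / n
}

#' Triangulated surface mesh
#'
#' Builds a triangle mesh from a vertex matrix and 1-based face indices and
#' attaches unit face normals. For the convex envelopes this package works
#' with, normals are oriented outward (positive dot product between each
#' normal and the face centroid minus the mesh centroid).
#'
#' @param vertices numeric matrix, one vertex per row, columns x/y/z in um.
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `face_normals` (unit outward normals, one row per face).
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")

  ctr <- colMeans(vertices)
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  n <- cross_rows(b - a, c3 - a)
  len <- sqrt(rowSums(n * n))
  if (any(len < .Machine$double.eps * 100))
    stop("degenerate (collinear) triangle: invalid mesh face")
  n <- n / len
  centroid_f <- (a + b + c3) / 3
  flip <- rowSums(n * (centroid_f - rep(ctr, each = nrow(n)))) < 0
  n[flip, ] <- -n[flip, , drop = FALSE]

  structure(list(vertices = vertices, faces = faces, face_normals = n),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  ext <- apply(x$vertices, 2L, range)
  cat(sprintf("  extent (um): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  cat(sprintf("  enclosed volume: %.1f um^3\n", mesh_volume(x)))
  invisible(x)
}

# row-wise cross product of two n x 3 matrices
cross_rows <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Volume enclosed by a closed triangle mesh
#'
#' Divergence-theorem volume using outward-oriented faces.
#'
#' @param mesh a [triangle_mesh()].
#' @return Volume in um^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  # signed tetrahedron volumes to the origin; orientation taken from the
  # stored outward normals so vertex ordering need not be consistent
  n <- cross_rows(b - a, c3 - a)
  sgn <- sign(rowSums(n * mesh$face_normals))
  abs(sum(sgn * (rowSums(a * cross_rows(b, c3))) / 6))
}

#' Closest point on a single triangle
#'
#' Minimizes Euclidean distance from `p` over the closed triangle `(a, b, c)`,
#' returning the interior-, edge- or vertex-region solution. Used by the
#' surface-projection step that finds, for every nucleus, the nearest point
#' of the spheroid envelope.
#'
#' @param p,a,b,c numeric length-3 points (um).
#' @return List with `point` (length-3) and `distance` (um).
#' @export
closest_point_on_triangle <- function(p, a, b, c) {
  p <- as_point3(p); a <- as_point3(a); b <- as_point3(b); c <- as_point3(c)
  ab <- b - a; ac <- c - a
  cr <- c(ab[2L] * ac[3L] - ab[3L] * ac[2L],
          ab[3L] * ac[1L] - ab[1L] * ac[3L],
          ab[1L] * ac[2L] - ab[2L] * ac[1L])
  scale <- max(vnorm(ab), vnorm(ac))
  if (vnorm(cr) <= .Machine$double.eps * 100 * scale^2)
    stop("degenerate (collinear) triangle: invalid mesh face")

  ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(list(point = a, distance = vnorm(p - a)))

  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(list(point = b, distance = vnorm(p - b)))

  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    q <- a + ab * (d1 / (d1 - d3))
    return(list(point = q, distance = vnorm(p - q)))
  }

  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(list(point = c, distance = vnorm(p - c)))

  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    q <- a + ac * (d2 / (d2 - d6))
    return(list(point = q, distance = vnorm(p - q)))
  }

  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    q <- b + (c - b) * w
    return(list(point = q, distance = vnorm(p - q)))
  }

  denom <- 1 / (va + vb + vc)
  q <- a + ab * (vb * denom) + ac * (vc * denom)
  list(point = q, distance = vnorm(p - q))
}

# Vectorized closest point over all faces of a mesh for a single query point.
# Same region classification as closest_point_on_triangle, evaluated for every
# face at once; returns the per-face closest points and distances.
closest_points_all_faces <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c3 <- v[f[, 3L], , drop = FALSE]
  m <- nrow(f)
  pm <- matrix(p, nrow = m, ncol = 3L, byrow = TRUE)

  ab <- b - a; ac <- c3 - a
  ap <- pm - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- pm - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- pm - c3
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4

  q <- matrix(NA_real_, m, 3L)
  done <- rep(FALSE, m)
  take <- function(cond) { s <- cond & !done; done <<- done | s; s }

  s <- take(d1 <= 0 & d2 <= 0)
  q[s, ] <- a[s, , drop = FALSE]
  s <- take(d3 >= 0 & d4 <= d3)
  q[s, ] <- b[s, , drop = FALSE]
  s <- take(vc <= 0 & d1 >= 0 & d3 <= 0)
  if (any(s)) {
    t1 <- d1[s] / (d1[s] - d3[s])
    q[s, ] <- a[s, , drop = FALSE] + ab[s, , drop = FALSE] * t1
  }
  s <- take(d6 >= 0 & d5 <= d6)
  q[s, ] <- c3[s, , drop = FALSE]
  s <- take(vb <= 0 & d2 >= 0 & d6 <= 0)
  if (any(s)) {
    t1 <- d2[s] / (d2[s] - d6[s])
    q[s, ] <- a[s, , drop = FALSE] + ac[s, , drop = FALSE] * t1
  }
  s <- take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0)
  if (any(s)) {
    w <- (d4[s] - d3[s]) / ((d4[s] - d3[s]) + (d5[s] - d6[s]))
    q[s, ] <- b[s, , drop = FALSE] + (c3[s, , drop = FALSE] - b[s, , drop = FALSE]) * w
  }
  s <- !done
  if (any(s)) {
    denom <- 1 / (va[s] + vb[s] + vc[s])
    q[s, ] <- a[s, , drop = FALSE] +
      ab[s, , drop = FALSE] * (vb[s] * denom) +
      ac[s, , drop = FALSE] * (vc[s] * denom)
  }
  d <- sqrt(rowSums((q - pm)^2))
  list(points = q, distances = d)
}

#' Closest point of a mesh surface to a query point
#'
#' Minimum of [closest_point_on_triangle()] over all faces; ties between
#' equidistant faces are broken by the lowest face index.
#'
#' @param mesh a [triangle_mesh()].
#' @param p numeric length-3 query point (um).
#' @return List with `point`, `face_index` (1-based) and `distance` (um).
#' @export
closest_surface_point <- function(mesh, p) {
  if (!inherits(mesh, "triangle_mesh")) stop("mesh must be a triangle_mesh")
  if (nrow(mesh$faces) == 0L) stop("mesh has no faces")
  p <- as_point3(p)
  res <- closest_points_all_faces(mesh, p)
  i <- which.min(res$distances)  # which.min returns the first (lowest) index
  list(point = res$points[i, ], face_index = i, distance = res$distances[i])
}

#' Angle between an axis and a surface normal
#'
#' Acute angle between two lines (not arrows): `acos(|axis . normal|)` after
#' normalization, in degrees in \[0, 90\]. 90 degrees means the axis lies in
#' the tangent plane, i.e. parallel to the surface; 0 means it is radial.
#'
#' @param axis,normal numeric length-3 direction vectors (any nonzero length).
#' @return Angle in degrees in \[0, 90\].
#' @export
angle_to_normal <- function(axis, normal) {
  u <- unitize(as_point3(axis), "axis")
  n <- unitize(as_point3(normal), "normal")
  acos(pmin(1, abs(sum(u * n)))) * 180 / pi
}

#' Convex hull of a 3D point set as a triangle mesh
#'
#' Quickhull on the given points (um coordinates). Every input point lies on
#' the non-positive side of every face plane, within `tol`.
#'
#' @param points numeric n x 3 matrix.
#' @param tol planarity tolerance in um; points within `tol` of a face plane
#'   are treated as on the hull.
#' @return A [triangle_mesh()] with outward normals.
#' @export
convex_hull_mesh <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (nrow(points) < 4L)
    stop("need at least 4 non-coplanar points for a 3D convex hull")
  h <- .qhull3d(points, tol)
  triangle_mesh(points[h$vertex_index + 1L, , drop = FALSE], h$faces + 1L)
}

# TRUE if p is inside (or within tol of) a convex mesh: non-positive signed
# distance to every face plane.
inside_convex_mesh <- function(mesh, p, tol = 1e-9) {
  signed_plane_distance(mesh, p) <= tol
}

# Largest signed distance of p to the face planes of a convex mesh
# (negative inside, positive outside; for points outside this lower-bounds
# the true surface distance).
signed_plane_distance <- function(mesh, p) {
  a <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  max(rowSums(mesh$face_normals *
                (matrix(p, nrow(a), 3L, byrow = TRUE) - a)))
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply",
               "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.10g %.10g %.10g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read an ASCII PLY triangle mesh
#'
#' Minimal reader for meshes written by [write_ply()] (ASCII, xyz vertex
#' properties, triangular faces).
#'
#' @param path PLY file path.
#' @return A [triangle_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1L] != "ply" ||
      !grepl("^format ascii", lines[2L]))
    stop("not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1L]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1L]))
  hdr <- which(lines == "end_header")[1L]
  if (is.na(nv) || is.na(nf) || is.na(hdr)) stop("malformed PLY header")
  vtx <- do.call(rbind, lapply(strsplit(lines[hdr + seq_len(nv)], "\\s+"),
                               function(x) as.numeric(x[1:3])))
  fac <- do.call(rbind, lapply(strsplit(lines[hdr + nv + seq_len(nf)], "\\s+"),
                               function(x) {
                                 x <- as.integer(x)
                                 if (x[1L] != 3L) stop("only triangular faces supported")
                                 x[2:4] + 1L
                               }))
  triangle_mesh(vtx, fac)
}
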