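# Per-nucleus orientation relative to the spheroid surface, the elongation
# and depth filters, and cohort summaries.

#' Orientation of one nucleus relative to the spheroid surface
#'
#' Projects the ellipsoid centre onto the envelope, takes the outward normal
#' of the nearest face, and measures the acute angle between the nucleus long
#' axis e1 and that normal. 90 degrees means the long axis is parallel to the
#' surface.
#'
#' @param e a fitted [ellipsoid()].
#' @param mesh the spheroid envelope ([triangle_mesh()]).
#' @param nucleus_id identifier copied into the record.
#' @param max_outside_um maximum tolerated distance of the centre outside the
#'   hull before an annotation/hull mismatch error is raised.
#' @return One-row data frame: `nucleus_id`, `aspect_ratio`, `depth_um`,
#'   `angle_deg`, `elongated`, `orientation_reliable`.
#' @export
nucleus_orientation <- function(e, mesh, nucleus_id = NA_character_,
                                max_outside_um = 5) {
  stopifnot(inherits(e, "ellipsoid"), inherits(mesh, "triangle_mesh"))
  sdist <- signed_plane_distance(mesh, e$center)
  if (sdist > max_outside_um)
    stop(sprintf(paste0("ellipsoid centre lies %.2f um outside the envelope ",
                        "(> %g um): annotation/hull mismatch"),
                 sdist, max_outside_um))
  csp <- closest_surface_point(mesh, e$center)
  depth <- if (sdist <= 0) csp$distance else 0  # centres just outside sit at depth 0
  normal <- mesh$face_normals[csp$face_index, ]
  data.frame(nucleus_id = as.character(nucleus_id),
             aspect_ratio = aspect_ratio(e),
             depth_um = depth,
             angle_deg = angle_to_normal(e$axes[, 1L], normal),
             elongated = is_elongated(e),
             orientation_reliable = e$orientation_reliable,
             stringsAsFactors = FALSE)
}

#' Orientation records for a set of nuclei
#'
#' @param ellipsoids named list of [ellipsoid()] objects.
#' @param mesh the spheroid envelope.
#' @param max_outside_um passed to [nucleus_orientation()].
#' @return Data frame with one row per nucleus.
#' @export
orientation_records <- function(ellipsoids, mesh, max_outside_um = 5) {
  ids <- names(ellipsoids)
  if (is.null(ids)) ids <- as.character(seq_along(ellipsoids))
  do.call(rbind, mapply(nucleus_orientation, ellipsoids, nucleus_id = ids,
                        MoreArgs = list(mesh = mesh,
                                        max_outside_um = max_outside_um),
                        SIMPLIFY = FALSE))
}

#' Keep nuclei within a depth shell below the surface
#'
#' Both bounds are inclusive; the default keeps nuclei between 0 and 100 um
#' from the surface (the peripheral layers where confinement acts).
#'
#' @param records orientation record data frame.
#' @param min_depth,max_depth shell bounds in um.
#' @return The filtered data frame.
#' @export
shell_filter <- function(records, min_depth = 0, max_depth = 100) {
  if (min_depth > max_depth) stop("min_depth must not exceed max_depth")
  records[records$depth_um >= min_depth & records$depth_um <= max_depth, ,
          drop = FALSE]
}

#' Cohort summary of nucleus geometry and orientation
#'
#' Aspect-ratio statistics cover all records; the elongated fraction uses the
#' strict L1/L3 > 1.5 criterion; angle statistics are restricted to nuclei
#' that are both elongated and have a reliable long-axis orientation
#' (near-spherical nuclei have no meaningful long axis).
#'
#' @param records orientation record data frame (>= 1 row).
#' @return List with `n`, type-7 quartiles of the aspect ratio,
#'   `elongated_fraction`, `n_angle` and angle quartiles (NA, with
#'   `angle_summary_empty = TRUE`, when no nucleus qualifies).
#' @export
summarize_orientation <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot summarize an empty cohort")
  q <- function(x) unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  rq <- q(records$aspect_ratio)
  sub <- records[records$elongated & records$orientation_reliable, , drop = FALSE]
  has_angle <- nrow(sub) > 0L
  aq <- if (has_angle) q(sub$angle_deg) else rep(NA_real_, 3L)
  list(n = nrow(records),
       ratio_q1 = rq[1L], ratio_median = rq[2L], ratio_q3 = rq[3L],
       elongated_fraction = mean(records$elongated),
       n_angle = nrow(sub),
       angle_q1 = aq[1L], angle_median = aq[2L], angle_q3 = aq[3L],
       angle_summary_empty = !has_angle)
}

#' Write orientation records and summary
#'
#' @param records orientation record data frame.
#' @param csv_path output CSV path (one record per row), or NULL to skip.
#' @param json_path output JSON path for the cohort summary, or NULL to skip.
#' @return The summary list, invisibly.
#' @export
write_orientation_results <- function(records, csv_path = NULL,
                                      json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(records, csv_path, row.names = FALSE)
  s <- summarize_orientation(records)
  if (!is.null(json_path))
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
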