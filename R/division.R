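# Division-axis orientation from metaphase-plate ellipsoids. The plate is a
# flattened ellipsoid; its shortest axis e3 is the division axis. The plate
# used is the last one detected strictly before anaphase onset.

#' Time-ordered metaphase-plate fits for one mitotic cell
#'
#' @param cell_id identifier.
#' @param frames strictly increasing integer frame indices, one per plate.
#' @param plates list of [ellipsoid()] plate fits, same length as `frames`.
#' @param anaphase_frame frame index of anaphase onset, or `NA` if anaphase
#'   was never observed in the recording.
#' @return An object of class `plate_track`.
#' @export
plate_track <- function(cell_id, frames, plates, anaphase_frame = NA) {
  frames <- as.integer(frames)
  if (length(frames) == 0L) stop("a plate track needs at least one plate")
  if (length(plates) != length(frames))
    stop("frames and plates must have the same length")
  if (any(diff(frames) <= 0L)) stop("plate frames must be strictly increasing")
  if (!all(vapply(plates, inherits, logical(1L), "ellipsoid")))
    stop("plates must be ellipsoid objects")
  structure(list(cell_id = cell_id, frames = frames, plates = plates,
                 anaphase_frame = if (is.na(anaphase_frame)) NA_integer_
                                  else as.integer(anaphase_frame)),
            class = "plate_track")
}

#' Reference metaphase plate of a track
#'
#' The plate with the largest frame index strictly below the anaphase frame.
#' When anaphase was never observed the last plate is used and the result is
#' flagged uncensored-by-anaphase.
#'
#' @param track a [plate_track()].
#' @return List with `plate` ([ellipsoid()]), `frame` and `anaphase_observed`.
#' @export
select_reference_plate <- function(track) {
  stopifnot(inherits(track, "plate_track"))
  if (is.na(track$anaphase_frame)) {
    k <- length(track$frames)
    return(list(plate = track$plates[[k]], frame = track$frames[k],
                anaphase_observed = FALSE))
  }
  before <- which(track$frames < track$anaphase_frame)
  if (length(before) == 0L)
    stop(sprintf("cell %s: no metaphase plate strictly before anaphase (frame %d)",
                 track$cell_id, track$anaphase_frame))
  k <- max(before)
  list(plate = track$plates[[k]], frame = track$frames[k],
       anaphase_observed = TRUE)
}

#' Division-axis angle relative to the spheroid surface
#'
#' The division axis is the shortest axis e3 of the flattened plate
#' ellipsoid; the angle is taken to the outward normal at the closest point
#' of the envelope to the plate centre. 90 degrees corresponds to a division
#' axis parallel to the spheroid surface (plate perpendicular to it).
#'
#' @param plate a plate [ellipsoid()].
#' @param mesh the spheroid envelope ([triangle_mesh()]).
#' @param min_flatness minimum L2/L3 ratio for the shortest axis to be
#'   considered well defined.
#' @return Angle in degrees in \[0, 90\].
#' @export
division_angle <- function(plate, mesh, min_flatness = 1.1) {
  stopifnot(inherits(plate, "ellipsoid"), inherits(mesh, "triangle_mesh"))
  if (plate$lengths[2L] / plate$lengths[3L] <= min_flatness)
    stop(sprintf("plate is not flattened (L2/L3 = %.3f <= %g): shortest axis ill-defined",
                 plate$lengths[2L] / plate$lengths[3L], min_flatness))
  csp <- closest_surface_point(mesh, plate$center)
  angle_to_normal(plate$axes[, 3L], mesh$face_normals[csp$face_index, ])
}

#' Division-axis records for a set of plate tracks
#'
#' Selects the reference plate of every track and measures its division-axis
#' angle and depth below the surface.
#'
#' @param tracks list of [plate_track()] objects.
#' @param mesh the spheroid envelope.
#' @param min_flatness passed to [division_angle()].
#' @return Data frame: `cell_id`, `frame`, `angle_deg`, `depth_um`,
#'   `anaphase_observed`.
#' @export
division_records <- function(tracks, mesh, min_flatness = 1.1) {
  rows <- lapply(tracks, function(tr) {
    ref <- select_reference_plate(tr)
    data.frame(cell_id = as.character(tr$cell_id),
               frame = ref$frame,
               angle_deg = division_angle(ref$plate, mesh, min_flatness),
               depth_um = depth_from_surface(ref$plate$center, mesh),
               anaphase_observed = ref$anaphase_observed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read metaphase-plate tracks from CSV
#'
#' One row per plate fit, columns `cell_id`, `frame`, `cx`, `cy`, `cz`,
#' `e1x`..`e3z`, `L1`, `L2`, `L3` and optionally `anaphase_frame` (constant
#' within a cell; missing or NA means anaphase was not observed). This is the
#' shared schema for plates fitted in-package and for centre+axes exports
#' from external segmentation tools.
#'
#' @param path CSV file path.
#' @return List of [plate_track()] objects.
#' @export
read_plate_tracks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "cx", "cy", "cz",
            "e1x", "e1y", "e1z", "e2x", "e2y", "e2z", "e3x", "e3y", "e3z",
            "L1", "L2", "L3")
  if (!all(need %in% names(d)))
    stop("plate CSV must have columns ", paste(need, collapse = ", "))
  has_ana <- "anaphase_frame" %in% names(d)
  lapply(split(d, d$cell_id), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    plates <- lapply(seq_len(nrow(g)), function(i)
      ellipsoid(c(g$cx[i], g$cy[i], g$cz[i]),
                cbind(c(g$e1x[i], g$e1y[i], g$e1z[i]),
                      c(g$e2x[i], g$e2y[i], g$e2z[i]),
                      c(g$e3x[i], g$e3y[i], g$e3z[i])),
                c(g$L1[i], g$L2[i], g$L3[i])))
    ana <- if (has_ana && any(!is.na(g$anaphase_frame)))
      g$anaphase_frame[!is.na(g$anaphase_frame)][1L] else NA
    plate_track(g$cell_id[1L], g$frame, plates, ana)
  })
}
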