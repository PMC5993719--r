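# Mitotic phase durations from time-lapse event annotations.
#
# Per cell, three annotated frames: DNA condensation (first frame where the
# nucleus appears non-homogeneous), metaphase-plate establishment, and
# anaphase onset (first frame with separated sister chromatids).
# Prometaphase = condensation -> plate; metaphase = plate -> anaphase.
# Frames are `frame_interval_min` minutes apart (4 min by default).

#' Build a table of mitosis event annotations
#'
#' @param cell_id identifiers.
#' @param condensation_frame,metaphase_frame,anaphase_frame integer frame
#'   indices; use `NA` when the event was not observed in the recording.
#' @param condensation_censored logical: condensation had already happened
#'   when the recording started (frame index is then the first recorded
#'   frame and the prometaphase duration is only a lower bound).
#' @param last_frame last recorded frame index, used to bound durations of
#'   cells whose plate or anaphase was never observed.
#' @return Data frame of class `mitosis_events`.
#' @export
mitosis_events <- function(cell_id, condensation_frame, metaphase_frame,
                           anaphase_frame, condensation_censored = FALSE,
                           last_frame) {
  d <- data.frame(cell_id = as.character(cell_id),
                  condensation_frame = as.integer(condensation_frame),
                  metaphase_frame = as.integer(metaphase_frame),
                  anaphase_frame = as.integer(anaphase_frame),
                  condensation_censored = rep_len(as.logical(condensation_censored),
                                                  length(cell_id)),
                  last_frame = as.integer(rep_len(last_frame, length(cell_id))),
                  stringsAsFactors = FALSE)
  ok1 <- is.na(d$metaphase_frame) | d$metaphase_frame >= d$condensation_frame
  ok2 <- is.na(d$anaphase_frame) | is.na(d$metaphase_frame) |
    d$anaphase_frame >= d$metaphase_frame
  if (any(!ok1 | !ok2))
    stop("frame ordering violated: need condensation <= metaphase <= anaphase")
  class(d) <- c("mitosis_events", "data.frame")
  d
}

#' Read mitosis event annotations from CSV
#'
#' Columns `cell_id`, `condensation_frame`, `metaphase_frame`,
#' `anaphase_frame`, `condensation_censored`, `last_frame`.
#'
#' @param path CSV file path.
#' @return A [mitosis_events()] data frame.
#' @export
read_mitosis_events <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condensation_frame", "metaphase_frame",
            "anaphase_frame", "condensation_censored", "last_frame")
  if (!all(need %in% names(d)))
    stop("event CSV must have columns ", paste(need, collapse = ", "))
  mitosis_events(d$cell_id, d$condensation_frame, d$metaphase_frame,
                 d$anaphase_frame, d$condensation_censored, d$last_frame)
}

#' Prometaphase and metaphase durations per cell
#'
#' Durations in minutes at the given frame interval. A cell whose
#' condensation predates the recording, or whose plate was never observed,
#' gets a lower-bound prometaphase (computed to the plate frame or to the
#' last recorded frame respectively) and `prometaphase_lower_bound = TRUE`;
#' likewise a cell without an observed anaphase gets a lower-bound metaphase
#' duration.
#'
#' @param events a [mitosis_events()] data frame.
#' @param frame_interval_min minutes per frame (default 4).
#' @return Data frame: `cell_id`, `prometaphase_min`,
#'   `prometaphase_lower_bound`, `metaphase_min`, `metaphase_lower_bound`.
#' @export
phase_durations <- function(events, frame_interval_min = 4) {
  if (!is.finite(frame_interval_min) || frame_interval_min <= 0)
    stop("frame_interval_min must be positive")
  met_seen <- !is.na(events$metaphase_frame)
  ana_seen <- !is.na(events$anaphase_frame)

  pro_end <- ifelse(met_seen, events$metaphase_frame, events$last_frame)
  pro <- (pro_end - events$condensation_frame) * frame_interval_min
  pro_lb <- events$condensation_censored | !met_seen

  met <- ifelse(met_seen,
                (ifelse(ana_seen, events$anaphase_frame, events$last_frame) -
                   events$metaphase_frame) * frame_interval_min,
                NA_real_)
  met_lb <- met_seen & !ana_seen

  data.frame(cell_id = events$cell_id,
             prometaphase_min = pro,
             prometaphase_lower_bound = pro_lb,
             metaphase_min = met,
             metaphase_lower_bound = met_lb,
             stringsAsFactors = FALSE)
}

#' Fraction of mitoses with a long prometaphase
#'
#' A cell counts as "long" when its observed prometaphase, or its lower
#' bound, exceeds the cutoff. Lower-bound cells whose bound does not exceed
#' the cutoff are indeterminate: they are excluded from the denominator and
#' reported separately.
#'
#' @param durations output of [phase_durations()].
#' @param cutoff_min duration cutoff in minutes (default 40).
#' @return List with `fraction`, `n_long`, `n_determinate`,
#'   `n_indeterminate`.
#' @export
long_prometaphase_fraction <- function(durations, cutoff_min = 40) {
  if (nrow(durations) == 0L) stop("no events")
  long <- durations$prometaphase_min > cutoff_min
  indeterminate <- durations$prometaphase_lower_bound & !long
  det <- !indeterminate
  if (!any(det))
    return(list(fraction = NA_real_, n_long = 0L, n_determinate = 0L,
                n_indeterminate = sum(indeterminate)))
  list(fraction = sum(long & det) / sum(det),
       n_long = sum(long & det),
       n_determinate = sum(det),
       n_indeterminate = sum(indeterminate))
}

#' Cohort statistics of mitotic phase durations
#'
#' Mean, sample (n-1) SD, median and n per phase, computed over fully
#' monitored cells only (lower-bound durations are excluded; they carry no
#' exact value).
#'
#' @param durations output of [phase_durations()].
#' @return List with `prometaphase` and `metaphase`, each holding `mean`,
#'   `sd` (NA when n < 2), `median`, `n`.
#' @export
cohort_summary <- function(durations) {
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(list(mean = NA_real_, sd = NA_real_, median = NA_real_, n = 0L))
    list(mean = mean(x),
         sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
         median = stats::median(x),
         n = length(x))
  }
  pro <- durations$prometaphase_min
  pro[durations$prometaphase_lower_bound] <- NA
  met <- durations$metaphase_min
  met[durations$metaphase_lower_bound] <- NA
  list(prometaphase = one(pro), metaphase = one(met))
}

#' Write per-cell durations and cohort summary
#'
#' @param durations output of [phase_durations()].
#' @param csv_path per-cell CSV output path, or NULL to skip.
#' @param json_path cohort summary JSON path, or NULL to skip.
#' @param cutoff_min cutoff for the long-prometaphase fraction.
#' @return The summary list, invisibly.
#' @export
write_timing_results <- function(durations, csv_path = NULL, json_path = NULL,
                                 cutoff_min = 40) {
  if (!is.null(csv_path)) utils::write.csv(durations, csv_path, row.names = FALSE)
  s <- cohort_summary(durations)
  s$long_prometaphase <- long_prometaphase_fraction(durations, cutoff_min)
  if (!is.null(json_path))
    jsonlite::write_json(s, json_path, auto_unbox = TRUE, digits = NA)
  invisible(s)
}
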