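# Figure-style plots: condition boxplots and per-cell phase-duration bars.

#' Boxplots of a measure across conditions
#'
#' One box per condition (Tukey whiskers), e.g. L1/L3 aspect ratios or
#' surface angles for control vs confined spheroids.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param ylab y-axis label.
#' @param path optional PNG output path; when NULL, plots to the active
#'   device.
#' @return Invisibly, the list of [boxplot_stats()] per group.
#' @export
plot_condition_boxplots <- function(groups, ylab = "value", path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(groups, range = 1.5, ylab = ylab, col = "grey85")
  invisible(lapply(groups, boxplot_stats))
}

#' Stacked per-cell bars of prometaphase and metaphase durations
#'
#' One bar per fully monitored cell, prometaphase below and metaphase above,
#' cells ordered by total duration; stars mark cells whose condensation
#' predates the recording (prometaphase is then a lower bound).
#'
#' @param durations output of [phase_durations()].
#' @param path optional PNG output path.
#' @return Invisibly, the plotted matrix.
#' @export
plot_duration_bars <- function(durations, path = NULL) {
  d <- durations[!is.na(durations$metaphase_min) &
                   !durations$metaphase_lower_bound, , drop = FALSE]
  if (nrow(d) == 0L) stop("no fully monitored cells to plot")
  ord <- order(d$prometaphase_min + d$metaphase_min)
  m <- rbind(prometaphase = d$prometaphase_min[ord],
             metaphase = d$metaphase_min[ord])
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
  }
  mid <- graphics::barplot(m, col = c("steelblue", "firebrick"),
                           border = NA, ylab = "duration (min)",
                           names.arg = rep("", ncol(m)))
  stars <- which(d$prometaphase_lower_bound[ord])
  if (length(stars) > 0L)
    graphics::points(mid[stars], colSums(m)[stars] + 2, pch = 8, cex = 0.7)
  invisible(m)
}
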