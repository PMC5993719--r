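# Group comparison and boxplot summaries used to contrast culture conditions
# (control vs latrunculin A vs agarose confinement).

#' Mann-Whitney (Wilcoxon rank-sum) test between two conditions
#'
#' Two-sided. The exact null distribution is used when both samples have at
#' most 8 observations and the pooled data are tie-free; otherwise the normal
#' approximation with tie and continuity corrections is used. The method
#' actually applied is recorded in the result.
#'
#' @param a,b numeric samples.
#' @return Object of class `mw_test`: `U` (statistic for `a` vs `b`),
#'   `p_value`, `n1`, `n2`, `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  structure(list(U = unname(wt$statistic),
                 p_value = wt$p.value,
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "normal-approximation"),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, n1 = %d, n2 = %d, p = %.4g (%s)\n",
              x$U, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Boxplot summary statistics (Tukey convention, type-7 quartiles)
#'
#' Quartiles by linear interpolation (R's default type 7); whiskers extend to
#' the most extreme observation within 1.5 IQR of the corresponding quartile;
#' points beyond the whiskers are outliers.
#'
#' @param values numeric vector (>= 1 value).
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no values")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]),
       n = length(values))
}
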