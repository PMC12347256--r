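# Quadrant stratification of a cohort by two thresholded markers.

#' Quadrant analysis with per-quadrant PH prevalence
#'
#' Splits subjects into four quadrants at (x_threshold, y_threshold);
#' boundary values are assigned to the abnormal (>=) side. For RV strain
#' on the x-axis, values >= -12.5 % (less negative) are the abnormal
#' side, so "right" means impaired strain.
#'
#' @param x,y marker values (e.g. RV strain %, diseased lung area %)
#' @param labels logical disease indicator
#' @param x_threshold,y_threshold cutpoints (typically Youden thresholds)
#' @return `quadrant_result`: data frame with one row per quadrant
#'   (upper_right, upper_left, lower_right, lower_left): `n_ph`,
#'   `n_total`, `prevalence` (%; NA for empty quadrants)
#' @export
quadrant_analysis <- function(x, y, labels, x_threshold, y_threshold) {
  if (length(x) != length(y) || length(x) != length(labels))
    stop("length mismatch")
  labels <- as.logical(labels)
  right <- x >= x_threshold
  upper <- y >= y_threshold
  quad <- ifelse(upper, ifelse(right, "upper_right", "upper_left"),
                        ifelse(right, "lower_right", "lower_left"))
  levels <- c("upper_right", "upper_left", "lower_right", "lower_left")
  rows <- lapply(levels, function(q) {
    sel <- quad == q
    n_tot <- sum(sel); n_ph <- sum(labels[sel])
    data.frame(quadrant = q, n_ph = n_ph, n_total = n_tot,
               prevalence = if (n_tot > 0) 100 * n_ph / n_tot else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- c(x = x_threshold, y = y_threshold)
  class(out) <- c("quadrant_result", "data.frame")
  out
}
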