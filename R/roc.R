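# ROC analysis: rank-estimator AUC, DeLong confidence intervals, and
# Youden-index cutpoints.
#
# The AUC is the Mann-Whitney pairwise concordance (ties count 1/2),
# computed from midranks. DeLong variance uses placement values, also from
# midranks, so the whole path is O(n log n) and tie-exact.

# orient scores so that larger = more disease-like
orient_scores <- function(scores, labels, direction) {
  if (direction == "auto")
    direction <- if (mean(scores[labels]) >= mean(scores[!labels])) ">" else "<"
  list(scores = if (direction == ">") scores else -scores,
       direction = direction)
}

#' ROC curve summary: AUC, DeLong CI, Youden cutpoint
#'
#' @param scores numeric marker values
#' @param labels logical (TRUE = disease-positive); both classes required
#' @param direction ">" if larger values are more disease-like, "<" for the
#'   opposite, or "auto" (chosen by group means). For RV strain use ">"
#'   (less negative = abnormal).
#' @param conf confidence level for the DeLong interval (default 0.95)
#' @return `roc_result`: `auc`, `ci`, `se`, `p` (vs AUC 0.5), `threshold`
#'   (Youden cutpoint on the original scale; ties resolved to the lower
#'   threshold), `sensitivity`, `specificity` (%), `direction`
#' @export
roc_auc <- function(scores, labels, direction = c("auto", ">", "<"),
                    conf = 0.95) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  ori <- orient_scores(scores, labels, direction)
  s <- ori$scores
  x <- s[labels]; y <- s[!labels]       # cases, controls
  m <- length(x); n <- length(y)

  # midrank placements (DeLong): V10_i = fraction of controls below case i
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)

  # Youden scan over observed cutoffs (predict positive when oriented
  # score >= c); ties resolved to the lower threshold
  cand <- sort(unique(s))
  sens <- vapply(cand, function(cc) mean(x >= cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(y < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]
  thr <- if (ori$direction == ">") cand[best] else -cand[best]

  structure(list(auc = auc, ci = ci, se = se, p = p,
                 threshold = thr, sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 direction = ori$direction),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f (95%% CI %.3f-%.3f, p = %.3g); threshold %.4g (%s), sens %.1f%%, spec %.1f%%\n",
    x$auc, x$ci[1], x$ci[2], x$p, x$threshold, x$direction,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Table of per-marker ROC summaries
#'
#' @param table data frame with logical `is_ph` and marker columns
#' @param features marker column names
#' @param directions named character vector of directions per marker
#'   (default "auto")
#' @return data frame with AUC, CI, p, threshold, sensitivity, specificity
#' @export
roc_table <- function(table, features = COHORT_FEATURES, directions = NULL) {
  rows <- lapply(features, function(f) {
    dir <- if (!is.null(directions) && f %in% names(directions))
      directions[[f]] else "auto"
    r <- roc_auc(table[[f]], table$is_ph, direction = dir)
    data.frame(feature = f, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2],
               p = r$p, threshold = r$threshold,
               sensitivity = r$sensitivity, specificity = r$specificity,
               direction = r$direction)
  })
  do.call(rbind, rows)
}
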