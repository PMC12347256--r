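# Reclassification indices for paired diagnostic models: continuous NRI
# and IDI, with seeded stratified-bootstrap confidence intervals and
# normal-approximation p-values from the bootstrap SE.

# point estimate of the continuous (category-free) NRI;
# ties contribute to neither direction
nri_point <- function(p_base, p_new, labels) {
  up <- p_new > p_base; down <- p_new < p_base
  (mean(up[labels]) - mean(down[labels])) +
    (mean(down[!labels]) - mean(up[!labels]))
}

# point estimate of the IDI (difference in discrimination slopes)
idi_point <- function(p_base, p_new, labels) {
  (mean(p_new[labels]) - mean(p_new[!labels])) -
    (mean(p_base[labels]) - mean(p_base[!labels]))
}

# stratified bootstrap (events and non-events resampled separately) of a
# paired-model statistic; returns percentile CI and normal-approx p
boot_ci <- function(stat_fn, p_base, p_new, labels, n_boot, seed, conf) {
  est <- stat_fn(p_base, p_new, labels)
  ev <- which(labels); ne <- which(!labels)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ev, length(ev), replace = TRUE),
             sample(ne, length(ne), replace = TRUE))
    stat_fn(p_base[idx], p_new[idx], labels[idx])
  }, numeric(1))
  alpha <- 1 - conf
  ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
  se <- stats::sd(boots)
  p <- if (se > 0) 2 * stats::pnorm(-abs(est) / se) else as.numeric(est == 0)
  list(estimate = est, ci = ci, se = se, p = p, n_boot = n_boot)
}

#' Continuous net reclassification improvement
#'
#' NRI = \[P(up | event) - P(down | event)\] +
#' \[P(down | non-event) - P(up | non-event)\], where up/down compare the
#' new model's predicted probability with the base model's; ties count for
#' neither. Range \[-2, 2\]. CI by seeded stratified bootstrap (percentile);
#' p from the bootstrap SE (normal approximation).
#'
#' @param p_base,p_new predicted probabilities from the base and new model
#' @param labels logical event indicator, aligned with the probabilities
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed integer seed for the bootstrap (default 1)
#' @param conf confidence level (default 0.95)
#' @return list: `estimate`, `ci`, `se`, `p`, `n_boot`
#' @export
continuous_nri <- function(p_base, p_new, labels, n_boot = 2000, seed = 1,
                           conf = 0.95) {
  labels <- as.logical(labels)
  if (length(p_base) != length(labels) || length(p_new) != length(labels))
    stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  boot_ci(nri_point, p_base, p_new, labels, n_boot, seed, conf)
}

#' Integrated discrimination improvement
#'
#' IDI = (mean p_new | event - mean p_new | non-event) -
#' (mean p_base | event - mean p_base | non-event). Range \[-1, 1\].
#' CI and p by the same seeded bootstrap as [continuous_nri()].
#'
#' @inheritParams continuous_nri
#' @return list: `estimate`, `ci`, `se`, `p`, `n_boot`
#' @export
idi <- function(p_base, p_new, labels, n_boot = 2000, seed = 1,
                conf = 0.95) {
  labels <- as.logical(labels)
  if (length(p_base) != length(labels) || length(p_new) != length(labels))
    stop("length mismatch")
  if (!any(labels) || all(labels)) stop("both classes must be present")
  boot_ci(idi_point, p_base, p_new, labels, n_boot, seed, conf)
}

#' Step-wise model augmentation with reclassification statistics
#'
#' Fits the base logistic model, then successively augmented models (each
#' adding the next feature in `added_features`), reporting each model's
#' AUC (of fitted probabilities) and, for each augmentation, NRI and IDI
#' versus its predecessor.
#'
#' @param table data frame with logical `is_ph` and feature columns
#' @param base_features features of the base model
#' @param added_features character vector; features added one at a time
#' @param n_boot,seed,conf bootstrap settings for NRI/IDI
#' @return data frame with one row per model: features, auc, auc CI,
#'   separation flag, and NRI/IDI (with CIs and p) vs the previous model
#' @export
stepwise_combination <- function(table, base_features, added_features,
                                 n_boot = 2000, seed = 1, conf = 0.95) {
  feature_sets <- Reduce(c, added_features, init = base_features,
                         accumulate = TRUE)
  models <- lapply(feature_sets, function(fs) fit_logistic(table, fs))
  labels <- as.logical(table$is_ph)
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    r <- roc_auc(m$fitted, labels, direction = ">")
    row <- data.frame(
      model = paste(m$features, collapse = " + "),
      auc = r$auc, auc_ci_lo = r$ci[1], auc_ci_hi = r$ci[2],
      separated = m$separated,
      nri = NA_real_, nri_ci_lo = NA_real_, nri_ci_hi = NA_real_,
      nri_p = NA_real_,
      idi = NA_real_, idi_ci_lo = NA_real_, idi_ci_hi = NA_real_,
      idi_p = NA_real_)
    if (i > 1) {
      pb <- models[[i - 1]]$fitted; pn <- m$fitted
      nr <- continuous_nri(pb, pn, labels, n_boot, seed, conf)
      id <- idi(pb, pn, labels, n_boot, seed, conf)
      row[c("nri", "nri_ci_lo", "nri_ci_hi", "nri_p")] <-
        c(nr$estimate, nr$ci, nr$p)
      row[c("idi", "idi_ci_lo", "idi_ci_hi", "idi_p")] <-
        c(id$estimate, id$ci, id$p)
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  out
}
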