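# Synthetic two-group ILD cohorts (PH vs non-PH).
#
# Feature distributions default to the study-condition group statistics:
# per-group multivariate normal draws with the stated means/SDs, clipped to
# their physical ranges. Hemodynamics are simulated conditionally on group
# so the hemodynamic PH definition reproduces the group labels exactly;
# the source cohort reports no hemodynamic summaries, so those parameters
# are explicitly synthetic.

COHORT_FEATURES <- c("rv_strain", "rvesv", "diseased_area", "ggo",
                     "honeycomb", "reticulation", "emphysema", "consolidation")

# percentage-of-lung features, clipped to [0, 100]
PERCENT_FEATURES <- c("diseased_area", "ggo", "honeycomb", "reticulation",
                      "emphysema", "consolidation")

#' Default per-group feature means and SDs
#'
#' PH group (n = 21 by default): RV strain -13.4 +/- 5.1 %, RVESV
#' 74.2 +/- 18.3 mL, diseased area 56.4 +/- 17.2 %, GGO 11.8 +/- 3.6 %,
#' honeycomb 17.7 +/- 4.9 %, reticulation 8.10 +/- 8.04 %, emphysema
#' 17.4 +/- 17.2 %, consolidation 1.48 +/- 3.20 %. Non-PH group (n = 51):
#' -16.4 +/- 5.2, 59.5 +/- 14.2, 38.4 +/- 12.5, 8.65 +/- 4.3,
#' 12.8 +/- 6.4, 5.66 +/- 5.75, 10.6 +/- 12.9, 0.662 +/- 0.798.
#'
#' @return list with `means_ph`, `sds_ph`, `means_nonph`, `sds_nonph`
#'   (named numeric vectors over the eight features)
#' @export
default_group_stats <- function() {
  list(
    means_ph = c(rv_strain = -13.4, rvesv = 74.2, diseased_area = 56.4,
                 ggo = 11.8, honeycomb = 17.7, reticulation = 8.10,
                 emphysema = 17.4, consolidation = 1.48),
    sds_ph = c(rv_strain = 5.1, rvesv = 18.3, diseased_area = 17.2,
               ggo = 3.6, honeycomb = 4.9, reticulation = 8.04,
               emphysema = 17.2, consolidation = 3.20),
    means_nonph = c(rv_strain = -16.4, rvesv = 59.5, diseased_area = 38.4,
                    ggo = 8.65, honeycomb = 12.8, reticulation = 5.66,
                    emphysema = 10.6, consolidation = 0.662),
    sds_nonph = c(rv_strain = 5.2, rvesv = 14.2, diseased_area = 12.5,
                  ggo = 4.3, honeycomb = 6.4, reticulation = 5.75,
                  emphysema = 12.9, consolidation = 0.798))
}

#' Cohort simulation specification
#'
#' @param n_ph,n_nonph group sizes (> 0); defaults 21 and 51
#' @param group_stats list as returned by [default_group_stats()]
#' @param corr 8x8 feature correlation matrix (symmetric positive definite,
#'   unit diagonal); default identity (independent features within group)
#' @param seed integer seed; regeneration with the same spec is bit-identical
#' @return `cohort_spec` object
#' @export
cohort_spec <- function(n_ph = 21, n_nonph = 51,
                        group_stats = default_group_stats(),
                        corr = diag(length(COHORT_FEATURES)), seed = 1) {
  if (n_ph <= 0 || n_nonph <= 0) stop("group sizes must be > 0")
  for (nm in c("means_ph", "sds_ph", "means_nonph", "sds_nonph")) {
    if (!all(COHORT_FEATURES %in% names(group_stats[[nm]])))
      stop("group_stats$", nm, " must name all features")
  }
  if (any(group_stats$sds_ph <= 0) || any(group_stats$sds_nonph <= 0))
    stop("feature SDs must be > 0")
  p <- length(COHORT_FEATURES)
  if (!is.matrix(corr) || !identical(dim(corr), c(p, p)))
    stop("corr must be ", p, "x", p)
  if (max(abs(corr - t(corr))) > 1e-8 || max(abs(diag(corr) - 1)) > 1e-8)
    stop("corr must be symmetric with unit diagonal")
  ch <- tryCatch(chol(corr), error = function(e) NULL)
  if (is.null(ch)) stop("correlation matrix must be positive definite")
  structure(list(n_ph = as.integer(n_ph), n_nonph = as.integer(n_nonph),
                 group_stats = group_stats, corr = corr, chol = ch,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal sampling by inverse CDF (vectorized bounds)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

# one group's feature block: correlated normal draws, then clipping
draw_group_features <- function(n, means, sds, ch) {
  z <- matrix(stats::rnorm(n * length(COHORT_FEATURES)), n) %*% ch
  x <- sweep(sweep(z, 2L, sds[COHORT_FEATURES], `*`),
             2L, means[COHORT_FEATURES], `+`)
  colnames(x) <- COHORT_FEATURES
  x[, PERCENT_FEATURES] <- pmin(pmax(x[, PERCENT_FEATURES], 0), 100)
  x[, "rv_strain"] <- pmin(x[, "rv_strain"], 0)
  x
}

#' Generate a synthetic two-group cohort
#'
#' Features are drawn per group from a multivariate normal with the
#' requested means/SDs/correlations, then clipped (percentages to \[0, 100\], strain
#' to <= 0). Hemodynamics are drawn from truncated normals so that every PH
#' subject satisfies mPAP >= 20 mmHg and PVR >= 3 WU and every non-PH
#' subject has mPAP < 20 (all PCWP <= 15, matching the wedge-pressure
#' exclusion).
#'
#' @param spec [cohort_spec()]
#' @return data frame (class `synthetic_cohort`) with columns `id`,
#'   `group` ("PH"/"nonPH"), `is_ph`, the eight features, and `mpap`
#'   (mmHg), `pcwp` (mmHg), `co` (L/min)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  gs <- spec$group_stats
  x_ph <- draw_group_features(spec$n_ph, gs$means_ph, gs$sds_ph, spec$chol)
  x_non <- draw_group_features(spec$n_nonph, gs$means_nonph, gs$sds_nonph,
                               spec$chol)

  # PH: mPAP ~ N(32, 6) truncated >= 20; PVR ~ N(5, 1.5) truncated >= 3 WU;
  # CO back-computed from the PVR definition so the label is exact.
  mpap_ph <- rtruncnorm(spec$n_ph, 32, 6, lower = 20)
  pcwp_ph <- rtruncnorm(spec$n_ph, 10, 2, lower = 5,
                        upper = pmin(15, mpap_ph - 2))
  pvr_ph <- rtruncnorm(spec$n_ph, 5, 1.5, lower = 3)
  co_ph <- (mpap_ph - pcwp_ph) / pvr_ph

  # non-PH: mPAP ~ N(16, 3) truncated < 20 (fails the pressure criterion)
  mpap_non <- rtruncnorm(spec$n_nonph, 16, 3, lower = 6, upper = 20)
  pcwp_non <- rtruncnorm(spec$n_nonph, 9, 2, lower = 4,
                         upper = pmin(15, mpap_non - 2))
  pvr_non <- rtruncnorm(spec$n_nonph, 1.8, 0.6, lower = 0.3, upper = 3)
  co_non <- (mpap_non - pcwp_non) / pvr_non

  n <- spec$n_ph + spec$n_nonph
  out <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    group = factor(rep(c("PH", "nonPH"), c(spec$n_ph, spec$n_nonph)),
                   levels = c("nonPH", "PH")),
    is_ph = rep(c(TRUE, FALSE), c(spec$n_ph, spec$n_nonph)),
    rbind(x_ph, x_non),
    mpap = c(mpap_ph, mpap_non),
    pcwp = c(pcwp_ph, pcwp_non),
    co = c(co_ph, co_non),
    row.names = NULL)
  class(out) <- c("synthetic_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}
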