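# Independent brute-force oracles and small fixtures used across tests.
# Every oracle recomputes the target quantity by direct definition,
# independently of the package's implementation path.

# independent re-statement of the histogram binning rule
hu_bin_for_test <- function(x, hs) {
  min(max(floor((x - hs$hu_min) / hs$bin_width) + 1, 1), hs$n_bins)
}

# six well-separated texture specs (>= 10 SD between adjacent means)
separated_class_specs <- function(sd = 10) {
  list(texture_class_spec("N", -900, sd), texture_class_spec("E", -700, sd),
       texture_class_spec("G", -500, sd), texture_class_spec("C", -300, sd),
       texture_class_spec("R", -100, sd), texture_class_spec("H", 50, sd))
}

# per-pixel classifier: local histograms and correlations computed one
# pixel at a time through the scalar operations
naive_classify <- function(intensity, mask, refs, kernel, hspec,
                           hspec_diff = NULL) {
  if (is.null(hspec_diff)) hspec_diff <- hspec
  dimg <- differential_image(intensity)
  labels <- matrix(NA_character_, nrow(intensity), ncol(intensity))
  scores <- matrix(NA_real_, nrow(intensity), ncol(intensity))
  for (idx in which(mask)) {
    i <- ((idx - 1) %% nrow(intensity)) + 1
    j <- ((idx - 1) %/% nrow(intensity)) + 1
    f <- c(local_gaussian_histogram(intensity, c(i, j), kernel, hspec),
           local_gaussian_histogram(dimg, c(i, j), kernel, hspec_diff))
    cors <- vapply(GHNC_CLASSES, function(cl)
      normalized_correlation(f, c(refs[[cl]]$original,
                                  refs[[cl]]$differential)), numeric(1))
    k <- which.max(cors)   # first max = fixed class-order tie-break
    labels[i, j] <- GHNC_CLASSES[k]
    scores[i, j] <- cors[k]
  }
  list(labels = labels, scores = scores)
}

# AUC as explicit pairwise concordance over all (case, control) pairs
auc_pair_oracle <- function(scores, labels) {
  x <- scores[labels]; y <- scores[!labels]
  pairs <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# continuous NRI by explicit per-subject counting
nri_oracle <- function(p_base, p_new, labels) {
  ev <- labels; ne <- !labels
  (sum(p_new[ev] > p_base[ev]) - sum(p_new[ev] < p_base[ev])) / sum(ev) +
    (sum(p_new[ne] < p_base[ne]) - sum(p_new[ne] > p_base[ne])) / sum(ne)
}

# IDI by direct mean differences
idi_oracle <- function(p_base, p_new, labels) {
  (mean(p_new[labels]) - mean(p_new[!labels])) -
    (mean(p_base[labels]) - mean(p_base[!labels]))
}

# Youden cutpoint by exhaustive scan (rule: positive if score >= c),
# lowest threshold on ties
youden_oracle <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- -Inf; best_c <- NA
  for (cc in cand) {
    sens <- mean(scores[labels] >= cc)
    spec <- mean(scores[!labels] < cc)
    if (sens + spec - 1 > best + 1e-12) {
      best <- sens + spec - 1; best_c <- cc
    }
  }
  best_c
}

# U statistic by explicit pair counting (oriented to group a)
u_pair_oracle <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# shorthand constructors for contour fixtures
ellipse_points <- function(a, b, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

cine_set <- function(phases, slice_thickness = 10, gap = 0) {
  cine_contour_set(phases, slice_thickness, gap)
}

# random label map over the lung classes
random_label_map <- function(nr, nc) {
  matrix(sample(GHNC_CLASSES, nr * nc, replace = TRUE), nr, nc)
}
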