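# Texture classifier: local histograms, reference construction,
# normalized correlation, pixel classification and volume fractions.

test_that("differential image handles constants, ramps, and matches a loop oracle", {
  expect_equal(differential_image(matrix(5, 8, 8)), matrix(0, 8, 8))

  ramp <- matrix(rep(3 * (1:12), each = 10), 10, 12)  # slope 3 HU/px along cols
  d <- differential_image(ramp)
  expect_equal(d[3:8, 3:10], matrix(3, 6, 8))

  set.seed(11)
  x <- matrix(rnorm(256, sd = 50), 16, 16)
  d <- differential_image(x)
  oracle <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    gx <- (x[min(i + 1, 16), j] - x[max(i - 1, 1), j]) / 2
    gy <- (x[i, min(j + 1, 16)] - x[i, max(j - 1, 1)]) / 2
    oracle[i, j] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(d, oracle, tolerance = 1e-14)
})

test_that("local Gaussian histogram: degenerate, symmetric, and brute-force cases", {
  kern <- gaussian_kernel_spec(2, 9)
  hs <- histogram_spec(-1024, 100, 25)

  h <- local_gaussian_histogram(matrix(-500, 20, 20), c(10, 10), kern, hs)
  expect_equal(sum(h), 1)
  expect_equal(max(h), 1)
  expect_equal(which.max(h), hu_bin_for_test(-500, hs))

  # checkerboard of two values, symmetric kernel, center far from edges:
  # mass splits close to 0.5/0.5 (exactly 0.5 up to the center pixel's own
  # parity; use odd window so counts balance via symmetry of the pattern)
  cb <- matrix(rep(c(-800, -400), 200), 20, 20)
  cb[, seq(2, 20, 2)] <- -1200 + cb[, seq(2, 20, 2)]  # break into checker
  cb <- outer(1:20, 1:20, function(i, j) ifelse((i + j) %% 2 == 0, -800, -400))
  h <- local_gaussian_histogram(cb, c(10, 10), kern, hs)
  b1 <- hu_bin_for_test(-800, hs); b2 <- hu_bin_for_test(-400, hs)
  expect_equal(sum(h[c(b1, b2)]), 1)
  expect_equal(h[b1], h[b2], tolerance = 0.02)

  set.seed(12)
  x <- matrix(runif(32 * 32, -1100, 200), 32, 32)  # exercises end-bin clamping
  g <- dnorm(-4:4, sd = 2); g <- g / sum(g)
  for (center in list(c(16, 16), c(2, 3), c(31, 32))) {
    oracle <- numeric(hs$n_bins)
    for (di in -4:4) for (dj in -4:4) {
      i <- center[1] + di; j <- center[2] + dj
      if (i < 1 || i > 32 || j < 1 || j > 32) next
      b <- hu_bin_for_test(x[i, j], hs)
      oracle[b] <- oracle[b] + g[di + 5] * g[dj + 5]
    }
    oracle <- oracle / sum(oracle)
    expect_equal(local_gaussian_histogram(x, center, kern, hs), oracle,
                 tolerance = 1e-12)
  }
})

test_that("reference histograms: one-hot constants, mean idempotence, averaged oracle", {
  kern <- gaussian_kernel_spec(1.5, 7)
  hs <- histogram_spec(-1024, 100, 25)
  means <- c(N = -850, E = -950, G = -650, C = -100, R = -500, H = -750)
  templates <- lapply(names(means), function(cl)
    list(label = cl, patch = matrix(means[[cl]], 15, 15)))

  refs <- build_reference_histograms(templates, kern, hs)
  for (cl in GHNC_CLASSES) {
    expect_equal(sum(refs[[cl]]$original), 1)
    expect_equal(which.max(refs[[cl]]$original), hu_bin_for_test(means[[cl]], hs))
    expect_equal(max(refs[[cl]]$original), 1)  # one-hot
  }

  refs_dup <- build_reference_histograms(c(templates, templates), kern, hs)
  expect_equal(refs_dup, refs)

  # two distinct random patches per class equal the hand-averaged oracle
  set.seed(13)
  t2 <- unlist(lapply(GHNC_CLASSES, function(cl) {
    list(list(label = cl, patch = matrix(rnorm(81, means[[cl]], 60), 9, 9)),
         list(label = cl, patch = matrix(rnorm(81, means[[cl]], 60), 9, 9)))
  }), recursive = FALSE)
  refs2 <- build_reference_histograms(t2, kern, hs)
  labs <- vapply(t2, `[[`, character(1), "label")
  for (cl in GHNC_CLASSES) {
    patches <- lapply(t2[labs == cl], `[[`, "patch")
    h_all <- do.call(rbind, lapply(patches, function(p) {
      t(sapply(seq_len(length(p)), function(idx) {
        i <- (idx - 1) %% nrow(p) + 1; j <- (idx - 1) %/% nrow(p) + 1
        local_gaussian_histogram(p, c(i, j), kern, hs)
      }))
    }))
    oracle <- colMeans(h_all); oracle <- oracle / sum(oracle)
    expect_equal(unname(refs2[[cl]]$original), unname(oracle), tolerance = 1e-12)
  }

  expect_error(build_reference_histograms(templates[1:5], kern, hs),
               "missing template class")
})

test_that("normalized correlation: identity, anti-correlation, formula oracle", {
  set.seed(14)
  a <- runif(45)
  expect_equal(normalized_correlation(a, a), 1)
  expect_equal(normalized_correlation(a, mean(a) - (a - mean(a))), -1)
  for (k in 1:20) {
    u <- rnorm(12); v <- rnorm(12)
    oracle <- sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
    expect_equal(normalized_correlation(u, v), oracle, tolerance = 1e-12)
  }
  expect_equal(normalized_correlation(rep(1, 5), rnorm(5)), 0)
  expect_error(normalized_correlation(1:4, 1:5), "length mismatch")
})

test_that("classification equals the naive per-pixel oracle on small inputs", {
  kern <- gaussian_kernel_spec(1.8, 9)
  hs <- histogram_spec(-1024, 100, 25)
  specs <- separated_class_specs(sd = 60)  # overlapping: labels nontrivial
  tpl <- generate_class_templates(specs, size = 13, seed = 21)
  refs <- build_reference_histograms(tpl, kern, hs)

  set.seed(22)
  for (trial in 1:3) {
    img <- matrix(runif(28 * 28, -1000, 80), 28, 28)
    mask <- matrix(runif(28 * 28) < 0.8, 28, 28)
    mask[1, 1] <- TRUE
    lm <- classify_image(img, mask, refs, kern, hs)
    oracle <- naive_classify(img, mask, refs, kern, hs)
    expect_identical(lm$labels, oracle$labels)
    expect_equal(lm$correlation_scores, oracle$scores, tolerance = 1e-9)
  }
})

test_that("classifier self-consistency, tie-break and permutation equivariance", {
  kern <- gaussian_kernel_spec(1.8, 9)
  hs <- histogram_spec(-1024, 100, 25)
  specs <- separated_class_specs(sd = 10)
  tpl <- generate_class_templates(specs, size = 21, seed = 31)
  refs <- build_reference_histograms(tpl, kern, hs)

  # an image that IS one class's template is labelled that class throughout
  for (cl in c("G", "H")) {
    patch <- tpl[[which(vapply(tpl, `[[`, character(1), "label") == cl)]]$patch
    mask <- matrix(TRUE, nrow(patch), ncol(patch))
    lm <- classify_image(patch, mask, refs, kern, hs)
    interior <- lm$labels[5:17, 5:17]
    expect_true(all(interior == cl))
  }

  # all-equal correlations resolve to N by the fixed class order
  const <- matrix(-500, 16, 16)
  const_tpl <- lapply(GHNC_CLASSES, function(cl)
    list(label = cl, patch = matrix(-500, 9, 9)))
  const_refs <- build_reference_histograms(const_tpl, kern, hs)
  lm <- classify_image(const, matrix(TRUE, 16, 16), const_refs, kern, hs)
  expect_true(all(lm$labels == "N"))

  # relabelling the templates by a permutation permutes the output labels
  set.seed(32)
  img <- matrix(runif(24 * 24, -1000, 80), 24, 24)
  mask <- matrix(TRUE, 24, 24)
  lm1 <- classify_image(img, mask, refs, kern, hs)
  perm <- c(N = "E", E = "G", G = "C", C = "R", R = "H", H = "N")
  tpl_perm <- lapply(tpl, function(t) list(label = perm[[t$label]],
                                           patch = t$patch))
  refs_perm <- build_reference_histograms(tpl_perm, kern, hs)
  lm2 <- classify_image(img, mask, refs_perm, kern, hs)
  expect_identical(unname(perm[lm1$labels]), as.vector(lm2$labels))

  expect_error(classify_image(img, matrix(FALSE, 24, 24), refs, kern, hs),
               "empty lung mask")
})

test_that("accuracy degrades monotonically as class separation shrinks", {
  kern <- gaussian_kernel_spec(1.8, 9)
  hs <- histogram_spec(-1024, 100, 25)
  accs <- vapply(c(1.0, 0.4, 0.1), function(shrink) {
    means <- -600 + shrink * (c(-300, -180, -60, 60, 180, 300))
    specs <- Map(function(cl, m) texture_class_spec(cl, m, 40),
                 GHNC_CLASSES, means)
    ph <- generate_phantom(96, 96, specs, layout_seed = 41, n_seeds = 12)
    tpl <- generate_class_templates(specs, size = 21, seed = 42)
    refs <- build_reference_histograms(tpl, kern, hs)
    lm <- classify_image(ph$intensity, ph$lung_mask, refs, kern, hs)
    phantom_accuracy(lm, ph)
  }, numeric(1))
  expect_true(accs[1] >= accs[2] - 2 && accs[2] >= accs[3] - 2)
  expect_gt(accs[1], accs[3])
})

test_that("class fractions conserve mass and match the counting oracle", {
  labels <- matrix(rep(c("N", "E", "G", "C", "R", "H"),
                       c(50, 10, 10, 5, 10, 15)), 10, 10)
  fr <- class_fractions(labels, matrix(TRUE, 10, 10),
                        pixel_spacing = 1, slice_thickness = 1)
  expect_equal(fr$diseased_area, 50)
  expect_equal(unname(fr$fractions),
               c(50, 10, 10, 5, 10, 15))
  expect_equal(fr$ctlv, 0.1)  # 100 px * 1 mm^2 * 1 mm = 100 mm^3

  allN <- matrix("N", 8, 8)
  fr <- class_fractions(allN, matrix(TRUE, 8, 8))
  expect_equal(fr$diseased_area, 0)
  expect_equal(sum(fr$fractions), 100)

  set.seed(43)
  for (k in 1:25) {
    lmap <- random_label_map(15, 15)
    mask <- matrix(runif(225) < 0.7, 15, 15)
    if (!any(mask)) next
    fr <- class_fractions(lmap, mask)
    counts <- vapply(GHNC_CLASSES, function(cl)
      sum(lmap[mask] == cl), numeric(1))
    expect_equal(unname(fr$fractions), unname(100 * counts / sum(mask)))
    expect_equal(sum(fr$fractions), 100, tolerance = 1e-9)
    expect_equal(fr$diseased_area, 100 - fr$fractions[["N"]])
  }
})

test_that("overlay uses the class palette and preserves dimensions", {
  img <- matrix(-500, 12, 14)
  labels <- matrix("N", 12, 14)
  lm <- structure(list(labels = labels, lung_mask = matrix(TRUE, 12, 14)),
                  class = "label_map")
  ov <- render_overlay(img, lm)
  expect_equal(dim(ov), c(12, 14, 3))
  pink <- grDevices::col2rgb(ghnc_palette()[["N"]]) / 255
  expect_true(all(abs(ov[1, 1, ] - pink[, 1]) < 1e-12))

  pal <- ghnc_palette()
  expect_identical(pal[["N"]], "#FFC0CB")  # pink
  expect_identical(pal[["E"]], "#00008B")  # dark blue
  expect_identical(pal[["G"]], "#FFA500")  # orange
  expect_identical(pal[["R"]], "#ADD8E6")  # light blue
  expect_identical(pal[["H"]], "#FFFF00")  # yellow
  expect_true(!is.na(pal[["C"]]))          # documented sixth color

  # off-mask pixels fall back to windowed grayscale
  lm$lung_mask[1, 1] <- FALSE
  lm$labels[1, 1] <- NA
  ov <- render_overlay(img, lm)
  g <- (-500 - (-1024)) / 1124
  expect_equal(unname(ov[1, 1, ]), rep(g, 3))
})
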