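# RV volumetry and longitudinal strain from contour sequences.

test_that("polygon area: exact shapes and a Monte-Carlo oracle", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(square), 1)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(polygon_area(tri), 6)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), ">= 3 points")

  # random convex polygon vs point-in-polygon Monte Carlo
  set.seed(51)
  th <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(3 * cos(th), 2 * sin(th))
  area <- polygon_area(poly)
  pts <- cbind(runif(2e5, -3, 3), runif(2e5, -2, 2))
  # convex polygon membership: same side of every directed edge
  inside <- rep(TRUE, nrow(pts))
  n <- nrow(poly)
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[k %% n + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
             (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cross >= 0
  }
  mc <- mean(inside) * 24
  expect_equal(area, mc, tolerance = 0.01)
})

test_that("disk summation: exact stacks and the analytic ellipsoid", {
  sq1000 <- rbind(c(0, 0), c(40, 0), c(40, 25), c(0, 25))  # 1000 mm^2
  expect_equal(volume_by_disk_summation(list(sq1000, sq1000), 10, 0), 20)

  a <- 25; b <- 20; cc <- 35
  z <- seq(-cc + 0.5, cc - 0.5, by = 1)
  contours <- lapply(z, function(zi) {
    r <- sqrt(max(0, 1 - (zi / cc)^2))
    th <- seq(0, 2 * pi, length.out = 201)[-201]
    cbind(a * r * cos(th), b * r * sin(th))
  })
  v <- volume_by_disk_summation(contours, 1, 0)
  expect_equal(v, 4 / 3 * pi * a * b * cc / 1000, tolerance = 0.02)

  degenerate <- rbind(c(0, 0), c(1, 0), c(2, 0))  # collinear: zero area
  expect_equal(volume_by_disk_summation(list(degenerate), 10), 0)
})

test_that("volume curve identifies ED and ES phases", {
  circ <- function(r) ellipse_points(r, r)
  shrink <- cine_set(lapply(seq(30, 21, -1), function(r) list(circ(r))))
  vc <- volume_curve(shrink)
  expect_equal(vc$ed_phase, 1)
  expect_equal(vc$es_phase, 10)

  const <- cine_set(lapply(1:5, function(i) list(circ(25))))
  cm <- cardiac_measures(const)
  expect_equal(cm$rvef, 0)
  expect_equal(cm$peak_longitudinal_strain, 0)

  # sinusoidal area modulation: ES at the analytic trough within one phase
  t <- 1:20
  r <- 25 * sqrt(1 - 0.4 * sin(pi * (t - 1) / 20)^2)
  sine <- cine_set(lapply(r, function(ri) list(circ(ri))))
  expect_true(abs(volume_curve(sine)$es_phase - 11) <= 1)
})

test_that("strain: length ratios, isometry invariance, affine closed form", {
  # open polyline shrinking 100 -> 80 mm gives peak strain -20%
  line_of <- function(L) cbind(seq(0, L, length.out = 10), 0)
  cine <- cine_set(list(list(line_of(100)), list(line_of(90)),
                        list(line_of(80)), list(line_of(100))))
  sc <- longitudinal_strain_curve(cine)
  expect_equal(sc$peak, -20)
  expect_equal(sc$strain[sc$ed_phase], 0)

  # rigid translation and rotation leave volumes and strain unchanged
  base <- shortening_cine(-18, phases = 12)
  ang <- 0.7; Rm <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  moved <- cine_set(lapply(base$contours, function(ph)
    lapply(ph, function(ct) sweep(ct %*% t(Rm), 2, c(12.3, -4.5), `+`))),
    slice_thickness = 8)
  expect_equal(cardiac_measures(moved)$peak_longitudinal_strain,
               cardiac_measures(base)$peak_longitudinal_strain,
               tolerance = 1e-9)
  expect_equal(volume_curve(moved)$volumes, volume_curve(base)$volumes,
               tolerance = 1e-9)

  # scaling coordinates by k: areas/volumes x k^2 (thickness fixed),
  # lengths x k, strain unchanged
  k <- 1.7
  scaled <- cine_set(lapply(base$contours, function(ph)
    lapply(ph, function(ct) ct * k)), slice_thickness = 8)
  expect_equal(volume_curve(scaled)$volumes,
               k^2 * volume_curve(base)$volumes, tolerance = 1e-9)
  expect_equal(longitudinal_strain_curve(scaled)$strain,
               longitudinal_strain_curve(base)$strain, tolerance = 1e-9)

  # affine scaling by s(t): strain = 100 (s(t) - 1) exactly
  s_t <- c(1, 0.95, 0.88, 0.8, 0.9, 1)
  u <- seq(0, pi, length.out = 30)
  arc <- cbind(cos(u), sin(u)) * 40
  aff <- cine_set(lapply(s_t, function(s) list(arc * s)))
  sc <- longitudinal_strain_curve(aff)
  expect_equal(sc$strain, 100 * (s_t - 1), tolerance = 1e-9)

  expect_error(longitudinal_strain_curve(
    cine_set(list(list(matrix(0, 4, 2)), list(matrix(0, 4, 2))))),
    "degenerate")
})

test_that("prescribed EDV, ESV and peak strain are recovered within 2%", {
  cm <- cardiac_measures(ellipsoid_cine(130, 65, slice_thickness = 1))
  expect_equal(cm$rvedv, 130, tolerance = 0.02)
  expect_equal(cm$rvesv, 65, tolerance = 0.02)
  expect_equal(cm$rvef, 50, tolerance = 0.02)
  expect_true(cm$rvef >= 0 && cm$rvef <= 100)

  cs <- cardiac_measures(shortening_cine(-15))
  expect_equal(cs$peak_longitudinal_strain, -15, tolerance = 0.02)
  expect_lte(cs$peak_longitudinal_strain, 0)
})

test_that("contour CSV round-trips through read/write", {
  cine <- ellipsoid_cine(120, 70, phases = 4, slice_thickness = 5,
                         n_points = 16)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contours_csv(cine, path)
  back <- read_contours_csv(path, slice_thickness = 5)
  expect_equal(back$contours, cine$contours, tolerance = 1e-12)
  expect_equal(volume_curve(back)$volumes, volume_curve(cine)$volumes)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_contours_csv(bad, 5), "columns")
})
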