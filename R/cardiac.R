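# Right-ventricular volumetry and longitudinal strain from endocardial
# contour sequences.
#
# Volumes come from area summation over a cine contour stack (Simpson-type
# disks); strain comes from the change in endocardial arc length of the
# open contour (the valve-plane closing segment is excluded), relative to
# end-diastole. End-diastole is the maximal-volume phase (no ECG gating in
# the contour representation).

#' Shoelace area of a closed polygon
#'
#' @param points n x 2 numeric matrix of vertex coordinates (mm), in order
#' @return absolute area, mm^2
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("polygon needs >= 3 points")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Resample a contour to equally spaced points along its arc length
#'
#' @param points n x 2 matrix
#' @param n_points number of output points (default 64)
#' @param closed treat the contour as a closed polygon (TRUE) or open
#'   polyline (FALSE)
#' @return n_points x 2 matrix
#' @export
resample_contour <- function(points, n_points = 64, closed = FALSE) {
  points <- as.matrix(points)
  if (closed) points <- rbind(points, points[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) stop("degenerate (zero-length) contour")
  target <- seq(0, s[length(s)], length.out = n_points + closed)
  out <- cbind(stats::approx(s, points[, 1], xout = target, ties = "ordered")$y,
               stats::approx(s, points[, 2], xout = target, ties = "ordered")$y)
  if (closed) out <- out[-nrow(out), , drop = FALSE]
  out
}

# open-polyline arc length (first-to-last segment not closed)
polyline_length <- function(points) {
  points <- as.matrix(points)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Ventricular volume by disk (area) summation
#'
#' Sum of contour areas times the slice increment (thickness + gap),
#' converted to millilitres.
#'
#' @param contours list of n x 2 contour matrices, one per slice
#' @param slice_thickness mm
#' @param gap inter-slice gap, mm
#' @return volume, mL
#' @export
volume_by_disk_summation <- function(contours, slice_thickness, gap = 0) {
  if (!length(contours)) stop("need at least one slice")
  areas <- vapply(contours, polygon_area, numeric(1))
  sum(areas) * (slice_thickness + gap) / 1000
}

#' Assemble a cine contour set
#'
#' @param contours list over cardiac phases; each element a list over slices
#'   of n x 2 contour matrices (mm)
#' @param slice_thickness mm
#' @param gap inter-slice gap, mm
#' @return `cine_contour_set` object
#' @export
cine_contour_set <- function(contours, slice_thickness, gap = 0) {
  if (length(contours) < 2) stop("need >= 2 cardiac phases")
  n_slices <- unique(vapply(contours, length, integer(1)))
  if (length(n_slices) != 1) stop("inconsistent slice count across phases")
  for (ph in contours) for (ct in ph)
    if (nrow(as.matrix(ct)) < 3) stop("contours need >= 3 points")
  structure(list(contours = contours, slice_thickness = slice_thickness,
                 gap = gap, phases = length(contours), n_slices = n_slices),
            class = "cine_contour_set")
}

#' Volume over the cardiac cycle with ED/ES phases
#'
#' End-diastole is the phase of maximum volume, end-systole the phase of
#' minimum volume (first phase on ties).
#'
#' @param cine [cine_contour_set()]
#' @return list: `volumes` (mL per phase), `ed_phase`, `es_phase`
#' @export
volume_curve <- function(cine) {
  v <- vapply(cine$contours, volume_by_disk_summation, numeric(1),
              slice_thickness = cine$slice_thickness, gap = cine$gap)
  list(volumes = v, ed_phase = which.max(v), es_phase = which.min(v))
}

#' RV longitudinal strain curve and peak strain
#'
#' Contours are resampled to `n_points` equally spaced points, lengths are
#' open-polyline arc lengths (valve-plane closing segment excluded, summed
#' over slices), and strain(t) = 100 (L(t) - L(ED)) / L(ED) with ED the
#' maximal-volume phase. Peak strain is the most negative curve value.
#'
#' @param cine [cine_contour_set()]
#' @param n_points resampling density (default 64)
#' @return list: `strain` (% per phase), `peak` (%), `ed_phase`
#' @export
longitudinal_strain_curve <- function(cine, n_points = 64) {
  lens <- vapply(cine$contours, function(ph)
    sum(vapply(ph, function(ct)
      polyline_length(resample_contour(ct, n_points, closed = FALSE)),
      numeric(1))),
    numeric(1))
  if (any(lens == 0)) stop("degenerate (zero-length) contour")
  ed <- volume_curve(cine)$ed_phase
  strain <- 100 * (lens - lens[ed]) / lens[ed]
  list(strain = strain, peak = min(strain), ed_phase = ed)
}

#' RV volumetric and strain measures for one subject
#'
#' @param cine [cine_contour_set()]
#' @return `cardiac_measures`: `rvedv`, `rvesv` (mL), `rvef` (%),
#'   `peak_longitudinal_strain` (%), `strain_curve`, `volume_curve`
#' @export
cardiac_measures <- function(cine) {
  vc <- volume_curve(cine)
  sc <- longitudinal_strain_curve(cine)
  rvedv <- vc$volumes[vc$ed_phase]
  rvesv <- vc$volumes[vc$es_phase]
  structure(list(
    rvedv = rvedv, rvesv = rvesv,
    rvef = 100 * (rvedv - rvesv) / rvedv,
    peak_longitudinal_strain = sc$peak,
    strain_curve = sc$strain, volume_curve = vc$volumes,
    ed_phase = vc$ed_phase, es_phase = vc$es_phase),
    class = "cardiac_measures")
}

#' @export
print.cardiac_measures <- function(x, ...) {
  cat(sprintf("RV EDV %.1f mL, ESV %.1f mL, EF %.1f%%, peak strain %.1f%%\n",
              x$rvedv, x$rvesv, x$rvef, x$peak_longitudinal_strain))
  invisible(x)
}

# ellipse contour (closed polygon) with semi-axes a, b
ellipse_contour <- function(a, b, n = 128, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + a * cos(th), center[2] + b * sin(th))
}

#' Synthetic contracting-ellipsoid cine for volumetry
#'
#' An ellipsoid with prescribed end-diastolic and end-systolic volumes,
#' sliced at `slice_thickness`; cross-sections contract isotropically so
#' that V(t) interpolates EDV -> ESV -> EDV over the cycle (ES at mid
#' cycle). Used to validate disk-summation volume recovery.
#'
#' @param edv,esv prescribed volumes, mL (EDV > ESV > 0)
#' @param phases phases per cycle (default 20)
#' @param slice_thickness mm (default 1)
#' @param long_axis ellipsoid semi-axis along the slice direction, mm
#' @param n_points contour vertices per slice
#' @return [cine_contour_set()]
#' @export
ellipsoid_cine <- function(edv, esv, phases = 20, slice_thickness = 1,
                           long_axis = 40, n_points = 128) {
  if (!(edv > esv && esv > 0)) stop("need EDV > ESV > 0")
  # a = b chosen so (4/3) pi a^2 c = EDV
  a <- sqrt(3 * edv * 1000 / (4 * pi * long_axis))
  z <- seq(-long_axis + slice_thickness / 2, long_axis - slice_thickness / 2,
           by = slice_thickness)
  rel <- sqrt(pmax(0, 1 - (z / long_axis)^2))
  t <- seq_len(phases)
  vol <- edv - (edv - esv) * sin(pi * (t - 1) / phases)^2
  k <- sqrt(vol / edv)   # areas scale k^2, thickness fixed
  contours <- lapply(k, function(ki)
    lapply(rel, function(ri)
      ellipse_contour(ki * a * ri, ki * a * ri, n = n_points)))
  cine_contour_set(contours, slice_thickness = slice_thickness, gap = 0)
}

#' Synthetic shortening four-chamber contour cine for strain
#'
#' A single-slice open-contour sequence whose arc length scales by
#' 1 + peak_strain/100 at mid cycle and returns to baseline, so the
#' prescribed peak longitudinal strain is recovered exactly in the limit
#' of dense resampling.
#'
#' @param peak_strain prescribed peak strain, % (negative = shortening)
#' @param phases phases per cycle (default 20)
#' @param base_length baseline contour arc length scale, mm
#' @param n_points contour vertices
#' @return [cine_contour_set()]
#' @export
shortening_cine <- function(peak_strain = -15, phases = 20,
                            base_length = 100, n_points = 64) {
  # U-shaped open endocardial contour (half ellipse), valve plane open
  th <- seq(0, pi, length.out = n_points)
  base <- cbind(cos(th), -sin(th)) * base_length / pi
  t <- seq_len(phases)
  s <- 1 + (peak_strain / 100) * sin(pi * (t - 1) / phases)^2
  contours <- lapply(s, function(si) list(base * si))
  cine_contour_set(contours, slice_thickness = 8, gap = 0)
}

#' Read contours from long-format CSV
#'
#' Expected columns: `slice`, `frame`, `point`, `x`, `y` (mm), optionally
#' `subject`.
#'
#' @param path CSV path
#' @param slice_thickness mm
#' @param gap mm
#' @return [cine_contour_set()] (single subject)
#' @export
read_contours_csv <- function(path, slice_thickness, gap = 0) {
  df <- utils::read.csv(path)
  need <- c("slice", "frame", "point", "x", "y")
  if (!all(need %in% names(df)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  slices <- sort(unique(df$slice))
  contours <- lapply(frames, function(f)
    lapply(slices, function(s) {
      d <- df[df$frame == f & df$slice == s, ]
      d <- d[order(d$point), ]
      cbind(d$x, d$y)
    }))
  cine_contour_set(contours, slice_thickness = slice_thickness, gap = gap)
}

#' Write a cine contour set to long-format CSV
#'
#' @param cine [cine_contour_set()]
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_contours_csv <- function(cine, path) {
  rows <- do.call(rbind, lapply(seq_len(cine$phases), function(f)
    do.call(rbind, lapply(seq_len(cine$n_slices), function(s) {
      ct <- as.matrix(cine$contours[[f]][[s]])
      data.frame(slice = s, frame = f, point = seq_len(nrow(ct)),
                 x = ct[, 1], y = ct[, 2])
    }))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
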