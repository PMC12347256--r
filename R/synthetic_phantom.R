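# Synthetic CT-like texture phantoms with known class maps.
#
# The phantom emulates the geometry the texture classifier sees: an
# ellipse-like lung field tiled with contiguous class regions (Voronoi
# cells), each filled with a class-specific intensity distribution and
# texture pattern. It does not model scanner noise, 3D fibrosis
# morphology, or respiratory motion.

#' Specification of one parenchymal texture class
#'
#' @param label one of N, E, G, C, R, H
#' @param mean_intensity mean attenuation, HU
#' @param sd_intensity noise SD, HU (> 0)
#' @param texture_kind "flat" (noise only), "periodic" (2D sinusoid, e.g.
#'   honeycomb-like cells) or "linear" (1D sinusoidal streaks, reticular)
#' @param texture_period pattern period, pixels (>= 2 unless flat)
#' @param texture_amplitude pattern amplitude, HU
#' @return `texture_class_spec` object
#' @export
texture_class_spec <- function(label, mean_intensity, sd_intensity,
                               texture_kind = c("flat", "periodic", "linear"),
                               texture_period = 8, texture_amplitude = 0) {
  texture_kind <- match.arg(texture_kind)
  if (!label %in% GHNC_CLASSES) stop("unknown class label: ", label)
  if (!(sd_intensity > 0)) stop("sd_intensity must be > 0")
  if (texture_kind != "flat" && texture_period < 2)
    stop("texture_period must be >= 2")
  structure(list(label = label, mean_intensity = mean_intensity,
                 sd_intensity = sd_intensity, texture_kind = texture_kind,
                 texture_period = texture_period,
                 texture_amplitude = texture_amplitude),
            class = "texture_class_spec")
}

#' Default texture class specifications
#'
#' Relative attenuations mimic real lung: normal -850 HU, emphysema -950,
#' GGO -650, consolidation -100, reticulation -500 with linear streaks,
#' honeycombing -750 with a periodic cellular pattern (period 8 px).
#'
#' @param sd_intensity common noise SD, HU
#' @return named list of [texture_class_spec()] objects
#' @export
default_class_specs <- function(sd_intensity = 40) {
  specs <- list(
    texture_class_spec("N", -850, sd_intensity),
    texture_class_spec("E", -950, sd_intensity),
    texture_class_spec("G", -650, sd_intensity),
    texture_class_spec("C", -100, sd_intensity),
    texture_class_spec("R", -500, sd_intensity, "linear",
                       texture_period = 6, texture_amplitude = 60),
    texture_class_spec("H", -750, sd_intensity, "periodic",
                       texture_period = 8, texture_amplitude = 80))
  names(specs) <- vapply(specs, `[[`, character(1), "label")
  specs
}

# deterministic texture pattern (no noise) for a region of the image plane
texture_pattern <- function(spec, rows, cols) {
  switch(spec$texture_kind,
    flat = 0,
    periodic = spec$texture_amplitude *
      sin(2 * pi * rows / spec$texture_period) *
      sin(2 * pi * cols / spec$texture_period),
    linear = spec$texture_amplitude *
      sin(2 * pi * cols / spec$texture_period))
}

#' Generate a texture phantom with ground-truth labels
#'
#' Lays out Voronoi-seeded contiguous blobs inside an elliptical lung mask,
#' assigns classes round-robin over the Voronoi seeds (so all six classes
#' are present), and fills each region with its class's mean, texture
#' pattern and Gaussian noise. Layouts in which any class covers less than
#' `min_fraction` of the mask are redrawn deterministically.
#'
#' @param width,height image size, pixels (>= 64)
#' @param class_specs list of six [texture_class_spec()], one per class
#' @param layout_seed integer seed; identical calls are bit-identical
#' @param pixel_spacing mm per pixel
#' @param slice_thickness mm
#' @param n_seeds number of Voronoi seeds (multiple of 6 recommended)
#' @param min_fraction minimum mask fraction per class (default 1%)
#' @return `phantom_image`: `intensity`, `truth_labels`, `lung_mask`,
#'   `pixel_spacing`, `slice_thickness`
#' @export
generate_phantom <- function(width = 256, height = 256,
                             class_specs = default_class_specs(),
                             layout_seed = 1, pixel_spacing = 0.7,
                             slice_thickness = 1, n_seeds = 24,
                             min_fraction = 0.01) {
  if (width < 64 || height < 64) stop("width and height must be >= 64")
  labs <- vapply(class_specs, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate class labels in class_specs")
  missing <- setdiff(GHNC_CLASSES, labs)
  if (length(missing))
    stop("missing class(es) in class_specs: ", paste(missing, collapse = ", "))
  names(class_specs) <- labs

  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  lung_mask <- ((rows - cy) / (0.45 * height))^2 +
               ((cols - cx) / (0.45 * width))^2 <= 1
  mask_idx <- which(lung_mask)

  set.seed(layout_seed)
  class_of_seed <- rep(GHNC_CLASSES, length.out = n_seeds)
  for (try in seq_len(100)) {
    seeds <- mask_idx[sample.int(length(mask_idx), n_seeds)]
    sr <- rows[seeds]; sc <- cols[seeds]
    d2 <- outer(rows[mask_idx], sr, `-`)^2 + outer(cols[mask_idx], sc, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    region_labels <- class_of_seed[nearest]
    fr <- table(factor(region_labels, levels = GHNC_CLASSES)) / length(mask_idx)
    if (all(fr >= min_fraction)) break
  }
  if (any(fr < min_fraction))
    stop("could not lay out all classes above min_fraction")

  truth <- matrix(NA_character_, height, width)
  truth[mask_idx] <- region_labels
  intensity <- matrix(-1000 + stats::rnorm(height * width, sd = 20),
                      height, width)
  for (cl in GHNC_CLASSES) {
    sel <- mask_idx[region_labels == cl]
    sp <- class_specs[[cl]]
    intensity[sel] <- sp$mean_intensity +
      texture_pattern(sp, rows[sel], cols[sel]) +
      stats::rnorm(length(sel), sd = sp$sd_intensity)
  }
  structure(list(intensity = intensity, truth_labels = truth,
                 lung_mask = lung_mask, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "phantom_image")
}

#' Generate template patches for reference-histogram construction
#'
#' One pure-texture patch per class, drawn from the same intensity model
#' as the phantom regions.
#'
#' @param class_specs list of [texture_class_spec()]
#' @param size patch side length, pixels
#' @param seed integer seed
#' @return list of `list(label =, patch =)` entries, one per class
#' @export
generate_class_templates <- function(class_specs = default_class_specs(),
                                     size = 33, seed = 1) {
  set.seed(seed)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  lapply(class_specs, function(sp) {
    patch <- sp$mean_intensity + texture_pattern(sp, rows, cols) +
      matrix(stats::rnorm(size * size, sd = sp$sd_intensity), size, size)
    list(label = sp$label, patch = patch)
  })
}

# pixels of `mask` whose full Chebyshev-radius neighborhood lies in `mask`
# (box erosion via separable box sums); used to score classifier accuracy
# away from class borders
erode_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  n <- 2L * as.integer(radius) + 1L
  box <- rep(1, n)
  Kr <- conv_matrix(nrow(mask), box)
  Kc <- conv_matrix(ncol(mask), box)
  full <- Kr %*% matrix(1, nrow(mask), ncol(mask)) %*% Kc
  inside <- Kr %*% (mask * 1) %*% Kc
  mask & (abs(inside - full) < 0.5)
}

#' Pixel accuracy of a label map against phantom ground truth
#'
#' @param labelmap `label_map` from [classify_image()]
#' @param phantom `phantom_image`
#' @param border_erosion Chebyshev radius, pixels: only truth regions eroded
#'   by this radius are scored (excludes mixed-window border pixels); 0
#'   scores every masked pixel
#' @return accuracy as a percentage
#' @export
phantom_accuracy <- function(labelmap, phantom, border_erosion = 0) {
  scored <- phantom$lung_mask
  if (border_erosion > 0) {
    interior <- matrix(FALSE, nrow(scored), ncol(scored))
    for (cl in GHNC_CLASSES) {
      cl_mask <- !is.na(phantom$truth_labels) & phantom$truth_labels == cl
      interior <- interior | erode_mask(cl_mask, border_erosion)
    }
    scored <- scored & interior
  }
  if (!any(scored)) stop("no scored pixels after erosion")
  100 * mean(labelmap$labels[scored] == phantom$truth_labels[scored])
}

#' Write a phantom as NIfTI volumes
#'
#' Writes `intensity.nii.gz`, `labels.nii.gz` (integer-coded, legend in
#' `labels_legend.json`) and `mask.nii.gz` into `dir`.
#'
#' @param phantom `phantom_image`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  codes <- matrix(match(phantom$truth_labels, GHNC_CLASSES), nrow(phantom$intensity))
  codes[is.na(codes)] <- 0L
  paths <- file.path(dir, c("intensity.nii.gz", "labels.nii.gz", "mask.nii.gz"))
  pd <- c(phantom$pixel_spacing, phantom$pixel_spacing)
  RNifti::writeNifti(RNifti::asNifti(phantom$intensity, pixdim = pd), paths[1])
  RNifti::writeNifti(RNifti::asNifti(codes, pixdim = pd), paths[2])
  RNifti::writeNifti(RNifti::asNifti(phantom$lung_mask * 1L, pixdim = pd), paths[3])
  legend <- file.path(dir, "labels_legend.json")
  jsonlite::write_json(as.list(stats::setNames(seq_along(GHNC_CLASSES), GHNC_CLASSES)),
                       legend, auto_unbox = TRUE)
  invisible(c(paths, legend))
}
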