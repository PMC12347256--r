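#' Parenchymal class labels in canonical order
#'
#' Six lung texture classes: normal (N), emphysema (E), ground-glass
#' opacity (G), consolidation (C), reticulation (R), honeycombing (H).
#' The order is the deterministic tie-break order of the classifier.
#'
#' @export
GHNC_CLASSES <- c("N", "E", "G", "C", "R", "H")

#' Histogram discretization for CT attenuation values
#'
#' Defines the binning used for local and reference histograms. The default
#' covers lung parenchyma, -1024 to 100 HU in 25-HU bins (45 bins).
#' Out-of-range values are clamped to the end bins.
#'
#' @param hu_min lower edge, HU
#' @param hu_max upper edge, HU
#' @param bin_width bin width, HU
#' @return object of class `histogram_spec` with `n_bins = ceiling((hu_max - hu_min)/bin_width)`
#' @export
histogram_spec <- function(hu_min = -1024, hu_max = 100, bin_width = 25) {
  if (!(hu_min < hu_max)) stop("hu_min must be < hu_max")
  if (!(bin_width > 0)) stop("bin_width must be > 0")
  structure(
    list(hu_min = hu_min, hu_max = hu_max, bin_width = bin_width,
         n_bins = as.integer(ceiling((hu_max - hu_min) / bin_width))),
    class = "histogram_spec")
}

# bin index for a value, clamped to the end bins
hu_bin <- function(x, hspec) {
  idx <- floor((x - hspec$hu_min) / hspec$bin_width) + 1
  pmin(pmax(idx, 1), hspec$n_bins)
}

#' Gaussian weighting kernel for local histograms
#'
#' A truncated, normalized Gaussian over a square window. The default
#' reads the classifier's "50-pixel neighborhood" as a 51x51 window with
#' sigma = window/4 = 12.75 ~ 12.5 px; both are configurable.
#'
#' @param sigma Gaussian standard deviation, pixels
#' @param window odd window side length, pixels (>= 3)
#' @return object of class `gaussian_kernel_spec`
#' @export
gaussian_kernel_spec <- function(sigma = 12.5, window = 51L) {
  window <- as.integer(window)
  if (!(sigma > 0)) stop("sigma must be > 0")
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  structure(list(sigma = sigma, window = window), class = "gaussian_kernel_spec")
}

# 1D Gaussian profile over window offsets, normalized so the 2D separable
# kernel outer(g, g) sums to 1
gaussian_profile <- function(kernel) {
  r <- (kernel$window - 1L) / 2L
  g <- stats::dnorm(seq(-r, r), mean = 0, sd = kernel$sigma)
  g / sum(g)
}

#' Gradient-magnitude (differential) image
#'
#' Per-pixel central-difference gradient magnitude; borders handled by
#' edge replication, so a linear ramp of slope s gives interior values s.
#'
#' @param intensity numeric matrix (HU)
#' @return matrix of gradient magnitudes, same shape
#' @export
differential_image <- function(intensity) {
  if (!is.matrix(intensity) || !all(is.finite(intensity)))
    stop("intensity must be a finite numeric matrix")
  nr <- nrow(intensity); nc <- ncol(intensity)
  gx <- (intensity[pmin(seq_len(nr) + 1L, nr), , drop = FALSE] -
         intensity[pmax(seq_len(nr) - 1L, 1L), , drop = FALSE]) / 2
  gy <- (intensity[, pmin(seq_len(nc) + 1L, nc), drop = FALSE] -
         intensity[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE]) / 2
  sqrt(gx^2 + gy^2)
}

#' Local Gaussian-weighted histogram at one pixel
#'
#' Each pixel of the window centered at `center` contributes its kernel
#' weight to the bin containing its value; window parts outside the image
#' are dropped and the result renormalized to sum 1.
#'
#' @param intensity numeric matrix
#' @param center c(row, col) pixel coordinate
#' @param kernel [gaussian_kernel_spec()]
#' @param hspec [histogram_spec()]
#' @return numeric vector of length `hspec$n_bins` summing to 1
#' @export
local_gaussian_histogram <- function(intensity, center, kernel, hspec) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  i <- as.integer(center[1]); j <- as.integer(center[2])
  if (i < 1L || i > nr || j < 1L || j > nc) stop("center outside grid")
  r <- (kernel$window - 1L) / 2L
  g <- gaussian_profile(kernel)
  ri <- (i - r):(i + r); ci <- (j - r):(j + r)
  okr <- ri >= 1L & ri <= nr; okc <- ci >= 1L & ci <= nc
  w <- outer(g[okr], g[okc])
  vals <- intensity[ri[okr], ci[okc], drop = FALSE]
  bins <- hu_bin(vals, hspec)
  h <- numeric(hspec$n_bins)
  sums <- rowsum(as.vector(w), group = as.vector(bins))
  h[as.integer(rownames(sums))] <- sums[, 1]
  h / sum(h)
}

# banded convolution matrix for the separable Gaussian (zero padding);
# symmetric because the profile is symmetric
conv_matrix <- function(n, g) {
  r <- (length(g) - 1L) / 2L
  d <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
  K <- matrix(0, n, n)
  ok <- abs(d) <= r
  K[ok] <- g[d[ok] + r + 1L]
  K
}

# local Gaussian histograms at every pixel, as an (npix x n_bins) matrix of
# row vectors each summing to 1; computed per bin by separable convolution
# (mathematically identical to local_gaussian_histogram at each pixel)
local_histogram_field <- function(intensity, kernel, hspec) {
  g <- gaussian_profile(kernel)
  Kr <- conv_matrix(nrow(intensity), g)
  Kc <- conv_matrix(ncol(intensity), g)
  norm <- Kr %*% matrix(1, nrow(intensity), ncol(intensity)) %*% Kc
  binmap <- matrix(hu_bin(intensity, hspec), nrow(intensity))
  H <- matrix(0, length(intensity), hspec$n_bins)
  for (b in seq_len(hspec$n_bins)) {
    if (!any(binmap == b)) next
    H[, b] <- as.vector((Kr %*% ((binmap == b) * 1) %*% Kc) / norm)
  }
  H
}

#' Build per-class reference histograms from labeled template patches
#'
#' For each class the original channel is the mean, over all template-patch
#' pixels, of their local Gaussian histograms; the differential channel is
#' the same computed on the gradient-magnitude image of each patch. Both
#' channels are renormalized to sum 1.
#'
#' @param templates list of `list(label =, patch =)` entries; all six classes
#'   must be covered, multiple patches per class allowed
#' @param kernel [gaussian_kernel_spec()]
#' @param hspec [histogram_spec()] for the original channel
#' @param hspec_diff optional [histogram_spec()] for the differential channel
#'   (defaults to `hspec`)
#' @return named list (by class) of `reference_histogram` objects with
#'   `original` and `differential` channels
#' @export
build_reference_histograms <- function(templates, kernel, hspec, hspec_diff = NULL) {
  if (is.null(hspec_diff)) hspec_diff <- hspec
  labels <- vapply(templates, function(t) t$label, character(1))
  missing <- setdiff(GHNC_CLASSES, labels)
  if (length(missing))
    stop("missing template class(es): ", paste(missing, collapse = ", "))
  refs <- lapply(GHNC_CLASSES, function(cl) {
    patches <- lapply(templates[labels == cl], `[[`, "patch")
    ho <- do.call(rbind, lapply(patches, local_histogram_field,
                                kernel = kernel, hspec = hspec))
    hd <- do.call(rbind, lapply(patches, function(p)
      local_histogram_field(differential_image(p), kernel, hspec_diff)))
    orig <- colMeans(ho); diff <- colMeans(hd)
    structure(list(label = cl, original = orig / sum(orig),
                   differential = diff / sum(diff)),
              class = "reference_histogram")
  })
  names(refs) <- GHNC_CLASSES
  refs
}

#' Normalized correlation between two histogram vectors
#'
#' Pearson-type normalized cross-correlation of mean-centered vectors,
#' in \[-1, 1\]; returns 0 if either vector has zero variance.
#'
#' @param a,b numeric vectors of equal length >= 2
#' @return correlation score
#' @export
normalized_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("vectors must have length >= 2")
  ca <- a - mean(a); cb <- b - mean(b)
  den <- sqrt(sum(ca^2) * sum(cb^2))
  if (den == 0) return(0)
  max(-1, min(1, sum(ca * cb) / den))
}

#' Classify every lung pixel into one of six parenchymal classes
#'
#' Per masked pixel the feature vector is the concatenation of the local
#' Gaussian histograms of the original and gradient-magnitude images; the
#' label is the class whose reference histogram has the highest normalized
#' correlation with the feature, ties broken by the fixed order N<E<G<C<R<H.
#'
#' @param intensity numeric matrix (HU)
#' @param lung_mask logical matrix, same shape, non-empty
#' @param references output of [build_reference_histograms()]
#' @param kernel [gaussian_kernel_spec()]
#' @param hspec [histogram_spec()] for the original channel
#' @param hspec_diff optional differential-channel spec (defaults to `hspec`)
#' @return `label_map` object with `labels` (character matrix, NA off-mask)
#'   and `correlation_scores` (winning score per pixel)
#' @export
classify_image <- function(intensity, lung_mask, references, kernel, hspec,
                           hspec_diff = NULL) {
  if (is.null(hspec_diff)) hspec_diff <- hspec
  if (!identical(dim(intensity), dim(lung_mask))) stop("shape mismatch")
  if (!any(lung_mask)) stop("empty lung mask")
  missing <- setdiff(GHNC_CLASSES, names(references))
  if (length(missing))
    stop("references missing class(es): ", paste(missing, collapse = ", "))
  idx <- which(lung_mask)
  Ho <- local_histogram_field(intensity, kernel, hspec)
  Hd <- local_histogram_field(differential_image(intensity), kernel, hspec_diff)
  feat <- cbind(Ho, Hd)[idx, , drop = FALSE]
  R <- vapply(GHNC_CLASSES, function(cl)
    c(references[[cl]]$original, references[[cl]]$differential),
    numeric(ncol(feat)))
  fc <- feat - rowMeans(feat)
  Rc <- sweep(R, 2L, colMeans(R))
  scores <- (fc %*% Rc) / outer(sqrt(rowSums(fc^2)), sqrt(colSums(Rc^2)))
  scores[!is.finite(scores)] <- 0
  win <- max.col(scores, ties.method = "first")
  labels <- matrix(NA_character_, nrow(intensity), ncol(intensity))
  labels[idx] <- GHNC_CLASSES[win]
  cors <- matrix(NA_real_, nrow(intensity), ncol(intensity))
  cors[idx] <- scores[cbind(seq_along(win), win)]
  structure(list(labels = labels, correlation_scores = cors,
                 lung_mask = lung_mask),
            class = "label_map")
}

#' Per-class volume fractions and the diseased-area aggregate
#'
#' Fractions are percentages of the CT lung volume (CTLV); the diseased
#' area is the sum of all non-normal fractions, i.e. exactly
#' 100 - fraction(N).
#'
#' @param labelmap a `label_map` or a character label matrix
#' @param lung_mask logical matrix (defaults to the label map's own mask)
#' @param pixel_spacing mm per pixel (isotropic in-plane)
#' @param slice_thickness mm
#' @return `class_fractions` object: named `fractions` (%), `ctlv` (mL),
#'   `diseased_area` (%)
#' @export
class_fractions <- function(labelmap, lung_mask = NULL, pixel_spacing = 0.7,
                            slice_thickness = 1) {
  labels <- if (inherits(labelmap, "label_map")) labelmap$labels else labelmap
  if (is.null(lung_mask)) {
    lung_mask <- if (inherits(labelmap, "label_map")) labelmap$lung_mask
                 else !is.na(labels)
  }
  n_total <- sum(lung_mask)
  if (n_total == 0) stop("empty lung mask")
  counts <- vapply(GHNC_CLASSES, function(cl)
    sum(labels[lung_mask] == cl, na.rm = TRUE), numeric(1))
  fractions <- 100 * counts / n_total
  structure(list(
    fractions = fractions,
    ctlv = n_total * pixel_spacing^2 * slice_thickness / 1000,
    diseased_area = 100 - fractions[["N"]]),
    class = "class_fractions")
}

#' Color palette of the parenchymal classes
#'
#' Normal pink, emphysema dark blue, GGO orange, reticulation light blue,
#' honeycombing yellow; consolidation is rendered firebrick red (the five
#' named colors cover the other classes only).
#'
#' @return named character vector of hex colors
#' @export
ghnc_palette <- function() {
  c(N = "#FFC0CB", E = "#00008B", G = "#FFA500",
    C = "#B22222", R = "#ADD8E6", H = "#FFFF00")
}

#' Render a color-coded class overlay
#'
#' Masked pixels take their class color; pixels outside the lung mask show
#' the windowed grayscale CT intensity.
#'
#' @param intensity numeric matrix
#' @param labelmap `label_map` (same shape)
#' @param window HU display window for the grayscale background
#' @return numeric array height x width x 3 in \[0, 1\]
#' @export
render_overlay <- function(intensity, labelmap, window = c(-1024, 100)) {
  labels <- if (inherits(labelmap, "label_map")) labelmap$labels else labelmap
  if (!identical(dim(intensity), dim(labels))) stop("shape mismatch")
  gray <- pmin(pmax((intensity - window[1]) / diff(window), 0), 1)
  out <- array(rep(gray, 3L), dim = c(dim(intensity), 3L))
  pal <- ghnc_palette()
  rgb <- grDevices::col2rgb(pal) / 255
  for (cl in GHNC_CLASSES) {
    sel <- which(!is.na(labels) & labels == cl)
    if (!length(sel)) next
    npix <- length(intensity)
    out[sel] <- rgb[1, cl]
    out[sel + npix] <- rgb[2, cl]
    out[sel + 2L * npix] <- rgb[3, cl]
  }
  out
}
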