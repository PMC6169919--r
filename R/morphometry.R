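# Mid-diaphyseal cortical morphometry from a calibrated density section.
# Image primitives (connected components, hull filling, distance transform)
# come from EBImage; the metrics follow the usual BoneJ conventions.

#' Calibrated density cross-section
#'
#' @param density Numeric matrix of calibrated densities in mg HA/cm^3,
#'   all >= 0.
#' @param pixel_size Isotropic pixel size in micrometres (default 12).
#' @return Object of class `section_image`.
#' @export
section_image <- function(density, pixel_size = 12) {
  if (!is.matrix(density) || !is.numeric(density)) {
    stop("density must be a numeric matrix")
  }
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("input error: densities must be finite and >= 0")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive")
  }
  structure(list(density = density, pixel_size = pixel_size),
            class = "section_image")
}

#' Segment the cortical shell by global density threshold
#'
#' Pixels at or above the threshold are bone; only the largest connected
#' component is retained (debris and partial-volume islands are discarded).
#'
#' @param image A [section_image()].
#' @param threshold Global lower threshold in mg HA/cm^3 (default 654).
#' @return Integer 0/1 matrix mask of the cortical shell.
#' @export
segment_cortex <- function(image, threshold = 654) {
  stopifnot(inherits(image, "section_image"))
  raw <- image$density >= threshold
  if (!any(raw)) {
    stop(sprintf("segmentation error: no pixels at or above %.0f mg HA/cm^3",
                 threshold))
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  counts <- tabulate(as.integer(lab[lab > 0]))
  keep <- which.max(counts)
  mask <- matrix(0L, nrow(raw), ncol(raw))
  mask[lab == keep] <- 1L
  mask
}

.fill_mask <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(as.integer(f > 0), nrow(mask), ncol(mask))
}

# connected components of the enclosed (endosteal) cavity
.hole_count <- function(mask) {
  holes <- .fill_mask(mask) - mask
  if (!any(holes > 0)) return(0L)
  lab <- EBImage::bwlabel(matrix(as.numeric(holes), nrow(mask), ncol(mask)))
  max(as.integer(lab))
}

#' Cross-sectional areas of the cortical section
#'
#' Total area Tt.Ar is the area enclosed by the periosteal boundary (filled
#' mask), cortical area Ct.Ar the bone pixel area, endosteal area Es.Ar their
#' difference, so Tt.Ar = Ct.Ar + Es.Ar holds by construction.
#'
#' @param mask 0/1 cortical mask from [segment_cortex()].
#' @param pixel_size Pixel size in micrometres.
#' @return List with `Tt.Ar`, `Ct.Ar`, `Es.Ar` in mm^2.
#' @export
section_areas <- function(mask, pixel_size) {
  if (!any(mask > 0)) stop("segmentation error: empty mask")
  px_mm2 <- (pixel_size / 1000)^2
  ct <- sum(mask > 0) * px_mm2
  tt <- sum(.fill_mask(mask) > 0) * px_mm2
  list(Tt.Ar = tt, Ct.Ar = ct, Es.Ar = tt - ct)
}

#' Mean cortical thickness
#'
#' Default `method = "local"` follows the local-thickness convention: the
#' Euclidean distance transform of the mask is evaluated on its medial ridge
#' (pixels that are maxima of the transform within their 8-neighbourhood) and
#' the mean of twice the ridge distance, with a half-pixel centring
#' correction, is reported. `method = "rays"` instead averages the radial
#' extent of the mask over angular bins around the section centroid.
#'
#' @param mask 0/1 annular cortical mask.
#' @param pixel_size Pixel size in micrometres.
#' @param method "local" (distance transform, default) or "rays".
#' @param n_rays Number of angular bins for `method = "rays"`.
#' @return Mean cortical thickness in mm.
#' @export
cortical_thickness <- function(mask, pixel_size, method = c("local", "rays"),
                               n_rays = 72) {
  method <- match.arg(method)
  if (!any(mask > 0)) stop("segmentation error: empty mask")
  if (.hole_count(mask) != 1L) {
    stop("topology error: mask is not a single annulus")
  }
  px <- pixel_size / 1000
  if (method == "local") {
    dt <- EBImage::distmap(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)))
    dt <- dt@.Data
    # medial ridge: distance value not exceeded by any 8-neighbour
    n <- nrow(dt); m <- ncol(dt)
    pad <- matrix(-Inf, n + 2, m + 2)
    pad[2:(n + 1), 2:(m + 1)] <- dt
    nb_max <- matrix(-Inf, n, m)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb_max <- pmax(nb_max, pad[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)])
    }
    ridge <- mask > 0 & dt >= nb_max
    mean(2 * dt[ridge] - 0.5) * px
  } else {
    idx <- which(mask > 0, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    r <- sqrt((idx[, 1] - cx)^2 + (idx[, 2] - cy)^2)
    phi <- atan2(idx[, 2] - cy, idx[, 1] - cx)
    bin <- findInterval(phi, seq(-pi, pi, length.out = n_rays + 1),
                        rightmost.closed = TRUE)
    spans <- tapply(r, bin, function(v) max(v) - min(v) + 1)
    mean(spans) * px
  }
}

#' Principal second moments of area
#'
#' Second moments of the bone pixel set about its centroid, including the
#' per-pixel self moment (p^4/12); principal values from the eigen
#' decomposition of the 2x2 inertia tensor.
#'
#' @param mask 0/1 cortical mask.
#' @param pixel_size Pixel size in micrometres.
#' @return List with `I_min`, `I_max` (mm^4) and `angle` (rad), the
#'   orientation of the major principal axis.
#' @export
principal_moments <- function(mask, pixel_size) {
  if (!any(mask > 0)) stop("segmentation error: empty mask")
  px <- pixel_size / 1000
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 1] * px; y <- idx[, 2] * px
  x <- x - mean(x); y <- y - mean(y)
  a <- px^2                       # pixel area
  self <- px^4 / 12               # pixel self moment
  n <- length(x)
  Ixx <- sum(y^2) * a + n * self
  Iyy <- sum(x^2) * a + n * self
  Ixy <- -sum(x * y) * a
  ev <- eigen(matrix(c(Ixx, Ixy, Ixy, Iyy), 2, 2), symmetric = TRUE)
  major <- ev$vectors[, 1]
  list(I_min = min(ev$values), I_max = max(ev$values),
       angle = atan2(major[2], major[1]))
}

#' Tissue mineral density over the segmented cortex
#'
#' @param image A [section_image()].
#' @param mask 0/1 cortical mask.
#' @return Mean calibrated density (mg HA/cm^3) over bone pixels.
#' @export
tissue_mineral_density <- function(image, mask) {
  stopifnot(inherits(image, "section_image"))
  if (!any(mask > 0)) stop("segmentation error: empty mask")
  mean(image$density[mask > 0])
}

#' Equivalent-area annulus fit
#'
#' Fits the idealized circular annulus with the same total and endosteal areas
#' as the mask: R_o = sqrt(Tt.Ar/pi), R_i = sqrt(Es.Ar/pi). The result is the
#' [cross_section()] consumed by the fracture-toughness chain.
#'
#' @param mask 0/1 annular cortical mask.
#' @param pixel_size Pixel size in micrometres.
#' @return A [cross_section()].
#' @export
fit_annulus <- function(mask, pixel_size) {
  if (.hole_count(mask) != 1L) {
    stop("topology error: mask is not a single annulus")
  }
  ar <- section_areas(mask, pixel_size)
  if (ar$Es.Ar <= 0) stop("topology error: no endosteal cavity")
  cross_section(sqrt(ar$Tt.Ar / pi), sqrt(ar$Es.Ar / pi))
}

#' Full morphometry row for one section
#'
#' Convenience wrapper running segmentation and all metrics.
#'
#' @param image A [section_image()].
#' @param threshold Density threshold in mg HA/cm^3 (default 654).
#' @param ... Passed to [cortical_thickness()].
#' @return data.frame with Tt.Ar, Ct.Ar, Es.Ar (mm^2), Ct.Th (mm), I_min,
#'   I_max (mm^4) and TMD (mg HA/cm^3).
#' @export
section_morphology <- function(image, threshold = 654, ...) {
  mask <- segment_cortex(image, threshold)
  ar <- section_areas(mask, image$pixel_size)
  mom <- principal_moments(mask, image$pixel_size)
  data.frame(
    Tt.Ar = ar$Tt.Ar, Ct.Ar = ar$Ct.Ar, Es.Ar = ar$Es.Ar,
    Ct.Th = cortical_thickness(mask, image$pixel_size, ...),
    I_min = mom$I_min, I_max = mom$I_max,
    TMD = tissue_mineral_density(image, mask)
  )
}
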