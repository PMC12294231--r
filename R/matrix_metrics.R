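#' @title Collagen lattice and peri-organoid remodeling metrics
#' @name matrix_metrics
NULL

#' Segment collagen fibers from an SHG-like image
#'
#' Per-slice Gaussian background subtraction followed by a global Otsu
#' threshold; deterministic for a fixed input. A blank image yields an empty
#' mask with a warning.
#'
#' @param image [VoxelImage-class] or numeric array (2D or 3D).
#' @param backgroundSigma sigma (px) of the background estimate.
#' @param invert set TRUE for inverted-contrast input (dark fibers).
#' @return logical fiber mask, same shape as the input.
#' @export
segmentFibers <- function(image, backgroundSigma = 20, invert = FALSE) {
  a <- if (is(image, "VoxelImage")) imgData(image) else image
  if (length(dim(a)) == 2L) a <- array(a, c(1L, dim(a)))
  if (invert) a <- max(a) - a
  if (diff(range(a)) <= 0) {
    warning("blank image: returning empty fiber mask")
    return(array(FALSE, dim(a)))
  }
  bgsub <- a
  for (z in seq_len(dim(a)[1L])) {
    sl <- a[z, , ]
    bg <- EBImage::gblur(sl, sigma = backgroundSigma)
    bgsub[z, , ] <- sl - bg
  }
  th <- otsuThreshold(as.vector(bgsub))
  bgsub > th
}

# regional maxima (26-neighborhood plateaus included) of a numeric volume,
# restricted to `mask`
regionalMaxima3D <- function(v, mask) {
  mx <- v
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dz && !dy && !dx) next
    mx <- pmax(mx, shiftArray(v, dz, dy, dx, fill = -Inf))
  }
  mask & (v >= mx)
}

#' Fiber lattice metrics: thickness, density, pore diameter
#'
#' Thickness is twice the mean Euclidean distance-transform value on the
#' fiber medial voxels (distance-ridge local maxima), corrected by half a
#' voxel per side for the center-to-center bias; density is the fiber voxel
#' percentage; pore diameter is the mean of twice the pore-space EDT at its
#' regional maxima.
#'
#' @param mask logical fiber mask ([VoxelImage-class] or array).
#' @param spacing voxel spacing in um (scalar or length 3; taken from the
#'   image when given one).
#' @return data.frame with `fiber_thickness_um`, `fiber_density_pct`,
#'   `pore_diameter_um`.
#' @export
fiberMetrics <- function(mask, spacing = NULL) {
  if (is(mask, "VoxelImage")) {
    spacing <- mask@spacing
    mask <- imgData(mask) > 0
  } else {
    if (is.null(spacing)) stop("spacing required for bare arrays")
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    mask <- mask > 0
  }
  if (!any(mask)) stop("empty fiber mask")
  d <- dim(mask)
  h <- mean(spacing)
  edtF <- .edt3d(mask, d, spacing)
  med <- regionalMaxima3D(edtF, mask)
  thick <- max(2 * mean(edtF[med]) - h, h)
  dens <- 100 * mean(mask)
  pore <- !mask
  poreD <- NA_real_
  if (any(pore)) {
    edtP <- .edt3d(pore, d, spacing)
    pmax_ <- regionalMaxima3D(edtP, pore)
    poreD <- 2 * mean(edtP[pmax_])
  }
  data.frame(fiber_thickness_um = thick, fiber_density_pct = dens,
             pore_diameter_um = poreD)
}

#' Doughnut ROI around an organoid
#'
#' The peri-organoid band: voxels within `bandWidth` micrometres outside the
#' organoid boundary; the control region is a band of equal thickness
#' starting `controlOffset` micrometres away from every organoid (the offset
#' must leave at least a doubled-band margin). Bands clipped by the image
#' border are flagged.
#'
#' @param organoid [LabelImage-class] or logical array of organoid voxels.
#' @param bandWidth band width in um (default 7).
#' @param controlOffset distance (um) from the organoid to the control band;
#'   default `3 * bandWidth`, minimum `2 * bandWidth`.
#' @param spacing spacing for bare arrays.
#' @return list with logical masks `band` and `control`, and `clipped`
#'   (TRUE when the band touches the image border).
#' @export
doughnutROI <- function(organoid, bandWidth = 7, controlOffset = NULL,
                        spacing = NULL) {
  if (is(organoid, "VoxelImage")) {
    spacing <- organoid@spacing
    org <- imgData(organoid) > 0
  } else {
    if (is.null(spacing)) stop("spacing required for bare arrays")
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    org <- organoid > 0
  }
  if (bandWidth <= 0) stop("bandWidth must be > 0")
  if (is.null(controlOffset)) controlOffset <- 3 * bandWidth
  if (controlOffset < 2 * bandWidth)
    stop("controlOffset must be >= 2 * bandWidth")
  d <- dim(org)
  dist <- .edt3d(!org, d, spacing)             # distance to the organoid
  band <- dist > 0 & dist <= bandWidth
  control <- dist > controlOffset & dist <= controlOffset + bandWidth
  edge <- array(FALSE, d)
  edge[1, , ] <- TRUE; edge[d[1L], , ] <- TRUE
  edge[, 1, ] <- TRUE; edge[, d[2L], ] <- TRUE
  edge[, , 1] <- TRUE; edge[, , d[3L]] <- TRUE
  clipped <- any(band & edge)
  if (clipped) warning("doughnut band clipped by the image border")
  list(band = band, control = control, clipped = clipped)
}

#' Peri-organoid fiber compaction
#'
#' Fiber density inside the doughnut band divided by the density in the
#' control region; 1 means no densification.
#'
#' @param fiberMask logical fiber mask.
#' @param roi a [doughnutROI()] result.
#' @return numeric compaction ratio.
#' @export
compaction <- function(fiberMask, roi) {
  if (is(fiberMask, "VoxelImage")) fiberMask <- imgData(fiberMask) > 0
  bandD <- mean(fiberMask[roi$band])
  ctrlD <- mean(fiberMask[roi$control])
  if (!is.finite(ctrlD) || ctrlD <= 0)
    stop("no fibers in the control region")
  bandD / ctrlD
}

#' Fiber anisotropy index and orientation histogram
#'
#' Orientations are estimated per pixel from the 2D structure tensor of the
#' axial maximum-intensity projection (Gaussian-smoothed gradient products),
#' restricted to the ROI and to fiber pixels. The anisotropy index is the
#' length of the coherence-weighted mean resultant vector of the doubled
#' orientation angles: 0 for an isotropic lattice, 1 for perfectly aligned
#' fibers; the doubled-angle construction makes it invariant to 180-degree
#' fiber flips. A normalized orientation histogram over `[0, pi)` is
#' returned for polar plots.
#'
#' @param x fiber image or mask ([VoxelImage-class], 2D matrix or 3D array).
#' @param roi optional logical ROI (3D array or 2D matrix; projected to 2D).
#' @param gradientSigma,tensorSigma Gaussian sigmas (px) for gradients and
#'   tensor smoothing.
#' @param nBins orientation histogram bins.
#' @param minPixels minimum fiber pixels inside the ROI (default 100).
#' @return list with `alpha`, `histogram` (data.frame: angle_rad, density)
#'   and `n_pixels`.
#' @export
fiberAnisotropy <- function(x, roi = NULL, gradientSigma = 1,
                            tensorSigma = 4, nBins = 36, minPixels = 100) {
  a <- if (is(x, "VoxelImage")) imgData(x) else x
  mip <- if (length(dim(a)) == 3L) apply(a, c(2L, 3L), max) else a
  mip <- mip * 1
  if (!is.null(roi)) {
    if (is(roi, "VoxelImage")) roi <- imgData(roi)
    roi2 <- if (length(dim(roi)) == 3L) apply(roi > 0, c(2L, 3L), any)
            else roi > 0
  } else roi2 <- matrix(TRUE, nrow(mip), ncol(mip))

  sm <- EBImage::gblur(mip, sigma = gradientSigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)  # Sobel, x = columns
  gy <- EBImage::filter2(sm, t(kx))
  gx <- EBImage::filter2(sm, kx)
  jxx <- EBImage::gblur(gx * gx, sigma = tensorSigma)
  jyy <- EBImage::gblur(gy * gy, sigma = tensorSigma)
  jxy <- EBImage::gblur(gx * gy, sigma = tensorSigma)

  # fiber pixels: the mask itself, or Otsu on intensity
  fiber <- if (is.logical(a) || all(a %in% c(0, 1)))
    mip > 0 else mip > otsuThreshold(as.vector(mip))
  sel <- fiber & roi2
  if (sum(sel) < minPixels)
    stop("fewer than ", minPixels, " fiber pixels in the ROI")

  # orientation of the dominant (fiber) axis: eigenvector of the structure
  # tensor for the smaller eigenvalue, as doubled angle
  two <- atan2(2 * jxy[sel], jxx[sel] - jyy[sel]) + pi  # doubled gradient angle
  coher <- sqrt((jxx[sel] - jyy[sel])^2 + 4 * jxy[sel]^2)
  w <- coher / (jxx[sel] + jyy[sel] + 1e-12)
  cw <- sum(w * cos(two)); sw <- sum(w * sin(two))
  alpha <- sqrt(cw^2 + sw^2) / max(sum(w), 1e-12)

  theta <- (atan2(sw, cw)) / 2                  # kept for reference
  ang <- ((two) / 2) %% pi
  br <- seq(0, pi, length.out = nBins + 1L)
  hcount <- tabulate(findInterval(ang, br, rightmost.closed = TRUE),
                     nbins = nBins)
  dens <- hcount / sum(hcount) / diff(br)[1L]
  list(alpha = alpha,
       histogram = data.frame(angle_rad = (br[-1L] + br[-length(br)]) / 2,
                              density = dens),
       n_pixels = sum(sel), mean_angle = theta)
}
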