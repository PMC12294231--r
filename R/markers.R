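#' @title Subcellular EMT-marker localization scoring
#' @name markers
NULL

#' Percentile-normalize a marker channel
#'
#' Linear rescale `(I - P1) / (P99 - P1)` using the channel's 1st and 99th
#' intensity percentiles, clipped below at 0 but deliberately not above 1 so
#' that junctions brighter than P99 keep their contrast. Constant images are
#' rejected.
#'
#' @param channel numeric array or [VoxelImage-class] (single channel).
#' @return normalized array (or [VoxelImage-class], matching the input).
#' @export
normalizePercentile <- function(channel) {
  wrap <- is(channel, "VoxelImage")
  a <- if (wrap) imgData(channel) else channel
  p <- quantile(a, c(0.01, 0.99), names = FALSE)
  if (p[2L] <= p[1L]) stop("constant image: P99 equals P1")
  out <- pmax((a - p[1L]) / (p[2L] - p[1L]), 0)
  if (wrap) VoxelImage(out, spacing(channel)) else out
}

#' Junction ROI between two nuclei
#'
#' The deterministic surrogate of a manually drawn junction line: the
#' straight 3D segment between two nucleus centroids, dilated to a band of
#' `bandWidth` micrometres, minus the nucleus interiors.
#'
#' @param nuclei a [LabelImage-class] of nucleus labels.
#' @param pair length-2 vector of nucleus labels to connect.
#' @param bandWidth band diameter in um (default 2).
#' @return logical array (the ROI mask) with attribute `endpoints` (the two
#'   centroids, um).
#' @export
junctionBand <- function(nuclei, pair, bandWidth = 2) {
  lab <- imgData(nuclei)
  sp <- spacing(nuclei)
  cent <- lapply(pair, function(i) {
    vox <- whichVoxels(lab == i)
    if (!nrow(vox)) stop("nucleus label ", i, " not found")
    colMeans(sweep(vox, 2L, sp, `*`))
  })
  a <- cent[[1L]]; b <- cent[[2L]]
  d <- dim(lab)
  vox <- whichVoxels(array(TRUE, d))
  pts <- sweep(vox, 2L, sp, `*`)
  ab <- b - a
  len2 <- sum(ab^2)
  tpar <- pmin(pmax(as.numeric(sweep(pts, 2L, a) %*% ab) / len2, 0), 1)
  closest <- outer(tpar, ab) + rep(a, each = nrow(pts))
  dist <- sqrt(rowSums((pts - closest)^2))
  roi <- array(dist <= bandWidth / 2, d)
  roi[lab > 0] <- FALSE
  attr(roi, "endpoints") <- rbind(a, b)
  roi
}

#' Junction-to-compartment intensity ratio of a marker
#'
#' Junctional intensity is the mean of ROI voxels at or above Otsu's
#' threshold (computed within the ROI); the ratio divides it by the mean
#' marker intensity over the reference compartment: cytoplasm for adherens
#' markers (CDH1), nuclei for CTNNB1. Channels should be percentile
#' normalized first. An empty supra-threshold junctional set yields ratio 0
#' with a warning flag.
#'
#' @param marker normalized marker array or [VoxelImage-class].
#' @param roi logical ROI mask from [junctionBand()].
#' @param reference `"cytoplasm"` or `"nuclei"`.
#' @param cytoplasm,nuclei logical masks (or label arrays) of the reference
#'   compartments; only the one named by `reference` is required.
#' @return numeric ratio with attributes `junctional_mean`,
#'   `reference_mean`, `flag` (`"ok"` or `"empty_junction"`).
#' @export
junctionRatio <- function(marker, roi, reference = c("cytoplasm", "nuclei"),
                          cytoplasm = NULL, nuclei = NULL) {
  reference <- match.arg(reference)
  a <- if (is(marker, "VoxelImage")) imgData(marker) else marker
  if (is(roi, "VoxelImage")) roi <- imgData(roi) > 0
  refMask <- if (reference == "cytoplasm") cytoplasm else nuclei
  if (is.null(refMask)) stop("reference compartment mask required")
  if (is(refMask, "VoxelImage")) refMask <- imgData(refMask)
  refMask <- refMask > 0
  if (!any(roi)) stop("empty ROI")
  vals <- a[roi]
  th <- otsuThreshold(vals)
  jun <- vals[vals >= th]
  flag <- "ok"
  if (!length(jun)) {
    jmean <- 0; flag <- "empty_junction"
    warning("no supra-threshold junctional voxels; ratio set to 0")
  } else jmean <- mean(jun)
  rmean <- mean(a[refMask])
  if (!is.finite(rmean) || rmean <= 0) stop("degenerate reference compartment")
  out <- jmean / rmean
  attr(out, "junctional_mean") <- jmean
  attr(out, "reference_mean") <- rmean
  attr(out, "flag") <- flag
  out
}

#' EMT phenotype call from CDH1 and VIM means
#'
#' `log10(CDH1 / VIM)` of the average junctional CDH1 over the average
#' cytoplasmic VIM: epithelial if > 0, mesenchymal if < 0, exactly 0 is
#' flagged indeterminate.
#'
#' @param cdh1JunctionalMean,vimCytoplasmicMean positive means.
#' @return list with `log_ratio` and `phenotype`
#'   (`"epithelial"`, `"mesenchymal"` or `"indeterminate"`).
#' @examples
#' emtPhenotypeCall(10, 1)  # log ratio 1, epithelial
#' @export
emtPhenotypeCall <- function(cdh1JunctionalMean, vimCytoplasmicMean) {
  if (vimCytoplasmicMean <= 0) stop("degenerate stain: VIM mean must be > 0")
  if (cdh1JunctionalMean <= 0) stop("CDH1 mean must be > 0")
  lr <- log10(cdh1JunctionalMean / vimCytoplasmicMean)
  phe <- if (lr > 0) "epithelial" else if (lr < 0) "mesenchymal"
         else "indeterminate"
  list(log_ratio = lr, phenotype = phe)
}

#' Score a multi-channel EMT marker stack
#'
#' Convenience wrapper running the full localization pipeline on a stack with
#' CDH1/VIM/CTNNB1 channels: percentile normalization, junction-band ROI
#' between a nucleus pair, junction/cytoplasm ratio for CDH1,
#' junction/nucleus ratio for CTNNB1, cytoplasmic VIM (mean above Otsu within
#' the cytoplasm) and the log CDH1/VIM phenotype call.
#'
#' @param image 4-channel [VoxelImage-class] with channels named CDH1, VIM,
#'   CTNNB1 (a DNA channel is ignored here).
#' @param nuclei nucleus [LabelImage-class].
#' @param cytoplasm logical/label cytoplasm mask.
#' @param pair nucleus labels to bridge (default the two smallest labels).
#' @param bandWidth junction band width in um.
#' @details The within-channel ratios use per-channel percentile
#'   normalization (the shared offset cancels in the ratio). The
#'   cross-channel CDH1/VIM comparison instead normalizes both channels with
#'   percentiles of their pooled intensities, so the two markers stay on one
#'   common scale and the log ratio reflects their true level difference.
#' @return data.frame with `cdh1_junction_cyto`, `ctnnb1_junction_nuclei`,
#'   `log_cdh1_vim`, `phenotype_call`, `flag`.
#' @export
scoreMarkerStack <- function(image, nuclei, cytoplasm, pair = NULL,
                             bandWidth = 2) {
  if (is.null(pair)) {
    labs <- setdiff(sort(unique(as.vector(imgData(nuclei)))), 0L)
    if (length(labs) < 2) stop("need two nuclei for a junction ROI")
    pair <- labs[1:2]
  }
  cdh1Raw <- imgData(getChannel(image, "CDH1"))
  vimRaw <- imgData(getChannel(image, "VIM"))
  cdh1 <- normalizePercentile(cdh1Raw)
  ctnnb1 <- normalizePercentile(imgData(getChannel(image, "CTNNB1")))
  if (is(cytoplasm, "VoxelImage")) cytoplasm <- imgData(cytoplasm)
  cyto <- cytoplasm > 0
  nucMask <- imgData(nuclei) > 0

  roi <- junctionBand(nuclei, pair, bandWidth = bandWidth)
  rc <- junctionRatio(cdh1, roi, "cytoplasm", cytoplasm = cyto)
  rn <- junctionRatio(ctnnb1, roi, "nuclei", nuclei = nucMask)

  # common scale for the cross-channel comparison
  p <- quantile(c(cdh1Raw, vimRaw), c(0.01, 0.99), names = FALSE)
  if (p[2L] <= p[1L]) stop("constant marker stack")
  cdh1C <- pmax((cdh1Raw - p[1L]) / (p[2L] - p[1L]), 0)
  vimC <- pmax((vimRaw - p[1L]) / (p[2L] - p[1L]), 0)
  jc <- cdh1C[roi]
  jth <- otsuThreshold(jc)
  cdh1Mean <- mean(jc[jc >= jth])
  vv <- vimC[cyto]
  vth <- otsuThreshold(vv)
  vimMean <- mean(vv[vv >= vth])
  call <- emtPhenotypeCall(max(cdh1Mean, 1e-12), max(vimMean, 1e-12))
  data.frame(cdh1_junction_cyto = as.numeric(rc),
             ctnnb1_junction_nuclei = as.numeric(rn),
             log_cdh1_vim = call$log_ratio,
             phenotype_call = call$phenotype,
             flag = attr(rc, "flag"))
}
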