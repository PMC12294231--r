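#' @title Scalar assay formulas
#' @description The study-wide scalar metrics: relative qPCR expression by
#'   the 2^-ddCt method, Z-score matrices with hierarchical heat-map
#'   ordering, the tumor growth inhibition index, spare respiratory /
#'   glycolytic capacity, the loss/storage modulus ratio and
#'   inoculum-normalized tumor volume.
#' @name derived_metrics
NULL

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_gene - Ct_housekeeping)_organoid -
#' (Ct_gene - Ct_housekeeping)_reference`; the fold change is `2^-ddCt`.
#'
#' @param ctGene,ctHousekeeping Ct values (cycles) in the condition of
#'   interest (e.g. 3D organoids).
#' @param ctGeneRef,ctHousekeepingRef Ct values in the reference condition
#'   (e.g. 2D-plated cells).
#' @return fold change (dimensionless, > 0); vectorized over genes.
#' @examples
#' foldChangeDDCT(24, 18, 25, 18)  # ddCt = -1 -> fold change 2
#' @export
foldChangeDDCT <- function(ctGene, ctHousekeeping, ctGeneRef,
                           ctHousekeepingRef) {
  ddct <- (ctGene - ctHousekeeping) - (ctGeneRef - ctHousekeepingRef)
  2^(-ddct)
}

#' Z-score matrix with hierarchical heat-map ordering
#'
#' Each row (gene) is centered and scaled to `Z = (x - mean) / sd`, with the
#' population standard deviation (no Bessel correction) matching the printed
#' formula; set `ddof = 1` for the sample sd. Row and column orders from
#' average-linkage hierarchical clustering on Euclidean distances are
#' returned for heat-map rendering.
#'
#' @param values numeric matrix, genes in rows.
#' @param ddof 0 (population sd, default) or 1 (sample sd).
#' @return list with `z` (matrix), `row_order`, `col_order`.
#' @export
zscoreMatrix <- function(values, ddof = 0) {
  values <- as.matrix(values)
  mu <- rowMeans(values)
  n <- ncol(values)
  ss <- rowSums((values - mu)^2)
  sdv <- sqrt(ss / (n - ddof))
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad))
    stop("zero-variance row(s): ",
         paste(if (is.null(rownames(values))) bad else rownames(values)[bad],
               collapse = ", "))
  z <- (values - mu) / sdv
  ro <- if (nrow(z) > 2) hclust(dist(z), method = "average")$order
        else seq_len(nrow(z))
  co <- if (ncol(z) > 2) hclust(dist(t(z)), method = "average")$order
        else seq_len(ncol(z))
  list(z = z, row_order = ro, col_order = co)
}

#' Tumor growth inhibition index
#'
#' `TGI = (Vf - Vi) / Vi`; positive values indicate growth, negative values
#' regression (reported in the `flag` attribute).
#'
#' @param vInitial,vFinal tumor volumes (mm^3) at enrollment and endpoint.
#' @return numeric TGI with attribute `flag` (`"growth"`, `"regression"` or
#'   `"stable"`).
#' @examples
#' tgi(50, 100)  # doubling: TGI = 1
#' @export
tgi <- function(vInitial, vFinal) {
  if (any(vInitial <= 0)) stop("initial volume must be > 0")
  out <- (vFinal - vInitial) / vInitial
  attr(out, "flag") <- ifelse(out > 0, "growth",
                              ifelse(out < 0, "regression", "stable"))
  out
}

#' Loss/storage modulus ratio (Tan-delta)
#'
#' `tan delta = G'' / G'`: near 0 for a predominantly elastic (solid-like)
#' hydrogel, larger when the viscous component contributes.
#'
#' @param gPrime storage modulus G' (Pa, > 0).
#' @param gDoublePrime loss modulus G'' (Pa, >= 0).
#' @return dimensionless ratio.
#' @export
tanDelta <- function(gPrime, gDoublePrime) {
  if (any(gPrime <= 0)) stop("storage modulus G' must be > 0")
  if (any(gDoublePrime < 0)) stop("loss modulus G'' must be >= 0")
  gDoublePrime / gPrime
}

#' Spare respiratory / glycolytic capacity
#'
#' The difference between the maximal and basal rate (OCR in pmol/min for
#' SRC, ECAR in mpH/min for GC).
#'
#' @param basal,maximal rates in matching units; `maximal >= basal`.
#' @return numeric difference.
#' @export
metabolicCapacity <- function(basal, maximal) {
  if (any(maximal < basal)) stop("maximal rate below basal rate")
  maximal - basal
}

#' Tumor volume normalized to the inoculated organoid mass
#'
#' @param volume tumor volume (mm^3).
#' @param inoculumUg inoculated organoid mass (ug, > 0).
#' @return mm^3 per ug.
#' @export
normalizedTumorVolume <- function(volume, inoculumUg) {
  if (any(inoculumUg <= 0)) stop("inoculum mass must be > 0")
  volume / inoculumUg
}
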