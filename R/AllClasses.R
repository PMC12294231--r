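#' @import methods
NULL

#' VoxelImage: a 3D (optionally multi-channel) voxel grid with physical spacing
#'
#' The substrate of all image operations in the package. Voxel data are stored
#' axis-ordered `(z, y, x)` (first index varies fastest along z) with per-axis
#' physical spacing in micrometres. Multi-channel stacks carry the channel as a
#' fourth dimension with channel names in `channelNames()`.
#'
#' @slot data numeric, logical or integer array of dim `(z, y, x)` or
#'   `(z, y, x, channel)`.
#' @slot spacing numeric length-3, micrometres per voxel along `(z, y, x)`.
#' @slot channels character vector of channel names (empty for single-channel).
#'
#' @seealso [LabelImage-class] for integer-labeled volumes.
#' @export
setClass("VoxelImage",
  representation(data = "array", spacing = "numeric", channels = "character"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            channels = character(0))
)

setValidity("VoxelImage", function(object) {
  d <- dim(object@data)
  if (!(length(d) %in% c(3L, 4L)))
    return("data must be a 3D (z,y,x) or 4D (z,y,x,channel) array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (z,y,x um)")
  if (length(d) == 4L && length(object@channels) != d[4L])
    return("channels must name every channel of a 4D stack")
  if (length(d) == 3L && length(object@channels) > 1L)
    return("a 3D array can carry at most one channel name")
  TRUE
})

#' LabelImage: integer-labeled 3D volume
#'
#' A [VoxelImage-class] whose voxels carry non-negative integer object labels
#' (0 = background). Used for organoid and nucleus segmentations.
#'
#' @export
setClass("LabelImage", contains = "VoxelImage")

setValidity("LabelImage", function(object) {
  if (length(dim(object@data)) != 3L)
    return("label images are single-channel 3D volumes")
  v <- object@data
  if (!(is.integer(v) || is.logical(v) ||
        (is.numeric(v) && all(v == floor(v)) && all(v >= 0))))
    return("labels must be non-negative integers")
  TRUE
})

#' OrganoidClassifier: fitted SVM phenotype model
#'
#' Wraps an RBF-kernel support vector machine together with the per-feature
#' standardization parameters fitted on its training data, the ordered feature
#' list it consumes, and the admissible class set. Standardization is always
#' refit on training data only; prediction refuses classes absent from the
#' model's class set.
#'
#' @slot model the underlying [e1071::svm()] fit.
#' @slot features ordered character vector of descriptor names used.
#' @slot center,scale named numeric vectors: training-set feature means / sds.
#' @slot classes character vector of admissible phenotype labels.
#' @slot cost,gamma numeric: SVM regularization C and RBF kernel width.
#' @slot seed integer seed recorded at training time.
#' @export
setClass("OrganoidClassifier",
  representation(model = "ANY", features = "character", center = "numeric",
                 scale = "numeric", classes = "character", cost = "numeric",
                 gamma = "numeric", seed = "integer"))

#' DoseResponseFit: four-parameter-logistic dose-response fit
#'
#' Parameters of the 4PL model
#' `viability = bottom + (top - bottom) / (1 + (dose/ig50)^hill)` fitted on a
#' log10 dose axis, together with the RMS residual and quality flags.
#'
#' @slot ig50 numeric, micromolar dose at half-maximal inhibition.
#' @slot hill numeric slope.
#' @slot top,bottom numeric viability plateaus (percent).
#' @slot residual numeric RMS residual of the fit.
#' @slot flags character vector of quality flags (e.g. "high_residual").
#' @slot data data.frame with columns dose_uM, viability_pct used for the fit.
#' @export
setClass("DoseResponseFit",
  representation(ig50 = "numeric", hill = "numeric", top = "numeric",
                 bottom = "numeric", residual = "numeric", flags = "character",
                 data = "data.frame"))
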