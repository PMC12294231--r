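#' Physical voxel spacing in micrometres
#'
#' @param x a [VoxelImage-class] or [LabelImage-class].
#' @return numeric length-3 `(z, y, x)` spacing in micrometres.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @param value numeric length-3 replacement spacing.
#' @export
setGeneric("spacing<-", function(x, value) standardGeneric("spacing<-"))

#' Raw voxel array of an image
#'
#' @param x a [VoxelImage-class].
#' @return the underlying array, dim `(z, y, x[, channel])`.
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' Number of channels of an image
#' @param x a [VoxelImage-class].
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Channel names of a multi-channel image
#' @param x a [VoxelImage-class].
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Extract one channel as a single-channel image
#' @param x a [VoxelImage-class].
#' @param channel channel name or index.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))
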