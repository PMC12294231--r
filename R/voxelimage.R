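#' Construct a VoxelImage
#'
#' @param data array of dim `(z, y, x)` or `(z, y, x, channel)`.
#' @param spacing numeric length-3, micrometres per voxel along `(z, y, x)`;
#'   a scalar is recycled (isotropic grid).
#' @param channels optional channel names for a 4D stack.
#' @return a [VoxelImage-class].
#' @examples
#' vi <- VoxelImage(array(0, c(4, 32, 32)), spacing = 1)
#' spacing(vi)
#' @export
VoxelImage <- function(data, spacing = c(1, 1, 1), channels = character(0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(dim(data)) == 4L && length(channels) == 0L)
    channels <- paste0("ch", seq_len(dim(data)[4L]))
  new("VoxelImage", data = data, spacing = as.numeric(spacing),
      channels = as.character(channels))
}

#' Construct a LabelImage
#'
#' @param data integer (or logical) array of dim `(z, y, x)`; 0 = background.
#' @param spacing per-axis spacing in micrometres (scalar recycled).
#' @return a [LabelImage-class].
#' @export
LabelImage <- function(data, spacing = c(1, 1, 1)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "integer"
  new("LabelImage", data = data, spacing = as.numeric(spacing),
      channels = character(0))
}

#' @rdname spacing
setMethod("spacing", "VoxelImage", function(x) x@spacing)

#' @rdname spacing
setReplaceMethod("spacing", "VoxelImage", function(x, value) {
  if (length(value) == 1L) value <- rep(value, 3L)
  x@spacing <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname imgData
setMethod("imgData", "VoxelImage", function(x) x@data)

#' @rdname nChannels
setMethod("nChannels", "VoxelImage", function(x) {
  d <- dim(x@data)
  if (length(d) == 4L) d[4L] else 1L
})

#' @rdname channelNames
setMethod("channelNames", "VoxelImage", function(x) x@channels)

#' @rdname getChannel
setMethod("getChannel", "VoxelImage", function(x, channel) {
  d <- dim(x@data)
  if (length(d) == 3L) {
    if (!identical(channel, 1L) && !identical(channel, 1) &&
        !(is.character(channel) && length(x@channels) &&
          channel == x@channels[1L]))
      stop("single-channel image; channel must be 1", call. = FALSE)
    return(VoxelImage(x@data, x@spacing))
  }
  if (is.character(channel)) {
    channel <- match(channel, x@channels)
    if (is.na(channel)) stop("unknown channel name", call. = FALSE)
  }
  a <- x@data[, , , channel, drop = FALSE]
  dim(a) <- d[1:3]
  VoxelImage(a, x@spacing)
})

setMethod("dim", "VoxelImage", function(x) dim(x@data))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object@data)
  cat(class(object), ": ", paste(d[1:3], collapse = " x "),
      " voxels (z,y,x)", sep = "")
  if (length(d) == 4L)
    cat(", ", d[4L], " channel(s) [", paste(object@channels, collapse = ", "),
        "]", sep = "")
  cat("\n  spacing: ", paste(signif(object@spacing, 4), collapse = " x "),
      " um\n", sep = "")
  if (is(object, "LabelImage")) {
    labs <- setdiff(unique(as.vector(object@data)), 0L)
    cat("  labels: ", length(labs), " object(s)\n", sep = "")
  }
  invisible(NULL)
})

#' Maximum-intensity projection along the z axis
#'
#' Collapses a 3D volume (or one channel of a stack) to the 2D axial
#' projection used for 2D descriptors, protrusion analysis and fiber
#' orientation mapping.
#'
#' @param x a [VoxelImage-class] (single channel) or 3D array.
#' @return a 2D matrix `(y, x)`.
#' @export
maxProject <- function(x) {
  a <- if (is(x, "VoxelImage")) imgData(x) else x
  if (length(dim(a)) != 3L) stop("maxProject expects a single-channel volume")
  apply(a, c(2L, 3L), max)
}

#' Write / read voxel images as multi-page TIFF
#'
#' Images are written one z-plane per page (channel-major for stacks:
#' all planes of channel 1, then channel 2, ...), as 32-bit float TIFF.
#' Physical spacing and channel names ride in a JSON sidecar
#' (`<file>.json`), since baseline TIFF has no standard 3-axis spacing tag.
#'
#' @param x a [VoxelImage-class] or [LabelImage-class].
#' @param path output TIFF path.
#' @return `writeVoxelImage` returns `path` invisibly; `readVoxelImage`
#'   returns a [VoxelImage-class] (or [LabelImage-class] if the sidecar marks
#'   integer labels).
#' @export
writeVoxelImage <- function(x, path) {
  stopifnot(is(x, "VoxelImage"))
  a <- imgData(x)
  d <- dim(a)
  nc <- if (length(d) == 4L) d[4L] else 1L
  mx <- max(abs(a), 1e-12)
  pages <- list()
  for (ch in seq_len(nc)) {
    vol <- if (nc > 1L || length(d) == 4L) a[, , , ch, drop = TRUE] else a
    for (z in seq_len(d[1L]))
      pages[[length(pages) + 1L]] <- matrix(as.numeric(vol[z, , ]) / mx,
                                            d[2L], d[3L])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(spacing_um = spacing(x), dim = d,
               channels = channelNames(x),
               scale = mx,
               labels = is(x, "LabelImage"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVoxelImage
#' @export
readVoxelImage <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  nc <- if (length(d) == 4L) d[4L] else 1L
  a <- array(0, d)
  k <- 1L
  for (ch in seq_len(nc)) for (z in seq_len(d[1L])) {
    if (length(d) == 4L) a[z, , , ch] <- pages[[k]] * meta$scale
    else a[z, , ] <- pages[[k]] * meta$scale
    k <- k + 1L
  }
  if (isTRUE(meta$labels))
    LabelImage(round(a), spacing = meta$spacing_um)
  else
    VoxelImage(a, spacing = meta$spacing_um,
               channels = as.character(meta$channels))
}
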