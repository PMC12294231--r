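#' @title Early-organoid-seed motility and protrusion analysis
#' @name motility
NULL

#' Per-track motility statistics
#'
#' Mean speed `v = (1/N) * sum_i ||p_i - p_(i-1)|| / (t_i - t_(i-1))` over the
#' N displacement segments of a track, and the directness index: Euclidean
#' distance between start and end divided by the accumulated path length
#' (1 = straight-line migration, 0 = indirect migration). Gaps in a track are
#' treated as single longer steps between consecutive recorded points.
#'
#' @param tracks data.frame with columns `track_id`, `t_h`, `x_um`, `y_um`,
#'   `z_um` (a single track may omit `track_id`).
#' @return data.frame, one row per track: `track_id`, `mean_speed_um_h`,
#'   `directness`, `euclidean_um`, `accumulated_um`, `n_steps`.
#' @examples
#' tr <- data.frame(t_h = 0:1, x_um = c(0, 3), y_um = c(0, 4), z_um = 0)
#' trackStats(tr)  # 3-4-5 triangle: speed 5 um/h, directness 1
#' @export
trackStats <- function(tracks) {
  if (is.null(tracks$track_id)) tracks$track_id <- 1L
  need <- c("t_h", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tracks)))
    stop("tracks need columns t_h, x_um, y_um, z_um")
  res <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$t_h), , drop = FALSE]
    if (nrow(tr) < 2L)
      stop("track ", tr$track_id[1L], ": need >= 2 points")
    dt <- diff(tr$t_h)
    if (any(dt <= 0))
      stop("track ", tr$track_id[1L], ": duplicate or non-increasing times")
    seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    accum <- sum(seg)
    eucl <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1L])^2 +
                 (tr$y_um[nrow(tr)] - tr$y_um[1L])^2 +
                 (tr$z_um[nrow(tr)] - tr$z_um[1L])^2)
    data.frame(track_id = tr$track_id[1L],
               mean_speed_um_h = mean(seg / dt),
               directness = if (accum > 0) eucl / accum else 0,
               euclidean_um = eucl, accumulated_um = accum,
               n_steps = length(seg))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read / write track tables as CSV
#'
#' Columns: `track_id`, `t_h`, `x_um`, `y_um`, `z_um`.
#' @param path CSV path.
#' @param tracks track data.frame.
#' @export
readTracks <- function(path) {
  tr <- read.csv(path)
  need <- c("track_id", "t_h", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tr)))
    stop("track CSV must have columns ", paste(need, collapse = ", "))
  tr
}

#' @rdname readTracks
#' @export
writeTracks <- function(tracks, path) {
  write.csv(tracks[, c("track_id", "t_h", "x_um", "y_um", "z_um")], path,
            row.names = FALSE)
  invisible(path)
}

#' Import tracks from TrackMate-dialect XML
#'
#' Maps spots to `(t, x, y, z)` in physical units using the spot features
#' POSITION_T/X/Y/Z (T converted from the file's unit to hours via
#' `tUnitHours`), following track edges (SPOT_SOURCE_ID/SPOT_TARGET_ID).
#'
#' @param path XML file path.
#' @param tUnitHours hours per time unit in the file (default 1).
#' @return track data.frame as in [readTracks()].
#' @export
readTrackMate <- function(path, tUnitHours = 1) {
  doc <- xml2::read_xml(path)
  spots <- xml2::xml_find_all(doc, ".//Spot")
  sid <- xml2::xml_attr(spots, "ID")
  sx <- as.numeric(xml2::xml_attr(spots, "POSITION_X"))
  sy <- as.numeric(xml2::xml_attr(spots, "POSITION_Y"))
  sz <- as.numeric(xml2::xml_attr(spots, "POSITION_Z"))
  st <- as.numeric(xml2::xml_attr(spots, "POSITION_T"))
  lut <- data.frame(id = sid, x = sx, y = sy, z = sz, t = st)
  tracks <- xml2::xml_find_all(doc, ".//Track")
  res <- list()
  for (k in seq_along(tracks)) {
    edges <- xml2::xml_find_all(tracks[[k]], ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    sub <- lut[match(ids, lut$id), , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    tid <- xml2::xml_attr(tracks[[k]], "TRACK_ID")
    if (is.na(tid)) tid <- as.character(k)
    res[[k]] <- data.frame(track_id = tid, t_h = sub$t * tUnitHours,
                           x_um = sub$x, y_um = sub$y, z_um = sub$z)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract cell protrusions from a seed image or mask
#'
#' For an intensity input the frame is maximum-intensity projected, filtered
#' with a Laplacian of Gaussian, thresholded (Otsu on the blob response) and
#' hole-filled; a precomputed binary mask bypasses segmentation. Binary
#' morphological opening with a disc of `openingRadius` removes the
#' protrusions; the exclusive-or of mask and opened body is the protrusion
#' mask. Components smaller than `minSize` pixels are discarded; each
#' retained component's length is its geodesic diameter times the pixel size.
#'
#' @param x 2D/3D intensity array, [VoxelImage-class], or 2D logical mask.
#' @param sigmaLog LoG sigma in pixels (intensity input only).
#' @param openingRadius opening disc radius in pixels; must exceed the
#'   expected protrusion half-width.
#' @param minSize minimum protrusion area in pixels.
#' @param pixelSize physical pixel size in um (for lengths).
#' @return list with `count`, `lengths_um`, `body_mask`, `protrusion_mask`.
#' @export
extractProtrusions <- function(x, sigmaLog = 2, openingRadius = 8,
                               minSize = 20, pixelSize = 1) {
  if (is(x, "VoxelImage")) x <- imgData(x)
  if (is.logical(x) && length(dim(x)) == 2L) {
    mask <- x
  } else {
    mip <- if (length(dim(x)) == 3L) apply(x, c(2L, 3L), max) else x
    # blob response: negated LoG (bright blobs on dark background)
    sm <- EBImage::gblur(mip, sigma = sigmaLog)
    lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
    resp <- -EBImage::filter2(sm, lap)
    resp <- resp - min(resp)
    th <- otsuThreshold(as.vector(resp))
    mask <- EBImage::fillHull(resp > th) > 0
  }
  if (!any(mask))
    return(list(count = 0L, lengths_um = numeric(0),
                body_mask = mask, protrusion_mask = mask & FALSE))
  kern <- EBImage::makeBrush(2L * as.integer(openingRadius) + 1L, "disc")
  body <- EBImage::opening(mask * 1, kern) > 0
  prot <- xor(mask, body) & mask               # mask XOR body, inside mask
  lab <- EBImage::bwlabel(prot * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  lengths <- vapply(keep, function(k) {
    m3 <- array(lab == k, c(1L, dim(lab)))
    .geodesic_diameter3d(m3, dim(m3), c(1, 1, 1)) * pixelSize
  }, numeric(1))
  protKeep <- array(lab %in% keep, dim(lab))
  list(count = length(keep), lengths_um = as.numeric(lengths),
       body_mask = body, protrusion_mask = protKeep)
}
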