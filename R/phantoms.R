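#' @title Synthetic phantoms with analytic ground truth
#' @description Generators emulating the study's data modalities: organoid
#'   bodies of the three phenotype classes, fibrous collagen lattices,
#'   early-organoid-seed migration tracks, compartmentalized EMT marker
#'   stacks, live/dead object fields and four-parameter-logistic
#'   dose-response tables. Every generator is seed-deterministic and returns
#'   machine-readable ground truth next to its data.
#' @name phantoms
NULL

# voxel offsets (z,y,x) whose physical norm is <= radius
ballOffsets <- function(radius, spacing) {
  rv <- pmax(0L, floor(radius / spacing))
  g <- expand.grid(dz = -rv[1L]:rv[1L], dy = -rv[2L]:rv[2L], dx = -rv[3L]:rv[3L])
  d2 <- (g$dz * spacing[1L])^2 + (g$dy * spacing[2L])^2 + (g$dx * spacing[3L])^2
  as.matrix(g[d2 <= radius^2, , drop = FALSE])
}

# stamp spheres of precomputed offsets at integer voxel centers (n x 3, z,y,x)
stampBalls <- function(mask, centers, offsets) {
  d <- dim(mask)
  for (k in seq_len(nrow(offsets))) {
    z <- centers[, 1L] + offsets[k, 1L]
    y <- centers[, 2L] + offsets[k, 2L]
    x <- centers[, 3L] + offsets[k, 3L]
    ok <- z >= 1L & z <= d[1L] & y >= 1L & y <= d[2L] & x >= 1L & x <= d[3L]
    if (any(ok)) mask[cbind(z[ok], y[ok], x[ok])] <- TRUE
  }
  mask
}

# physical coordinate arrays centered on the grid midpoint
coordGrids <- function(dim, spacing) {
  cz <- (seq_len(dim[1L]) - (dim[1L] + 1) / 2) * spacing[1L]
  cy <- (seq_len(dim[2L]) - (dim[2L] + 1) / 2) * spacing[2L]
  cx <- (seq_len(dim[3L]) - (dim[3L] + 1) / 2) * spacing[3L]
  list(z = array(cz, dim), y = array(rep(cy, each = dim[1L]), dim),
       x = array(rep(cx, each = dim[1L] * dim[2L]), dim))
}

# minimum-separation random unit vectors (spike axes), dart throwing; the
# separation constraint is relaxed geometrically when the sphere cannot
# accommodate n cones at the requested angle
spikeDirections <- function(n, minAngle, maxTries = 2000L) {
  ang <- minAngle
  repeat {
    dirs <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(dirs) < n && tries < maxTries) {
      tries <- tries + 1L
      v <- rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (nrow(dirs) == 0L || all(acos(pmin(1, dirs %*% v)) > ang))
        dirs <- rbind(dirs, v)
    }
    if (nrow(dirs) == n) return(dirs)
    if (ang < 0.05)
      stop("could not place ", n, " spike directions")
    ang <- ang * 0.8
  }
}

#' Simulate a single organoid phantom
#'
#' Voxelizes one of the three phenotype classes observed in hydrogel-grown
#' organoids: a cystic shell enclosing a lumen, a solid (optionally
#' anisotropically stretched) ellipsoid, or an invasive body carrying conical
#' protrusion-like spikes with random outward orientation. Nuclei are seeded
#' on/in the body by non-overlapping dart throwing.
#'
#' @param shapeClass one of `"cyst"`, `"solid"`, `"invasive"`.
#' @param outerRadius body radius in micrometres (> 0).
#' @param shellThickness cyst shell thickness in micrometres
#'   (< `outerRadius`).
#' @param nSpikes number of invasive spikes (>= 1 for `"invasive"`).
#' @param spikeLength,spikeBaseRadius spike cone length / base radius (um).
#' @param stretch length-3 axis scale factors `(z, y, x)` (dimensionless).
#' @param spacing voxel spacing in micrometres (scalar or length 3).
#' @param extent optional physical image extent in um (scalar or length 3);
#'   defaults to a cube of side `3 * outerRadius` enlarged to fit spikes.
#'   An extent too small to contain the body is an error.
#' @param nucleusRadius,nNuclei nucleus phantom radius (um) and count.
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return list with `labels` ([LabelImage-class], organoid mask labeled 1),
#'   `nuclei` ([LabelImage-class]) and `truth` (one-row data.frame with
#'   analytic volume, lumen radius and spike count).
#' @examples
#' ph <- simulateOrganoid("cyst", outerRadius = 20, shellThickness = 5,
#'                        spacing = 2, seed = 1)
#' ph$truth
#' @export
simulateOrganoid <- function(shapeClass = c("cyst", "solid", "invasive"),
                             outerRadius = 30, shellThickness = 8,
                             nSpikes = 6, spikeLength = 15,
                             spikeBaseRadius = 4, stretch = c(1, 1, 1),
                             spacing = 1, extent = NULL,
                             nucleusRadius = 3, nNuclei = 20, seed = 1) {
  shapeClass <- match.arg(shapeClass)
  if (outerRadius <= 0) stop("outerRadius must be > 0")
  if (shapeClass == "cyst" && shellThickness >= outerRadius)
    stop("shellThickness must be < outerRadius for a cyst")
  if (shapeClass == "invasive" && nSpikes < 1)
    stop("invasive phantoms need nSpikes >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(stretch) == 1L) stretch <- rep(stretch, 3L)
  set.seed(seed)

  reach <- outerRadius * max(stretch) +
    if (shapeClass == "invasive") spikeLength else 0
  need <- 2 * reach + 4 * max(spacing)
  if (is.null(extent)) extent <- max(3 * outerRadius, need)
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  if (any(extent < need))
    stop("image extent too small to contain the body (need >= ",
         signif(need, 4), " um)")
  dm <- pmax(8L, as.integer(ceiling(extent / spacing)))
  g <- coordGrids(dm, spacing)
  uz <- g$z / stretch[1L]; uy <- g$y / stretch[2L]; ux <- g$x / stretch[3L]
  rho <- sqrt(uz^2 + uy^2 + ux^2)

  lumenR <- 0
  if (shapeClass == "cyst") {
    body <- rho <= outerRadius & rho > (outerRadius - shellThickness)
    lumenR <- outerRadius - shellThickness
    volume <- 4 / 3 * pi * (outerRadius^3 - lumenR^3) * prod(stretch)
  } else {
    body <- rho <= outerRadius
    volume <- 4 / 3 * pi * outerRadius^3 * prod(stretch)
  }

  if (shapeClass == "invasive") {
    minAng <- 2 * atan(spikeBaseRadius / outerRadius) + 0.35
    dirs <- spikeDirections(nSpikes, minAng)
    # work in the stretched frame so spikes sit on the actual surface
    for (k in seq_len(nSpikes)) {
      dk <- dirs[k, ]
      s <- uz * dk[1L] + uy * dk[2L] + ux * dk[3L]   # along-axis coordinate
      perp2 <- pmax(0, uz^2 + uy^2 + ux^2 - s^2)
      frac <- (s - outerRadius) / spikeLength
      w <- spikeBaseRadius * (1 - frac)
      inSpike <- s > outerRadius - spacing[1L] & frac <= 1 & perp2 <= w^2
      body <- body | inSpike
    }
    volume <- volume + nSpikes * pi / 3 * spikeBaseRadius^2 * spikeLength
  }

  # nuclei: dart-thrown non-overlapping balls on/in the body
  nucMask <- array(FALSE, dm)
  nucLab <- array(0L, dm)
  bodyIdx <- whichVoxels(body)
  if (shapeClass == "cyst") {
    shellMid <- abs(rho[body] - (outerRadius - shellThickness / 2)) <
      shellThickness / 2
    candidates <- bodyIdx[shellMid, , drop = FALSE]
  } else {
    deep <- rho[body] <= max(outerRadius - nucleusRadius, outerRadius * 0.5)
    candidates <- bodyIdx[deep, , drop = FALSE]
  }
  if (nrow(candidates) > 0 && nNuclei > 0) {
    offs <- ballOffsets(nucleusRadius, spacing)
    centers <- matrix(0L, 0, 3)
    tries <- 0L
    while (nrow(centers) < nNuclei && tries < 200L * nNuclei) {
      tries <- tries + 1L
      cand <- candidates[sample.int(nrow(candidates), 1L), ]
      if (nrow(centers) > 0) {
        dd <- sweep(centers, 2L, cand)
        phys <- sweep(dd, 2L, spacing, `*`)
        if (min(rowSums(phys^2)) < (2 * nucleusRadius)^2) next
      }
      centers <- rbind(centers, cand)
      one <- array(FALSE, dm)
      one <- stampBalls(one, matrix(cand, 1), offs)
      nucLab[one] <- nrow(centers)
      nucMask <- nucMask | one
    }
  }

  truth <- data.frame(
    shape_class = shapeClass,
    volume_um3 = volume,
    lumen_radius_um = lumenR,
    n_spikes = if (shapeClass == "invasive") nSpikes else 0L,
    outer_radius_um = outerRadius,
    seed = seed
  )
  list(labels = LabelImage(array(as.integer(body), dm), spacing),
       nuclei = LabelImage(nucLab, spacing),
       truth = truth)
}

#' Simulate a descriptor panel of phantom organoids
#'
#' Renders `nPerClass` phantoms of each phenotype class with parameters drawn
#' from class-specific ranges, computes their 3D descriptors and returns the
#' labeled descriptor table used for classifier training and validation.
#' Cystic phantoms are drawn larger than solid/invasive ones, mirroring the
#' size ordering seen in hydrogel cultures.
#'
#' @param nPerClass phantoms per class.
#' @param spacing rendering spacing in micrometres (isotropic).
#' @param seed integer seed.
#' @return list with `descriptors` (data.frame of morphometric features),
#'   `classes` (factor) and `truth` (per-phantom generator parameters).
#' @export
simulatePhenotypePanel <- function(nPerClass = 100, spacing = 2, seed = 1) {
  set.seed(seed)
  classes <- rep(c("cyst", "solid", "invasive"), each = nPerClass)
  seeds <- sample.int(.Machine$integer.max %/% 2L, length(classes))
  rows <- vector("list", length(classes))
  truth <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    set.seed(seeds[i])
    if (cl == "cyst") {
      ph <- simulateOrganoid("cyst",
        outerRadius = runif(1, 24, 40), shellThickness = runif(1, 5, 10),
        stretch = c(1, 1, 1), spacing = spacing, nNuclei = 0,
        seed = seeds[i])
    } else if (cl == "solid") {
      ph <- simulateOrganoid("solid",
        outerRadius = runif(1, 14, 26),
        stretch = runif(3, 0.85, 1.2), spacing = spacing, nNuclei = 0,
        seed = seeds[i])
    } else {
      ph <- simulateOrganoid("invasive",
        outerRadius = runif(1, 14, 24), nSpikes = sample(4:9, 1),
        spikeLength = runif(1, 10, 18), spikeBaseRadius = runif(1, 3.5, 5),
        stretch = runif(3, 0.9, 1.15), spacing = spacing, nNuclei = 0,
        seed = seeds[i])
    }
    rows[[i]] <- computeDescriptors(ph$labels)
    truth[[i]] <- ph$truth
  }
  desc <- do.call(rbind, rows)
  desc$label <- NULL
  list(descriptors = desc, classes = factor(classes),
       truth = do.call(rbind, truth))
}

#' Simulate a fibrous collagen-like lattice
#'
#' Draws straight fiber segments of fixed radius whose in-plane orientations
#' follow a von Mises law on the doubled angle (the standard axial-orientation
#' model: `orientationKappa = 0` is isotropic, `Inf` a single orientation),
#' until the fiber voxel fraction reaches `targetDensity`. With
#' `densificationFactor > 1` additional fibers are seeded inside a band
#' around `organoidMask` until the band density reaches that multiple of the
#' pre-densification density, emulating peri-organoid matrix compaction.
#'
#' @param targetDensity fiber voxel fraction in (0, 0.5).
#' @param orientationKappa von Mises concentration (>= 0, may be `Inf`).
#' @param mu mean fiber orientation (radians, in-plane).
#' @param fiberRadius,fiberLength fiber radius / segment length in um.
#' @param dim grid size in voxels `(z, y, x)`.
#' @param spacing voxel spacing in um (scalar or length 3).
#' @param densificationFactor at least 1; requires `organoidMask` when
#'   above 1.
#' @param organoidMask optional [LabelImage-class] (or logical array) of the
#'   organoid body, on the same grid.
#' @param bandWidth densification band width around the organoid (um).
#' @param intensity if TRUE also return a noisy SHG-like intensity volume.
#' @param seed integer seed.
#' @return list with `mask` ([VoxelImage-class], logical), optionally
#'   `intensity`, and `truth` (realized density, kappa, densification factor).
#' @export
simulateFiberField <- function(targetDensity = 0.10, orientationKappa = 0,
                               mu = 0, fiberRadius = 0.75, fiberLength = 10,
                               dim = c(4, 1024, 1024), spacing = 1,
                               densificationFactor = 1, organoidMask = NULL,
                               bandWidth = 7, intensity = FALSE, seed = 1) {
  if (targetDensity <= 0 || targetDensity >= 0.5)
    stop("targetDensity must lie in (0, 0.5)")
  if (orientationKappa < 0) stop("orientationKappa must be >= 0")
  if (densificationFactor < 1) stop("densificationFactor must be >= 1")
  if (densificationFactor > 1 && is.null(organoidMask))
    stop("densificationFactor > 1 requires an organoidMask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dm <- as.integer(dim)
  set.seed(seed)

  org <- NULL
  if (!is.null(organoidMask)) {
    org <- if (is(organoidMask, "VoxelImage")) imgData(organoidMask) > 0
           else organoidMask > 0
    if (!identical(base::dim(org), dm)) stop("organoidMask grid mismatch")
  }

  offs <- ballOffsets(fiberRadius, spacing)
  step <- 0.5 * min(spacing)
  nsamp <- max(2L, ceiling(fiberLength / step) + 1L)
  tvals <- seq(-fiberLength / 2, fiberLength / 2, length.out = nsamp)

  drawAngle <- function(n) {
    if (is.infinite(orientationKappa)) rep(mu, n)
    else rvonmises(n, 2 * mu, orientationKappa) / 2
  }
  sampleFiberVoxels <- function(n, inBand = FALSE) {
    # voxel centers covered by n random fibers (possibly restricted to band)
    if (inBand) {
      cand <- whichVoxels(bandMask)
      ctr <- cand[sample.int(nrow(cand), n, replace = TRUE), , drop = FALSE]
      cz <- ctr[, 1L] * spacing[1L]; cy <- ctr[, 2L] * spacing[2L]
      cx <- ctr[, 3L] * spacing[3L]
    } else {
      cz <- runif(n, 0, dm[1L] * spacing[1L])
      cy <- runif(n, 0, dm[2L] * spacing[2L])
      cx <- runif(n, 0, dm[3L] * spacing[3L])
    }
    th <- drawAngle(n)
    dy <- sin(th); dx <- cos(th)
    pz <- rep(cz, each = nsamp)
    py <- rep(cy, each = nsamp) + rep(dy, each = nsamp) * tvals
    px <- rep(cx, each = nsamp) + rep(dx, each = nsamp) * tvals
    cbind(pmax(1L, pmin(dm[1L], as.integer(round(pz / spacing[1L])))),
          pmax(1L, pmin(dm[2L], as.integer(round(py / spacing[2L])))),
          pmax(1L, pmin(dm[3L], as.integer(round(px / spacing[3L])))))
  }

  mask <- array(FALSE, dm)
  volPerFiber <- max(1, length(offs[, 1L])) * fiberLength / min(spacing)
  nTarget <- prod(dm) * targetDensity
  batch <- max(50L, ceiling(nTarget / volPerFiber / 10))
  tries <- 0L
  while (mean(mask) < targetDensity && tries < 200L) {
    tries <- tries + 1L
    centers <- sampleFiberVoxels(batch)
    mask <- stampBalls(mask, centers, offs)
  }
  if (mean(mask) < 0.9 * targetDensity)
    stop("unreachable fiber density (overcrowded lattice)")
  baseDensity <- mean(mask)

  bandMask <- NULL
  if (!is.null(org)) {
    dOrg <- .edt3d(!org, base::dim(org), spacing)  # distance to organoid
    bandMask <- dOrg > 0 & dOrg <= bandWidth
    mask[org] <- FALSE
  }
  if (densificationFactor > 1) {
    refDensity <- baseDensity
    tries <- 0L
    while (mean(mask[bandMask]) < densificationFactor * refDensity &&
           tries < 2000L) {
      tries <- tries + 1L
      centers <- sampleFiberVoxels(max(10L, batch %/% 50L), inBand = TRUE)
      add <- array(FALSE, dm)
      add <- stampBalls(add, centers, offs)
      add <- add & bandMask          # only the in-band portion densifies
      mask <- mask | add
    }
  }

  out <- list(mask = VoxelImage(mask * 1, spacing),
              truth = data.frame(density = baseDensity,
                                 kappa = orientationKappa,
                                 mu = mu,
                                 densification_factor = densificationFactor,
                                 seed = seed))
  if (intensity) {
    img <- mask * 1 + 0.05
    img <- img + array(rnorm(length(img), 0, 0.02), dm)
    # smooth illumination gradient, exercised by background subtraction
    gx <- array(rep(seq(0, 0.1, length.out = dm[3L]),
                    each = dm[1L] * dm[2L]), dm)
    out$intensity <- VoxelImage(pmax(img + gx, 0), spacing)
  }
  out
}

#' Simulate early-organoid-seed migration tracks
#'
#' Biased 3D random walks with exact per-step displacement
#' `speed * stepInterval`: each step direction is a persistence-weighted blend
#' of the previous direction and a fresh isotropic direction
#' (`persistence = 1` gives a straight line, `0` an uncorrelated walk).
#' Defaults mirror a 16 h time lapse sampled every 20 min.
#'
#' @param nTracks,nSteps number of tracks and displacement steps per track.
#' @param stepInterval frame interval in hours.
#' @param speed step speed in um/h (>= 0).
#' @param persistence directional bias in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `tracks` (data.frame: track_id, t_h, x_um, y_um, z_um)
#'   and `truth` (speed, persistence, expected directness where closed-form:
#'   1 for `persistence = 1`, `sqrt(8/(3*pi*nSteps))` for `0`, NA otherwise).
#' @export
simulateTracks <- function(nTracks = 20, nSteps = 48, stepInterval = 1 / 3,
                           speed = 10, persistence = 0.5, seed = 1) {
  if (speed < 0) stop("speed must be >= 0")
  if (persistence < 0 || persistence > 1) stop("persistence must be in [0,1]")
  set.seed(seed)
  stepLen <- speed * stepInterval
  res <- vector("list", nTracks)
  for (tr in seq_len(nTracks)) {
    p <- matrix(0, nSteps + 1L, 3L)
    dprev <- rnorm(3)
    dprev <- dprev / sqrt(sum(dprev^2))
    for (i in seq_len(nSteps)) {
      if (i == 1L) d <- dprev
      else {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        d <- persistence * dprev + (1 - persistence) * u
        nrm <- sqrt(sum(d^2))
        if (nrm < 1e-12) d <- u else d <- d / nrm
      }
      p[i + 1L, ] <- p[i, ] + d * stepLen
      dprev <- d
    }
    res[[tr]] <- data.frame(track_id = tr,
                            t_h = (0:nSteps) * stepInterval,
                            x_um = p[, 1L], y_um = p[, 2L], z_um = p[, 3L])
  }
  expDir <- if (persistence == 1) 1
            else if (persistence == 0) sqrt(8 / (3 * pi * nSteps))
            else NA_real_
  list(tracks = do.call(rbind, res),
       truth = data.frame(speed = speed, persistence = persistence,
                          step_interval_h = stepInterval, n_steps = nSteps,
                          expected_directness = expDir, seed = seed))
}

#' Simulate a 2D star mask (disc with rectangular spikes)
#'
#' Deterministic protrusion phantom: a disc with `nSpikes` evenly spaced
#' radial spikes, used to validate protrusion extraction (count and length
#' recovery).
#'
#' @param nSpikes spike count (>= 0).
#' @param discRadius,spikeLength,spikeWidth geometry in pixels.
#' @param size image side in pixels.
#' @return logical `size x size` matrix.
#' @export
simulateStarMask <- function(nSpikes = 4, discRadius = 30, spikeLength = 25,
                             spikeWidth = 7, size = 160) {
  cy <- cx <- (size + 1) / 2
  y <- matrix(seq_len(size), size, size) - cy
  x <- t(y)                                   # x varies along columns
  mask <- (y^2 + x^2) <= discRadius^2
  if (nSpikes > 0) {
    angs <- 2 * pi * (seq_len(nSpikes) - 1L) / nSpikes + 0.3
    for (a in angs) {
      s <- x * cos(a) + y * sin(a)            # along spike axis
      t2 <- -x * sin(a) + y * cos(a)          # across
      mask <- mask | (s > 0 & s <= discRadius + spikeLength &
                        abs(t2) <= spikeWidth / 2)
    }
  }
  mask
}

#' Simulate a compartmentalized EMT marker stack
#'
#' Two adjacent cells sharing an adherens-type junction band, rendered into
#' four channels (CDH1, VIM, CTNNB1, DNA). The epithelial configuration puts
#' `junctionContrast`-fold CDH1 (and CTNNB1) signal on the junction relative
#' to the cytoplasm with low VIM; the mesenchymal configuration inverts both
#' (dim, patchy junction, high cytoplasmic VIM, nuclear CTNNB1). Nuclei abut
#' the junction so that the band between their centroids, minus the nucleus
#' interiors, is dominated by the junction zone.
#'
#' @param phenotype `"epithelial"` or `"mesenchymal"`.
#' @param junctionContrast membrane-to-cytoplasm ratio of the adherens
#'   channel (> 0). Default 3 (epithelial) or 0.5 (mesenchymal).
#' @param vimLevel cytoplasmic VIM intensity. Default 0.05 (epithelial) or
#'   0.6 (mesenchymal).
#' @param noiseSd additive Gaussian intensity noise (>= 0).
#' @param spacing voxel spacing (um), isotropic scalar or length 3.
#' @param seed integer seed.
#' @return list with `image` (4-channel [VoxelImage-class]), `nuclei`
#'   ([LabelImage-class], labels 1 and 2), `compartments`
#'   ([LabelImage-class]: 1 cytoplasm, 2 junction, 3 nucleus) and `truth`
#'   (expected junction/cytoplasm ratio and log10 CDH1/VIM).
#' @export
simulateMarkerStack <- function(phenotype = c("epithelial", "mesenchymal"),
                                junctionContrast = NULL, vimLevel = NULL,
                                noiseSd = 0, spacing = 1, seed = 1) {
  phenotype <- match.arg(phenotype)
  if (is.null(junctionContrast))
    junctionContrast <- if (phenotype == "epithelial") 3 else 0.5
  if (is.null(vimLevel))
    vimLevel <- if (phenotype == "epithelial") 0.05 else 0.6
  if (junctionContrast <= 0) stop("junctionContrast must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  set.seed(seed)

  dm <- c(8L, 64L, 64L)
  g <- coordGrids(dm, spacing)
  cellR <- 14; nucR <- 3.5; jHalf <- 1; nucOff <- jHalf + nucR  # um
  # nuclei abut the junction band: the centroid-to-centroid band minus the
  # nucleus interiors is then the junction zone itself
  cA <- sqrt((g$x + 11)^2 + g$y^2 + g$z^2) <= cellR
  cB <- sqrt((g$x - 11)^2 + g$y^2 + g$z^2) <= cellR
  body <- cA | cB
  junction <- body & abs(g$x) <= jHalf
  nA <- sqrt((g$x + nucOff)^2 + g$y^2 + g$z^2) <= nucR & g$x < -jHalf
  nB <- sqrt((g$x - nucOff)^2 + g$y^2 + g$z^2) <= nucR & g$x > jHalf
  nuclei <- nA | nB
  cyto <- body & !junction & !nuclei

  c0 <- 0.2
  cdh1 <- array(0, dm)
  cdh1[cyto] <- c0
  cdh1[junction] <- junctionContrast * c0
  vim <- array(0, dm)
  vim[cyto | junction] <- vimLevel
  ctnnb1 <- array(0, dm)
  if (phenotype == "epithelial") {
    ctnnb1[cyto] <- c0; ctnnb1[nuclei] <- c0
    ctnnb1[junction] <- junctionContrast * c0
  } else {
    ctnnb1[cyto] <- c0; ctnnb1[nuclei] <- 3 * c0
    ctnnb1[junction] <- 0.5 * c0
  }
  dna <- array(0, dm)
  dna[nuclei] <- 0.9

  stack <- array(0, c(dm, 4L))
  stack[, , , 1L] <- cdh1; stack[, , , 2L] <- vim
  stack[, , , 3L] <- ctnnb1; stack[, , , 4L] <- dna
  if (noiseSd > 0)
    stack <- pmax(stack + array(rnorm(length(stack), 0, noiseSd), dim(stack)), 0)

  nucLab <- array(0L, dm); nucLab[nA] <- 1L; nucLab[nB] <- 2L
  comp <- array(0L, dm)
  comp[cyto] <- 1L; comp[junction] <- 2L; comp[nuclei] <- 3L

  truth <- data.frame(
    phenotype = phenotype,
    junction_cyto_ratio = junctionContrast,
    log_cdh1_vim = log10(junctionContrast * c0 / vimLevel),
    vim_level = vimLevel, noise_sd = noiseSd, seed = seed)
  list(image = VoxelImage(stack, spacing,
                          channels = c("CDH1", "VIM", "CTNNB1", "DNA")),
       nuclei = LabelImage(nucLab, spacing),
       compartments = LabelImage(comp, spacing),
       truth = truth)
}

#' Simulate a two-channel live/dead object field
#'
#' Non-overlapping disc-shaped objects in one plane; exactly
#' `round(nObjects * liveFraction)` carry the live-channel (Syto9-like)
#' signature, the rest the dead-channel (PI-like) signature.
#'
#' @param nObjects object count.
#' @param liveFraction fraction in `[0, 1]`.
#' @param objectRadius disc radius (um).
#' @param dim grid `(z, y, x)` in voxels.
#' @param spacing voxel spacing (um).
#' @param seed integer seed.
#' @return list with `image` (2-channel [VoxelImage-class], channels
#'   `"live"`, `"dead"`), `labels` ([LabelImage-class]) and `truth`
#'   (per-object live/dead assignment).
#' @export
simulateLiveDeadField <- function(nObjects = 500, liveFraction = 0.5,
                                  objectRadius = 3, dim = c(1, 512, 512),
                                  spacing = 1, seed = 1) {
  if (liveFraction < 0 || liveFraction > 1) stop("liveFraction must be in [0,1]")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  dm <- as.integer(dim)
  set.seed(seed)
  rpx <- objectRadius / min(spacing[2:3])
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < nObjects && tries < 400L * nObjects) {
    tries <- tries + 1L
    cand <- c(runif(1, rpx + 2, dm[2L] - rpx - 1),
              runif(1, rpx + 2, dm[3L] - rpx - 1))
    if (nrow(centers) == 0 ||
        min((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2) >
          (2 * rpx + 2)^2)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < nObjects)
    stop("could not place ", nObjects, " non-overlapping objects")
  nLive <- round(nObjects * liveFraction)
  isLive <- rep(FALSE, nObjects)
  isLive[sample.int(nObjects, nLive)] <- TRUE

  lab <- array(0L, dm)
  offs <- ballOffsets(objectRadius, spacing)
  offs <- offs[offs[, 1L] == 0L, , drop = FALSE]   # in-plane discs
  zmid <- (dm[1L] + 1L) %/% 2L
  for (i in seq_len(nObjects)) {
    ctr <- matrix(c(zmid, as.integer(round(centers[i, 1L])),
                    as.integer(round(centers[i, 2L]))), 1)
    one <- array(FALSE, dm)
    one <- stampBalls(one, ctr, offs)
    lab[one] <- i
  }
  live <- array(0, dm); dead <- array(0, dm)
  live[lab > 0 & array(isLive[pmax(lab, 1L)], dm)] <- 0.9
  dead[lab > 0 & array(!isLive[pmax(lab, 1L)], dm)] <- 0.9
  img <- array(0, c(dm, 2L))
  img[, , , 1L] <- live; img[, , , 2L] <- dead

  list(image = VoxelImage(img, spacing, channels = c("live", "dead")),
       labels = LabelImage(lab, spacing),
       truth = data.frame(object = seq_len(nObjects), live = isLive,
                          y_px = centers[, 1L], x_px = centers[, 2L]))
}

#' Simulate a four-parameter-logistic dose-response table
#'
#' `viability = bottom + (top - bottom) / (1 + (dose/ig50)^hill)` with
#' optional multiplicative noise; dose 0 is the untreated control (viability
#' `top` before noise). The default grid is the seven-point gemcitabine
#' concentration series 0, 0.001, 0.1, 1, 10, 100 and 1000 uM.
#'
#' @param ig50 half-inhibitory dose (uM, > 0).
#' @param hill slope.
#' @param top,bottom viability plateaus (percent).
#' @param noiseCv multiplicative noise coefficient of variation.
#' @param doses dose grid (uM, may include 0).
#' @param seed integer seed.
#' @return list with `table` (data.frame: dose_uM, viability_pct) and `truth`.
#' @export
simulateDoseResponse <- function(ig50 = 0.05, hill = 1, top = 100, bottom = 0,
                                 noiseCv = 0,
                                 doses = c(0, 0.001, 0.1, 1, 10, 100, 1000),
                                 seed = 1) {
  if (ig50 <= 0) stop("ig50 must be > 0")
  set.seed(seed)
  v <- ifelse(doses == 0, top,
              bottom + (top - bottom) / (1 + (doses / ig50)^hill))
  if (noiseCv > 0) v <- pmax(v * (1 + rnorm(length(v), 0, noiseCv)), 0)
  list(table = data.frame(dose_uM = doses, viability_pct = v),
       truth = data.frame(ig50 = ig50, hill = hill, top = top,
                          bottom = bottom, noise_cv = noiseCv, seed = seed))
}
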