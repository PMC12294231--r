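#' @title 3D organoid morphometry and phenotype classification
#' @name morphology
NULL

# Crofton 13-direction surface area estimate (um^2) for a 3D logical mask on a
# near-isotropic grid. Boundary crossings are counted along the 3 axes, 6 face
# diagonals and 4 body diagonals; weights after Legland et al. (the estimator
# family used by MorphoLibJ). Outside the array counts as background.
croftonSurfaceArea <- function(mask, spacing) {
  h <- exp(mean(log(spacing)))                 # geometric mean spacing
  vvol <- prod(spacing)
  dirs <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  wts <- c(rep(0.04577789120476, 3), rep(0.03698062787608, 6),
           rep(0.03519563978232, 4))
  crossings <- function(dz, dy, dx) {
    sh <- shiftArray(mask, dz, dy, dx, fill = FALSE)
    s1 <- sum(xor(mask, sh))
    # shiftArray leaves the in-flow border at `fill`; crossings into the
    # out-of-bounds region are counted once by the pair direction, which the
    # symmetric count below handles: count both directions and halve.
    sh2 <- shiftArray(mask, -dz, -dy, -dx, fill = FALSE)
    s2 <- sum(xor(mask, sh2))
    (s1 + s2) / 2
  }
  total <- 0
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    dk <- sqrt(sum((d * spacing)^2))
    n <- crossings(d[1L], d[2L], d[3L])
    total <- total + wts[k] * n * (vvol / dk)
  }
  4 * total * (h / h)                          # area in um^2
}

# Crofton 4-direction perimeter (um) of a 2D logical mask, isotropic pixel
# size `h`: P = (pi/4) * sum_theta w(theta), w = crossings * line spacing / 2.
croftonPerimeter2D <- function(mask, h = 1) {
  m3 <- array(mask, c(1L, dim(mask)))
  cross2 <- function(dy, dx) {
    sh1 <- shiftArray(m3, 0L, dy, dx, fill = FALSE)
    sh2 <- shiftArray(m3, 0L, -dy, -dx, fill = FALSE)
    (sum(xor(m3, sh1)) + sum(xor(m3, sh2))) / 2
  }
  w0 <- cross2(0L, 1L) * h / 2
  w90 <- cross2(1L, 0L) * h / 2
  w45 <- cross2(1L, 1L) * (h / sqrt(2)) / 2
  w135 <- cross2(1L, -1L) * (h / sqrt(2)) / 2
  pi / 4 * (w0 + w90 + w45 + w135)
}

# largest-inscribed-ball radius (um): max EDT inside the mask, plus a
# quarter-voxel compensation for the expected loss from sampling the
# continuous EDT maximum at voxel centers
inscribedRadius <- function(mask, spacing) {
  if (!any(mask)) return(0)
  max(.edt3d(mask, dim(mask), spacing)) + mean(spacing) / 4
}

# convex-hull volume of the mask's boundary voxel centers (um^3)
convexHullVolume <- function(mask, spacing) {
  bnd <- mask &
    !(shiftArray(mask, 1L, 0L, 0L, FALSE) & shiftArray(mask, -1L, 0L, 0L, FALSE) &
      shiftArray(mask, 0L, 1L, 0L, FALSE) & shiftArray(mask, 0L, -1L, 0L, FALSE) &
      shiftArray(mask, 0L, 0L, 1L, FALSE) & shiftArray(mask, 0L, 0L, -1L, FALSE))
  vox <- whichVoxels(bnd)
  if (nrow(vox) < 4) return(sum(mask) * prod(spacing))
  pts <- sweep(vox, 2L, spacing, `*`)
  .hull_volume3d(pts)
}

# lumen radii per label: enclosed background cavities (6-connectivity for the
# background, foreground grown with 26-connectivity), assigned to the unique
# label they touch; radius = largest ball inscribed in the cavity.
lumenRadii <- function(lab, spacing) {
  bg <- lab == 0L
  comp <- .cc_label3d(bg, dim(lab), 6L)
  d <- dim(lab)
  border <- unique(c(comp[1, , ], comp[d[1L], , ], comp[, 1, ], comp[, d[2L], ],
                     comp[, , 1], comp[, , d[3L]]))
  border <- setdiff(border, 0L)
  cavities <- setdiff(unique(as.vector(comp)), c(0L, border))
  out <- numeric(0)
  for (cv in cavities) {
    cav <- comp == cv
    # owning label = labels adjacent to the cavity (6-neighborhood)
    nb <- integer(0)
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      sh <- shiftArray(lab, s[1L], s[2L], s[3L], 0L)
      nb <- union(nb, unique(sh[cav]))
    }
    nb <- setdiff(nb, 0L)
    if (length(nb) != 1L) next
    r <- max(.edt3d(cav, d, spacing))
    out[as.character(nb)] <- max(r, out[as.character(nb)], 0, na.rm = TRUE)
  }
  out
}

#' Compute per-organoid 3D morphometric descriptors
#'
#' One row per label: voxel-count volume, Crofton surface area, equivalent
#' diameter, sphericity `pi^(1/3) (6V)^(2/3) / A`, circularity `4 pi A / P^2`
#' on the axial (z) projection, convexity `V / V(convex hull)`, geodesic
#' elongation (geodesic diameter over the diameter of the largest inscribed
#' ball) and lumen radius (largest ball inscribed in a background cavity
#' fully enclosed by the body; 0 if none). Labels touching the image border
#' are flagged (`border_touching`), since their descriptors may be truncated.
#'
#' @param labels a [LabelImage-class] (or integer array with `spacing`).
#' @param nuclei optional nucleus [LabelImage-class] on the same grid; adds a
#'   nucleus count per organoid.
#' @param spacing spacing override in um when `labels` is a bare array.
#' @return data.frame of descriptors, one row per label.
#' @examples
#' ph <- simulateOrganoid("solid", outerRadius = 12, spacing = 2, nNuclei = 0)
#' computeDescriptors(ph$labels)
#' @export
computeDescriptors <- function(labels, nuclei = NULL, spacing = NULL) {
  if (is(labels, "LabelImage")) {
    sp <- labels@spacing
    lab <- imgData(labels)
  } else {
    if (is.null(spacing)) stop("spacing required for bare arrays")
    sp <- if (length(spacing) == 1L) rep(spacing, 3L) else spacing
    lab <- labels
  }
  storage.mode(lab) <- "integer"
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) stop("label image is empty")
  d <- dim(lab)
  lumen <- lumenRadii(lab, sp)
  nucCount <- NULL
  if (!is.null(nuclei)) {
    nl <- imgData(nuclei)
    nucCount <- vapply(ids, function(i) {
      length(setdiff(unique(nl[lab == i]), 0L))
    }, integer(1))
  }

  rows <- lapply(seq_along(ids), function(j) {
    i <- ids[j]
    vox <- whichVoxels(lab == i)
    lo <- pmax(apply(vox, 2L, min) - 2L, 1L)
    hi <- pmin(apply(vox, 2L, max) + 2L, d)
    sub <- lab[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE] == i
    touches <- any(vox[, 1L] %in% c(1L, d[1L])) ||
      any(vox[, 2L] %in% c(1L, d[2L])) || any(vox[, 3L] %in% c(1L, d[3L]))

    V <- sum(sub) * prod(sp)
    A <- croftonSurfaceArea(sub, sp)
    sph <- min(pi^(1 / 3) * (6 * V)^(2 / 3) / A, 1)
    hullV <- convexHullVolume(sub, sp)
    conv <- if (hullV > 0) min(V / hullV, 1) else NA_real_
    mip <- apply(sub, c(2L, 3L), any)
    h2d <- sqrt(sp[2L] * sp[3L])
    A2 <- sum(mip) * sp[2L] * sp[3L]
    P2 <- croftonPerimeter2D(mip, h2d)
    circ <- if (P2 > 0) min(4 * pi * A2 / P2^2, 1) else NA_real_
    geo <- .geodesic_diameter3d(sub, dim(sub), sp)
    rin <- inscribedRadius(sub, sp)
    elong <- if (rin > 0) max(geo / (2 * rin), 1) else NA_real_
    lum <- if (as.character(i) %in% names(lumen)) lumen[[as.character(i)]] else 0

    data.frame(label = i, volume = V, surface_area = A,
               equivalent_diameter = 2 * (3 * V / (4 * pi))^(1 / 3),
               sphericity = sph, circularity = circ, convexity = conv,
               geodesic_elongation = elong, lumen_radius = lum,
               border_touching = touches)
  })
  out <- do.call(rbind, rows)
  if (!is.null(nucCount)) out$n_nuclei <- nucCount
  rownames(out) <- NULL
  out
}

# descriptor columns eligible as classifier features
descriptorFeatures <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  setdiff(names(table)[num], c("label", "border_touching"))
}

# 1D nearest-class-mean classifier: train on (x, y), predict for x2
nearestMeanPredict <- function(xTrain, yTrain, xTest) {
  mu <- tapply(xTrain, yTrain, mean)
  mu <- mu[!is.na(mu)]
  names(mu)[max.col(-abs(outer(xTest, as.numeric(mu), `-`)), "first")]
}

#' Rank descriptors by single-feature Cohen's kappa
#'
#' Each feature is scored by the Cohen's kappa of a one-dimensional
#' nearest-class-mean classifier under seeded stratified cross-validation;
#' constant features score 0 and ties are broken lexicographically by feature
#' name. Mirrors kappa-statistic feature selection ahead of SVM training.
#'
#' @param table descriptor data.frame.
#' @param classes class label vector (length `nrow(table)`).
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param features candidate feature names (default: all numeric descriptors).
#' @return data.frame with columns `feature`, `kappa`, ordered best-first.
#' @export
rankFeatures <- function(table, classes, folds = 10, seed = 1,
                         features = descriptorFeatures(table)) {
  classes <- as.character(classes)
  if (length(unique(classes)) < 2) stop("need >= 2 classes")
  if (min(table(classes)) < folds)
    stop("need >= `folds` samples per class")
  fold <- stratifiedFolds(classes, folds, seed)
  kap <- vapply(features, function(f) {
    x <- table[[f]]
    if (length(unique(x)) <= 1L) return(0)
    preds <- character(length(x))
    for (k in seq_len(folds)) {
      te <- fold == k
      preds[te] <- nearestMeanPredict(x[!te], classes[!te], x[te])
    }
    cohenKappa(classes, preds)
  }, numeric(1))
  out <- data.frame(feature = features, kappa = as.numeric(kap))
  out <- out[order(-out$kappa, out$feature), ]
  rownames(out) <- NULL
  out
}

# z-score parameters on training data; sd 0 mapped to 1 (constant feature)
fitStandardizer <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
applyStandardizer <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)
}

#' Train the RBF-kernel SVM phenotype classifier
#'
#' Radial-basis-function SVM with regularization `C = 1`; features are
#' Z-score standardized with parameters fitted on the training data, and the
#' kernel width is the variance-scaled heuristic
#' `gamma = 1 / (n_features * mean feature variance)` computed after
#' standardization. The admissible class set is fixed at training time: the
#' regular-media model distinguishes Cyst/Solid/Invasive, the TGF-beta model
#' is the binary Solid/Invasive classifier.
#'
#' @param table descriptor data.frame.
#' @param classes class labels (must contain >= 2 distinct classes, all of
#'   them in `classLevels` if given).
#' @param features ordered feature names to use.
#' @param classLevels admissible classes (default: those observed).
#' @param cost SVM regularization parameter C.
#' @param seed integer seed (recorded; SVM training itself is deterministic).
#' @return an [OrganoidClassifier-class].
#' @export
trainPhenotypeClassifier <- function(table, classes,
                                     features = descriptorFeatures(table),
                                     classLevels = NULL, cost = 1, seed = 1) {
  classes <- as.character(classes)
  if (length(unique(classes)) < 2) stop("single-class input: cannot train")
  if (is.null(classLevels)) classLevels <- sort(unique(classes))
  if (!all(classes %in% classLevels))
    stop("classes outside the admissible class set: ",
         paste(setdiff(classes, classLevels), collapse = ", "))
  missing <- setdiff(features, names(table))
  if (length(missing))
    stop("features absent from table: ", paste(missing, collapse = ", "))
  x <- as.matrix(table[, features, drop = FALSE])
  std <- fitStandardizer(x)
  xs <- applyStandardizer(x, std)
  mv <- mean(apply(xs, 2L, stats::var))
  gam <- if (mv > 0) 1 / (ncol(xs) * mv) else 1 / ncol(xs)
  set.seed(seed)
  fit <- e1071::svm(xs, factor(classes, classLevels), kernel = "radial",
                    cost = cost, gamma = gam, scale = FALSE)
  new("OrganoidClassifier", model = fit, features = features,
      center = std$center, scale = std$scale,
      classes = classLevels, cost = cost, gamma = gam,
      seed = as.integer(seed))
}

#' Predict organoid phenotypes with a fitted classifier
#'
#' @param object an [OrganoidClassifier-class].
#' @param newdata descriptor data.frame containing the model's features.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
setMethod("predict", "OrganoidClassifier", function(object, newdata, ...) {
  x <- as.matrix(newdata[, object@features, drop = FALSE])
  xs <- applyStandardizer(x, list(center = object@center, scale = object@scale))
  predict(object@model, xs)
})

setMethod("show", "OrganoidClassifier", function(object) {
  cat("OrganoidClassifier (RBF SVM)\n",
      "  classes : ", paste(object@classes, collapse = ", "), "\n",
      "  features: ", paste(object@features, collapse = ", "), "\n",
      "  C = ", object@cost, ", gamma = ", signif(object@gamma, 4), "\n",
      "  support vectors: ", object@model$tot.nSV, "\n", sep = "")
})

#' Stratified k-fold cross-validation of the phenotype classifier
#'
#' Folds are stratified by class and seeded; the Z-score standardization is
#' refit inside each training fold (never on held-out data).
#'
#' @inheritParams trainPhenotypeClassifier
#' @param folds number of folds (>= 2, <= smallest class size).
#' @return list with `accuracy`, `kappa`, `fold_accuracy` (per-fold), `folds`
#'   (assignment vector) and `predictions`.
#' @export
crossValidate <- function(table, classes,
                          features = descriptorFeatures(table),
                          folds = 10, cost = 1, seed = 1) {
  classes <- as.character(classes)
  if (min(table(classes)) < folds)
    stop("fewer samples than folds in at least one class")
  fold <- stratifiedFolds(classes, folds, seed)
  preds <- character(length(classes))
  for (k in seq_len(folds)) {
    te <- fold == k
    model <- trainPhenotypeClassifier(table[!te, , drop = FALSE],
                                      classes[!te], features = features,
                                      cost = cost, seed = seed + k)
    preds[te] <- as.character(predict(model, table[te, , drop = FALSE]))
  }
  acc <- mean(preds == classes)
  foldAcc <- vapply(seq_len(folds),
                    function(k) mean(preds[fold == k] == classes[fold == k]),
                    numeric(1))
  list(accuracy = acc, kappa = cohenKappa(classes, preds),
       fold_accuracy = foldAcc, folds = fold, predictions = preds)
}

#' t-SNE embedding of a descriptor table
#'
#' Standardized features embedded in 2D by t-distributed stochastic neighbor
#' embedding (1000 iterations, perplexity 50, Euclidean metric by default);
#' deterministic for a fixed seed. Requires `perplexity < n/3`.
#'
#' @param table descriptor data.frame.
#' @param perplexity t-SNE perplexity.
#' @param iterations gradient-descent iterations.
#' @param seed integer seed.
#' @param features feature names to embed.
#' @return data.frame with columns `tsne1`, `tsne2`.
#' @export
embedDescriptors <- function(table, perplexity = 50, iterations = 1000,
                             seed = 1, features = descriptorFeatures(table)) {
  n <- nrow(table)
  if (perplexity >= n / 3)
    stop("perplexity must be < n/3 (n = ", n, ")")
  x <- as.matrix(table[, features, drop = FALSE])
  std <- fitStandardizer(x)
  xs <- applyStandardizer(x, std)
  set.seed(seed)
  fit <- Rtsne::Rtsne(xs, dims = 2, perplexity = perplexity,
                      max_iter = iterations, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE)
  data.frame(tsne1 = fit$Y[, 1L], tsne2 = fit$Y[, 2L])
}

#' Per-condition phenotype abundance matrix
#'
#' @param classes phenotype label vector.
#' @param condition condition label vector (same length); a single condition
#'   may be omitted.
#' @return matrix of proportions, conditions in rows (each row sums to 1).
#' @examples
#' phenotypeAbundance(rep(c("cyst", "solid", "invasive"), c(29, 17, 4)))
#' @export
phenotypeAbundance <- function(classes, condition = NULL) {
  if (!length(classes)) stop("empty class vector")
  if (is.null(condition)) condition <- rep("all", length(classes))
  if (any(tapply(classes, condition, length) == 0))
    stop("empty condition")
  tab <- table(condition, classes)
  prop <- sweep(tab, 1L, rowSums(tab), `/`)
  as.matrix(prop)
}
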