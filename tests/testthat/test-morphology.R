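test_that("descriptor engine matches brute-force oracles on digital balls", {
  ph <- simulateOrganoid("solid", outerRadius = 20, spacing = 1,
                         nNuclei = 0, seed = 2)
  d <- computeDescriptors(ph$labels)
  # volume oracle: independent voxel count
  vox <- 0
  arr <- imgData(ph$labels)
  for (i in seq_along(arr)) if (arr[i] == 1L) vox <- vox + 1
  expect_identical(d$volume, vox * 1)
  expect_gte(d$sphericity, 0.97)
  expect_gte(d$convexity, 0.98)
  expect_lte(d$geodesic_elongation, 1.1)
  expect_equal(d$lumen_radius, 0)
  expect_false(d$border_touching)
})

test_that("cyst lumen radius matches the shell geometry", {
  cy <- simulateOrganoid("cyst", outerRadius = 40, shellThickness = 8,
                         spacing = 1, nNuclei = 0, seed = 3)
  d <- computeDescriptors(cy$labels)
  expect_lt(abs(d$lumen_radius - 32), 1)
  # distance-transform oracle: the cavity's inscribed ball, computed directly
  cav <- organoidkit:::.cc_label3d(imgData(cy$labels) == 0L,
                                   dim(imgData(cy$labels)), 6L)
  center <- cav[(dim(cav)[1] + 1) %/% 2, (dim(cav)[2] + 1) %/% 2,
                (dim(cav)[3] + 1) %/% 2]
  oracle <- max(organoidkit:::.edt3d(cav == center, dim(cav), c(1, 1, 1)))
  expect_equal(d$lumen_radius, oracle)
})

test_that("dimensionless descriptors are scale and rotation robust", {
  # analytic ellipsoid (semi-axes um), optionally rotated about z, voxelized
  # at an arbitrary grid spacing
  ellipsoid <- function(axes, h, angle = 0) {
    ext <- 2 * max(axes) + 8
    n <- ceiling(ext / h)
    cc <- (seq_len(n) - (n + 1) / 2) * h
    z <- array(cc, c(n, n, n))
    y <- array(rep(cc, each = n), c(n, n, n))
    x <- array(rep(cc, each = n * n), c(n, n, n))
    xr <- cos(angle) * x - sin(angle) * y
    yr <- sin(angle) * x + cos(angle) * y
    m <- (z / axes[1])^2 + (yr / axes[2])^2 + (xr / axes[3])^2 <= 1
    LabelImage(array(as.integer(m), dim(m)), spacing = h)
  }
  axes <- c(16, 20, 28)
  da <- computeDescriptors(ellipsoid(axes, 1))
  db <- computeDescriptors(ellipsoid(axes, 0.5))
  for (f in c("circularity", "convexity", "sphericity",
              "geodesic_elongation"))
    expect_lt(abs(da[[f]] - db[[f]]) / da[[f]], 0.02)

  dr <- computeDescriptors(ellipsoid(axes, 1, angle = 0.6))
  for (f in c("circularity", "convexity", "sphericity",
              "geodesic_elongation"))
    expect_lt(abs(da[[f]] - dr[[f]]) / da[[f]], 0.05)
  # volume differs only by voxelization at the boundary
  expect_lt(abs(da$volume - dr$volume) / da$volume, 0.02)
})

test_that("kappa feature ranking rewards proxies and ignores noise", {
  set.seed(10)
  n <- 200
  cls <- rep(c("a", "b"), each = n / 2)
  tab <- data.frame(
    proxy = ifelse(cls == "a", 0, 1) + rnorm(n, 0, 0.01),
    noise = rnorm(n),
    const = rep(1, n))
  rk <- rankFeatures(tab, cls, folds = 10, seed = 1,
                     features = c("proxy", "noise", "const"))
  expect_equal(rk$feature[1], "proxy")
  expect_equal(rk$kappa[1], 1)
  expect_lt(abs(rk$kappa[rk$feature == "noise"]), 0.1)
  expect_equal(rk$kappa[rk$feature == "const"], 0)
  expect_error(rankFeatures(tab, rep("a", n)), "classes")
})

test_that("SVM training is exact on separable data and guards its classes", {
  panel <- simulatePhenotypePanel(nPerClass = 15, spacing = 2, seed = 21)
  model <- trainPhenotypeClassifier(panel$descriptors, panel$classes)
  pred <- predict(model, panel$descriptors)
  expect_equal(mean(pred == panel$classes), 1.0)
  expect_error(trainPhenotypeClassifier(panel$descriptors,
                                        rep("one", nrow(panel$descriptors))),
               "single-class")
  expect_error(trainPhenotypeClassifier(panel$descriptors, panel$classes,
                                        classLevels = c("Solid", "Invasive")),
               "admissible")
  expect_error(trainPhenotypeClassifier(panel$descriptors, panel$classes,
                                        features = c("volume", "nope")),
               "absent")
  # binary model restricted to two classes works
  keep <- panel$classes %in% c("solid", "invasive")
  m2 <- trainPhenotypeClassifier(panel$descriptors[keep, ],
                                 droplevels(panel$classes[keep]),
                                 classLevels = c("invasive", "solid"))
  expect_setequal(m2@classes, c("solid", "invasive"))
})

test_that("cross-validation is stratified, seeded and honest", {
  panel <- simulatePhenotypePanel(nPerClass = 15, spacing = 2, seed = 22)
  cv1 <- crossValidate(panel$descriptors, panel$classes, folds = 5, seed = 9)
  cv2 <- crossValidate(panel$descriptors, panel$classes, folds = 5, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_gte(cv1$accuracy, 0.9)
  # every fold is stratified
  for (k in 1:5)
    expect_equal(as.vector(table(panel$classes[cv1$folds == k])),
                 rep(3L, 3))
  expect_error(crossValidate(panel$descriptors, panel$classes, folds = 20),
               "fewer samples")
  # indistinguishable duplicated inputs cannot beat the majority prior
  dup <- panel$descriptors[rep(1, 60), ]
  cls <- rep(c("a", "a", "b"), 20)
  cvd <- suppressWarnings(crossValidate(dup, cls, folds = 5, seed = 1))
  expect_lte(cvd$accuracy, 2 / 3 + 1e-9)
})

test_that("t-SNE embedding separates blobs, is seeded, validates perplexity", {
  set.seed(2)
  X <- data.frame(a = c(rnorm(60), rnorm(60) + 25),
                  b = c(rnorm(60), rnorm(60) + 25))
  em <- embedDescriptors(X, perplexity = 15, iterations = 1000, seed = 4,
                         features = c("a", "b"))
  expect_gt(meanSilhouette(em, rep(1:2, each = 60)), 0.8)
  em2 <- embedDescriptors(X, perplexity = 15, iterations = 1000, seed = 4,
                          features = c("a", "b"))
  expect_identical(em, em2)
  expect_error(embedDescriptors(X[1:10, ], perplexity = 50,
                                features = c("a", "b")), "perplexity")
})

test_that("abundance matrices normalize per condition", {
  ab <- phenotypeAbundance(rep(c("cyst", "solid", "invasive"), c(29, 17, 4)))
  expect_equal(as.numeric(ab[1, c("cyst", "solid", "invasive")]),
               c(0.58, 0.34, 0.08))
  expect_equal(sum(ab), 1)
  one <- phenotypeAbundance(rep("solid", 5))
  expect_equal(as.numeric(one), 1)
  expect_error(phenotypeAbundance(character(0)), "empty")
  two <- phenotypeAbundance(c("a", "a", "b", "b"), c("x", "x", "x", "y"))
  expect_equal(rowSums(two), c(x = 1, y = 1))
})
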