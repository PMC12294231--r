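test_that("fiber segmentation recovers phantom density and symmetries", {
  ff <- simulateFiberField(targetDensity = 0.10, dim = c(4, 256, 256),
                           intensity = TRUE, seed = 1)
  mask <- segmentFibers(ff$intensity)
  expect_gt(mean(mask), 0.08)
  expect_lt(mean(mask), 0.12)
  # inverted-contrast input with invert = TRUE gives the identical mask
  a <- imgData(ff$intensity)
  inv <- max(a) - a
  expect_identical(segmentFibers(inv, invert = TRUE), mask)
  expect_warning(m0 <- segmentFibers(array(0, c(2, 32, 32))), "blank")
  expect_false(any(m0))
})

test_that("fiber metrics match EDT oracles on drawn geometry", {
  # straight rods of radius 2 um at 0.5 um spacing
  d <- c(24L, 48L, 96L)
  g <- expand.grid(z = 1:d[1], y = 1:d[2])
  rod <- array(FALSE, d)
  for (cy in c(12, 36)) {
    sel <- (g$z - 12)^2 + (g$y - cy)^2 <= (2 / 0.5)^2
    for (x in 1:d[3]) rod[cbind(g$z[sel], g$y[sel], x)] <- TRUE
  }
  fm <- fiberMetrics(rod, spacing = 0.5)
  expect_lt(abs(fm$fiber_thickness_um - 4), 0.5)

  # density is a plain voxel percentage
  half <- array(FALSE, c(4, 10, 10))
  half[, , 1:5] <- TRUE
  expect_equal(fiberMetrics(half, spacing = 1)$fiber_density_pct, 50)

  # a spherical pore of radius r in a solid block reads ~2r
  d2 <- c(40L, 40L, 40L)
  gg <- expand.grid(z = 1:40, y = 1:40, x = 1:40)
  pore <- array((gg$z - 20)^2 + (gg$y - 20)^2 + (gg$x - 20)^2 <= 8^2, d2)
  block <- !pore
  pm <- fiberMetrics(block, spacing = 1)
  expect_lt(abs(pm$pore_diameter_um - 16) / 16, 0.15)

  expect_error(fiberMetrics(array(FALSE, c(2, 4, 4)), spacing = 1), "empty")
  # density + pore fraction account for the whole volume
  expect_equal(fm$fiber_density_pct + 100 * mean(!rod), 100)
})

test_that("doughnut ROI geometry follows the band definition", {
  org <- simulateOrganoid("solid", outerRadius = 20, spacing = 1,
                          extent = 100, nNuclei = 0, seed = 1)
  roi <- doughnutROI(org$labels, bandWidth = 7)
  om <- imgData(org$labels) > 0
  expect_false(any(roi$band & om))
  expect_false(any(roi$band & roi$control))
  d <- organoidkit:::.edt3d(!om, dim(om), c(1, 1, 1))
  expect_true(all(d[roi$band] <= 7 & d[roi$band] > 0))
  expect_true(all(d[roi$control] > 21))     # default offset 3x band
  expect_false(roi$clipped)
  expect_error(doughnutROI(org$labels, bandWidth = 7, controlOffset = 10),
               "controlOffset")
  # a band cut by the image border is flagged
  tight <- simulateOrganoid("solid", outerRadius = 20, spacing = 1,
                            extent = 50, nNuclei = 0, seed = 1)
  expect_warning(roi2 <- doughnutROI(tight$labels, bandWidth = 7,
                                     controlOffset = 14), "clipped")
  expect_true(roi2$clipped)
})

test_that("compaction reads 1 on uniform fields and tracks densification", {
  org <- simulateOrganoid("solid", outerRadius = 25, spacing = 1,
                          extent = c(56, 128, 128), nNuclei = 0, seed = 2)
  om <- imgData(org$labels) > 0
  vals <- vapply(1:3, function(s) {
    ff <- simulateFiberField(targetDensity = 0.1, fiberLength = 6,
                             fiberRadius = 0.6, dim = dim(om),
                             organoidMask = om, seed = s)
    roi <- suppressWarnings(doughnutROI(org$labels, bandWidth = 7))
    compaction(ff$mask, roi)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.1)

  ff2 <- simulateFiberField(targetDensity = 0.1, fiberLength = 6,
                            fiberRadius = 0.6, dim = dim(om),
                            densificationFactor = 2, organoidMask = om,
                            seed = 9)
  roi <- suppressWarnings(doughnutROI(org$labels, bandWidth = 7))
  expect_lt(abs(compaction(ff2$mask, roi) - 2) / 2, 0.15)
  # masks only: intensity rescaling cannot change it
  expect_identical(compaction(imgData(ff2$mask) > 0, roi),
                   compaction(imgData(ff2$mask) * 40 > 0, roi))
})

test_that("anisotropy hits its limiting values and is flip/rotation safe", {
  iso <- simulateFiberField(targetDensity = 0.1, orientationKappa = 0,
                            seed = 31)
  expect_lt(fiberAnisotropy(iso$mask)$alpha, 0.05)
  ali <- simulateFiberField(targetDensity = 0.1, orientationKappa = Inf,
                            mu = 0.9, seed = 32)
  a1 <- fiberAnisotropy(ali$mask)
  expect_gt(a1$alpha, 0.95)
  # orientation histogram integrates to 1 over [0, pi)
  expect_equal(sum(a1$histogram$density) * pi / nrow(a1$histogram), 1,
               tolerance = 1e-9)
  # 90-degree rotation leaves alpha unchanged
  m <- imgData(ali$mask)
  rot <- aperm(m, c(1, 3, 2))[, , dim(m)[2]:1]
  expect_lt(abs(fiberAnisotropy(rot)$alpha - a1$alpha), 0.02)
  expect_error(fiberAnisotropy(matrix(FALSE, 50, 50)), "fiber pixels")
})

test_that("anisotropy grows with the orientation concentration", {
  alphas <- vapply(c(0, 1, 2, 4, 8), function(k) {
    f <- simulateFiberField(targetDensity = 0.1, orientationKappa = k,
                            seed = 40 + k)
    fiberAnisotropy(f$mask)$alpha
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
})
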