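test_that("organoid phantoms carry analytic ground truth per shape class", {
  cy <- simulateOrganoid("cyst", outerRadius = 40, shellThickness = 8,
                         spacing = 1, nNuclei = 0, seed = 1)
  expect_equal(cy$truth$lumen_radius_um, 32)
  so <- simulateOrganoid("solid", outerRadius = 20, spacing = 1,
                         nNuclei = 0, seed = 1)
  expect_equal(so$truth$lumen_radius_um, 0)
  expect_equal(so$truth$n_spikes, 0L)
  iv <- simulateOrganoid("invasive", nSpikes = 6, outerRadius = 18,
                         spacing = 1, nNuclei = 0, seed = 1)
  expect_equal(iv$truth$n_spikes, 6L)
  # analytic vs voxelized volume agree at the few-percent level
  expect_lt(abs(sum(imgData(so$labels) > 0) - so$truth$volume_um3) /
              so$truth$volume_um3, 0.05)
})

test_that("organoid phantom parameter validation and sizing errors", {
  expect_error(simulateOrganoid("cyst", outerRadius = 10, shellThickness = 12),
               "shellThickness")
  expect_error(simulateOrganoid("solid", outerRadius = -1), "outerRadius")
  expect_error(simulateOrganoid("invasive", nSpikes = 0), "nSpikes")
  expect_error(simulateOrganoid("solid", outerRadius = 20, extent = 30),
               "extent too small")
})

test_that("generators are seed-deterministic", {
  a <- simulateOrganoid("invasive", seed = 7, spacing = 2)
  b <- simulateOrganoid("invasive", seed = 7, spacing = 2)
  expect_identical(imgData(a$labels), imgData(b$labels))
  expect_identical(imgData(a$nuclei), imgData(b$nuclei))

  f1 <- simulateFiberField(dim = c(2, 128, 128), seed = 3)
  f2 <- simulateFiberField(dim = c(2, 128, 128), seed = 3)
  expect_identical(imgData(f1$mask), imgData(f2$mask))

  m1 <- simulateMarkerStack("epithelial", noiseSd = 0.05, seed = 11)
  m2 <- simulateMarkerStack("epithelial", noiseSd = 0.05, seed = 11)
  expect_identical(imgData(m1$image), imgData(m2$image))

  t1 <- simulateTracks(seed = 5)$tracks
  t2 <- simulateTracks(seed = 5)$tracks
  expect_identical(t1, t2)
})

test_that("fiber fields hit the requested density and densify on demand", {
  ff <- simulateFiberField(targetDensity = 0.10, orientationKappa = 0,
                           dim = c(4, 256, 256), seed = 2)
  dens <- mean(imgData(ff$mask) > 0)
  expect_gt(dens, 0.09)
  expect_lt(dens, 0.11)
  expect_error(simulateFiberField(densificationFactor = 2), "organoidMask")
  expect_error(simulateFiberField(targetDensity = 0.7), "targetDensity")

  org <- simulateOrganoid("solid", outerRadius = 25, spacing = 1,
                          extent = c(56, 128, 128), nNuclei = 0, seed = 4)
  om <- imgData(org$labels) > 0
  ff2 <- simulateFiberField(targetDensity = 0.1, fiberLength = 6,
                            fiberRadius = 0.6, dim = dim(om),
                            densificationFactor = 2, organoidMask = om,
                            seed = 5)
  dOrg <- organoidkit:::.edt3d(!om, dim(om), c(1, 1, 1))
  band <- dOrg > 0 & dOrg <= 7
  far <- dOrg > 21 & dOrg <= 28
  m <- imgData(ff2$mask) > 0
  ratio <- mean(m[band]) / mean(m[far])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("track phantoms have exact step geometry and limiting directness", {
  tk <- simulateTracks(nTracks = 4, nSteps = 12, stepInterval = 0.5,
                       speed = 8, persistence = 0.3, seed = 1)
  for (tr in split(tk$tracks, tk$tracks$track_id)) {
    expect_equal(nrow(tr), 13L)
    seg <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2 + diff(tr$z_um)^2)
    expect_equal(seg, rep(8 * 0.5, 12), tolerance = 1e-12)
  }
  straight <- simulateTracks(nTracks = 3, persistence = 1, seed = 2)
  st <- trackStats(straight$tracks)
  expect_equal(st$directness, rep(1, 3), tolerance = 1e-12)
  expect_equal(st$mean_speed_um_h, rep(10, 3), tolerance = 1e-12)

  # uncorrelated walk matches the Monte-Carlo directness oracle
  walks <- simulateTracks(nTracks = 400, nSteps = 20, persistence = 0,
                          seed = 3)
  got <- mean(trackStats(walks$tracks)$directness)
  expected <- oracleRandomWalkDirectness(20)
  expect_lt(abs(got - expected), 0.03)
  expect_equal(walks$truth$expected_directness, sqrt(8 / (3 * pi * 20)))
})

test_that("marker phantoms encode the configured localization contrast", {
  ep <- simulateMarkerStack("epithelial", junctionContrast = 3,
                            noiseSd = 0, seed = 1)
  expect_equal(ep$truth$junction_cyto_ratio, 3)
  expect_gt(ep$truth$log_cdh1_vim, 0)
  me <- simulateMarkerStack("mesenchymal", seed = 1)
  expect_lt(me$truth$log_cdh1_vim, 0)
  cdh1 <- imgData(getChannel(ep$image, "CDH1"))
  comp <- imgData(ep$compartments)
  expect_equal(mean(cdh1[comp == 2L]) / mean(cdh1[comp == 1L]), 3,
               tolerance = 1e-12)
  expect_error(simulateMarkerStack("epithelial", junctionContrast = 0),
               "junctionContrast")
})

test_that("live/dead fields hold exact live counts", {
  ld <- simulateLiveDeadField(nObjects = 100, liveFraction = 0.5,
                              dim = c(1, 256, 256), seed = 1)
  expect_equal(sum(ld$truth$live), 50L)
  ld2 <- simulateLiveDeadField(nObjects = 40, liveFraction = 1,
                               dim = c(1, 160, 160), seed = 2)
  s <- segmentLiveDead(ld2$image)
  expect_equal(relativeViability(s, s), 1)
})

test_that("dose-response phantom follows the 4PL and the printed dose grid", {
  dr <- simulateDoseResponse(ig50 = 0.05, hill = 1.2, top = 100, bottom = 5,
                             noiseCv = 0, doses = c(0, 0.05, 1), seed = 1)
  expect_equal(dr$table$viability_pct[dr$table$dose_uM == 0.05],
               (100 + 5) / 2)
  expect_equal(dr$table$viability_pct[dr$table$dose_uM == 0], 100)
  grid <- simulateDoseResponse(seed = 1)$table$dose_uM
  expect_equal(grid, c(0, 0.001, 0.1, 1, 10, 100, 1000))
  expect_error(simulateDoseResponse(ig50 = 0), "ig50")
})
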