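test_that("track statistics reproduce closed-form cases", {
  tr <- data.frame(t_h = c(0, 1), x_um = c(0, 3), y_um = c(0, 4),
                   z_um = c(0, 0))
  st <- trackStats(tr)
  expect_equal(st$mean_speed_um_h, 5)
  expect_equal(st$directness, 1)
  # out-and-back path returns to the origin
  ob <- data.frame(t_h = 0:2, x_um = c(0, 10, 0), y_um = 0, z_um = 0)
  expect_equal(trackStats(ob)$directness, 0)
  expect_error(trackStats(data.frame(t_h = c(0, 0), x_um = 0:1, y_um = 0,
                                     z_um = 0)), "non-increasing")
  expect_error(trackStats(data.frame(t_h = 0, x_um = 0, y_um = 0, z_um = 0)),
               ">= 2 points")
})

test_that("speed and directness match the direct-summation oracle", {
  walks <- simulateTracks(nTracks = 25, nSteps = 30, stepInterval = 0.4,
                          speed = 7, persistence = 0.5, seed = 8)
  st <- trackStats(walks$tracks)
  for (id in st$track_id) {
    o <- oracleTrackStats(walks$tracks[walks$tracks$track_id == id, ])
    expect_lt(abs(st$mean_speed_um_h[st$track_id == id] - o$v), 1e-9)
    expect_lt(abs(st$directness[st$track_id == id] - o$directness), 1e-9)
  }
})

test_that("speed is rigid-motion invariant and scales linearly", {
  tk <- simulateTracks(nTracks = 1, nSteps = 20, persistence = 0.3,
                       seed = 3)$tracks
  v0 <- trackStats(tk)$mean_speed_um_h
  # translation
  tt <- tk; tt$x_um <- tt$x_um + 100; tt$z_um <- tt$z_um - 40
  expect_equal(trackStats(tt)$mean_speed_um_h, v0, tolerance = 1e-12)
  # rotation about z
  th <- 0.83
  rt <- tk
  rt$x_um <- cos(th) * tk$x_um - sin(th) * tk$y_um
  rt$y_um <- sin(th) * tk$x_um + cos(th) * tk$y_um
  expect_equal(trackStats(rt)$mean_speed_um_h, v0, tolerance = 1e-9)
  expect_equal(trackStats(rt)$directness, trackStats(tk)$directness,
               tolerance = 1e-9)
  # spatial scaling
  sc <- tk; sc[c("x_um", "y_um", "z_um")] <- sc[c("x_um", "y_um", "z_um")] * 3
  expect_equal(trackStats(sc)$mean_speed_um_h, 3 * v0, tolerance = 1e-9)
})

test_that("track CSV and TrackMate XML import round trip", {
  tk <- simulateTracks(nTracks = 3, nSteps = 5, seed = 2)$tracks
  f <- tempfile(fileext = ".csv")
  writeTracks(tk, f)
  expect_equal(readTracks(f), tk, tolerance = 1e-12)

  xml <- paste0(
    '<TrackMate><Model><AllSpots>',
    '<Spot ID="1" POSITION_X="0" POSITION_Y="0" POSITION_Z="0" POSITION_T="0"/>',
    '<Spot ID="2" POSITION_X="3" POSITION_Y="4" POSITION_Z="0" POSITION_T="1"/>',
    '<Spot ID="3" POSITION_X="6" POSITION_Y="8" POSITION_Z="0" POSITION_T="2"/>',
    '</AllSpots><AllTracks><Track TRACK_ID="0">',
    '<Edge SPOT_SOURCE_ID="1" SPOT_TARGET_ID="2"/>',
    '<Edge SPOT_SOURCE_ID="2" SPOT_TARGET_ID="3"/>',
    '</Track></AllTracks></Model></TrackMate>')
  fx <- tempfile(fileext = ".xml")
  writeLines(xml, fx)
  tm <- readTrackMate(fx)
  expect_equal(nrow(tm), 3L)
  st <- trackStats(tm)
  expect_equal(st$mean_speed_um_h, 5)
  expect_equal(st$directness, 1)
})

test_that("protrusion extraction counts and measures drawn spikes", {
  for (k in c(0, 3, 6)) {
    star <- simulateStarMask(k, discRadius = 30, spikeLength = 25,
                             spikeWidth = 7)
    pr <- extractProtrusions(star, openingRadius = 8, minSize = 20)
    expect_equal(pr$count, k)
    if (k > 0)
      expect_true(all(abs(pr$lengths_um - 25) / 25 < 0.1))
  }
  # protrusion mask stays inside the original mask
  star <- simulateStarMask(4)
  pr <- extractProtrusions(star, openingRadius = 8, minSize = 20)
  expect_true(all(star[pr$protrusion_mask]))
  # idempotent on its own body output
  again <- extractProtrusions(pr$body_mask, openingRadius = 8, minSize = 20)
  expect_equal(again$count, 0L)
  # empty mask is not an error
  none <- extractProtrusions(matrix(FALSE, 32, 32), openingRadius = 4)
  expect_equal(none$count, 0L)
  expect_length(none$lengths_um, 0L)
})

test_that("the intensity path (MIP + LoG + Otsu) segments seed bodies", {
  star <- simulateStarMask(5)
  set.seed(1)
  img <- star * 1 + matrix(rnorm(length(star), 0, 0.03), nrow(star))
  pr <- extractProtrusions(img, sigmaLog = 2, openingRadius = 8, minSize = 20)
  expect_equal(pr$count, 5L)
  # pixel size scales lengths
  pr2 <- extractProtrusions(star, openingRadius = 8, minSize = 20,
                            pixelSize = 0.5)
  expect_equal(pr2$lengths_um,
               extractProtrusions(star, openingRadius = 8,
                                  minSize = 20)$lengths_um / 2)
})
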