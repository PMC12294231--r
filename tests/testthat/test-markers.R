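test_that("percentile normalization is the expected linear map", {
  set.seed(1)
  a <- array(runif(8000, 10, 110), c(20, 20, 20))
  p <- quantile(a, c(0.01, 0.99), names = FALSE)
  out <- normalizePercentile(a)
  mid <- (p[1] + p[2]) / 2
  i <- which.min(abs(a - mid))
  expect_equal(out[i], (a[i] - p[1]) / (p[2] - p[1]), tolerance = 1e-12)
  expect_equal(min(out), 0)            # below-P1 values clip to 0
  expect_gt(max(out), 1)               # above-P99 values keep contrast
  expect_error(normalizePercentile(array(5, c(4, 4, 4))), "constant")
})

test_that("junction ratios recover generator ground truth", {
  ep <- simulateMarkerStack("epithelial", junctionContrast = 3, noiseSd = 0,
                            seed = 1)
  sc <- scoreMarkerStack(ep$image, ep$nuclei,
                         imgData(ep$compartments) == 1L)
  expect_lt(abs(sc$cdh1_junction_cyto - 3), 0.1)
  expect_gt(sc$log_cdh1_vim, 0)
  expect_equal(sc$phenotype_call, "epithelial")

  me <- simulateMarkerStack("mesenchymal", noiseSd = 0, seed = 1)
  sm <- scoreMarkerStack(me$image, me$nuclei,
                         imgData(me$compartments) == 1L)
  expect_lt(sm$cdh1_junction_cyto, 1)
  expect_lt(sm$ctnnb1_junction_nuclei, 1)    # nuclear translocation
  expect_lt(sm$log_cdh1_vim, 0)
  expect_equal(sm$phenotype_call, "mesenchymal")
})

test_that("a uniform marker yields ratio 1", {
  ep <- simulateMarkerStack("epithelial", seed = 2)
  uni <- array(0.4, dim(imgData(ep$nuclei)))
  roi <- junctionBand(ep$nuclei, c(1, 2), bandWidth = 2)
  r <- junctionRatio(uni, roi, "cytoplasm",
                     cytoplasm = imgData(ep$compartments) == 1L)
  expect_equal(as.numeric(r), 1, tolerance = 1e-12)
})

test_that("ratios are invariant to global intensity rescaling", {
  ep <- simulateMarkerStack("epithelial", noiseSd = 0.02, seed = 3)
  sc1 <- scoreMarkerStack(ep$image, ep$nuclei,
                          imgData(ep$compartments) == 1L)
  scaled <- VoxelImage(imgData(ep$image) * 7.3, spacing(ep$image),
                       channels = channelNames(ep$image))
  sc2 <- scoreMarkerStack(scaled, ep$nuclei,
                          imgData(ep$compartments) == 1L)
  expect_equal(sc1$cdh1_junction_cyto, sc2$cdh1_junction_cyto,
               tolerance = 1e-9)
  expect_equal(sc1$log_cdh1_vim, sc2$log_cdh1_vim, tolerance = 1e-9)
})

test_that("ratio recovery degrades with noise", {
  err <- vapply(c(0, 0.05, 0.15), function(ns) {
    e <- vapply(1:3, function(s) {
      ph <- simulateMarkerStack("epithelial", junctionContrast = 3,
                                noiseSd = ns, seed = s)
      sc <- scoreMarkerStack(ph$image, ph$nuclei,
                             imgData(ph$compartments) == 1L)
      abs(sc$cdh1_junction_cyto - 3)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  expect_lt(err[1], 0.3)
  expect_lte(err[1], err[3])
})

test_that("the EMT phenotype call flips exactly at log ratio zero", {
  expect_equal(emtPhenotypeCall(10, 1)$log_ratio, 1)
  expect_equal(emtPhenotypeCall(10, 1)$phenotype, "epithelial")
  expect_equal(emtPhenotypeCall(1, 10)$phenotype, "mesenchymal")
  eq <- emtPhenotypeCall(2, 2)
  expect_equal(eq$log_ratio, 0)
  expect_equal(eq$phenotype, "indeterminate")
  expect_equal(emtPhenotypeCall(2 * (1 + 1e-9), 2)$phenotype, "epithelial")
  expect_equal(emtPhenotypeCall(2, 2 * (1 + 1e-9))$phenotype, "mesenchymal")
  expect_error(emtPhenotypeCall(1, 0), "VIM")
})

test_that("the junction band excludes nuclei and connects the centroids", {
  ep <- simulateMarkerStack("epithelial", seed = 4)
  roi <- junctionBand(ep$nuclei, c(1, 2), bandWidth = 2)
  expect_false(any(roi & imgData(ep$nuclei) > 0))
  expect_gt(sum(roi), 0)
  ends <- attr(roi, "endpoints")
  expect_equal(nrow(ends), 2L)
  expect_error(junctionBand(ep$nuclei, c(1, 9)), "not found")
})
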