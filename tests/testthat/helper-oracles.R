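# independent brute-force oracles used across tests

# segment-wise track statistics by plain loops (independent of trackStats)
oracleTrackStats <- function(tr) {
  tr <- tr[order(tr$t_h), ]
  n <- nrow(tr)
  speeds <- numeric(n - 1L)
  accum <- 0
  for (i in 2:n) {
    seg <- sqrt((tr$x_um[i] - tr$x_um[i - 1])^2 +
                (tr$y_um[i] - tr$y_um[i - 1])^2 +
                (tr$z_um[i] - tr$z_um[i - 1])^2)
    speeds[i - 1L] <- seg / (tr$t_h[i] - tr$t_h[i - 1])
    accum <- accum + seg
  }
  eucl <- sqrt((tr$x_um[n] - tr$x_um[1])^2 + (tr$y_um[n] - tr$y_um[1])^2 +
               (tr$z_um[n] - tr$z_um[1])^2)
  list(v = mean(speeds), directness = eucl / accum)
}

# Monte-Carlo expected directness of an uncorrelated 3D walk of n unit steps
oracleRandomWalkDirectness <- function(nSteps, nWalks = 1e4, seed = 99) {
  set.seed(seed)
  vals <- replicate(nWalks, {
    u <- matrix(rnorm(3 * nSteps), nSteps, 3)
    u <- u / sqrt(rowSums(u^2))
    sqrt(sum(colSums(u)^2)) / nSteps
  })
  mean(vals)
}

# mean silhouette width of a 2-group labeling over 2D points
meanSilhouette <- function(xy, lab) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  mean(vapply(seq_len(n), function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(n) != i])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1)))
}
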