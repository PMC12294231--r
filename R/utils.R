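#' @useDynLib organoidkit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile sd hclust dist as.dendrogram predict
#'   coef median setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Otsu's threshold on an arbitrary value vector (histogram-based, maximizing
# between-class variance). EBImage's otsu() wants a rectangular image, whereas
# here thresholds are taken inside irregular ROIs.
otsuThreshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values for Otsu threshold")
  r <- range(v)
  if (diff(r) <= 0) return(r[1L])
  br <- seq(r[1L], r[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[levels]
  sb2 <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# Cohen's kappa between two label vectors.
cohenKappa <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  lev <- union(truth, pred)
  tab <- table(factor(truth, lev), factor(pred, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# Seed-deterministic stratified fold assignment: within each class, shuffled
# samples are dealt round-robin into folds.
stratifiedFolds <- function(classes, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assign <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Integer voxel coordinates (z,y,x) of TRUE voxels, as an n x 3 matrix.
whichVoxels <- function(mask) {
  d <- dim(mask)
  i <- which(mask)
  i0 <- i - 1L
  z <- i0 %% d[1L]
  rem <- i0 %/% d[1L]
  y <- rem %% d[2L]
  x <- rem %/% d[2L]
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection scheme).
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  out + mu
}

# Shift a 3D logical/numeric array by integer offsets (z,y,x), padding with
# `fill`. Used by the Crofton estimators and regional-maximum filters.
shiftArray <- function(a, dz, dy, dx, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- seq_len(d[1L]); ys <- seq_len(d[2L]); xs <- seq_len(d[3L])
  zsrc <- zs - dz; ysrc <- ys - dy; xsrc <- xs - dx
  zok <- zsrc >= 1L & zsrc <= d[1L]
  yok <- ysrc >= 1L & ysrc <= d[2L]
  xok <- xsrc >= 1L & xsrc <= d[3L]
  out[zs[zok], ys[yok], xs[xok]] <- a[zsrc[zok], ysrc[yok], xsrc[xok]]
  out
}
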