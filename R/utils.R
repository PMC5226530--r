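# internal helpers shared across modules

# run expr under a temporary RNG state when seed is given
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# physical centres (um) of 1-based voxel coordinates, columns z,y,x
.voxelCenterUm <- function(coords, voxelSize) {
  coords <- rbind(coords)
  sweep(coords - 0.5, 2L, voxelSize, "*")
}

# 1-based voxel coordinate containing a physical position (um), clamped
.umToVoxel <- function(pos, voxelSize, dims) {
  pos <- rbind(pos)
  v <- sweep(pos, 2L, voxelSize, "/")
  v <- floor(v) + 1L
  for (j in 1:3) v[, j] <- pmin(pmax(v[, j], 1L), dims[j])
  storage.mode(v) <- "integer"
  v
}

# linear index (1-based) of voxel coords in a (z,y,x) array
.linearIndex <- function(coords, dims) {
  coords <- rbind(coords)
  (coords[, 1L] - 1L) +
    dims[1L] * (coords[, 2L] - 1L) +
    dims[1L] * dims[2L] * (coords[, 3L] - 1L) + 1L
}

# robust background spread from the lower half-distribution of in-mask
# voxels: the interpolated one-sigma lower-tail quantile distance from the
# median (exact for Gaussian background). The interpolated quantile is used
# instead of a plain MAD of deviations because on quantized Poisson-like
# backgrounds the discrete MAD collapses to small integers.
.backgroundSigma <- function(values, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(values) else as.numeric(values[mask])
  if (length(unique(v)) == 1L) return(0)
  if (all(v == round(v))) {
    med <- .hquantile(v, 0.5)
    as.numeric(med - .hquantile(v, pnorm(-1)))
  } else {
    as.numeric(median(v) - quantile(v, pnorm(-1), names = FALSE))
  }
}

# quantile of integer-valued data with within-bin linear interpolation
# (each integer treated as uniform over +-0.5), avoiding the snapping of
# empirical quantiles to the few occupied code values
.hquantile <- function(v, p) {
  lo <- min(v)
  counts <- tabulate(as.integer(v) - lo + 1L)
  cf <- cumsum(counts) / length(v)
  c0 <- c(0, head(cf, -1L))
  i <- which(cf >= p)[1L]
  (lo + i - 1L) - 0.5 + (p - c0[i]) / (cf[i] - c0[i])
}

.backgroundMedian <- function(values, mask = NULL) {
  v <- if (is.null(mask)) as.numeric(values) else as.numeric(values[mask])
  median(v)
}

# Otsu threshold from the volumetric histogram of an integer-valued stack
# (between-class variance maximization over all integer cut points)
.otsuThreshold <- function(values, maxValue = 255L) {
  counts <- as.numeric(tabulate(as.integer(values) + 1L,
                                nbins = maxValue + 1L))
  lev <- 0:maxValue
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * lev)
  mu <- m0[length(m0)] / n
  w0h <- head(w0, -1L); m0h <- head(m0, -1L)
  valid <- w0h > 0 & w0h < n
  if (!any(valid)) stop("degenerate histogram: cannot compute a threshold")
  bc <- rep(-Inf, length(w0h))
  bc[valid] <- (mu * w0h[valid] - m0h[valid])^2 /
    (w0h[valid] * (n - w0h[valid]))
  lev[which.max(bc)] + 0.5
}

# normalized 1D Gaussian kernel over +-4 sigma (sigma in voxels)
.gaussKernel1d <- function(sigmaVox) {
  if (sigmaVox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-(seq(-half, half))^2 / (2 * sigmaVox^2))
  k / sum(k)
}

.logCollector <- function() {
  msgs <- character()
  list(add = function(...) msgs <<- c(msgs, paste0(...)),
       get = function() msgs)
}
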