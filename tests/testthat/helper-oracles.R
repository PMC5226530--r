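`%+%` <- function(a, b) paste0(a, b)

# Brute-force reference implementations, kept deliberately independent of
# the package internals: the 2D maxima oracle works from the declarative
# rule via igraph connected components; the flood oracle is a full-scan
# synchronous re-implementation; distance oracles enumerate all pairs.

# declarative prominence-maxima rule: a candidate c (pixel >= all 8
# neighbours) is reported iff the 8-connected component of
# {v > v(c) - prominence} containing c has no pixel brighter than c, does
# not cover the whole image, and c is the lowest-index candidate of its
# value in the component.
oracleMaxima2D <- function(img, prom) {
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  idx <- matrix(seq_len(n), nr, nc)
  edges <- rbind(
    cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ])),
    cbind(as.vector(idx[, -nc]), as.vector(idx[, -1])),
    cbind(as.vector(idx[-nr, -nc]), as.vector(idx[-1, -1])),
    cbind(as.vector(idx[-1, -nc]), as.vector(idx[-nr, -1])))
  isCand <- vapply(seq_len(n), function(p) {
    i <- (p - 1L) %% nr + 1L; j <- (p - 1L) %/% nr + 1L
    all(img[max(1, i - 1):min(nr, i + 1),
            max(1, j - 1):min(nc, j + 1)] <= img[p])
  }, TRUE)
  cand <- which(isCand)
  accepted <- integer()
  for (vc in sort(unique(img[cand]), decreasing = TRUE)) {
    thr <- vc - prom
    keepPix <- img > thr
    sub <- edges[keepPix[edges[, 1]] & keepPix[edges[, 2]], , drop = FALSE]
    g <- igraph::graph_from_edgelist(sub, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (c0 in cand[img[cand] == vc]) {
      region <- which(comp == comp[c0] & keepPix)
      if (any(img[region] > vc)) next
      if (length(region) == n) next
      rc <- cand[isCand[cand] & img[cand] == vc & cand %in% region]
      if (min(rc) != c0) next
      accepted <- c(accepted, c0)
    }
  }
  accepted <- sort(accepted)
  cbind(row = (accepted - 1L) %% nr + 1L,
        col = (accepted - 1L) %/% nr + 1L)
}

# full-scan synchronous level-descending flood (26-connectivity)
oracleFlood <- function(img, peaks, floorLevel, step, voxelSize,
                        mask = NULL) {
  d <- dim(img)
  lab <- array(0L, d); frozen <- array(FALSE, d)
  np <- nrow(peaks)
  for (k in seq_len(np)) lab[peaks[k, 1], peaks[k, 2], peaks[k, 3]] <- k
  pv <- img[peaks]
  allowed <- if (is.null(mask)) array(TRUE, d) else mask
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  levels <- seq(max(pv), floorLevel, by = -step)
  for (lev in levels) {
    repeat {
      cand <- which(lab == 0L & allowed & img >= lev)
      if (!length(cand)) break
      ci <- arrayInd(cand, d)
      newlab <- integer(length(cand)); newfroz <- logical(length(cand))
      for (m in seq_along(cand)) {
        nb <- sweep(offs, 2, ci[m, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
          nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
        nb <- nb[ok, , drop = FALSE]
        ls <- lab[nb]
        ls <- unique(ls[ls > 0L & !frozen[nb]])
        if (!length(ls)) next
        if (length(ls) == 1L) { newlab[m] <- ls; next }
        dd <- vapply(ls, function(l) {
          sum(((ci[m, ] - peaks[l, ]) * voxelSize)^2)
        }, 0)
        best <- ls[1]; bd <- dd[1]; bv <- pv[ls[1]]
        for (q in seq_along(ls)[-1]) {
          if (dd[q] < bd - 1e-12 ||
              (abs(dd[q] - bd) <= 1e-12 &&
               (pv[ls[q]] > bv || (pv[ls[q]] == bv && ls[q] < best)))) {
            best <- ls[q]; bd <- dd[q]; bv <- pv[ls[q]]
          }
        }
        newlab[m] <- best; newfroz[m] <- TRUE
      }
      hit <- newlab > 0L
      if (!any(hit)) break
      lab[cand[hit]] <- newlab[hit]
      frozen[cand[hit]] <- newfroz[hit]
    }
  }
  list(labels = lab, frozen = frozen)
}

# exhaustive O(n^2) distance oracles
oracleNN <- function(src, tgt, auto = FALSE) {
  vapply(seq_len(nrow(src)), function(i) {
    d2 <- colSums((t(tgt) - src[i, ])^2)
    if (auto) d2[i] <- Inf
    sqrt(min(d2))
  }, 0)
}

oraclePairCounts <- function(src, tgt, r, auto = FALSE) {
  cnt <- numeric(length(r))
  for (i in seq_len(nrow(src))) {
    d <- sqrt(colSums((t(tgt) - src[i, ])^2))
    if (auto) d <- d[-i]
    for (k in seq_along(r)) cnt[k] <- cnt[k] + sum(d <= r[k])
  }
  cnt
}

# greedy ground-truth matching: recall/precision at a match radius
matchPrecisionRecall <- function(det, tru, radius = 0.3) {
  if (nrow(det) == 0L) return(c(recall = 0, precision = NA_real_))
  used <- rep(FALSE, nrow(tru)); tp <- 0L
  nearest <- apply(det, 1, function(p) min(sqrt(colSums((t(tru) - p)^2))))
  for (i in order(nearest)) {
    d <- sqrt(colSums((t(tru) - det[i, ])^2)); d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= radius) { used[j] <- TRUE; tp <- tp + 1L }
  }
  c(recall = tp / nrow(tru), precision = tp / nrow(det))
}

# shared small-scale study conditions for image-level tests
smallGeometry <- function()
  NucleusGeometry(dim = c(32, 96, 96), semiAxes = c(1.8, 2.6, 2.6))

smallConfig <- function(...) {
  args <- utils::modifyList(list(nBright = 8L, nDim = 12L, n53BP1 = 8L,
                                 nEdU = 30L), list(...))
  do.call(fociSimConfig, args)
}

# noiseless renderer arguments
noNoise <- list(offset = 0, poissonScale = 0, gaussianSD = 0)
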