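# --- nearest-neighbour and normalized Ripley (L-function) statistics --------

#' Nearest-neighbour distances between two point sets
#'
#' One 3D Euclidean distance per source point, to its nearest target, on
#' physical (um) coordinates. In auto mode (a point set against itself)
#' self-pairs are excluded.
#'
#' @param source,target numeric matrices, columns z, y, x in um.
#' @param auto logical; set TRUE when \code{source} and \code{target} are
#'   the same set (row i is excluded as its own neighbour).
#' @return numeric vector, one distance per source row.
#' @export
nnDistances <- function(source, target, auto = FALSE) {
  source <- rbind(source); target <- rbind(target)
  if (nrow(target) == 0L || (auto && nrow(target) < 2L))
    stop(structure(class = c("foci3d_no_targets", "error", "condition"),
                   list(message = "no target foci in nucleus",
                        call = sys.call())))
  if (nrow(source) == 0L) return(numeric())
  cpp_nn_dist(source, target, auto)
}

#' Histogram of nearest-neighbour distances
#'
#' Right-open bins [k w, (k+1) w) up to \code{rMax}, plus one overflow bin;
#' counts sum to the number of distances. The median is computed on the
#' unbinned distances (undefined and flagged for an empty input).
#'
#' @param distances numeric vector (um).
#' @param binWidth bin width in um (default 0.1).
#' @param rMax last regular bin edge in um (default 2).
#' @return list with \code{breaks} (regular edges), \code{counts}
#'   (including the trailing overflow bin), \code{median}, and
#'   \code{n}.
#' @export
nnHistogram <- function(distances, binWidth = 0.1, rMax = 2) {
  stopifnot(binWidth > 0)
  edges <- seq(0, rMax, by = binWidth)
  k <- floor(distances / binWidth)
  k[k >= length(edges) - 1L] <- length(edges) - 1L  # overflow bin
  counts <- tabulate(k + 1L, nbins = length(edges))
  list(breaks = edges, counts = counts,
       median = if (length(distances)) median(distances) else NA_real_,
       n = length(distances))
}

#' Raw Ripley pair counts
#'
#' For each distance r of the grid, the number of ordered (source, target)
#' pairs separated by at most r — the unnormalized cumulative ingredient of
#' the L-function. Self-pairs are excluded in auto mode (target omitted).
#'
#' @param source numeric matrix (um, columns z, y, x).
#' @param target optional second set; omitting it selects auto mode, which
#'   requires at least 2 points.
#' @param rGrid strictly increasing distances (um).
#' @return numeric vector of cumulative pair counts, one per r.
#' @export
ripleyK <- function(source, target = NULL, rGrid) {
  source <- rbind(source)
  if (is.unsorted(rGrid, strictly = TRUE))
    stop("rGrid must be strictly increasing")
  auto <- is.null(target)
  if (auto) {
    if (nrow(source) < 2L)
      stop(structure(class = c("foci3d_too_few_points", "error",
                               "condition"),
                     list(message = "auto pair counts need >= 2 points",
                          call = sys.call())))
    target <- source
  }
  target <- rbind(target)
  cpp_pair_counts(source, target, as.numeric(rGrid), auto)
}

#' Monte-Carlo CSR reference pair counts inside a mask
#'
#' The expectation of \code{\link{ripleyK}} under complete spatial
#' randomness of both point sets inside the actual nuclear mask, estimated
#' over \code{nSims} independent draws with the same point counts. Because
#' points are drawn inside the mask itself, boundary (edge) effects are
#' baked into the reference by construction — no analytic edge correction
#' is needed, and the mask may be arbitrarily irregular.
#'
#' @param mask a \linkS4class{NuclearMask}.
#' @param nSource source point count (> 0).
#' @param nTarget target count; NULL for auto mode.
#' @param rGrid strictly increasing distances (um).
#' @param nSims number of CSR draws (>= 100 recommended for production).
#' @param seed optional integer seed; the reference is deterministic
#'   given it.
#' @return list with \code{mean} and \code{sd} of the per-draw pair counts
#'   at each r, and \code{nSims}.
#' @export
csrReference <- function(mask, nSource, nTarget = NULL, rGrid,
                         nSims = 100L, seed = NULL) {
  stopifnot(is(mask, "NuclearMask"), nSims >= 2L)
  if (nSource <= 0L || (!is.null(nTarget) && nTarget <= 0L))
    stop("point counts must be positive")
  auto <- is.null(nTarget)
  if (auto && nSource < 2L) stop("auto reference needs >= 2 points")
  .withSeed(seed, {
    acc <- matrix(0, nSims, length(rGrid))
    for (s in seq_len(nSims)) {
      a <- samplePositions(mask, nSource, "csr")
      b <- if (auto) NULL else samplePositions(mask, nTarget, "csr")
      acc[s, ] <- ripleyK(a, b, rGrid)
    }
    list(mean = colMeans(acc), sd = apply(acc, 2L, sd), nSims = nSims)
  })
}

#' Normalize pair counts into the L-function
#'
#' L(r) = observed(r) / reference(r) - 1, so that L = 0 is random
#' association and L = 1 means the pair count exceeds the random
#' expectation by 100 percent. Distances where the reference is zero are
#' undefined (NA).
#'
#' @param observed numeric vector of observed pair counts per r.
#' @param reference numeric vector of CSR-expected pair counts per r (e.g.
#'   \code{csrReference(...)$mean}).
#' @param rGrid the distance grid (um).
#' @param nSource,nTarget point counts (metadata).
#' @param pair character(2) source/target labels.
#' @param nucleus nucleus identifier.
#' @return An \linkS4class{LCurve}.
#' @export
normalizeL <- function(observed, reference, rGrid,
                       nSource = NA_integer_, nTarget = NA_integer_,
                       pair = c("", ""), nucleus = "") {
  stopifnot(length(observed) == length(reference),
            length(observed) == length(rGrid))
  L <- ifelse(reference > 0, observed / reference - 1, NA_real_)
  new("LCurve", r = as.numeric(rGrid), L = as.numeric(L),
      nSource = as.integer(nSource), nTarget = as.integer(nTarget),
      pair = pair, nucleus = nucleus)
}

#' Per-distance test of the mean L-function against zero
#'
#' At each distance of the common grid, a one-sample two-sided t-test of
#' the per-nucleus L values against 0, flagged at alpha. No multiplicity
#' correction across distances is applied by default (set
#' \code{adjust = "BH"} for Benjamini-Hochberg), and this choice is
#' recorded in the output. Distances where fewer than two nuclei contribute
#' are undefined. With zero variance across nuclei the p-value degenerates:
#' reported as below machine precision when the mean differs from 0, and 1
#' otherwise.
#'
#' @param lcurves list of \linkS4class{LCurve}s on one common r grid.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return data.frame: \code{r}, \code{meanL}, \code{sdL}, \code{n},
#'   \code{p}, \code{significant}; attribute \code{"adjust"} records the
#'   multiplicity handling.
#' @export
testLvsZero <- function(lcurves, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(lcurves) >= 1L)
  r <- rGrid(lcurves[[1L]])
  for (lc in lcurves)
    if (!isTRUE(all.equal(rGrid(lc), r)))
      stop("all L-curves must share one r grid")
  Lmat <- do.call(rbind, lapply(lcurves, lValues))
  out <- data.frame(r = r, meanL = NA_real_, sdL = NA_real_, n = 0L,
                    p = NA_real_, significant = NA)
  for (j in seq_along(r)) {
    v <- Lmat[, j]
    v <- v[!is.na(v)]
    out$n[j] <- length(v)
    if (length(v) < 2L) next
    out$meanL[j] <- mean(v)
    out$sdL[j] <- sd(v)
    if (out$sdL[j] == 0) {
      out$p[j] <- if (out$meanL[j] == 0) 1 else .Machine$double.xmin
    } else {
      out$p[j] <- t.test(v, mu = 0)$p.value
    }
  }
  padj <- if (adjust == "BH") p.adjust(out$p, "BH") else out$p
  out$significant <- !is.na(padj) & padj < alpha
  out$significant[is.na(out$p)] <- NA
  attr(out, "adjust") <- adjust
  out
}

#' Two-sample comparison of per-nucleus counts
#'
#' Independent two-sided t-test (Welch, unequal variances by default)
#' between two groups of per-nucleus counts, significant at p < 0.05.
#' Degenerate zero-variance groups are handled as in
#' \code{\link{testLvsZero}}.
#'
#' @param a,b numeric vectors of per-nucleus counts (>= 2 each).
#' @param varEqual assume equal variances (default FALSE).
#' @return list: \code{t}, \code{p}, \code{meanA}, \code{meanB},
#'   \code{significant}.
#' @export
compareCounts <- function(a, b, varEqual = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (sd(a) == 0 && sd(b) == 0) {
    same <- mean(a) == mean(b)
    return(list(t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                p = if (same) 1 else .Machine$double.xmin,
                meanA = mean(a), meanB = mean(b), significant = !same))
  }
  tt <- t.test(a, b, var.equal = varEqual)
  list(t = unname(tt$statistic), p = tt$p.value,
       meanA = mean(a), meanB = mean(b),
       significant = tt$p.value < 0.05)
}

#' @importFrom stats p.adjust
NULL
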