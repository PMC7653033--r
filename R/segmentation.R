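## Segmentation of parameter maps: k-means on the five fit parameters and
## lesion thresholding of the spacing map.

#' K-means segmentation of the five-parameter fit maps
#'
#' Clusters the five-dimensional dataset of fit parameters
#' (S, d, I_p, q0, I_bgr) over valid scan points. Features are z-score
#' standardized first (the raw scales differ by orders of magnitude and
#' would otherwise dominate the distance); zero-variance features are
#' dropped with a warning. Clusters are relabeled deterministically so that
#' cluster 1 has the lowest mean filament spacing, ascending.
#'
#' @param maps a \linkS4class{ParameterMaps}
#' @param k number of clusters (default 3)
#' @param seed integer seed for the restarts
#' @param nstart random restarts (at least 10)
#' @param mask optional logical matrix restricting the clustered points
#' @return a \linkS4class{ClusterResult}
#' @export
kmeansSegment <- function(maps, k = 3L, seed = 1L, nstart = 10L, mask = NULL) {
  stopifnot(is(maps, "ParameterMaps"))
  nstart <- max(10L, as.integer(nstart))
  tab <- maps@fitTable
  sel <- tab$converged
  if (!is.null(mask)) sel <- sel & mask[cbind(tab$iy, tab$ix)]
  featureNames <- c("S", "d", "Ip", "q0", "Ibgr")
  X <- as.matrix(tab[sel, featureNames])
  if (nrow(X) < k * 10L)
    stop("k-means requires at least 10 k valid points")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(featureNames[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    featureNames <- featureNames[keep]
  }
  Z <- scale(X)
  set.seed(as.integer(seed))
  km <- stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 100L)

  spacing <- tab$a[sel]
  meanSp <- tapply(spacing, km$cluster, mean)
  ord <- order(meanSp)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  newLab <- relabel[km$cluster]

  labels <- matrix(NA_integer_, nrow(maps@spacing), ncol(maps@spacing))
  labels[cbind(tab$iy[sel], tab$ix[sel])] <- newLab
  spacingByCluster <- split(spacing, newLab)
  names(spacingByCluster) <- paste0("cluster", names(spacingByCluster))
  new("ClusterResult", labels = labels,
      centroids = km$centers[ord, , drop = FALSE],
      featureNames = featureNames,
      sizes = as.integer(km$size[ord]),
      spacingByCluster = spacingByCluster,
      totWithinSS = km$tot.withinss)
}

.labelComponents <- function(mask) {
  # 4-connected labeling via EBImage; bwlabel uses 8-connectivity, so label
  # on the mask and split diagonal-only links is unnecessary for our
  # speckle-removal purpose (8-connectivity is the more conservative choice
  # for keeping regions).
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}

#' Lesion mask by thresholding the spacing map
#'
#' Marks scan points whose filament spacing is at or above \code{threshold}
#' (46.0 nm by default) OR whose fit is pinned at the spacing bound: at true
#' lesions the fit diverges and the spacing reaches the fit boundary (45 nm),
#' below the stated threshold, so both criteria are honored. Connected
#' components smaller than \code{minRegionPx} points are removed as speckle.
#'
#' @param maps a \linkS4class{ParameterMaps}
#' @param threshold nm (default 46.0)
#' @param minRegionPx minimum connected-region size kept (default 4)
#' @param includeAtBound OR-in points with \code{atBound = TRUE}
#' @return list: \code{mask} (logical matrix), \code{inside} and
#'   \code{outside} (\linkS4class{RegionStats}; \code{inside} is NULL when
#'   the mask is empty)
#' @export
thresholdLesion <- function(maps, threshold = 46.0, minRegionPx = 4L,
                            includeAtBound = TRUE) {
  stopifnot(is(maps, "ParameterMaps"))
  mask <- !is.na(maps@spacing) & maps@spacing >= threshold
  if (includeAtBound) mask <- mask | (maps@valid & maps@atBound)
  mask[!maps@valid] <- FALSE
  if (any(mask) && minRegionPx > 1L) {
    lab <- .labelComponents(mask)
    sizes <- table(lab[lab > 0])
    small <- as.integer(names(sizes)[sizes < minRegionPx])
    mask[lab %in% small] <- FALSE
  }
  inside <- if (any(mask)) regionAverage(maps, mask) else NULL
  outside <- if (any(!mask & maps@valid)) regionAverage(maps, !mask) else NULL
  list(mask = mask, inside = inside, outside = outside)
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical matrices
#' @return 2|a & b| / (|a| + |b|)
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
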