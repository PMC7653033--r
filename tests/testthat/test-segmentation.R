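# build a ParameterMaps directly from a synthetic fit table (no detector
# simulation), for clustering and thresholding tests
mapsFromTable <- function(tab, ny, nx, anis = NULL) {
  orient <- data.frame(iy = tab$iy, ix = tab$ix, phi0 = 0,
                       fiber = 0,
                       anisotropy = if (is.null(anis)) 0.5 else anis,
                       circVariance = 0.5, defined = TRUE)
  assembleMaps(tab, orient, matrix(1, ny, nx))
}

blobTable <- function(n = 100, seed = 31) {
  set.seed(seed)
  centers <- list(c(S = 0.004, d = 2.2, Ip = 1.2, q0 = 0.328, Ibgr = 0.04),
                  c(S = 0.006, d = 2.6, Ip = 2.0, q0 = 0.318, Ibgr = 0.05),
                  c(S = 0.009, d = 3.0, Ip = 2.8, q0 = 0.308, Ibgr = 0.07))
  rows <- do.call(rbind, lapply(seq_along(centers), function(k) {
    c0 <- centers[[k]]
    data.frame(S = rnorm(n, c0["S"], 1e-4), d = rnorm(n, c0["d"], 0.01),
               Ip = rnorm(n, c0["Ip"], 0.02), q0 = rnorm(n, c0["q0"], 2e-4),
               Ibgr = rnorm(n, c0["Ibgr"], 5e-4), truthCluster = k)
  }))
  ny <- 15L; nx <- 20L
  rows$iy <- rep(seq_len(ny), each = nx)
  rows$ix <- rep(seq_len(nx), ny)
  rows$sigma <- 0.034
  rows$a <- 4 * pi / rows$q0
  rows$residRms <- 0.01
  rows$converged <- TRUE
  rows$atBound <- FALSE
  rows
}

test_that("k-means separates constructed 5-D blobs perfectly", {
  tab <- blobTable()
  m <- mapsFromTable(tab, 15, 20)
  cl <- kmeansSegment(m, k = 3, seed = 1)
  lab <- cl@labels[cbind(tab$iy, tab$ix)]
  ari <- mclust::adjustedRandIndex(lab, tab$truthCluster)
  expect_equal(ari, 1.0)
})

test_that("k-means labeling is deterministic and ascending in spacing", {
  tab <- blobTable()
  m <- mapsFromTable(tab, 15, 20)
  cl1 <- kmeansSegment(m, k = 3, seed = 7)
  cl2 <- kmeansSegment(m, k = 3, seed = 7)
  expect_identical(cl1@labels, cl2@labels)
  meansp <- sapply(cl1@spacingByCluster, mean)
  expect_true(all(diff(meansp) > 0))
})

test_that("zero-variance features are dropped with a warning", {
  tab <- blobTable()
  tab$Ibgr <- 0.05
  m <- mapsFromTable(tab, 15, 20)
  expect_warning(cl <- kmeansSegment(m, k = 3, seed = 1), "Ibgr")
  expect_false("Ibgr" %in% cl@featureNames)
})

test_that("k-means objective is non-increasing along Lloyd iterations", {
  tab <- blobTable()
  Z <- scale(as.matrix(tab[, c("S", "d", "Ip", "q0", "Ibgr")]))
  obj <- sapply(1:6, function(it) {
    set.seed(3)
    suppressWarnings(stats::kmeans(Z, centers = 3, iter.max = it,
                                   nstart = 1,
                                   algorithm = "Lloyd")$tot.withinss)
  })
  expect_true(all(diff(obj) <= 1e-9))
})

test_that("sham phantom clusters localize the rim and the outer layer", {
  fx <- shamFixture()
  cl <- kmeansSegment(fx$maps, k = 3, seed = 1)
  edge <- pmin(row(fx$truth@spacing) - 1, 16 - row(fx$truth@spacing),
               col(fx$truth@spacing) - 1, 16 - col(fx$truth@spacing))
  rim <- edge < 1
  outer <- edge >= 1 & edge < 4
  expect_gt(mean(rim[cl@labels == 1]), 0.8)
  expect_gt(mean(outer[cl@labels == 3]), 0.8)
  meansp <- sapply(cl@spacingByCluster, mean)
  expect_true(all(diff(meansp) > 0))
})

test_that("lesion thresholding is monotone in the threshold", {
  fx <- lesionFixture()
  m1 <- thresholdLesion(fx$maps, threshold = 44, minRegionPx = 1)$mask
  m2 <- thresholdLesion(fx$maps, threshold = 46, minRegionPx = 1)$mask
  m3 <- thresholdLesion(fx$maps, threshold = 48, minRegionPx = 1)$mask
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m2))
})

test_that("lesion mask honors the at-bound OR rule and speckle removal", {
  set.seed(9)
  tab <- data.frame(iy = rep(1:16, each = 16), ix = rep(1:16, 16),
                    S = 0.005, d = 2.5, Ip = rnorm(256, 2, 0.1),
                    q0 = 4 * pi / 39, Ibgr = 0.05, sigma = 0.034,
                    a = 39, residRms = 0.01, converged = TRUE,
                    atBound = FALSE)
  # a 3x3 at-bound region (fit pinned at 45 nm, below the 46 threshold)
  inBlock <- tab$iy %in% 5:7 & tab$ix %in% 5:7
  tab$a[inBlock] <- 45; tab$q0[inBlock] <- 4 * pi / 45
  tab$atBound[inBlock] <- TRUE
  # one isolated high-spacing speckle pixel
  spk <- tab$iy == 14 & tab$ix == 2
  tab$a[spk] <- 47; tab$q0[spk] <- 4 * pi / 47
  m <- mapsFromTable(tab, 16, 16)
  les <- thresholdLesion(m, threshold = 46, minRegionPx = 4)
  expect_true(all(les$mask[5:7, 5:7]))
  expect_false(les$mask[14, 2])            # speckle removed
  expect_equal(sum(les$mask), 9L)
  lesNoBound <- thresholdLesion(m, threshold = 46, minRegionPx = 4,
                                includeAtBound = FALSE)
  expect_equal(sum(lesNoBound$mask), 0L)
})

test_that("an empty lesion mask yields zero area, not an error", {
  fx <- shamFixture()
  les <- thresholdLesion(fx$maps)
  expect_equal(sum(les$mask), 0L)
  expect_null(les$inside)
})

test_that("lesion phantom is segmented against ground truth", {
  fx <- lesionFixture()
  les <- thresholdLesion(fx$maps)
  expect_gt(diceCoefficient(les$mask, fx$truth@lesionMask), 0.9)
  expect_lt(les$inside@meanAnisotropy, les$outside@meanAnisotropy)
  # at-bound fractions inside/outside the true lesion
  ab <- atBoundMap(fx$maps)
  expect_gt(mean(ab[fx$truth@lesionMask]), 0.9)
  expect_lt(mean(ab[!fx$truth@lesionMask]), 0.05)
})
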