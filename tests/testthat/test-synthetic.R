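test_that("phantom scenarios produce the documented structures", {
  sham <- makeDefaultPhantom(c(16L, 16L), "sham")
  expect_false(any(sham@lesionMask))
  expect_equal(sort(unique(as.vector(sham@spacing))), c(38.3, 39.5, 40.8))

  ring <- makeDefaultPhantom(c(16L, 16L), "ring", params = list(ringDelta = 2.2))
  expect_true(any(ring@ringMask))
  inner <- ring@spacing[ring@ringMask]; outer <- ring@spacing[!ring@ringMask]
  expect_equal(unique(outer) - unique(inner), 2.2)

  les <- makeDefaultPhantom(c(16L, 16L), "tac_lesion")
  expect_true(any(les@lesionMask))
  expect_true(all(les@spacing[les@lesionMask] > 46.0))
  expect_true(any(les@peakIntensity[les@lesionMask] == 0))
  expect_true(all(les@peakIntensity[!les@lesionMask] > 0))
  # lesion anisotropy is depressed relative to surrounding tissue
  expect_lt(mean(les@anisotropy[les@lesionMask]),
            mean(les@anisotropy[!les@lesionMask]))
})

test_that("phantom rejects bad inputs", {
  expect_error(makeDefaultPhantom(c(8L, 8L)), "16")
  expect_error(makeDefaultPhantom(c(16L, 16L), "nonsense"))
})

test_that("von Mises order parameter calibration is consistent", {
  k <- vonMisesConcentration(c(0.1, 0.4, 0.7, 0.9))
  expect_true(all(diff(k) > 0))
  expect_equal(vonMisesOrder(k), c(0.1, 0.4, 0.7, 0.9), tolerance = 1e-3)
  expect_identical(vonMisesConcentration(0), 0)
})

test_that("simulateScan validates truth and empty-frame requirements", {
  tr <- uniformTruth(c(2L, 2L))
  expect_error(simulateScan(tr, smallGeom(), nEmpty = 0L), "empty")
  bad <- tr
  bad@orientation <- matrix(0, 3, 3)
  expect_error(validObject(bad), "shape")
})

test_that("Poisson frames average to the noise-free forward model", {
  geom <- syntheticGeometry(c(64L, 64L))
  tr <- uniformTruth(c(1L, 1L), anisotropy = 0.4, orientation = 90)
  exp0 <- simulateScan(tr, geom, poisson = FALSE, nEmpty = 1L)
  lamF <- getFrame(exp0, 1, 2)
  N <- 100L
  acc <- matrix(0, 64, 64)
  for (s in seq_len(N))
    acc <- acc + getFrame(simulateScan(tr, geom, noiseSeed = s,
                                       poisson = TRUE, nEmpty = 1L), 1, 2)
  m <- acc / N
  tol <- 3 * sqrt(pmax(lamF, 1e-6)) / sqrt(N)
  ok <- abs(m - lamF) <= tol
  expect_gt(mean(ok), 0.99)   # the 3-sigma bound admits ~0.3% excursions
})

test_that("empty frames carry only the instrument background", {
  geom <- fullGeom()
  tr <- uniformTruth(c(2L, 2L), anisotropy = 0.5, orientation = 90)
  st <- simulateScan(tr, geom, poisson = FALSE, nEmpty = 2L)
  maps <- coordinateMaps(geom)
  prof <- azimuthalAverage(getFrame(st, 1, 1), maps, detectorMask(st),
                           seq(0, 0.9, length.out = 201))
  fit <- fitProfile(prof)
  expect_equal(fit$d, st@instrument$d, tolerance = 0.05)
  expect_lt(fit$Ip, 1e-3)     # no ring component in empty frames
})

test_that("scan stack round trip through disk is lossless", {
  geom <- syntheticGeometry(c(64L, 64L))
  tr <- makeDefaultPhantom(c(16L, 16L), "tac_lesion")
  st <- simulateScan(tr, geom, noiseSeed = 11L, poisson = TRUE, nEmpty = 2L)
  dir <- file.path(tempdir(), "stack_rt")
  writeScanStack(st, dir)
  st2 <- readScanStack(dir)
  expect_identical(st2@frames, st@frames)
  expect_identical(st2@mask, st@mask)
  expect_identical(st2@emptyFlags, st@emptyFlags)
  expect_equal(st2@truth@spacing, st@truth@spacing)
  expect_equal(st2@truth@anisotropy, st@truth@anisotropy)
  expect_identical(st2@truth@lesionMask, st@truth@lesionMask)
  expect_equal(st2@geometry@detectorDistance, st@geometry@detectorDistance)
  unlink(dir, recursive = TRUE)
})

test_that("SHG generator produces the stated striation spectrum", {
  # orientation 30 deg, period 20 px -> PSD peak at radius N/20 and
  # azimuth 30 deg
  px <- 0.109
  im <- simulateShg(c(256L, 256L), orientation = 30, period = 20 * px,
                    pixelSize = px, undulationAmp = 0, noiseSd = 0, seed = 1)
  P <- computePsd(im@pixels, window = FALSE)
  ctr <- floor(dim(P) / 2) + 1L
  peak <- which(P == max(P), arr.ind = TRUE)[1, ]
  dy <- unname(peak[1] - ctr[1]); dx <- unname(peak[2] - ctr[2])
  expect_equal(sqrt(dx^2 + dy^2), 256 / 20, tolerance = 1 / (256 / 20))
  expect_lt(axialDistance(atan2(dy, dx) * 180 / pi, 30), 3)
})

test_that("SHG generator rejects aliased periods", {
  expect_error(simulateShg(period = 0.2, pixelSize = 0.109), "aliasing")
})

test_that("undulation spreads the PSD azimuthally (monotone second moment)", {
  moment <- sapply(c(0, 0.2, 0.4, 0.6), function(U) {
    im <- simulateShg(c(256L, 256L), orientation = 30, period = 2,
                      undulationAmp = U, noiseSd = 0, seed = 1)
    P <- computePsd(im@pixels)
    ax <- principalAxes(P)
    d <- dim(P); ctr <- floor(d / 2) + 1L
    fy <- row(P) - ctr[1]; fx <- col(P) - ctr[2]
    r <- sqrt(fx^2 + fy^2)
    phi <- atan2(fy, fx) * 180 / pi
    sel <- r > 3
    dax <- axialDistance(phi[sel], ax$angles[1]) * pi / 180
    sum(P[sel] * dax^2) / sum(P[sel])
  })
  expect_true(all(diff(moment) > 0))
})

test_that("SHG image round trip through TIFF preserves pixels and truth", {
  im <- simulateShg(c(128L, 128L), orientation = 45, period = 2,
                    undulationAmp = 0.3, noiseSd = 0.05, seed = 2)
  path <- file.path(tempdir(), "shg_rt.tif")
  writeShgImage(im, path)
  im2 <- readShgImage(path)
  expect_equal(im2@pixels, im@pixels, tolerance = 1e-6)
  expect_equal(im2@truth$orientation, 45)
  expect_equal(im2@pixelSize, im@pixelSize)
  unlink(c(path, paste0(path, ".json")))
})
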