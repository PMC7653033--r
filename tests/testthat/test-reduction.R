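mkStack <- function(frames4d, mask, emptyFlags, geom = smallGeom()) {
  new("ScanStack", frames = frames4d, mask = mask, emptyFlags = emptyFlags,
      geometry = geom, stepSizes = c(5, 5), truth = list(),
      instrument = list())
}

test_that("line background is the pixel-wise mean of the empty frames", {
  fr <- array(0, c(1, 21, 8, 8))
  for (k in 1:20) fr[1, k, , ] <- k
  fr[1, 21, , ] <- 7
  ef <- matrix(c(rep(TRUE, 20), FALSE), 1)
  st <- mkStack(fr, matrix(FALSE, 8, 8), ef)
  expect_equal(lineBackground(st, 1), matrix(10.5, 8, 8))
})

test_that("identical empty frames reproduce themselves as background", {
  fr <- array(3, c(1, 3, 4, 4))
  st <- mkStack(fr, matrix(FALSE, 4, 4), matrix(c(TRUE, TRUE, FALSE), 1))
  expect_equal(lineBackground(st, 1), matrix(3, 4, 4))
})

test_that("a line without empty frames is an error naming the line", {
  fr <- array(1, c(2, 3, 4, 4))
  ef <- matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), 2)
  st <- mkStack(fr, matrix(FALSE, 4, 4), ef)
  expect_error(lineBackground(st, 2), "line 2")
})

test_that("background subtraction flags masked pixels and keeps negatives", {
  f <- matrix(1:16, 4, 4); b <- matrix(8, 4, 4)
  mask <- matrix(FALSE, 4, 4); mask[2, 2] <- TRUE
  out <- subtractBackground(f, b, mask)
  expect_true(is.na(out[2, 2]))
  expect_equal(out[1, 1], -7)              # negatives retained, not clipped
  expect_equal(subtractBackground(b, b), matrix(0, 4, 4))
  expect_error(subtractBackground(f, matrix(0, 3, 3)), "shape")
})

test_that("azimuthal average of a constant image is that constant", {
  g <- smallGeom()
  cm <- coordinateMaps(g)
  prof <- azimuthalAverage(matrix(7, 128, 128), cm,
                           qBreaks = seq(0, 0.9, length.out = 51))
  expect_true(all(abs(prof@intensity[prof@valid] - 7) < 1e-12))
})

test_that("azimuthal average bins the q map onto itself", {
  g <- smallGeom()
  cm <- coordinateMaps(g)
  breaks <- seq(0, 0.95, length.out = 101)
  prof <- azimuthalAverage(qMap(cm), cm, qBreaks = breaks)
  v <- prof@valid
  # binned q equals the per-bin mean abscissa exactly, and stays within
  # half a bin width of the nominal center
  expect_equal(prof@intensity[v], prof@qCenters[v], tolerance = 1e-12)
  nominal <- (breaks[-1] + breaks[-length(breaks)]) / 2
  expect_true(all(abs(prof@intensity[v] - nominal[v]) <= diff(breaks)[1] / 2))
})

test_that("radial profile matches the forward model within 1%", {
  g <- fullGeom()
  # isotropic ring: the azimuthal modulation is mean-1, so the angular
  # average reproduces the radial model; the beamstop-masked arc would
  # otherwise couple to the modulation
  fr <- forwardFrame(g, spacing = 38.9, kappa = 0)
  cm <- coordinateMaps(g)
  prof <- azimuthalAverage(fr, cm, beamstopMask(g),
                           seq(0, 0.9, length.out = 201))
  sel <- prof@valid & prof@qCenters > 0.15 & prof@qCenters < 0.6
  model <- peakModel(prof@qCenters[sel], 0.005, 2.5, 2, 4 * pi / 38.9, 0.05)
  expect_lt(max(abs(prof@intensity[sel] - model) / model), 0.01)
})

test_that("all-masked input raises an error", {
  g <- smallGeom()
  cm <- coordinateMaps(g)
  expect_error(azimuthalAverage(matrix(1, 128, 128), cm,
                                mask = matrix(TRUE, 128, 128),
                                qBreaks = seq(0, 0.9, length.out = 51)),
               "masked")
})

test_that("azimuthal profile implements the printed normalization exactly", {
  g <- fullGeom()
  fr <- forwardFrame(g, kappa = 2, phiScatterDeg = 150)
  cm <- coordinateMaps(g)
  ap <- azimuthalProfile(fr, cm, beamstopMask(g))
  v <- ap@valid
  manual <- (ap@intensity[v] - min(ap@intensity[v])) / sum(ap@intensity[v])
  expect_equal(ap@normalized[v], manual, tolerance = 1e-14)
  # a constant offset changes the normalized profile exactly per the
  # formula (the sum in the denominator changes), not by offset invariance
  ap2 <- azimuthalProfile(fr + 0.5, cm, beamstopMask(g))
  v2 <- ap2@valid
  manual2 <- (ap2@intensity[v2] - min(ap2@intensity[v2])) /
    sum(ap2@intensity[v2])
  expect_equal(ap2@normalized[v2], manual2, tolerance = 1e-14)
  expect_false(isTRUE(all.equal(ap2@normalized[v2], ap@normalized[v])))
})

test_that("azimuthal profile is isotropically flat for an isotropic frame", {
  g <- fullGeom()
  fr <- forwardFrame(g, kappa = 0)
  ap <- azimuthalProfile(fr, coordinateMaps(g), beamstopMask(g))
  v <- ap@valid
  expect_lt(stats::sd(ap@intensity[v]) / mean(ap@intensity[v]), 0.03)
})

test_that("azimuthal argmax sits at the scattering azimuth", {
  g <- fullGeom()
  fr <- forwardFrame(g, kappa = 3, phiScatterDeg = 150)
  ap <- azimuthalProfile(fr, coordinateMaps(g), beamstopMask(g))
  pk <- ap@phiCenters[which.max(ap@intensity)]
  expect_lt(axialDistance(pk, 150), 2.01)
})

test_that("partially beamstop-occluded phi bins are invalid, not biased", {
  g <- fullGeom()
  fr <- forwardFrame(g, kappa = 0)
  ap <- azimuthalProfile(fr, coordinateMaps(g), beamstopMask(g))
  inv <- ap@phiCenters[!ap@valid]
  expect_true(all(axialDistance(inv, 90) < 25))
  expect_gt(sum(!ap@valid), 0)
})

test_that("total intensity is a masked sum with the stated properties", {
  f1 <- matrix(1, 8, 8); f2 <- matrix(runif(64), 8, 8)
  mask <- matrix(FALSE, 8, 8); mask[1, ] <- TRUE
  expect_equal(totalIntensity(matrix(0, 8, 8)), 0)
  expect_equal(totalIntensity(f1, mask), 56)
  expect_equal(totalIntensity(f1 + f2, mask),
               totalIntensity(f1, mask) + totalIntensity(f2, mask))
})

test_that("pixel counts are conserved over the q binning", {
  g <- smallGeom()
  st <- simulateScan(uniformTruth(c(1L, 1L)), g, poisson = FALSE,
                     nEmpty = 1L)
  red <- reduceScan(st)
  expect_equal(sum(red@nPixQ), sum(!detectorMask(st)))
})

test_that("reduceScan agrees with the standalone reduction operations", {
  st <- shamFixture()$stack
  red <- shamFixture()$reduced
  g <- beamGeometry(st)
  cm <- coordinateMaps(g)
  bg <- lineBackground(st, 3)
  fr <- subtractBackground(getFrame(st, 3, 2 + 4), bg, detectorMask(st))
  breaks <- seq(0, max(qMap(cm)) * (1 + 1e-9), length.out = 201)
  prof <- azimuthalAverage(fr, cm, qBreaks = breaks)
  expect_equal(red@Iq[3, 4, ], prof@intensity, tolerance = 1e-12)
  ap <- azimuthalProfile(fr, cm)
  expect_equal(red@Iphi[3, 4, ], ap@intensity, tolerance = 1e-12)
  expect_equal(red@total[3, 4], totalIntensity(fr), tolerance = 1e-12)
})
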