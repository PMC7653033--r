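test_that("PSD satisfies Parseval's identity and basic Fourier facts", {
  set.seed(2)
  img <- matrix(rnorm(128 * 128), 128)
  x <- img - mean(img)
  P <- computePsd(img, window = FALSE)
  expect_lt(abs(sum(P) - sum(x^2)) / sum(x^2), 1e-6)

  # pure cosine grating along x: mass at +-1/p on the x axis
  p <- 16
  g <- matrix(cos(2 * pi * col(matrix(0, 128, 128)) / p), 128, 128)
  Pg <- computePsd(g, window = FALSE)
  ctr <- floor(dim(Pg) / 2) + 1L
  peaks <- which(Pg > max(Pg) / 2, arr.ind = TRUE)
  expect_true(all(peaks[, 1] == ctr[1]))
  expect_true(all(abs(abs(peaks[, 2] - ctr[2]) - 128 / p) <= 1))
  expect_gt(sum(Pg[ctr[1], c(ctr[2] - 8, ctr[2] + 8)]) / sum(Pg), 0.99)
})

test_that("white-noise PSD is azimuthally flat", {
  set.seed(4)
  P <- computePsd(matrix(rnorm(256 * 256), 256), window = FALSE)
  ctr <- floor(dim(P) / 2) + 1L
  fy <- row(P) - ctr[1]; fx <- col(P) - ctr[2]
  phi <- (atan2(fy, fx) * 180 / pi) %% 360
  r <- sqrt(fx^2 + fy^2)
  sel <- r > 10 & r < 120
  qmeans <- tapply(P[sel], floor(phi[sel] / 90), mean)
  expect_lt(diff(range(qmeans)) / mean(qmeans), 0.05)
})

test_that("degenerate and undersized images are handled", {
  expect_error(computePsd(matrix(1, 32, 32)), ">= 64")
  Pc <- computePsd(matrix(5, 128, 128))
  expect_true(attr(Pc, "degenerate"))
  expect_error(principalAxes(Pc), "degenerate")
})

test_that("principal axes find a grating orientation and are equivariant", {
  im <- simulateShg(c(256L, 256L), orientation = 30, period = 2,
                    noiseSd = 0.02, seed = 4)
  ax <- principalAxes(computePsd(im@pixels))
  expect_lt(axialDistance(ax$angles[1], 30), 1)
  expect_equal(axialDistance(ax$angles[1], ax$angles[2]), 90,
               tolerance = 1e-6)
  # rotating the image by 90 degrees rotates the axes by 90
  r90 <- t(im@pixels)[, nrow(im@pixels):1]
  ax90 <- principalAxes(computePsd(r90))
  expect_lt(axialDistance(ax90$angles[1], 30 + 90), 1)
})

test_that("isotropic noise flags unstable axes", {
  set.seed(8)
  ax <- principalAxes(computePsd(matrix(rnorm(256 * 256), 256)))
  expect_true(ax$unstable)
})

test_that("cake sectors at 45 degrees cover exactly half the plane", {
  P <- matrix(1, 256, 256)
  ck <- cakeProfile(P, c(10, 100), openingAngle = 45)
  ctr <- floor(dim(P) / 2) + 1L
  fy <- row(P) - ctr[1]; fx <- col(P) - ctr[2]
  r <- round(sqrt(fx^2 + fy^2))
  total <- sum(r >= 1 & r <= 128)
  expect_equal(sum(ck$n), total / 2, tolerance = 0.01)
})

test_that("cake profile of a smooth isotropic PSD is angle-independent", {
  ctr <- 129L
  fx <- col(matrix(0, 256, 256)) - ctr; fy <- row(matrix(0, 256, 256)) - ctr
  P <- 1 / (1 + (fx^2 + fy^2) / 100)
  c5 <- cakeProfile(P, c(37, 127), 5)
  c20 <- cakeProfile(P, c(37, 127), 20)
  # inner radial bins hold only a handful of pixels per 5-degree sector;
  # the comparison is meaningful from ~15 bins outward
  sel <- c5$valid & c20$valid & c5$r > 15
  expect_lt(max(abs(c20$value[sel] / c5$value[sel] - 1)), 0.03)
  res <- undulationIndicator(P, axes = c(37, 127), band = which(sel))
  expect_lt(indicatorScalar(res), 0.03)
})

test_that("grating peak dilutes as the opening angle grows", {
  im <- simulateShg(c(256L, 256L), orientation = 30, period = 2,
                    noiseSd = 0, seed = 1)
  P <- computePsd(im@pixels)
  ax <- principalAxes(P)
  pk <- sapply(c(5, 10, 20, 40), function(oa)
    max(cakeProfile(P, ax, oa)$value, na.rm = TRUE))
  expect_true(all(diff(pk) < 0))
})

test_that("undulation indicator decreases strictly with undulation", {
  for (seed in c(1L, 10L)) {
    sc <- sapply(c(0, 0.1, 0.2, 0.3) * 2, function(U)
      indicatorScalar(shgIndicator(
        simulateShg(c(512L, 512L), orientation = 30, period = 2,
                    undulationAmp = U, noiseSd = 0.05, seed = seed))))
    expect_true(all(diff(sc) < 0))
  }
})

test_that("indicator scalar is scale invariant and rotation stable", {
  im <- simulateShg(c(512L, 512L), orientation = 30, period = 2,
                    undulationAmp = 0.2, noiseSd = 0.05, seed = 3)
  s0 <- indicatorScalar(shgIndicator(im))
  expect_equal(indicatorScalar(shgIndicator(im@pixels * 11.3)), s0,
               tolerance = 1e-12)
  r90 <- t(im@pixels)[, nrow(im@pixels):1]
  expect_lt(abs(indicatorScalar(shgIndicator(r90)) - s0) / s0, 0.02)
})

test_that("an image without directional signal scores zero", {
  set.seed(9)
  noise <- matrix(rnorm(512 * 512), 512)
  res <- undulationIndicator(computePsd(noise))
  expect_lt(indicatorScalar(res), 0.05)
})

test_that("paired t-test matches its closed form and the reference
          implementation", {
  a <- c(3.1, 4.0, 5.2, 4.4); b <- c(1.0, 2.1, 3.2, 2.4)
  res <- pairedTTest(a, b)
  d <- a - b
  tManual <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, tManual, tolerance = 1e-10)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$dof, 3L)
})

test_that("degenerate and symmetric difference cases are flagged", {
  res0 <- pairedTTest(c(1, 2, 3), c(2, 3, 4))
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p))
  resSym <- pairedTTest(c(1, 2, 3), c(2, 2, 2))
  expect_equal(resSym$t, 0)
  expect_equal(resSym$p, 1)
  expect_error(pairedTTest(1:3, 1:4), "equal length")
  expect_error(pairedTTest(1, 2), "at least 2")
})

test_that("group comparison averages within hearts before pairing", {
  sc <- c(1, 3, 10, 12, 2, 4, 11, 13, 3, 5, 12, 14)
  grp <- rep(c("sham", "sham", "tac", "tac"), 3)
  hrt <- rep(c("s1", "s2", "t1", "t2"), 3)
  gt <- groupIndicatorTest(sc, grp, hrt)
  expect_equal(sort(gt$perHeart$scalar), c(2, 4, 11, 13))
  expect_equal(gt$test$n, 2L)
  expect_equal(gt$test$dof, 1L)
  expect_error(groupIndicatorTest(sc[1:4], grp[1:4], c("a", "b", "c", "c")),
               "two groups|equal numbers")
})
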