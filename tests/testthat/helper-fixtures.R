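# Shared fixtures, built once per test run and cached across test files.
# All simulated data are generated in code with fixed seeds.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small detector for cheap geometric tests; the beamstop is relatively wide
# on this grid, so orientation-sensitive checks use fullGeom()
smallGeom <- function() syntheticGeometry(c(128L, 128L))
fullGeom <- function() syntheticGeometry()

# noise-free sham phantom scan, fully processed
shamFixture <- function() fixture("sham", function() {
  truth <- makeDefaultPhantom(c(16L, 16L), "sham")
  stack <- simulateScan(truth, fullGeom(), poisson = FALSE, nEmpty = 2L)
  reduced <- reduceScan(stack)
  fits <- fitScan(reduced)
  orient <- orientationMap(reduced)
  maps <- assembleMaps(fits, orient, reduced@total)
  list(truth = truth, stack = stack, reduced = reduced, fits = fits,
       orient = orient, maps = maps)
})

# Poisson-noise lesion phantom scan, fully processed
lesionFixture <- function() fixture("lesion", function() {
  truth <- makeDefaultPhantom(c(16L, 16L), "tac_lesion")
  stack <- simulateScan(truth, fullGeom(), noiseSeed = 3L, poisson = TRUE,
                        nEmpty = 20L)
  reduced <- reduceScan(stack)
  fits <- fitScan(reduced)
  orient <- orientationMap(reduced)
  maps <- assembleMaps(fits, orient, reduced@total)
  list(truth = truth, stack = stack, reduced = reduced, fits = fits,
       orient = orient, maps = maps)
})

# noise-free forward-model frame rendered directly on the detector,
# bypassing simulateScan (independent of the stack machinery)
forwardFrame <- function(geom, spacing = 38.9, Ip = 2, S = 0.005, d = 2.5,
                         Ibgr = 0.05, kappa = 0, phiScatterDeg = 120,
                         sigma = 0.034) {
  maps <- coordinateMaps(geom)
  qv <- pmax(as.vector(qMap(maps)), 1e-4)
  phiv <- as.vector(phiMap(maps)) * pi / 180
  q0 <- 4 * pi / spacing
  A <- if (kappa == 0) 1 else
    exp(kappa * (cos(2 * (phiv - phiScatterDeg * pi / 180)) - 1)) /
      besselI(kappa, 0, expon.scaled = TRUE)
  matrix(S * qv^(-d) + Ibgr + Ip * exp(-(qv - q0)^2 / sigma^2) * A,
         geom@detectorShape[1], geom@detectorShape[2])
}

# an AzimuthalProfile built directly from a vector of bin intensities,
# normalized per the printed equation (valid bins only)
azProfileFromIntensity <- function(I, valid = !is.na(I)) {
  n <- length(I)
  norm <- rep(NA_real_, n)
  s <- sum(I[valid])
  if (any(valid) && s > 0) norm[valid] <- (I[valid] - min(I[valid])) / s
  new("AzimuthalProfile", phiCenters = (seq_len(n) - 0.5) * 360 / n,
      intensity = I, normalized = norm, valid = valid)
}

# model I(q) used by the peak fitter, for profile-level tests
peakModel <- function(q, S, d, Ip, q0, Ibgr, sigma = 0.034)
  S * q^(-d) + Ip * exp(-(q - q0)^2 / sigma^2) + Ibgr

# RadialProfile from a closed-form model on a regular q grid
profileFromModel <- function(q, I) {
  new("RadialProfile", qCenters = q, intensity = I,
      nPixels = rep(100L, length(q)), valid = rep(TRUE, length(q)))
}
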