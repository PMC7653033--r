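HC_KEV_NM <- 1.23984  # hc, keV * nm

#' BeamGeometry: beam and detector geometry of a scanning diffraction setup
#'
#' Holds the beam parameters (photon energy \eqn{E}, flux \eqn{I_0}, exposure
#' \eqn{\tau}, focal FWHM \eqn{\Delta x \times \Delta y}, mass absorption
#' coefficient \eqn{\mu/\rho}) and the detector parameters (sample-detector
#' distance, pixel size, beam center, shape) needed to build reciprocal-space
#' coordinate maps and to estimate the deposited dose.
#'
#' @slot photonEnergy photon energy, keV
#' @slot fluxI0 photon flux \eqn{I_0}, photons/s
#' @slot exposure exposure time \eqn{\tau} per scan point, s
#' @slot beamFwhm focal spot FWHM \code{c(horizontal, vertical)}, micrometers
#' @slot massAbsCoeff mass absorption coefficient \eqn{\mu/\rho}, cm^2/g
#' @slot detectorDistance sample-detector distance, mm
#' @slot pixelSize detector pixel pitch, micrometers
#' @slot beamCenter beam center \code{c(row, col)} in fractional pixels
#' @slot detectorShape detector \code{c(rows, cols)}
#' @export
setClass("BeamGeometry", representation(
  photonEnergy = "numeric",
  fluxI0 = "numeric",
  exposure = "numeric",
  beamFwhm = "numeric",
  massAbsCoeff = "numeric",
  detectorDistance = "numeric",
  pixelSize = "numeric",
  beamCenter = "numeric",
  detectorShape = "integer"
))

setValidity("BeamGeometry", function(object) {
  msg <- character()
  pos <- c(photonEnergy = object@photonEnergy, fluxI0 = object@fluxI0,
           exposure = object@exposure, massAbsCoeff = object@massAbsCoeff,
           detectorDistance = object@detectorDistance,
           pixelSize = object@pixelSize, beamFwhm = object@beamFwhm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all physical magnitudes must be finite and strictly positive")
  if (length(object@beamFwhm) != 2L)
    msg <- c(msg, "beamFwhm must be c(horizontal, vertical)")
  if (length(object@beamCenter) != 2L || length(object@detectorShape) != 2L)
    msg <- c(msg, "beamCenter and detectorShape must have length 2")
  else if (any(object@beamCenter < 1) || any(object@beamCenter > object@detectorShape))
    msg <- c(msg, "beamCenter must lie inside the detector bounds")
  if (length(msg)) msg else TRUE
})

#' CoordinateMaps: per-pixel reciprocal-space coordinates
#'
#' Per-pixel wavevector transfer \eqn{q = (4\pi/\lambda)\sin(\theta/2)}
#' (1/nm), azimuth \eqn{\varphi} (degrees in [0, 360), counter-clockwise from
#' the +column axis) and scattering angle \eqn{\theta} (rad).
#'
#' @slot qMap matrix, 1/nm
#' @slot phiMap matrix, degrees in [0, 360)
#' @slot thetaMap matrix, rad
#' @export
setClass("CoordinateMaps", representation(
  qMap = "matrix", phiMap = "matrix", thetaMap = "matrix"
))

setValidity("CoordinateMaps", function(object) {
  if (!all(dim(object@qMap) == dim(object@phiMap)) ||
      !all(dim(object@qMap) == dim(object@thetaMap)))
    return("qMap, phiMap and thetaMap must share one shape")
  if (any(object@qMap < 0)) return("qMap must be non-negative")
  if (any(object@phiMap < 0 | object@phiMap >= 360))
    return("phiMap must lie in [0, 360)")
  TRUE
})

#' GroundTruthFields: per-scan-point ground truth of a synthetic scan
#'
#' All fields are (ny x nx) matrices over the sample scan grid. Spacing is the
#' acto-myosin lattice spacing in nm, orientation the cardiomyocyte chain
#' (fiber) orientation in degrees modulo 180, anisotropy the target of the
#' azimuthal order estimator in [0, 1], peakIntensity the Gaussian ring peak
#' amplitude in counts/exposure, and (bgS, bgD, bgIbgr) the sample matrix
#' scattering power law and flat background of the fitted model.
#'
#' @slot spacing nm
#' @slot orientation degrees mod 180
#' @slot anisotropy dimensionless in [0, 1]
#' @slot peakIntensity counts/exposure
#' @slot bgS power-law scale
#' @slot bgD power-law decay exponent
#' @slot bgIbgr flat background, counts/exposure
#' @slot lesionMask logical
#' @slot ringMask logical
#' @slot scenario character label
#' @export
setClass("GroundTruthFields", representation(
  spacing = "matrix", orientation = "matrix", anisotropy = "matrix",
  peakIntensity = "matrix", bgS = "matrix", bgD = "matrix", bgIbgr = "matrix",
  lesionMask = "matrix", ringMask = "matrix", scenario = "character"
))

setValidity("GroundTruthFields", function(object) {
  d <- dim(object@spacing)
  nm <- c("orientation", "anisotropy", "peakIntensity", "bgS", "bgD",
          "bgIbgr", "lesionMask", "ringMask")
  for (s in nm)
    if (!all(dim(slot(object, s)) == d))
      return(sprintf("slot '%s' does not match the spacing grid shape", s))
  if (any(object@spacing <= 0)) return("spacing must be strictly positive")
  if (any(object@anisotropy < 0 | object@anisotropy > 1))
    return("anisotropy must lie in [0, 1]")
  if (any(object@peakIntensity < 0)) return("peakIntensity must be >= 0")
  TRUE
})

#' ScanStack: grid of 2D detector frames with mask and flags
#'
#' Raw input of the diffraction pipeline. \code{frames} is a 4D array
#' \code{[ny, nxTotal, rows, cols]}; each scan line (first index) contains
#' \code{nxTotal} frames of which the empty-flagged ones (leading columns by
#' default) were recorded without sample and are used for per-line background
#' subtraction. Counts are non-negative (integers when Poisson noise was
#' drawn; expectation values in the noise-free mode of the generator).
#'
#' @slot frames numeric 4D array, counts/exposure
#' @slot mask logical matrix (rows x cols); TRUE = masked (beamstop/bad pixel)
#' @slot emptyFlags logical matrix (ny x nxTotal)
#' @slot geometry a \linkS4class{BeamGeometry}
#' @slot stepSizes scan step \code{c(dx, dy)}, micrometers
#' @slot truth a \linkS4class{GroundTruthFields}, or NULL-like empty list for
#'   external data
#' @slot instrument list of instrument-background truth
#'   (\code{S}, \code{d}, \code{flat}) present in every frame
#' @export
setClass("ScanStack", representation(
  frames = "array", mask = "matrix", emptyFlags = "matrix",
  geometry = "BeamGeometry", stepSizes = "numeric",
  truth = "ANY", instrument = "list"
))

setValidity("ScanStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 4L) return("frames must be a 4D array [ny, nx, rows, cols]")
  if (!all(dim(object@mask) == d[3:4]))
    return("mask shape must match the detector frame shape")
  if (!all(dim(object@emptyFlags) == d[1:2]))
    return("emptyFlags shape must match the scan grid")
  if (any(object@frames < 0)) return("counts must be non-negative")
  TRUE
})

#' RadialProfile: azimuthally averaged 1D intensity profile I(q)
#'
#' @slot qCenters bin centers, 1/nm, ascending
#' @slot intensity mean counts/exposure per bin (NA where no pixels)
#' @slot nPixels contributing unmasked pixels per bin
#' @slot valid logical; bins with nPixels == 0 are invalid, never interpolated
#' @export
setClass("RadialProfile", representation(
  qCenters = "numeric", intensity = "numeric", nPixels = "integer",
  valid = "logical"
))

setValidity("RadialProfile", function(object) {
  n <- length(object@qCenters)
  if (length(object@intensity) != n || length(object@nPixels) != n ||
      length(object@valid) != n) return("all fields must share one length")
  if (is.unsorted(object@qCenters, strictly = TRUE))
    return("qCenters must be strictly ascending")
  if (any(object@valid & object@nPixels == 0L))
    return("bins without pixels must be flagged invalid")
  TRUE
})

#' AzimuthalProfile: 1D azimuthal intensity profile I(phi) and its
#' normalized form
#'
#' \code{normalized} follows the printed definition
#' \deqn{I_{norm}(\varphi) = (I(\varphi) - \min I(\varphi)) / \sum_\varphi I(\varphi),}
#' with min and sum taken over valid bins only (empty bins behind the
#' beamstop are excluded). It is non-negative with sum at most 1.
#'
#' @slot phiCenters degrees in [0, 360)
#' @slot intensity mean counts/exposure per bin
#' @slot normalized dimensionless
#' @slot valid logical per bin
#' @export
setClass("AzimuthalProfile", representation(
  phiCenters = "numeric", intensity = "numeric", normalized = "numeric",
  valid = "logical"
))

setValidity("AzimuthalProfile", function(object) {
  n <- length(object@phiCenters)
  if (length(object@intensity) != n || length(object@normalized) != n ||
      length(object@valid) != n) return("all fields must share one length")
  if (any(object@phiCenters < 0 | object@phiCenters >= 360))
    return("phiCenters must lie in [0, 360)")
  v <- object@valid
  if (isTRUE(any(object@normalized[v] < -1e-12, na.rm = TRUE)))
    return("normalized intensity must be non-negative")
  TRUE
})

#' ReducedScan: per-scan-point 1D profiles of a reduced scan
#'
#' Background-subtracted radial profiles I(q), azimuthal profiles I(phi)
#' restricted to the anisotropy q-range, and total scattered intensity, for
#' every sample (non-empty) scan point.
#'
#' @slot q radial bin centers, 1/nm
#' @slot Iq array [ny, nx, nQBins]
#' @slot nPixQ integer vector: unmasked pixels per q bin (same for all points)
#' @slot phi azimuthal bin centers, degrees
#' @slot Iphi array [ny, nx, nPhiBins]
#' @slot nPixPhi integer vector: unmasked pixels per phi bin
#' @slot total matrix [ny, nx], counts/exposure
#' @slot qRangeAnisotropy the q window of the azimuthal profiles, 1/nm
#' @slot intensityUnit character, "counts/exposure"
#' @export
setClass("ReducedScan", representation(
  q = "numeric", Iq = "array", nPixQ = "integer",
  phi = "numeric", Iphi = "array", nPixPhi = "integer",
  total = "matrix", qRangeAnisotropy = "numeric", intensityUnit = "character"
))

#' ParameterMaps: per-scan-point 2D maps of fitted structural parameters
#'
#' @slot spacing filament spacing a = 4*pi/q0, nm
#' @slot peakIntensity fitted I_p, counts/exposure
#' @slot anisotropy 1 - circular variance of I_norm(phi)
#' @slot orientation fiber orientation, degrees mod 180 (NA where undefined)
#' @slot totalIntensity counts/exposure
#' @slot valid logical (fit converged and profiles valid)
#' @slot atBound logical (spacing pinned at a fit bound)
#' @slot fitTable per-point data.frame of the five fit parameters
#' @slot provenance list (config hash, package version, stage)
#' @export
setClass("ParameterMaps", representation(
  spacing = "matrix", peakIntensity = "matrix", anisotropy = "matrix",
  orientation = "matrix", totalIntensity = "matrix", valid = "matrix",
  atBound = "matrix", fitTable = "data.frame", provenance = "list"
))

setValidity("ParameterMaps", function(object) {
  d <- dim(object@spacing)
  for (s in c("peakIntensity", "anisotropy", "orientation", "totalIntensity",
              "valid", "atBound"))
    if (!all(dim(slot(object, s)) == d))
      return(sprintf("slot '%s' does not match the map shape", s))
  TRUE
})

#' ClusterResult: k-means segmentation of the five-parameter maps
#'
#' Labels are relabeled deterministically so that cluster 1 has the lowest
#' mean filament spacing, ascending.
#'
#' @slot labels integer matrix in 1..k (NA at invalid points)
#' @slot centroids k x p matrix in standardized feature space
#' @slot featureNames character
#' @slot sizes integer per cluster
#' @slot spacingByCluster list of per-cluster spacing vectors (nm)
#' @slot totWithinSS total within-cluster sum of squares
#' @export
setClass("ClusterResult", representation(
  labels = "matrix", centroids = "matrix", featureNames = "character",
  sizes = "integer", spacingByCluster = "list", totWithinSS = "numeric"
))

#' RegionStats: summary statistics of a masked map region
#'
#' @slot mask logical matrix
#' @slot nPoints valid points in the region
#' @slot areaFraction fraction of valid map points inside the region
#' @slot meanAnisotropy,medianAnisotropy region anisotropy
#' @slot meanPeakIntensity counts/exposure
#' @slot modalSpacing KDE mode of the region spacing, nm (median when the
#'   region is too small for a density estimate)
#' @export
setClass("RegionStats", representation(
  mask = "matrix", nPoints = "integer", areaFraction = "numeric",
  meanAnisotropy = "numeric", medianAnisotropy = "numeric",
  meanPeakIntensity = "numeric", modalSpacing = "numeric"
))

#' SHGImage: a (synthetic) second-harmonic-generation micrograph
#'
#' @slot pixels grayscale float matrix
#' @slot pixelSize micrometers per pixel
#' @slot truth list of generator parameters (orientation deg, period um,
#'   undulation amplitude um, undulation wavelength um, noise sd), empty for
#'   external images
#' @export
setClass("SHGImage", representation(
  pixels = "matrix", pixelSize = "numeric", truth = "list"
))

#' PSDIndicatorResult: PSD cake-ratio undulation indicator of one micrograph
#'
#' @slot psd centered 2D power spectral density (DC bin zeroed)
#' @slot axes the two principal axis angles, degrees mod 180 (major first)
#' @slot axesUnstable logical; TRUE when the PSD is near-isotropic
#' @slot radialBins radial frequency bin centers, cycles/pixel
#' @slot cakeCurves named list of 1D cake curves, one per opening angle (deg)
#' @slot indicatorCurve ratio wide/narrow per radial bin
#' @slot indicatorScalar RMS of (indicatorCurve - 1) over the band
#' @slot band integer indices of the radial bins entering the RMS
#' @slot openingAngles c(narrow, wide), degrees (full sector width)
#' @export
setClass("PSDIndicatorResult", representation(
  psd = "matrix", axes = "numeric", axesUnstable = "logical",
  radialBins = "numeric", cakeCurves = "list", indicatorCurve = "numeric",
  indicatorScalar = "numeric", band = "integer", openingAngles = "numeric"
))

setValidity("PSDIndicatorResult", function(object) {
  if (length(object@axes) != 2L) return("axes must hold two angles")
  d <- abs(((object@axes[1] - object@axes[2] + 90) %% 180) - 90)
  if (abs(d - 90) > 1e-4) return("principal axes must be orthogonal")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "BeamGeometry", function(object) {
  cat("BeamGeometry\n")
  cat(sprintf("  E = %.4g keV (lambda = %.5g nm), I0 = %.4g ph/s, tau = %.4g s\n",
              object@photonEnergy, HC_KEV_NM / object@photonEnergy,
              object@fluxI0, object@exposure))
  cat(sprintf("  FWHM %.3g x %.3g um, mu/rho = %.5g cm^2/g\n",
              object@beamFwhm[1], object@beamFwhm[2], object@massAbsCoeff))
  cat(sprintf("  detector %d x %d px, pixel %.4g um, distance %.5g mm, center (%.2f, %.2f)\n",
              object@detectorShape[1], object@detectorShape[2],
              object@pixelSize, object@detectorDistance,
              object@beamCenter[1], object@beamCenter[2]))
})

setMethod("show", "ScanStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ScanStack: %d x %d frames (%d empty/line) of %d x %d px\n",
              d[1], d[2], sum(object@emptyFlags[1, ]), d[3], d[4]))
  cat(sprintf("  masked pixels: %d; ground truth: %s\n",
              sum(object@mask),
              if (is(object@truth, "GroundTruthFields")) object@truth@scenario else "none"))
})

setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@spacing)
  cat(sprintf("ParameterMaps: %d x %d scan points (%d valid, %d at fit bound)\n",
              d[1], d[2], sum(object@valid), sum(object@atBound, na.rm = TRUE)))
  sp <- object@spacing[object@valid]
  if (length(sp))
    cat(sprintf("  spacing %.2f-%.2f nm, median anisotropy %.3f\n",
                min(sp), max(sp),
                stats::median(object@anisotropy[object@valid], na.rm = TRUE)))
})

setMethod("show", "PSDIndicatorResult", function(object) {
  cat(sprintf("PSDIndicatorResult: scalar = %.4g (angles %g/%g deg, axes %.1f/%.1f deg%s)\n",
              object@indicatorScalar, object@openingAngles[1],
              object@openingAngles[2], object@axes[1], object@axes[2],
              if (object@axesUnstable) ", unstable" else ""))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d, sizes %s, tot within-SS %.4g\n",
              nrow(object@centroids), paste(object@sizes, collapse = "/"),
              object@totWithinSS))
})

## ---- accessors --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("wavelength", "BeamGeometry", function(object)
  HC_KEV_NM / object@photonEnergy)

#' @rdname accessors
#' @export
setMethod("qMap", "CoordinateMaps", function(object) object@qMap)

#' @rdname accessors
#' @export
setMethod("phiMap", "CoordinateMaps", function(object) object@phiMap)

#' @rdname accessors
#' @export
setMethod("thetaMap", "CoordinateMaps", function(object) object@thetaMap)

#' @rdname accessors
#' @export
setMethod("beamGeometry", "ScanStack", function(object) object@geometry)

#' @rdname accessors
#' @export
setMethod("detectorMask", "ScanStack", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("emptyFlags", "ScanStack", function(object) object@emptyFlags)

#' @rdname accessors
#' @export
setMethod("groundTruth", "ScanStack", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("scanShape", "ScanStack", function(object) {
  d <- dim(object@frames)
  c(ny = d[1], nxTotal = d[2])
})

#' @rdname accessors
#' @export
setMethod("getFrame", "ScanStack", function(object, iy, ix)
  object@frames[iy, ix, , ])

#' @rdname accessors
#' @export
setMethod("spacingMap", "ParameterMaps", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("anisotropyMap", "ParameterMaps", function(object) object@anisotropy)

#' @rdname accessors
#' @export
setMethod("orientationMapDeg", "ParameterMaps", function(object) object@orientation)

#' @rdname accessors
#' @export
setMethod("peakIntensityMap", "ParameterMaps", function(object) object@peakIntensity)

#' @rdname accessors
#' @export
setMethod("validMap", "ParameterMaps", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("atBoundMap", "ParameterMaps", function(object) object@atBound)

#' @rdname accessors
#' @export
setMethod("fitTable", "ParameterMaps", function(object) object@fitTable)

#' @rdname accessors
#' @export
setMethod("indicatorScalar", "PSDIndicatorResult", function(object)
  object@indicatorScalar)

#' @rdname accessors
#' @export
setMethod("indicatorCurve", "PSDIndicatorResult", function(object)
  object@indicatorCurve)

#' @rdname accessors
#' @export
setMethod("principalAxesOf", "PSDIndicatorResult", function(object) object@axes)
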