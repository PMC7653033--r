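#' X-ray wavelength from photon energy
#'
#' \eqn{\lambda = hc/E} with \eqn{hc = 1.23984} keV nm.
#'
#' @param energy photon energy, keV
#' @return wavelength in nm
#' @examples
#' wavelengthFromEnergy(13.0)   # 0.09537 nm
#' @export
wavelengthFromEnergy <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop("photon energy must be strictly positive")
  HC_KEV_NM / energy
}

#' Construct a BeamGeometry
#'
#' @param photonEnergy keV
#' @param fluxI0 photons/s
#' @param exposure s
#' @param beamFwhm c(horizontal, vertical) focal FWHM, micrometers
#' @param massAbsCoeff mu/rho, cm^2/g
#' @param detectorDistance mm
#' @param pixelSize micrometers
#' @param beamCenter c(row, col), fractional pixels
#' @param detectorShape c(rows, cols)
#' @return a \linkS4class{BeamGeometry}
#' @export
BeamGeometry <- function(photonEnergy = 13.0, fluxI0 = 1.57e12,
                         exposure = 0.010, beamFwhm = c(2.9, 1.4),
                         massAbsCoeff = 3.1582, detectorDistance = 990,
                         pixelSize = 75, beamCenter = NULL,
                         detectorShape = c(256L, 256L)) {
  detectorShape <- as.integer(detectorShape)
  if (is.null(beamCenter)) beamCenter <- (detectorShape + 1) / 2
  new("BeamGeometry", photonEnergy = photonEnergy, fluxI0 = fluxI0,
      exposure = exposure, beamFwhm = as.numeric(beamFwhm),
      massAbsCoeff = massAbsCoeff, detectorDistance = detectorDistance,
      pixelSize = pixelSize, beamCenter = as.numeric(beamCenter),
      detectorShape = detectorShape)
}

#' Reciprocal-space coordinate maps of a detector
#'
#' For each pixel, the scattering angle \eqn{\theta = \arctan(r/L)} (with
#' \eqn{r} the in-plane distance from the beam center and \eqn{L} the
#' sample-detector distance), the wavevector transfer
#' \eqn{q = (4\pi/\lambda)\sin(\theta/2)} and the azimuth
#' \eqn{\varphi = \mathrm{atan2}(\Delta row, \Delta col)} mapped to [0, 360)
#' degrees.
#'
#' @param geom a \linkS4class{BeamGeometry}
#' @return a \linkS4class{CoordinateMaps}
#' @export
coordinateMaps <- function(geom) {
  stopifnot(is(geom, "BeamGeometry"))
  validObject(geom)
  rows <- geom@detectorShape[1]; cols <- geom@detectorShape[2]
  px_mm <- geom@pixelSize / 1000
  dr <- (seq_len(rows) - geom@beamCenter[1]) * px_mm
  dc <- (seq_len(cols) - geom@beamCenter[2]) * px_mm
  DR <- matrix(dr, rows, cols)
  DC <- matrix(dc, rows, cols, byrow = TRUE)
  r <- sqrt(DR^2 + DC^2)
  theta <- atan(r / geom@detectorDistance)
  lambda <- wavelength(geom)
  q <- (4 * pi / lambda) * sin(theta / 2)
  phi <- (atan2(DR, DC) * 180 / pi) %% 360
  new("CoordinateMaps", qMap = q, phiMap = phi, thetaMap = theta)
}

#' Surface dose of a scanning diffraction exposure
#'
#' \eqn{D = I_0 \tau E (\mu/\rho) / (\Delta x \Delta y)}, with the photon
#' energy converted to joules, \eqn{\mu/\rho} to m^2/kg, and the focal FWHM
#' product \eqn{\Delta x \Delta y} (not a Gaussian-integral area) to m^2.
#'
#' @param geom a \linkS4class{BeamGeometry}
#' @return dose in Gy
#' @examples
#' xrayDose(BeamGeometry()) / 1e6   # ~2.54 MGy for the default geometry
#' @export
xrayDose <- function(geom) {
  stopifnot(is(geom, "BeamGeometry"))
  validObject(geom)
  keV_J <- 1.602176634e-16
  E_J <- geom@photonEnergy * keV_J
  mu_rho <- geom@massAbsCoeff * 0.1              # cm^2/g -> m^2/kg
  area <- prod(geom@beamFwhm * 1e-6)             # um^2 -> m^2
  if (area <= 0) stop("beam area must be strictly positive")
  geom@fluxI0 * geom@exposure * E_J * mu_rho / area
}

#' A beam geometry tuned for the synthetic detector
#'
#' Convenience constructor whose sample-detector distance is chosen so that
#' the acto-myosin (1,1) ring at \code{qRing} falls at half the detector
#' half-width (mid-detector radius), keeping the full 0.15-0.60 1/nm fit
#' window on the detector.
#'
#' @param detectorShape c(rows, cols)
#' @param pixelSize micrometers
#' @param qRing ring position to place at mid-radius, 1/nm
#' @param ... further arguments passed to \code{\link{BeamGeometry}}
#' @return a \linkS4class{BeamGeometry}
#' @export
syntheticGeometry <- function(detectorShape = c(256L, 256L), pixelSize = 75,
                              qRing = 0.32, ...) {
  detectorShape <- as.integer(detectorShape)
  lambda <- wavelengthFromEnergy(13.0)
  rHalf_mm <- min(detectorShape) / 4 * pixelSize / 1000
  # small-angle inversion of q = (4 pi / lambda) sin(atan(r/L)/2)
  theta <- 2 * asin(qRing * lambda / (4 * pi))
  distance <- rHalf_mm / tan(theta)
  BeamGeometry(detectorShape = detectorShape, pixelSize = pixelSize,
               detectorDistance = distance, ...)
}
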