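## Assembly of per-point fit results into parameter maps, and the
## distribution models used on spacing histograms (KDE mode, pseudo-Voigt).

#' Assemble parameter maps from per-point results
#'
#' Joins the peak-fit table, the orientation table and the total-intensity
#' matrix into a \linkS4class{ParameterMaps} with a shared validity mask.
#' Invalid points (failed fits) are propagated as NA, never zero-filled.
#'
#' @param fits data.frame from \code{\link{fitScan}}
#' @param orient data.frame from \code{\link{orientationMap}}
#' @param totals matrix of total intensities (from
#'   \code{\link{reduceScan}}'s \code{total} slot)
#' @param provenance optional list recorded with the maps
#' @return a \linkS4class{ParameterMaps}
#' @export
assembleMaps <- function(fits, orient, totals, provenance = list()) {
  ny <- max(fits$iy); nx <- max(fits$ix)
  if (!all(dim(totals) == c(ny, nx)))
    stop("totals shape does not match the fit grid")
  if (nrow(orient) != nrow(fits))
    stop("orientation and fit tables have different point counts")
  m <- function(col, tab = fits) {
    out <- matrix(NA_real_, ny, nx)
    out[cbind(tab$iy, tab$ix)] <- tab[[col]]
    out
  }
  valid <- matrix(FALSE, ny, nx)
  valid[cbind(fits$iy, fits$ix)] <- fits$converged
  atB <- matrix(FALSE, ny, nx)
  atB[cbind(fits$iy, fits$ix)] <- fits$atBound
  spacing <- m("a"); spacing[!valid] <- NA_real_
  new("ParameterMaps",
      spacing = spacing, peakIntensity = m("Ip"),
      anisotropy = m("anisotropy", orient),
      orientation = m("fiber", orient),
      totalIntensity = totals, valid = valid, atBound = atB,
      fitTable = fits,
      provenance = c(provenance,
                     list(package = "cardioSAXS",
                          version = as.character(utils::packageVersion("cardioSAXS")))))
}

#' Mode of a distribution by kernel density estimation
#'
#' Gaussian-kernel density on a 512-point grid spanning the data range plus
#' 3 bandwidths on each side; Silverman's rule of thumb by default.
#'
#' @param values numeric sample (at least 30 values)
#' @param bw bandwidth: a number, or a rule name accepted by
#'   \code{\link[stats]{density}} ("nrd0" = Silverman)
#' @return the mode location
#' @export
kdeMode <- function(values, bw = "nrd0") {
  values <- values[is.finite(values)]
  if (length(values) < 30L)
    stop("KDE mode requires at least 30 valid values")
  if (diff(range(values)) < .Machine$double.eps^0.5)
    return(values[1])
  h <- if (is.numeric(bw)) bw else
    switch(bw, nrd0 = stats::bw.nrd0(values), nrd = stats::bw.nrd(values),
           SJ = stats::bw.SJ(values), stop("unknown bandwidth rule"))
  d <- stats::density(values, bw = h, n = 512L,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  d$x[which.max(d$y)]
}

.pseudoVoigt <- function(x, amplitude, center, width, eta) {
  u <- (x - center) / width
  L <- 1 / (1 + u^2)
  G <- exp(-log(2) * u^2)
  amplitude * (eta * L + (1 - eta) * G)
}

#' Pseudo-Voigt fit of a histogram
#'
#' Least-squares fit of
#' \eqn{A [\eta L(x; x_0, \gamma) + (1-\eta) G(x; x_0, \gamma)]} with the
#' Lorentzian and Gaussian sharing the half width at half maximum
#' \eqn{\gamma} and the mixing parameter \eqn{\eta} constrained to [0, 1].
#'
#' @param mids histogram bin centers
#' @param counts histogram counts (at least 10 nonzero bins)
#' @return list: amplitude, center, width (HWHM), eta, residRms, converged
#' @export
pseudoVoigtFit <- function(mids, counts) {
  stopifnot(length(mids) == length(counts))
  if (sum(counts > 0) < 10L)
    stop("pseudo-Voigt fit requires at least 10 nonzero bins")
  cInit <- mids[which.max(counts)]
  aInit <- max(counts)
  above <- mids[counts >= aInit / 2]
  wInit <- max(diff(range(above)) / 2, diff(mids[1:2]) / 2)
  par0 <- c(amplitude = aInit, center = cInit, width = wInit, eta = 0.5)
  lower <- c(0, min(mids), diff(mids[1:2]) / 10, 0)
  upper <- c(Inf, max(mids), diff(range(mids)), 1)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) .pseudoVoigt(mids, p[1], p[2], p[3], p[4]) - counts,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  list(amplitude = p[["amplitude"]], center = p[["center"]],
       width = p[["width"]], eta = p[["eta"]],
       residRms = sqrt(mean(fit$fvec^2)),
       converged = fit$info %in% 1:3)
}

#' Summary statistics of a map region
#'
#' Means, medians and the modal spacing over valid points of a mask region.
#' The modal spacing uses the KDE mode when the region holds at least 30
#' valid points, the median otherwise.
#'
#' @param maps a \linkS4class{ParameterMaps}
#' @param mask logical matrix matching the map shape
#' @return a \linkS4class{RegionStats}
#' @export
regionAverage <- function(maps, mask) {
  stopifnot(is(maps, "ParameterMaps"))
  if (!all(dim(mask) == dim(maps@spacing)))
    stop("mask shape does not match the maps")
  sel <- mask & maps@valid
  n <- sum(sel)
  if (n == 0L) stop("empty region: no valid points under the mask")
  sp <- maps@spacing[sel]
  new("RegionStats", mask = mask, nPoints = as.integer(n),
      areaFraction = n / sum(maps@valid),
      meanAnisotropy = mean(maps@anisotropy[sel], na.rm = TRUE),
      medianAnisotropy = stats::median(maps@anisotropy[sel], na.rm = TRUE),
      meanPeakIntensity = mean(maps@peakIntensity[sel], na.rm = TRUE),
      modalSpacing = if (n >= 30L) kdeMode(sp) else
        stats::median(sp, na.rm = TRUE))
}
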