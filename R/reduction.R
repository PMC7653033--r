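## Reduction of raw detector frames to background-subtracted 1D profiles.

.binMeans <- function(values, bin, nBins) {
  ok <- !is.na(values) & bin >= 1L & bin <= nBins
  s <- rowsum(values[ok], bin[ok])
  n <- tabulate(bin[ok], nBins)
  out <- rep(NA_real_, nBins)
  out[as.integer(rownames(s))] <- s
  list(mean = out / ifelse(n > 0, n, NA_real_), n = n)
}

#' Per-line empty-frame background
#'
#' Pixel-wise mean over the empty-flagged frames of one scan line. These
#' frames were recorded without sample and capture the instrument background
#' (air scattering, beamstop halo) that is subtracted from every sample frame
#' of the same line.
#'
#' @param stack a \linkS4class{ScanStack}
#' @param lineIndex scan line (1-based)
#' @return background frame (matrix)
#' @export
lineBackground <- function(stack, lineIndex) {
  stopifnot(is(stack, "ScanStack"))
  flags <- stack@emptyFlags[lineIndex, ]
  if (!any(flags))
    stop(sprintf("scan line %d has no empty-flagged frames", lineIndex))
  idx <- which(flags)
  d <- dim(stack@frames)
  acc <- matrix(0, d[3], d[4])
  for (ie in idx) acc <- acc + stack@frames[lineIndex, ie, , ]
  acc / length(idx)
}

#' Subtract a background frame
#'
#' \code{frame - background} on unmasked pixels; masked pixels are set to NA
#' (flagged invalid). Negative values are retained, not clipped: clipping
#' would bias the fitted flat background upward.
#'
#' @param frame raw counts matrix
#' @param background matrix of the same shape
#' @param mask logical matrix, TRUE = masked; NULL for none
#' @return subtracted frame with NA at masked pixels
#' @export
subtractBackground <- function(frame, background, mask = NULL) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background shapes differ")
  out <- frame - background
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(frame))) stop("mask shape differs from frame")
    out[mask] <- NA_real_
  }
  out
}

#' Azimuthal (angular) average: I(q)
#'
#' Mean of unmasked pixel values per q bin. Bins without contributing pixels
#' are flagged invalid and never interpolated. The reported \code{qCenters}
#' are the mean q of the contributing pixels of each bin (the unbiased
#' abscissa for the subsequent peak fit); empty bins carry the nominal bin
#' center.
#'
#' @param frame intensity matrix (NA = invalid pixel)
#' @param maps a \linkS4class{CoordinateMaps}
#' @param mask logical matrix, TRUE = masked; NULL for none
#' @param qBreaks ascending bin edges, 1/nm (at least 9 edges / 8 bins)
#' @return a \linkS4class{RadialProfile}
#' @export
azimuthalAverage <- function(frame, maps, mask = NULL, qBreaks) {
  if (is.unsorted(qBreaks, strictly = TRUE) || length(qBreaks) < 9L)
    stop("qBreaks must be strictly ascending with at least 8 bins")
  v <- as.vector(frame)
  if (!is.null(mask)) v[as.vector(mask)] <- NA_real_
  qv <- as.vector(maps@qMap)
  bin <- findInterval(qv, qBreaks, rightmost.closed = TRUE)
  bin[bin == length(qBreaks)] <- 0L   # beyond the last edge
  nb <- length(qBreaks) - 1L
  bm <- .binMeans(v, bin, nb)
  if (all(bm$n == 0L))
    stop("all pixels are masked in the requested q range")
  qc <- .binMeans(ifelse(is.na(v), NA_real_, qv), bin, nb)$mean
  nominal <- (qBreaks[-1] + qBreaks[-length(qBreaks)]) / 2
  qc[is.na(qc)] <- nominal[is.na(qc)]
  new("RadialProfile",
      qCenters = qc, intensity = bm$mean,
      nPixels = as.integer(bm$n), valid = bm$n > 0L)
}

#' Azimuthal intensity profile I(phi) and its normalized form
#'
#' Mean unmasked intensity per phi bin, restricted to \code{qRange}
#' (the anisotropy annulus, 0.2-0.5 1/nm by default in the pipeline). The
#' normalized profile follows
#' \deqn{I_{norm}(\varphi) = (I(\varphi) - \min I(\varphi)) / \sum_\varphi I(\varphi)}
#' with min and sum over valid bins only; bins emptied by the beamstop are
#' flagged invalid and excluded from the normalization.
#'
#' To decouple the azimuthal profile from the radially non-uniform pixel
#' sampling caused by the beamstop shadow, the annulus is regrouped into
#' (phi bin) x (radial cell) cake cells: each cell contributes the mean of
#' its pixels, a phi bin is valid only when all of its radial cells are
#' covered (bins partially occluded by the beamstop are flagged invalid
#' rather than biased), and the bin intensity is the unweighted mean over
#' cells.
#'
#' @param frame intensity matrix (NA = invalid pixel)
#' @param maps a \linkS4class{CoordinateMaps}
#' @param mask logical matrix or NULL
#' @param qRange c(qmin, qmax), 1/nm
#' @param phiBins number of azimuthal bins over [0, 360)
#' @param nRadialCells radial sub-cells per phi bin used to equalize the
#'   radial sampling
#' @return an \linkS4class{AzimuthalProfile}
#' @export
azimuthalProfile <- function(frame, maps, mask = NULL, qRange = c(0.2, 0.5),
                             phiBins = 180L, nRadialCells = 12L) {
  phiBins <- as.integer(phiBins)
  v <- as.vector(frame)
  if (!is.null(mask)) v[as.vector(mask)] <- NA_real_
  qv <- as.vector(maps@qMap)
  v[qv < qRange[1] | qv > qRange[2]] <- NA_real_
  cellBin <- .cakeCellIndex(qv, as.vector(maps@phiMap), qRange, phiBins,
                            nRadialCells)
  if (all(is.na(v) | cellBin == 0L))
    stop("no unmasked pixels inside the requested q range")
  .finishAzimuthal(v, cellBin, phiBins, nRadialCells)
}

.cakeCellIndex <- function(qv, phiv, qRange, phiBins, nCells) {
  phiBin <- pmin(floor(phiv / 360 * phiBins) + 1L, phiBins)
  cell <- pmin(floor((qv - qRange[1]) / diff(qRange) * nCells) + 1L, nCells)
  idx <- phiBin + phiBins * (cell - 1L)
  idx[qv < qRange[1] | qv > qRange[2]] <- 0L
  idx
}

.finishAzimuthal <- function(v, cellBin, phiBins, nCells) {
  bm <- .binMeans(v, cellBin, phiBins * nCells)
  cellMeans <- matrix(bm$mean, phiBins, nCells)
  cellN <- matrix(bm$n, phiBins, nCells)
  nPix <- as.integer(rowSums(cellN))
  valid <- rowSums(cellN > 0L & !is.na(cellMeans)) == nCells
  I <- rowMeans(cellMeans)
  I[!valid] <- NA_real_
  norm <- rep(NA_real_, phiBins)
  s <- sum(I[valid])
  if (any(valid) && s > 0)
    norm[valid] <- (I[valid] - min(I[valid])) / s
  new("AzimuthalProfile",
      phiCenters = (seq_len(phiBins) - 0.5) * 360 / phiBins,
      intensity = I, normalized = norm, valid = valid)
}

#' Total scattered intensity of a frame
#'
#' Sum of unmasked pixel values, optionally restricted to a q range.
#'
#' @param frame intensity matrix (NA = invalid pixel)
#' @param mask logical matrix or NULL
#' @param maps a \linkS4class{CoordinateMaps}; required when qRange is given
#' @param qRange optional c(qmin, qmax), 1/nm
#' @return counts/exposure
#' @export
totalIntensity <- function(frame, mask = NULL, maps = NULL, qRange = NULL) {
  v <- as.vector(frame)
  if (!is.null(mask)) v[as.vector(mask)] <- NA_real_
  if (!is.null(qRange)) {
    if (is.null(maps)) stop("qRange restriction requires coordinate maps")
    qv <- as.vector(maps@qMap)
    v[qv < qRange[1] | qv > qRange[2]] <- NA_real_
  }
  sum(v, na.rm = TRUE)
}

#' Reduce a full scan to per-point 1D profiles
#'
#' For every sample (non-empty) scan point: subtract the per-line empty-frame
#' background, compute the radial profile I(q) on \code{qBins} linear bins
#' over the detector's q range, the azimuthal profile I(phi) inside
#' \code{qRangeAnisotropy}, and the total scattered intensity.
#'
#' @param stack a \linkS4class{ScanStack}
#' @param qBins number of linear q bins (default 200)
#' @param phiBins number of azimuthal bins (default 180, i.e. 2 deg)
#' @param qRangeAnisotropy q window of the azimuthal profile, 1/nm
#' @param nRadialCells radial sub-cells per phi bin (see
#'   \code{\link{azimuthalProfile}})
#' @return a \linkS4class{ReducedScan}
#' @export
reduceScan <- function(stack, qBins = 200L, phiBins = 180L,
                       qRangeAnisotropy = c(0.2, 0.5), nRadialCells = 12L) {
  stopifnot(is(stack, "ScanStack"))
  geom <- stack@geometry
  maps <- coordinateMaps(geom)
  maskv <- as.vector(stack@mask)
  qv <- as.vector(maps@qMap)
  phiv <- as.vector(maps@phiMap)

  qBreaks <- seq(0, max(qv) * (1 + 1e-9), length.out = qBins + 1L)
  qBin <- findInterval(qv, qBreaks, rightmost.closed = TRUE)
  qBin[maskv] <- 0L
  nPixQ <- tabulate(qBin, qBins)
  qUnmasked <- qv; qUnmasked[maskv] <- NA_real_
  qCenters <- .binMeans(qUnmasked, qBin, qBins)$mean
  nominal <- (qBreaks[-1] + qBreaks[-length(qBreaks)]) / 2
  qCenters[is.na(qCenters)] <- nominal[is.na(qCenters)]

  cellBin <- .cakeCellIndex(qv, phiv, qRangeAnisotropy, phiBins, nRadialCells)
  cellBin[maskv] <- 0L
  nPixPhi <- as.integer(rowSums(matrix(tabulate(cellBin,
                                                phiBins * nRadialCells),
                                       phiBins, nRadialCells)))

  d <- dim(stack@frames)
  ny <- d[1]
  sampleCols <- which(!stack@emptyFlags[1, ])
  nx <- length(sampleCols)
  Iq <- array(NA_real_, c(ny, nx, qBins))
  Iphi <- array(NA_real_, c(ny, nx, phiBins))
  total <- matrix(NA_real_, ny, nx)

  for (iy in seq_len(ny)) {
    bg <- as.vector(lineBackground(stack, iy))
    cols <- which(!stack@emptyFlags[iy, ])
    for (k in seq_along(cols)) {
      v <- as.vector(stack@frames[iy, cols[k], , ]) - bg
      v[maskv] <- NA_real_
      Iq[iy, k, ] <- .binMeans(v, qBin, qBins)$mean
      az <- .finishAzimuthal(v, cellBin, phiBins, nRadialCells)
      Iphi[iy, k, ] <- az@intensity
      total[iy, k] <- sum(v, na.rm = TRUE)
    }
  }

  new("ReducedScan",
      q = qCenters,
      Iq = Iq, nPixQ = as.integer(nPixQ),
      phi = (seq_len(phiBins) - 0.5) * 360 / phiBins,
      Iphi = Iphi, nPixPhi = nPixPhi,
      total = total, qRangeAnisotropy = as.numeric(qRangeAnisotropy),
      intensityUnit = "counts/exposure")
}

#' Extract one point's radial profile from a reduced scan
#'
#' @param reduced a \linkS4class{ReducedScan}
#' @param iy,ix scan indices (sample grid)
#' @return a \linkS4class{RadialProfile}
#' @export
radialProfileAt <- function(reduced, iy, ix) {
  I <- reduced@Iq[iy, ix, ]
  new("RadialProfile", qCenters = reduced@q, intensity = I,
      nPixels = reduced@nPixQ, valid = reduced@nPixQ > 0L & !is.na(I))
}

#' Extract one point's azimuthal profile from a reduced scan
#'
#' @param reduced a \linkS4class{ReducedScan}
#' @param iy,ix scan indices (sample grid)
#' @return an \linkS4class{AzimuthalProfile}
#' @export
azimuthalProfileAt <- function(reduced, iy, ix) {
  I <- reduced@Iphi[iy, ix, ]
  phiBins <- length(reduced@phi)
  valid <- !is.na(I)
  norm <- rep(NA_real_, phiBins)
  s <- sum(I[valid])
  if (any(valid) && s > 0)
    norm[valid] <- (I[valid] - min(I[valid])) / s
  new("AzimuthalProfile", phiCenters = reduced@phi, intensity = I,
      normalized = norm, valid = valid)
}
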