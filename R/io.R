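## Serialization: scan stacks and maps as multi-page 32-bit TIFF with JSON
## sidecars (geometry, flags and ground truth at full double precision).

.writeJson <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")

.mat <- function(x) {
  if (is.matrix(x)) return(x)   # jsonlite simplifies regular nested arrays
  matrix(unlist(x), nrow = length(x), byrow = TRUE)
}

#' Write a ScanStack to a directory
#'
#' Layout: \code{frames.tif} (one page per frame, line-major including empty
#' frames, scaled to [0, 1] by the stored \code{scale}), \code{mask.tif},
#' \code{meta.json} (geometry, empty flags, scale, step sizes, instrument
#' background, whether counts are integer) and \code{truth.json} (full
#' double-precision ground truth). The round trip through
#' \code{\link{readScanStack}} is lossless for integer-count stacks and for
#' all ground-truth fields.
#'
#' @param stack a \linkS4class{ScanStack}
#' @param dir output directory (created)
#' @return \code{dir}, invisibly
#' @export
writeScanStack <- function(stack, dir) {
  stopifnot(is(stack, "ScanStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack@frames)
  scale <- max(stack@frames, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) {
    k <- k + 1L
    pages[[k]] <- stack@frames[iy, ix, , ] / scale
  }
  tiff::writeTIFF(pages, file.path(dir, "frames.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(matrix(as.numeric(stack@mask), d[3], d[4]),
                  file.path(dir, "mask.tif"), bits.per.sample = 8L)
  g <- stack@geometry
  meta <- list(
    gridShape = d[1:2], frameShape = d[3:4], scale = scale,
    integerCounts = all(stack@frames == round(stack@frames)),
    emptyFlags = asplit(stack@emptyFlags, 1),
    stepSizes = stack@stepSizes, instrument = stack@instrument,
    geometry = list(photonEnergy = g@photonEnergy, fluxI0 = g@fluxI0,
                    exposure = g@exposure, beamFwhm = g@beamFwhm,
                    massAbsCoeff = g@massAbsCoeff,
                    detectorDistance = g@detectorDistance,
                    pixelSize = g@pixelSize, beamCenter = g@beamCenter,
                    detectorShape = g@detectorShape))
  .writeJson(meta, file.path(dir, "meta.json"))
  if (is(stack@truth, "GroundTruthFields")) {
    tr <- stack@truth
    .writeJson(list(
      scenario = tr@scenario,
      spacing = asplit(tr@spacing, 1), orientation = asplit(tr@orientation, 1),
      anisotropy = asplit(tr@anisotropy, 1),
      peakIntensity = asplit(tr@peakIntensity, 1),
      bgS = asplit(tr@bgS, 1), bgD = asplit(tr@bgD, 1),
      bgIbgr = asplit(tr@bgIbgr, 1),
      lesionMask = asplit(tr@lesionMask, 1),
      ringMask = asplit(tr@ringMask, 1)),
      file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' Read a ScanStack written by \code{\link{writeScanStack}}
#'
#' @param dir directory holding frames.tif, mask.tif, meta.json and
#'   optionally truth.json
#' @return a \linkS4class{ScanStack}
#' @export
readScanStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gs <- as.integer(meta$gridShape); fs <- as.integer(meta$frameShape)
  pages <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)
  frames <- array(0, c(gs, fs))
  k <- 0L
  for (iy in seq_len(gs[1])) for (ix in seq_len(gs[2])) {
    k <- k + 1L
    f <- pages[[k]] * meta$scale
    if (isTRUE(meta$integerCounts)) f <- round(f)
    frames[iy, ix, , ] <- f
  }
  mask <- tiff::readTIFF(file.path(dir, "mask.tif")) > 0.5
  gm <- meta$geometry
  geom <- BeamGeometry(photonEnergy = gm$photonEnergy, fluxI0 = gm$fluxI0,
                       exposure = gm$exposure, beamFwhm = gm$beamFwhm,
                       massAbsCoeff = gm$massAbsCoeff,
                       detectorDistance = gm$detectorDistance,
                       pixelSize = gm$pixelSize, beamCenter = gm$beamCenter,
                       detectorShape = gm$detectorShape)
  ef <- .mat(meta$emptyFlags) > 0
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    tj <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    new("GroundTruthFields",
        spacing = .mat(tj$spacing), orientation = .mat(tj$orientation),
        anisotropy = .mat(tj$anisotropy),
        peakIntensity = .mat(tj$peakIntensity),
        bgS = .mat(tj$bgS), bgD = .mat(tj$bgD), bgIbgr = .mat(tj$bgIbgr),
        lesionMask = .mat(tj$lesionMask) > 0,
        ringMask = .mat(tj$ringMask) > 0, scenario = tj$scenario)
  } else list()
  new("ScanStack", frames = frames, mask = mask, emptyFlags = ef,
      geometry = geom, stepSizes = as.numeric(meta$stepSizes),
      truth = truth, instrument = as.list(meta$instrument))
}

#' Write an SHG image as 32-bit TIFF with a JSON truth sidecar
#'
#' @param image an \linkS4class{SHGImage}
#' @param path output TIFF path; the sidecar is \code{path.json}
#' @return \code{path}, invisibly
#' @export
writeShgImage <- function(image, path) {
  stopifnot(is(image, "SHGImage"))
  lo <- min(image@pixels); hi <- max(image@pixels)
  scale <- max(hi - lo, .Machine$double.eps)
  tiff::writeTIFF((image@pixels - lo) / scale, path, bits.per.sample = 32L)
  .writeJson(c(list(pixelSize = image@pixelSize, offset = lo, scale = scale),
               image@truth),
             paste0(path, ".json"))
  invisible(path)
}

#' Read an SHG image (grayscale TIFF, optional sidecar)
#'
#' 8/16-bit or float TIFF; multi-channel images are averaged to grayscale.
#'
#' @param path TIFF path
#' @return an \linkS4class{SHGImage}
#' @export
readShgImage <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  sidecar <- paste0(path, ".json")
  truth <- list(); pixelSize <- NA_real_
  if (file.exists(sidecar)) {
    sj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    px <- px * sj$scale + sj$offset
    pixelSize <- sj$pixelSize
    truth <- sj[setdiff(names(sj), c("pixelSize", "offset", "scale"))]
  }
  new("SHGImage", pixels = px, pixelSize = pixelSize, truth = truth)
}

#' Export parameter maps as TIFFs, a combined CSV table and a provenance
#' sidecar
#'
#' One 32-bit TIFF per parameter (value-scaled; scales recorded in the
#' sidecar), an 8-bit validity mask, and \code{maps.csv} with the per-point
#' fit table joined with orientation, anisotropy and total intensity.
#'
#' @param maps a \linkS4class{ParameterMaps}
#' @param dir output directory (created)
#' @return \code{dir}, invisibly
#' @export
writeParameterMaps <- function(maps, dir) {
  stopifnot(is(maps, "ParameterMaps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- list(spacing = maps@spacing, peak_intensity = maps@peakIntensity,
                 anisotropy = maps@anisotropy, orientation = maps@orientation,
                 total_intensity = maps@totalIntensity)
  scales <- list()
  for (nm in names(layers)) {
    m <- layers[[nm]]
    lo <- min(m, na.rm = TRUE); hi <- max(m, na.rm = TRUE)
    sc <- max(hi - lo, .Machine$double.eps)
    m01 <- (m - lo) / sc
    m01[!is.finite(m01)] <- 0
    tiff::writeTIFF(m01, file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32L)
    scales[[nm]] <- list(offset = lo, scale = sc)
  }
  tiff::writeTIFF(matrix(as.numeric(maps@valid), nrow(maps@valid)),
                  file.path(dir, "valid.tif"), bits.per.sample = 8L)
  tab <- maps@fitTable
  idx <- cbind(tab$iy, tab$ix)
  tab$anisotropy <- maps@anisotropy[idx]
  tab$fiber_deg <- maps@orientation[idx]
  tab$total_intensity <- maps@totalIntensity[idx]
  utils::write.csv(tab, file.path(dir, "maps.csv"), row.names = FALSE)
  .writeJson(list(shape = dim(maps@spacing),
                  fitTable = maps@fitTable,
                  anisotropy = asplit(maps@anisotropy, 1),
                  orientation = asplit(maps@orientation, 1),
                  totalIntensity = asplit(maps@totalIntensity, 1)),
             file.path(dir, "maps.json"))
  .writeJson(c(maps@provenance, list(layerScales = scales)),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

#' Read parameter maps written by \code{\link{writeParameterMaps}}
#'
#' Reconstructs the \linkS4class{ParameterMaps} from the full-precision JSON
#' representation (the TIFF layers are for viewing).
#'
#' @param dir directory written by \code{\link{writeParameterMaps}}
#' @return a \linkS4class{ParameterMaps}
#' @export
readParameterMaps <- function(dir) {
  mj <- jsonlite::read_json(file.path(dir, "maps.json"),
                            simplifyVector = TRUE)
  pj <- jsonlite::read_json(file.path(dir, "provenance.json"),
                            simplifyVector = TRUE)
  toMat <- function(x) {
    if (is.matrix(x)) return(x)
    do.call(rbind, lapply(x, function(r) as.numeric(unlist(
      lapply(r, function(v) if (is.null(v)) NA_real_ else v)))))
  }
  fits <- as.data.frame(mj$fitTable)
  assembleMaps(fits,
               data.frame(iy = fits$iy, ix = fits$ix,
                          phi0 = NA_real_,
                          fiber = toMat(mj$orientation)[cbind(fits$iy, fits$ix)],
                          anisotropy = toMat(mj$anisotropy)[cbind(fits$iy, fits$ix)],
                          circVariance = NA_real_, defined = TRUE),
               toMat(mj$totalIntensity),
               provenance = pj[setdiff(names(pj), c("layerScales",
                                                    "package", "version"))])
}
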