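## Run configuration: YAML with documented defaults and strict unknown-key
## rejection.

#' Default run configuration
#'
#' All tunable constants of the pipeline with their defaults: the beam and
#' detector geometry, reduction binning, the fixed Gaussian width and spacing
#' bounds of the peak fit, the anisotropy q window, segmentation settings
#' (k, seed, 46.0 nm lesion threshold) and the SHG indicator angles.
#'
#' @return nested list of defaults
#' @export
defaultRunConfig <- function() {
  list(
    geometry = list(
      energy_keV = 13.0, flux = 1.57e12, exposure_s = 0.010,
      fwhm_um = c(2.9, 1.4), mu_rho_cm2_g = 3.1582,
      distance_mm = 988.2, pixel_um = 75,
      center_px = NULL, shape_px = c(256L, 256L)),
    simulate = list(
      scenario = "sham", grid = c(16L, 16L), n_empty = 20L,
      poisson = TRUE, seed = 1L, step_um = c(5, 5)),
    reduction = list(
      q_bins = 200L, phi_bins = 180L, q_range_anisotropy = c(0.2, 0.5)),
    fit = list(
      sigma = 0.034, a_bounds = c(30, 45), window = c(0.15, 0.60),
      weighted = FALSE),
    segmentation = list(
      k = 3L, seed = 1L, threshold_nm = 46.0, min_region_px = 4L),
    shg = list(
      angles_deg = c(5, 20), crop_px = 512L, window = TRUE,
      dc_exclusion = 3),
    paths = list(out = "cardiosaxs_out")
  )
}

.checkKeys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(cfg[[nm]]))
      .checkKeys(cfg[[nm]], ref[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (strict mode); unspecified fields take the
#' documented defaults of \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file, or NULL for pure defaults
#' @return the effective configuration list, with attribute \code{hash}
#'   (md5 of the canonical YAML dump) for provenance
#' @export
readRunConfig <- function(path = NULL) {
  ref <- defaultRunConfig()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  .checkKeys(cfg, ref)
  eff <- utils::modifyList(ref, cfg)
  attr(eff, "hash") <- configHash(eff)
  eff
}

#' MD5 hash of a configuration
#'
#' Hash of the canonical YAML serialization, recorded in every output's
#' provenance sidecar.
#'
#' @param cfg configuration list
#' @return character md5
#' @export
configHash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' BeamGeometry from the geometry block of a run configuration
#'
#' @param cfg configuration list (see \code{\link{defaultRunConfig}})
#' @return a \linkS4class{BeamGeometry}
#' @export
geometryFromConfig <- function(cfg) {
  g <- cfg$geometry
  BeamGeometry(photonEnergy = g$energy_keV, fluxI0 = g$flux,
               exposure = g$exposure_s, beamFwhm = g$fwhm_um,
               massAbsCoeff = g$mu_rho_cm2_g,
               detectorDistance = g$distance_mm, pixelSize = g$pixel_um,
               beamCenter = g$center_px,
               detectorShape = g$shape_px)
}
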