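## Stage orchestration. Each stage reads its inputs from the output
## directory of the previous stage, writes its artifacts plus a provenance
## sidecar, and returns its result invisibly. runPipeline() is the
## programmatic entry point; inst/scripts/cardiosaxs.R wraps it for shell
## use.

.provenance <- function(cfg, stage)
  list(stage = stage, configHash = configHash(cfg),
       package = "cardioSAXS",
       version = as.character(utils::packageVersion("cardioSAXS")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

.stageLog <- function(stage, msg, t0, logLevel) {
  if (identical(logLevel, "quiet")) return(invisible())
  message(sprintf("[%s] %s (%.2f s)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run pipeline stages
#'
#' Composable stages over a shared output directory:
#' \describe{
#'   \item{simulate}{phantom + forward model -> \code{scan/}}
#'   \item{reduce}{profiles I(q), I(phi), totals -> \code{profiles.csv}}
#'   \item{fit}{per-point peak fits -> \code{fits.csv}}
#'   \item{orient}{orientation/anisotropy -> \code{orientation.csv}}
#'   \item{maps}{assembled parameter maps -> \code{maps/}}
#'   \item{cluster}{k-means segmentation -> \code{clusters.csv},
#'     \code{cluster_spacing.csv}}
#'   \item{lesion}{threshold mask + region stats -> \code{lesion_mask.tif},
#'     \code{lesion_stats.json}}
#'   \item{dose}{dose of the configured geometry -> \code{dose.json}}
#'   \item{shg-indicator}{manifest CSV (image_path, group, heart_id) ->
#'     per-image/per-heart indicator CSVs + stats JSON}
#'   \item{all}{simulate through lesion, in order}
#' }
#' Rerunning with the same seed and configuration reproduces CSV outputs
#' byte-identically.
#'
#' @param stage one of the stage names above
#' @param config a configuration list from \code{\link{readRunConfig}} (or a
#'   YAML path)
#' @param outDir output directory (defaults to \code{config$paths$out})
#' @param manifest CSV path for stage "shg-indicator"
#' @param logLevel "info" or "quiet"
#' @return the stage result, invisibly (a named list for "all")
#' @export
runPipeline <- function(stage = c("all", "simulate", "reduce", "fit",
                                  "orient", "maps", "cluster", "lesion",
                                  "dose", "shg-indicator"),
                        config = NULL, outDir = NULL, manifest = NULL,
                        logLevel = "info") {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) readRunConfig(config)
         else if (is.null(config)) readRunConfig(NULL) else config
  if (is.null(outDir)) outDir <- cfg$paths$out
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (stage == "all") {
    res <- list()
    for (s in c("simulate", "reduce", "fit", "orient", "maps", "cluster",
                "lesion"))
      res[[s]] <- runPipeline(s, cfg, outDir, logLevel = logLevel)
    env <- .pipelineCache(outDir)
    rm(list = ls(env), envir = env)   # frames/profiles can be large
    return(invisible(res))
  }

  t0 <- as.numeric(Sys.time())
  env <- .pipelineCache(outDir)

  result <- switch(stage,
    "simulate" = {
      sc <- cfg$simulate
      truth <- makeDefaultPhantom(sc$grid, sc$scenario)
      geom <- geometryFromConfig(cfg)
      stack <- simulateScan(truth, geom, noiseSeed = sc$seed,
                            nEmpty = sc$n_empty, poisson = sc$poisson,
                            sigma = cfg$fit$sigma, stepSizes = sc$step_um,
                            qRangeAnisotropy = cfg$reduction$q_range_anisotropy)
      writeScanStack(stack, file.path(outDir, "scan"))
      env$stack <- stack
      .stageLog(stage, sprintf("%d x %d points simulated", sc$grid[1],
                               sc$grid[2]), t0, logLevel)
      stack
    },
    "reduce" = {
      stack <- .getStack(env, outDir)
      red <- reduceScan(stack, qBins = cfg$reduction$q_bins,
                        phiBins = cfg$reduction$phi_bins,
                        qRangeAnisotropy = cfg$reduction$q_range_anisotropy)
      env$reduced <- red
      .writeProfilesCsv(red, file.path(outDir, "profiles.csv"))
      .stageLog(stage, sprintf("%d points reduced", prod(dim(red@total))),
                t0, logLevel)
      red
    },
    "fit" = {
      red <- .getReduced(env, outDir, cfg)
      fc <- fitConfig(sigma = cfg$fit$sigma, aBounds = cfg$fit$a_bounds,
                      window = cfg$fit$window, weighted = cfg$fit$weighted)
      fits <- fitScan(red, fc)
      env$fits <- fits
      utils::write.csv(fits, file.path(outDir, "fits.csv"),
                       row.names = FALSE)
      .stageLog(stage, sprintf("%d/%d fits converged", sum(fits$converged),
                               nrow(fits)), t0, logLevel)
      fits
    },
    "orient" = {
      red <- .getReduced(env, outDir, cfg)
      om <- orientationMap(red)
      env$orient <- om
      utils::write.csv(om, file.path(outDir, "orientation.csv"),
                       row.names = FALSE)
      .stageLog(stage, sprintf("%d orientations (%d defined)", nrow(om),
                               sum(om$defined)), t0, logLevel)
      om
    },
    "maps" = {
      red <- .getReduced(env, outDir, cfg)
      fits <- .getFits(env, outDir, cfg)
      om <- .getOrient(env, outDir, cfg)
      maps <- assembleMaps(fits, om, red@total,
                           provenance = .provenance(cfg, "maps"))
      env$maps <- maps
      writeParameterMaps(maps, file.path(outDir, "maps"))
      .stageLog(stage, "maps assembled", t0, logLevel)
      maps
    },
    "cluster" = {
      maps <- .getMaps(env, outDir, cfg)
      sg <- cfg$segmentation
      cl <- kmeansSegment(maps, k = sg$k, seed = sg$seed)
      lab <- maps@fitTable[, c("iy", "ix")]
      lab$cluster <- cl@labels[cbind(lab$iy, lab$ix)]
      utils::write.csv(lab, file.path(outDir, "clusters.csv"),
                       row.names = FALSE)
      sp <- do.call(rbind, lapply(names(cl@spacingByCluster), function(nm)
        data.frame(cluster = nm, spacing_nm = cl@spacingByCluster[[nm]])))
      utils::write.csv(sp, file.path(outDir, "cluster_spacing.csv"),
                       row.names = FALSE)
      .stageLog(stage, sprintf("k = %d, sizes %s", sg$k,
                               paste(cl@sizes, collapse = "/")), t0, logLevel)
      cl
    },
    "lesion" = {
      maps <- .getMaps(env, outDir, cfg)
      sg <- cfg$segmentation
      les <- thresholdLesion(maps, threshold = sg$threshold_nm,
                             minRegionPx = sg$min_region_px)
      tiff::writeTIFF(matrix(as.numeric(les$mask), nrow(les$mask)),
                      file.path(outDir, "lesion_mask.tif"),
                      bits.per.sample = 8L)
      st <- function(r) if (is.null(r)) NULL else
        list(nPoints = r@nPoints, areaFraction = r@areaFraction,
             meanAnisotropy = r@meanAnisotropy,
             meanPeakIntensity = r@meanPeakIntensity,
             modalSpacing = r@modalSpacing)
      .writeJson(list(threshold_nm = sg$threshold_nm,
                      inside = st(les$inside), outside = st(les$outside),
                      provenance = .provenance(cfg, stage)),
                 file.path(outDir, "lesion_stats.json"))
      .stageLog(stage, sprintf("lesion area fraction %.3g",
                               if (is.null(les$inside)) 0 else
                                 les$inside@areaFraction), t0, logLevel)
      les
    },
    "dose" = {
      D <- xrayDose(geometryFromConfig(cfg))
      .writeJson(list(dose_Gy = D, dose_MGy = D / 1e6,
                      provenance = .provenance(cfg, stage)),
                 file.path(outDir, "dose.json"))
      .stageLog(stage, sprintf("D = %.3f MGy", D / 1e6), t0, logLevel)
      D
    },
    "shg-indicator" = {
      if (is.null(manifest)) stop("stage 'shg-indicator' needs a manifest CSV")
      man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
      need <- c("image_path", "group", "heart_id")
      if (!all(need %in% names(man)))
        stop("manifest must have columns image_path, group, heart_id")
      sc <- vapply(man$image_path, function(p)
        indicatorScalar(shgIndicator(readShgImage(p),
                                     crop = cfg$shg$crop_px,
                                     window = cfg$shg$window,
                                     narrowAngle = cfg$shg$angles_deg[1],
                                     wideAngle = cfg$shg$angles_deg[2],
                                     dcExclusionRadius = cfg$shg$dc_exclusion)),
        numeric(1))
      man$indicator <- unname(sc)
      utils::write.csv(man, file.path(outDir, "shg_indicators.csv"),
                       row.names = FALSE)
      gt <- groupIndicatorTest(man$indicator, man$group, man$heart_id)
      utils::write.csv(gt$perHeart, file.path(outDir, "shg_per_heart.csv"),
                       row.names = FALSE)
      .writeJson(list(t = gt$test$t, dof = gt$test$dof, p = gt$test$p,
                      n_pairs = gt$test$n, groups = gt$groups,
                      provenance = .provenance(cfg, stage)),
                 file.path(outDir, "shg_stats.json"))
      .stageLog(stage, sprintf("%d images, p = %.4g", nrow(man),
                               gt$test$p), t0, logLevel)
      gt
    })

  .writeJson(.provenance(cfg, stage),
             file.path(outDir, paste0("provenance_", gsub("-", "_", stage),
                                      ".json")))
  invisible(result)
}

## per-outDir in-session cache so `all` composes stages without re-reading;
## stages fall back to on-disk artifacts when run individually.
.pipelineCaches <- new.env(parent = emptyenv())
.pipelineCache <- function(outDir) {
  key <- normalizePath(outDir, mustWork = FALSE)
  if (is.null(.pipelineCaches[[key]]))
    .pipelineCaches[[key]] <- new.env(parent = emptyenv())
  .pipelineCaches[[key]]
}

.getStack <- function(env, outDir) {
  if (!is.null(env$stack)) return(env$stack)
  readScanStack(file.path(outDir, "scan"))
}

.getReduced <- function(env, outDir, cfg) {
  if (!is.null(env$reduced)) return(env$reduced)
  red <- reduceScan(.getStack(env, outDir), qBins = cfg$reduction$q_bins,
                    phiBins = cfg$reduction$phi_bins,
                    qRangeAnisotropy = cfg$reduction$q_range_anisotropy)
  env$reduced <- red
  red
}

.getFits <- function(env, outDir, cfg) {
  if (!is.null(env$fits)) return(env$fits)
  p <- file.path(outDir, "fits.csv")
  if (file.exists(p)) return(utils::read.csv(p))
  runPipeline("fit", cfg, outDir, logLevel = "quiet")
  env$fits
}

.getOrient <- function(env, outDir, cfg) {
  if (!is.null(env$orient)) return(env$orient)
  p <- file.path(outDir, "orientation.csv")
  if (file.exists(p)) return(utils::read.csv(p))
  runPipeline("orient", cfg, outDir, logLevel = "quiet")
  env$orient
}

.getMaps <- function(env, outDir, cfg) {
  if (!is.null(env$maps)) return(env$maps)
  runPipeline("maps", cfg, outDir, logLevel = "quiet")
  env$maps
}

.writeProfilesCsv <- function(red, path) {
  d <- dim(red@Iq)
  grid <- expand.grid(ix = seq_len(d[2]), iy = seq_len(d[1]))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    iy <- grid$iy[k]; ix <- grid$ix[k]
    data.frame(iy = iy, ix = ix, q = red@q, Iq = red@Iq[iy, ix, ])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}
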