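# Umbrella pipeline: tissue labels -> interface mesh -> motion-censored
# surface GLM -> mesh-seeded tractography -> two-stage classification ->
# tract metrics, with every intermediate persisted and a structured
# report.  Exit states distinguish the three dataset-exclusion modes:
# "dataset rejected (motion)", "no activation", "no tracks".

#' Default pipeline configuration
#'
#' All stage parameters with their protocol defaults: mesh spacing 0.9
#' mm, triangle decimation 0.5, projection offset +1 mm / seeding shrink
#' -1 mm, 8 mm FWHM surface smoothing, FD threshold 0.9 mm with dataset
#' rejection at 20 censored frames, 120 s high-pass, FWE alpha 0.05,
#' 0.2 mm step, 1 mm minimum curvature radius, FA cutoff 0.1, 20000
#' target tracks, 3 and 20 clustering attempts with weights 0.49/1.69,
#' 20 dispersion node-positions.
#'
#' @return named list of parameters.
#' @export
defaultPipelineConfig <- function() {
  list(
    spacing = 0.9, decimate = 0.5, projectOffset = 1, seedShrink = 1,
    fwhm = 8, fdThreshold = 0.9, maxRejected = 20L, highpass = 120,
    alpha = 0.05, step = 0.2, minRadius = 1, faCutoff = 0.1,
    maxLength = 250, target = 20000L, maxAttemptsFactor = 100L,
    attemptsStage1 = 3L, attemptsStage2 = 20L, maxIter = 1000L,
    dispersionPositions = 20L, headRadius = 50, TR = 3,
    blockDuration = 30, nBlocks = 9L, seed = 1L,
    clusterSelection = "all", impairedSide = "left",
    # file paths (set by the caller)
    seg = NULL, epi = NULL, motion = NULL, peaks = NULL, fa = NULL,
    md = NULL, rois = NULL, outDir = NULL)
}

#' Build a pipeline configuration
#'
#' Starts from [defaultPipelineConfig()] and overrides named entries;
#' unknown keys are rejected.
#'
#' @param ... named overrides.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- defaultPipelineConfig()
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Read / write pipeline configuration JSON
#' @param path .json file.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname readPipelineConfig
#' @param cfg configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(cfg, path) {
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))], path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# FNV-1a hash of a serialised object, for provenance stamping
configHash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(
    x[!vapply(x, is.null, logical(1))], auto_unbox = TRUE, digits = NA)))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full surface-seeded tractography pipeline
#'
#' Executes the stages in the published order - segmentation cleanup,
#' interface-mesh extraction and decimation, motion censoring, surface
#' projection and smoothing, vertex-wise GLM with FWE thresholding and
#' cluster filtering (per scan, OR-combined), mesh-seeded tractography
#' through the supplied direction field under the anatomical mesh
#' constraint, hemisphere split and corticomotor/thalamocortical
#' classification, and tract metrics (dispersion, superior/inferior
#' FA/MD, asymmetry indices).  Each intermediate is written under
#' \code{cfg$outDir}; the returned report (also written as report.json)
#' carries counts from every stage, the config hash and the seed.
#'
#' @param cfg configuration from [pipelineConfig()] with file paths set:
#'   \code{seg} (label NIfTI, labels background/GM/WM as 0/1/2),
#'   \code{epi} (character vector of 4D NIfTI scans), \code{motion}
#'   (matching .par files), \code{peaks} (4D direction NIfTI),
#'   \code{fa}, \code{md} (scalar NIfTI), \code{rois} (JSON from
#'   [writePlanarROIs()]), \code{outDir}.
#' @return report list with \code{status} ("ok", "dataset rejected
#'   (motion)", "no activation" or "no tracks") and per-stage entries.
#' @export
runPipeline <- function(cfg) {
  for (key in c("seg", "epi", "motion", "peaks", "fa", "rois", "outDir"))
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'")
  for (f in c(cfg$seg, cfg$epi, cfg$motion, cfg$peaks, cfg$fa, cfg$md,
              cfg$rois))
    if (!file.exists(f)) stop("input not found before pipeline start: ", f)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(configHash = configHash(cfg), seed = cfg$seed)
  set.seed(cfg$seed)

  # -- mesh stage
  segIn <- readNiftiVolume(cfg$seg)
  seg <- LabelVolume(segIn$data, segIn$affine,
                     labels = c(background = 0L, GM = 1L, WM = 2L))
  seg <- cleanWMSegmentation(seg)
  mesh <- decimateMesh(extractInterfaceMesh(seg, spacing = cfg$spacing),
                       fraction = cfg$decimate)
  writeGifti(mesh, file.path(cfg$outDir, "interface_mesh.gii"))
  report$mesh <- list(nVertices = nVertices(mesh),
                      nTriangles = nTriangles(mesh),
                      meanEdge = meanEdgeLength(mesh))

  # -- motion censoring across all scans
  traces <- lapply(cfg$motion, readMotionPar, TR = cfg$TR)
  fds <- lapply(traces, framewiseDisplacement, headRadius = cfg$headRadius)
  cens <- censorFrames(fds, threshold = cfg$fdThreshold,
                       maxRejected = cfg$maxRejected)
  report$censoring <- list(nRejected = cens$nRejected)
  if (cens$status == "rejected") {
    report$status <- "dataset rejected (motion)"
    jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(report)
  }

  # -- surface fMRI per scan, OR-combined mask
  design <- alternatingBlockDesign(cfg$nBlocks, cfg$blockDuration, cfg$TR)
  masks <- list()
  report$fmri <- list()
  for (s in seq_along(cfg$epi)) {
    epiIn <- readNiftiVolume(cfg$epi[[s]])
    series <- projectToSurface(epiIn$data, epiIn$affine, mesh,
                               offset = cfg$projectOffset, TR = cfg$TR)
    series@keptMask <- cens$keptMasks[[s]]
    series <- smoothOnSurface(series, fwhm = cfg$fwhm)
    X <- buildDesign(design, series@frameTimes, series@keptMask,
                     traces[[s]])
    stats <- fitGLM(series, X)
    mask <- thresholdFWE(stats, alpha = cfg$alpha)
    mask <- filterClusters(mask, mesh, selection = cfg$clusterSelection)
    masks[[s]] <- mask
    report$fmri[[s]] <- list(nSignificant = sum(mask),
                             arCoef = stats@arCoef)
  }
  seedMask <- Reduce(combineTaskMasks, masks)
  writeLines(as.character(as.integer(seedMask)),
             file.path(cfg$outDir, "seed_mask.txt"))
  report$seedVertices <- sum(seedMask)
  if (!any(seedMask)) {
    report$status <- "no activation"
    jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(report)
  }

  # -- tractography
  rois <- readPlanarROIs(cfg$rois)
  faIn <- readNiftiVolume(cfg$fa)
  peaksIn <- readNiftiVolume(cfg$peaks)
  field <- peakField(peaksIn$data, peaksIn$affine, interpolate = TRUE)
  seedMesh <- offsetMesh(mesh, -cfg$seedShrink)
  tk <- generateTracks(seedMesh, seedMask, field, faIn$data, faIn$affine,
                       rois, target = cfg$target,
                       maxAttempts = cfg$maxAttemptsFactor * cfg$target,
                       constraint = mesh, step = cfg$step,
                       minRadius = cfg$minRadius, faCutoff = cfg$faCutoff,
                       maxLength = cfg$maxLength,
                       stopROI = rois$brainstem)
  report$tracking <- list(accepted = tk$accepted, attempted = tk$attempted)
  if (tk$status == "no tracks found") {
    report$status <- "no tracks"
    jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(report)
  }
  writeTck(tk$tractogram, file.path(cfg$outDir, "tracks.tck"))

  # -- classification
  brainCentre <- colMeans(voxelToWorld(which(brainMask(seg), arr.ind = TRUE) - 1L,
                                       seg@affine))
  hemis <- splitHemispheres(tk$tractogram, rois$thalamus, rois$plic,
                            attempts = cfg$attemptsStage1)
  mdIn <- if (!is.null(cfg$md)) readNiftiVolume(cfg$md) else NULL
  report$tracts <- list()
  metricsRows <- NULL
  for (h in c("left", "right")) {
    hemi <- hemis[[h]]
    if (nTracks(hemi) == 0L) next
    if (nTracks(hemi) >= 2L) {
      cl <- classifyMotorThalamic(hemi, rois$thalamus, rois$plic,
                                  rois$brainstem, brainCentre,
                                  attempts = cfg$attemptsStage2)
      labs <- attr(cl, "labelNames")[cl@labels]
      report$tracts[[h]] <- list(cost = cl@cost,
                                 iterations = cl@iterations,
                                 nClamped = sum(attr(cl, "clamped")))
    } else labs <- "corticomotor"
    for (cls in unique(labs)) {
      tract <- subsetTracks(hemi, labs == cls)
      writeTck(tract, file.path(cfg$outDir,
                                paste0(h, "_", cls, ".tck")))
      disp <- if (nTracks(tract) >= 2L)
        tractDispersion(tract, nPositions = cfg$dispersionPositions)
      else NA_real_
      segs <- suppressWarnings(splitAtMidbrain(tract, rois$thalamus))
      for (part in c("superior", "inferior")) {
        tt <- segs[[part]]
        if (nTracks(tt) == 0L) next
        faMean <- as.numeric(suppressWarnings(
          sampleScalar(tt, faIn$data, faIn$affine)))
        mdMean <- if (!is.null(mdIn)) as.numeric(suppressWarnings(
          sampleScalar(tt, mdIn$data, mdIn$affine))) else NA_real_
        metricsRows <- rbind(metricsRows, data.frame(
          hemisphere = h, class = cls, segment = part,
          nTracks = nTracks(tract), dispersion = disp,
          meanFA = faMean, meanMD = mdMean))
      }
    }
  }
  report$metrics <- metricsRows
  if (!is.null(metricsRows))
    utils::write.csv(metricsRows, file.path(cfg$outDir, "metrics.csv"),
                     row.names = FALSE)

  # asymmetry indices: A and I are the hemispheres opposite the able and
  # impaired hands; with the impaired HAND on cfg$impairedSide, the able
  # hand is contralateral, so the A hemisphere carries the same side
  # name as the impaired hand
  if (!is.null(metricsRows)) {
    ai <- NULL
    for (cls in unique(metricsRows$class))
      for (part in c("superior", "inferior"))
        for (metric in c("meanFA", "meanMD")) {
          rows <- metricsRows[metricsRows$class == cls &
                              metricsRows$segment == part, ]
          if (nrow(rows) == 2L) {
            aSide <- cfg$impairedSide      # contralateral to the able hand
            iSide <- setdiff(c("left", "right"), aSide)
            a <- rows[rows$hemisphere == aSide, metric]
            i <- rows[rows$hemisphere == iSide, metric]
            if (length(a) == 1L && length(i) == 1L &&
                is.finite(a) && is.finite(i) && a + i != 0)
              ai <- rbind(ai, data.frame(class = cls, segment = part,
                                         metric = sub("mean", "", metric),
                                         AI = asymmetryIndex(a, i)))
          }
        }
    report$asymmetry <- ai
  }
  report$status <- "ok"
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}
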