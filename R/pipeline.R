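#' @include AllClasses.R stack_io.R phantom.R preprocess.R
#' @include vessel_morphometry.R plaque_morphometry.R signal_quality.R
#' @include longitudinal_stats.R
NULL

.runSummary <- function(outDir, command, inputs, config, seed = NULL) {
  summary <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    config = config,
    seed = seed,
    versions = list(
      morph3p = as.character(utils::packageVersion("morph3p")),
      R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Generate and write a phantom dataset
#'
#' Writes vessel.tif, plaque.tif, vessel_truth.tif, plaque_truth.tif and
#' truth.json (analytic per-vessel and per-plaque ground truth) to
#' \code{outDir}.
#'
#' @param outDir output directory (created if missing)
#' @param spec a \linkS4class{PhantomSpec}; default
#'   \code{defaultPhantomSpec(seed)}
#' @param seed seed used when \code{spec} is NULL
#' @return invisibly, the phantom list from \code{\link{generatePhantom}}
#' @export
runPhantom <- function(outDir, spec = NULL, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- defaultPhantomSpec(seed = seed)
  ph <- generatePhantom(spec)
  writeStack(ph$vessel, file.path(outDir, "vessel.tif"))
  writeStack(ph$plaque, file.path(outDir, "plaque.tif"))
  writeMask(ph$vesselTruth, file.path(outDir, "vessel_truth.tif"))
  writeMask(ph$plaqueTruth, file.path(outDir, "plaque_truth.tif"))
  truth <- list(
    shape = spec@shape,
    spacing = c(dx = spec@spacing@dx, dy = spec@spacing@dy,
                dz = spec@spacing@dz),
    vessels = lapply(spec@vessels, function(v) list(
      radius = v@radius, length = truthLength(v),
      tortuosity = truthTortuosity(v), intensity = v@intensity)),
    plaques = lapply(spec@plaques, function(p) list(
      center = p@center, radius = p@radius,
      volume = 4 / 3 * pi * p@radius^3, intensity = p@intensity)),
    attenuationLength = spec@attenuationLength,
    backgroundLevel = spec@backgroundLevel,
    noiseGaussianSD = spec@noiseGaussianSD,
    crosstalkAlpha = spec@crosstalkAlpha,
    seed = spec@seed)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .runSummary(outDir, "phantom", list(), list(), seed = spec@seed)
  invisible(ph)
}

#' Preprocess a two-channel acquisition
#'
#' Runs the fixed chain (equalize, crosstalk-correct, dura-remove,
#' normalize, denoise) on both channels, assesses motion on the raw vessel
#' channel, and writes vessel_proc.tif, plaque_proc.tif and
#' motion_report.csv.
#'
#' @param vesselPath,plaquePath input TIFF stacks
#' @param thgPath optional THG stack enabling "from-thg" dura removal
#' @param outDir output directory
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param config settings list
#' @return invisibly, list of the processed stacks and the
#'   \linkS4class{MotionReport}
#' @export
runPreprocess <- function(vesselPath, plaquePath, thgPath = NULL,
                          outDir = ".", spacing = voxelSpacing(),
                          config = defaultConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  vessel <- readStack(vesselPath, spacing, "vessel")
  plaque <- readStack(plaquePath, spacing, "plaque")
  thg <- if (!is.null(thgPath)) readStack(thgPath, spacing, "thg")
  motion <- assessMotion(vessel,
                         nStructures = config$n_motion_structures)
  boundary <- if (is.null(thg)) 0L else "from-thg"
  vesselP <- preprocessStack(vessel, other = plaque, thg = thg,
                             duraBoundary = boundary, config = config)
  plaqueP <- preprocessStack(plaque, other = vessel, thg = thg,
                             duraBoundary = boundary, config = config)
  writeStack(vesselP, file.path(outDir, "vessel_proc.tif"))
  writeStack(plaqueP, file.path(outDir, "plaque_proc.tif"))
  writeTable(motionShifts(motion), file.path(outDir, "motion_report.csv"))
  .runSummary(outDir, "preprocess",
              list(vessel = vesselPath, plaque = plaquePath,
                   thg = thgPath), config)
  invisible(list(vessel = vesselP, plaque = plaqueP, motion = motion))
}

#' Vascular morphometry of a stack or imported mask
#'
#' Segments (global Otsu baseline) unless a mask is supplied, optionally
#' QCs the mask against a reference annotation (Dice), then computes the
#' segment metrics. Writes segments.csv, summary.json and skeleton.tif.
#'
#' @param maskPath externally produced binary mask TIFF (preferred input)
#' @param stackPath raw stack TIFF, segmented with the baseline Otsu
#'   segmenter when \code{maskPath} is NULL
#' @param truthPath optional reference mask for Dice QC
#' @param outDir output directory
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param config settings list
#' @return invisibly, the \linkS4class{SegmentSet}
#' @export
runVessels <- function(maskPath = NULL, stackPath = NULL, truthPath = NULL,
                       outDir = ".", spacing = voxelSpacing(),
                       config = defaultConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(maskPath) && is.null(stackPath))
    stop("supply a mask or a stack")
  mask <- if (!is.null(maskPath)) {
    readMask(maskPath, spacing)
  } else {
    baselineSegment(readStack(stackPath, spacing, "vessel"),
                    minComponentVoxels = config$min_component_voxels)
  }
  dice <- NULL
  if (!is.null(truthPath)) {
    dice <- diceCoefficient(mask, readMask(truthPath, spacing),
                            threshold = config$dice_threshold)
    if (!is.null(attr(dice, "flag")))
      .logMsg("Dice ", signif(dice, 3), " below QC threshold: ",
              attr(dice, "flag"))
  }
  segset <- vesselMorphometry(mask, minNodes = config$min_segment_nodes)
  writeTable(segmentMetrics(segset), file.path(outDir, "segments.csv"))
  writeMask(skeletonize(mask), file.path(outDir, "skeleton.tif"))
  jsonlite::write_json(
    list(totalVolume = totalVolume(segset),
         nVesselVoxels = nVesselVoxels(segset),
         voxelVolume = segset@voxelVolume,
         nSegments = length(segments(segset)),
         dice = if (is.null(dice)) NULL else as.numeric(dice),
         diceFlagged = if (is.null(dice)) NULL else
           !is.null(attr(dice, "flag"))),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, null = "null")
  .runSummary(outDir, "vessels",
              list(mask = maskPath, stack = stackPath, truth = truthPath),
              config)
  invisible(segset)
}

#' Plaque morphometry of a plaque-channel stack
#'
#' Segments plaques (multilevel Otsu or an imported manual mask), applies
#' the area filter, measures per-plaque volume, equivalent radius, centroid
#' and nearest-vessel distance, and writes plaques.csv plus
#' plaque_labels.tif.
#'
#' @param stackPath plaque-channel TIFF (semi_auto mode)
#' @param vesselMaskPath optional vessel mask for nearest-vessel distances
#' @param mode "semi_auto" or "manual"
#' @param manualMaskPath mask TIFF for manual mode
#' @param outDir output directory
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param config settings list
#' @return invisibly, the plaque morphometry data.frame
#' @export
runPlaques <- function(stackPath = NULL, vesselMaskPath = NULL,
                       mode = c("semi_auto", "manual"),
                       manualMaskPath = NULL, outDir = ".",
                       spacing = voxelSpacing(), config = defaultConfig()) {
  mode <- match.arg(mode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  labels <- if (mode == "manual") {
    segmentPlaques(mode = "manual_mask",
                   manual = readMask(manualMaskPath, spacing))
  } else {
    segmentPlaques(readStack(stackPath, spacing, "plaque"),
                   mode = "semi_auto", minObjectPx = config$min_object_px)
  }
  labels <- filterSmallRegions(labels, minArea = config$min_plaque_area,
                               mode = config$plaque_area_mode)
  vmask <- if (!is.null(vesselMaskPath)) readMask(vesselMaskPath, spacing)
  tab <- plaqueMorphometry(labels, vesselMask = vmask)
  writeTable(tab, file.path(outDir, "plaques.csv"))
  writeMask(labels, file.path(outDir, "plaque_labels.tif"))
  .runSummary(outDir, "plaques",
              list(stack = stackPath, vesselMask = vesselMaskPath,
                   manualMask = manualMaskPath, mode = mode), config)
  invisible(tab)
}

#' Depth-resolved image-quality metrics
#'
#' Writes depth_profile.csv (per-plane signal strength and SBR).
#'
#' @param stackPath input TIFF stack
#' @param outDir output directory
#' @param spacing a \linkS4class{VoxelSpacing}
#' @param config settings list
#' @return invisibly, the depth-profile data.frame
#' @export
runQuality <- function(stackPath, outDir = ".", spacing = voxelSpacing(),
                       config = defaultConfig()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stack <- readStack(stackPath, spacing, "vessel")
  prof <- depthProfile(stack, topFraction = config$top_fraction,
                       nExtreme = config$n_extreme)
  writeTable(prof, file.path(outDir, "depth_profile.csv"))
  .runSummary(outDir, "quality", list(stack = stackPath), config)
  invisible(prof)
}

#' Compare the metric tables of two session runs
#'
#' Consumes segments.csv, plaques.csv and summary.json from two
#' \code{\link{runVessels}} / \code{\link{runPlaques}} output directories
#' and writes comparison.csv.
#'
#' @param dir1,dir2 session output directories
#' @param outDir output directory
#' @return invisibly, the comparison data.frame
#' @export
runCompare <- function(dir1, dir2, outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  readSession <- function(d) {
    seg <- readTable(file.path(d, "segments.csv"))
    out <- list(diameter = seg$diameter, length = seg$length,
                tortuosity = seg$tortuosity[!is.na(seg$tortuosity)],
                ivd = seg$ivd[!is.na(seg$ivd)])
    pf <- file.path(d, "plaques.csv")
    if (file.exists(pf)) {
      pl <- readTable(pf)
      out$plaqueRadius <- pl$equivalentRadius
      out$plaqueVolume <- sum(pl$volume)
    }
    sf <- file.path(d, "summary.json")
    if (file.exists(sf))
      out$vesselVolume <- jsonlite::read_json(sf)$totalVolume
    out
  }
  cmp <- compareSessions(readSession(dir1), readSession(dir2))
  writeTable(cmp, file.path(outDir, "comparison.csv"))
  .runSummary(outDir, "compare", list(s1 = dir1, s2 = dir2), list())
  invisible(cmp)
}
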