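## End-to-end orchestration: simulate -> segment -> variance/UD -> combine
## -> categorize -> overlap, with every stage artifact written to disk and a
## manifest that makes reruns verifiable.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the corridor
#' analysis design: window 17, margin 7, 18 m location error, 1 km cells,
#' 100 km migration threshold, wind power class >= 3, turbine height
#' >= 100 m.
#'
#' @param seed master RNG seed.
#' @param outdir output directory for stage artifacts.
#' @param simulate generate synthetic inputs (TRUE) or read them from
#'   `tracksCsv` / `turbinesPath` / `wpcPath`.
#' @param nIndividuals synthetic individuals when simulating.
#' @param window,margin,locErrorSd,cellSize,substeps see [bridgeParams()].
#' @param minKm,minDailyKm,maxStopoverDays see [findMigrationSegments()].
#' @param padHours see [padSegment()].
#' @param mode categorization mode, see [categorizeUD()].
#' @param minClass,minHeightM see [wpcOverlap()] and [countTurbines()].
#' @param nClusters,turbinesPerCluster synthetic turbine field size.
#' @param tracksCsv,turbinesPath,wpcPath input paths when `simulate = FALSE`.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, outdir = tempfile("corridorUD-"),
                           simulate = TRUE, nIndividuals = 3L,
                           window = 17, margin = 7, locErrorSd = 18,
                           cellSize = 1000, substeps = 10,
                           minKm = 100, minDailyKm = 20, maxStopoverDays = 1,
                           padHours = 24, mode = "count",
                           minClass = 3, minHeightM = 100,
                           nClusters = 6L, turbinesPerCluster = 15L,
                           tracksCsv = NULL, turbinesPath = NULL,
                           wpcPath = NULL) {
  bp <- bridgeParams(window = window, margin = margin,
                     locErrorSd = locErrorSd, cellSize = cellSize,
                     substeps = substeps)
  if (!mode %in% c("count", "volume")) stop("mode must be count or volume")
  if (!simulate && (is.null(tracksCsv) || is.null(turbinesPath) ||
                    is.null(wpcPath)))
    stop("simulate = FALSE requires tracksCsv, turbinesPath and wpcPath")
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulate = isTRUE(simulate),
                 nIndividuals = as.integer(nIndividuals),
                 bridge = bp, minKm = minKm, minDailyKm = minDailyKm,
                 maxStopoverDays = maxStopoverDays, padHours = padHours,
                 mode = mode, minClass = minClass, minHeightM = minHeightM,
                 nClusters = as.integer(nClusters),
                 turbinesPerCluster = as.integer(turbinesPerCluster),
                 tracksCsv = tracksCsv, turbinesPath = turbinesPath,
                 wpcPath = wpcPath),
            class = "PipelineConfig")
}

#' Run the full corridor analysis
#'
#' Executes simulate (optional) -> read -> segment -> dynamic variance ->
#' per-segment UD -> population UD -> categorization -> hazard overlap,
#' writing every stage artifact under `config$outdir` plus a `manifest.json`
#' with the configuration, seed and MD5 of each artifact. Reruns with the
#' same configuration and seed are bit-identical.
#'
#' @param config a [pipelineConfig()] object.
#' @param verbose print per-stage progress (default TRUE).
#' @return Invisibly, a list with the tracks, segment tables, per-segment
#'   UDs, population UD, category map, overlap report and manifest path.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1f s", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  paths <- list()

  ## ------------------------------------------------------------ simulate
  if (config$simulate) {
    stage("simulate", {
      cfg <- simConfig(seed = config$seed,
                       nIndividuals = config$nIndividuals,
                       locErrorSd = config$bridge$locErrorSd)
      sims <- lapply(seq_len(config$nIndividuals), function(i)
        simulateTrack(cfg, individual = i))
      tracks <- lapply(sims, `[[`, "track")
      paths$tracks <- file.path(config$outdir, "tracks.csv")
      writeTracks(tracks, paths$tracks)
      allFix <- do.call(rbind, lapply(tracks, trackFixes))
      ext <- c(range(allFix$x) + c(-2e4, 2e4), range(allFix$y))
      turb <- simulateTurbines(config$seed + 1L, config$nClusters,
                               config$turbinesPerCluster,
                               clusterSdM = 3000, extent = ext,
                               heightRangeM = c(80, 150))
      paths$turbines <- file.path(config$outdir, "turbines.geojson")
      writePointsGeoJSON(turb, paths$turbines)
      gridAll <- trackGrid(allFix, profile = NULL, params = config$bridge)
      wpc <- simulateWpcRaster(config$seed + 2L, gridAll)
      paths$wpc <- file.path(config$outdir, "wpc.asc")
      writeRaster(wpc, paths$wpc)
    })
  } else {
    paths$tracks <- config$tracksCsv
    paths$turbines <- config$turbinesPath
    paths$wpc <- config$wpcPath
  }

  ## ---------------------------------------------------------------- read
  inputs <- stage("read", list(
    tracks = readTracks(paths$tracks,
                        defaultErrSd = config$bridge$locErrorSd),
    turbines = readPoints(paths$turbines),
    wpc = readWpc(paths$wpc)))
  tracks <- inputs$tracks
  turbines <- inputs$turbines
  wpc <- inputs$wpc

  ## ------------------------------------------------------------- segment
  seg <- stage("segment", {
    segs <- list(); parents <- list()
    for (tr in tracks) {
      ss <- findMigrationSegments(tr, minKm = config$minKm,
                                  minDailyKm = config$minDailyKm,
                                  maxStopoverDays = config$maxStopoverDays)
      ss <- lapply(ss, padSegment, track = tr, padHours = config$padHours)
      segs <- c(segs, ss)
      parents <- c(parents, rep(list(tr), length(ss)))
    }
    ex <- applyExclusion(segs, window = config$bridge$window)
    keptIdx <- !vapply(segs, function(s) segmentNFixes(s) <
                         config$bridge$window, logical(1))
    tab <- rbind(segmentTable(ex$kept, tracks, excluded = FALSE),
                 segmentTable(ex$excluded, tracks, excluded = TRUE))
    utils::write.csv(tab, file.path(config$outdir, "segments.csv"),
                     row.names = FALSE)
    list(kept = ex$kept, parents = parents[keptIdx], table = tab)
  })
  if (!length(seg$kept)) stop("pipeline stage 'segment' produced no segments")

  ## -------------------------------------------------------- variance, UD
  uds <- stage("ud", {
    segFixes <- Map(segmentFixes, seg$kept, seg$parents)
    allFix <- do.call(rbind, segFixes)
    profiles <- lapply(segFixes, dynamicVariance, params = config$bridge)
    maxSig <- max(vapply(profiles, function(p) max(p@sigma2), numeric(1)))
    grid <- trackGrid(allFix, profile = maxSig, params = config$bridge)
    out <- vector("list", length(segFixes))
    for (k in seq_along(segFixes)) {
      out[[k]] <- computeUD(segFixes[[k]], profiles[[k]], grid,
                            params = config$bridge)
      writeRaster(out[[k]],
                  file.path(config$outdir, sprintf("ud-seg%03d.asc", k)))
      prof <- data.frame(
        start = segFixes[[k]]$t[-nrow(segFixes[[k]])],
        sigma2 = profiles[[k]]@sigma2,
        nWindows = profiles[[k]]@nWindows)
      utils::write.csv(prof, file.path(config$outdir,
                                       sprintf("sigma-seg%03d.csv", k)),
                       row.names = FALSE)
    }
    out
  })

  ## ------------------------------------------- combine, categorize, overlap
  popUD <- stage("combine", {
    p <- combineUDs(uds)
    writeRaster(p, file.path(config$outdir, "population-ud.asc"))
    p
  })
  catMap <- stage("categorize", {
    cm <- categorizeUD(popUD, mode = config$mode)
    writeRaster(cm, file.path(config$outdir, "categories.asc"))
    utils::write.csv(categoryAreas(cm),
                     file.path(config$outdir, "category-areas.csv"),
                     row.names = FALSE)
    cm
  })
  report <- stage("overlap", {
    wpcR <- resampleNearest(wpc, catMap@grid)
    counts <- countTurbines(catMap, turbines, minHeightM = config$minHeightM)
    rep <- buildReport(categoryAreas(catMap),
                       wpcOverlap(catMap, wpcR, minClass = config$minClass),
                       counts)
    utils::write.csv(rep, file.path(config$outdir, "overlap-report.csv"),
                     row.names = FALSE)
    utils::write.csv(assignTurbines(catMap, turbines,
                                    minHeightM = config$minHeightM),
                     file.path(config$outdir, "turbine-categories.csv"),
                     row.names = FALSE)
    rep
  })

  ## ------------------------------------------------------------ manifest
  arts <- list.files(config$outdir, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  manifest <- list(
    seed = config$seed,
    package = as.character(utils::packageVersion("corridorUD")),
    config = config[setdiff(names(config), c("outdir"))],
    artifacts = as.list(stats::setNames(unname(tools::md5sum(arts)),
                                        basename(arts))))
  manifestPath <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  say("[manifest] %d artifacts", length(arts))

  invisible(list(tracks = tracks, segments = seg$kept,
                 segmentTable = seg$table, uds = uds, populationUD = popUD,
                 categoryMap = catMap, report = report,
                 manifest = manifestPath))
}
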