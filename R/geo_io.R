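## Readers and writers for the pipeline's plain formats: Movebank-style fix
## CSV, ESRI ASCII grid rasters, and GeoJSON / CSV turbine points. All
## analysis happens in a single planar equal-area CRS in meters; conversion
## from geographic coordinates is an ingest concern outside this package.

movebankCols <- c("individual-local-identifier", "timestamp", "x", "y")

#' Read telemetry tracks from a Movebank-style CSV
#'
#' Expected columns: `individual-local-identifier`, `timestamp` (ISO-8601
#' UTC), `x`, `y` (planar meters) and optionally `loc-error-sd` (meters,
#' default 18). Rows with missing coordinates are dropped (count reported via
#' `message()`); fixes sharing an individual and timestamp are deduplicated
#' keeping the first; fixes are returned time-sorted.
#'
#' @param path CSV file path.
#' @param defaultErrSd location-error SD applied when the column is absent.
#' @return A list of [TelemetryTrack-class], one per individual.
#' @export
readTracks <- function(path, defaultErrSd = 18) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(movebankCols, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  t <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (f in fmts) {
    need <- is.na(t)
    if (!any(need)) break
    t[need] <- as.POSIXct(strptime(df$timestamp[need], f, tz = "UTC"))
  }
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop(sprintf("unparseable timestamp '%s' at row %d",
                 df$timestamp[bad], bad))
  }
  nodrop <- !is.na(df$x) & !is.na(df$y)
  if (any(!nodrop))
    message(sum(!nodrop), " row(s) dropped for missing coordinates")
  df <- df[nodrop, , drop = FALSE]; t <- t[nodrop]
  err <- if ("loc-error-sd" %in% names(df)) df[["loc-error-sd"]]
         else defaultErrSd
  err <- rep_len(err, nrow(df))
  ids <- as.character(df[["individual-local-identifier"]])
  out <- lapply(split(seq_len(nrow(df)), ids), function(idx) {
    ti <- t[idx]
    o <- idx[order(ti)]
    dup <- duplicated(t[o])
    if (any(dup))
      message(sum(dup), " duplicate-timestamp fix(es) dropped for ",
              ids[idx[1]])
    o <- o[!dup]
    telemetryTrack(ids[o[1]], t[o], df$x[o], df$y[o], err[o])
  })
  unname(out)
}

#' Write tracks to a Movebank-style CSV
#'
#' @param tracks list of [TelemetryTrack-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    f <- trackFixes(tr)
    data.frame(`individual-local-identifier` = individualId(tr),
               timestamp = format(f$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               x = f$x, y = f$y, `loc-error-sd` = f$errSd,
               check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## ESRI ASCII grid
## ---------------------------------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written at full double precision (`%.17g`) so a round trip
#' reproduces them exactly; grid metadata (dimensions, lower-left corner,
#' cell size) is exact. `NA` cells become the NODATA sentinel.
#'
#' @param x a [UDRaster-class], [ClassRaster-class], [CategoryMap-class], or
#'   a list with elements `grid` and a `nRows x nCols` matrix `values`.
#' @param path output file path.
#' @param format only `"ascii"` is supported.
#' @param nodata NODATA sentinel written for `NA` cells (default -9999).
#' @return `path`, invisibly.
#' @export
writeRaster <- function(x, path, format = c("ascii"), nodata = -9999) {
  format <- match.arg(format)
  if (is(x, "UDRaster")) { grid <- x@grid; vals <- x@values }
  else if (is(x, "ClassRaster")) { grid <- x@grid; vals <- x@classes }
  else if (is(x, "CategoryMap")) { grid <- x@grid; vals <- x@categories }
  else { grid <- x$grid; vals <- x$values }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid@nCols),
               sprintf("nrows %d", grid@nRows),
               sprintf("xllcorner %.17g", grid@origin[1]),
               sprintf("yllcorner %.17g", grid@origin[2]),
               sprintf("cellsize %.17g", grid@cellSize),
               sprintf("NODATA_value %.17g", nodata)), con)
  ## ESRI ASCII rows run top to bottom; our row 1 is the bottom row
  for (j in grid@nRows:1) {
    row <- vals[j, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `grid` (an [AnalysisGrid-class]), `values` (matrix,
#'   row 1 = bottom row, NODATA as `NA`) and `nodata` (the sentinel).
#' @export
readAsciiRaster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header, need: ", paste(need, collapse = ", "))
  nodata <- hdr$nodata_value %||% -9999
  vals <- t(vapply(lines[i:(i + hdr$nrows - 1L)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
    numeric(hdr$ncols), USE.NAMES = FALSE))
  vals <- vals[hdr$nrows:1, , drop = FALSE]  # back to bottom-row-first
  vals[vals == nodata] <- NA
  list(grid = analysisGrid(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize,
                           hdr$ncols, hdr$nrows),
       values = vals, nodata = nodata)
}

#' Read a wind-power-class raster
#'
#' Reads an ESRI ASCII grid and validates that all non-missing cells are
#' integer classes 1-7.
#'
#' @param path ESRI ASCII grid path.
#' @return A [ClassRaster-class].
#' @export
readWpc <- function(path) {
  r <- readAsciiRaster(path)
  v <- r$values[!is.na(r$values)]
  if (length(v) && (any(v != round(v)) || any(v < 1) || any(v > 7)))
    stop("wind power classes must be integers in 1..7")
  classRaster(r$grid, r$values)
}

## ---------------------------------------------------------------------------
## Turbine points
## ---------------------------------------------------------------------------

#' Read turbine points from GeoJSON or CSV
#'
#' GeoJSON must be a FeatureCollection of Point features with a height
#' property (`heightM` or `height`); CSV must have columns `x`, `y` and
#' `heightM`/`height`. Coordinates are planar meters in the analysis CRS —
#' geographic input must be reprojected before ingest. Points outside the
#' grid extent are retained and flagged, never dropped.
#'
#' @param path `.geojson`/`.json` or `.csv` file.
#' @param grid optional [AnalysisGrid-class]; adds a logical `outOfExtent`
#'   column.
#' @return data.frame with `id`, `x`, `y`, `heightM` (and `outOfExtent`).
#' @export
readPoints <- function(path, grid = NULL) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    if (!identical(gj$type, "FeatureCollection"))
      stop("GeoJSON must be a FeatureCollection")
    rows <- lapply(seq_along(gj$features), function(k) {
      ft <- gj$features[[k]]
      if (!identical(ft$geometry$type, "Point"))
        stop("feature ", k, " is not a Point")
      h <- ft$properties$heightM %||% ft$properties$height %||% NA_real_
      data.frame(id = as.character(ft$properties$id %||% sprintf("T%04d", k)),
                 x = as.numeric(ft$geometry$coordinates[[1]]),
                 y = as.numeric(ft$geometry$coordinates[[2]]),
                 heightM = as.numeric(h))
    })
    pts <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("x", "y") %in% names(df)))
      stop("point CSV needs columns x, y")
    hcol <- intersect(c("heightM", "height"), names(df))[1]
    pts <- data.frame(
      id = as.character(if ("id" %in% names(df)) df$id
                        else sprintf("T%04d", seq_len(nrow(df)))),
      x = df$x, y = df$y,
      heightM = if (!is.na(hcol)) as.numeric(df[[hcol]])
                else rep(NA_real_, nrow(df)))
  }
  if (!all(is.finite(pts$x)) || !all(is.finite(pts$y)))
    stop("non-finite point coordinates")
  if (!is.null(grid)) {
    idx <- cellIndexOf(grid, pts$x, pts$y)
    pts$outOfExtent <- is.na(idx[, "col"])
    if (any(pts$outOfExtent))
      message(sum(pts$outOfExtent), " point(s) outside the grid extent")
  }
  pts
}

#' Write turbine points as GeoJSON
#'
#' @param turbines data.frame with `id`, `x`, `y`, `heightM`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePointsGeoJSON <- function(turbines, path) {
  feats <- lapply(seq_len(nrow(turbines)), function(k) list(
    type = "Feature",
    geometry = list(type = "Point",
                    coordinates = c(turbines$x[k], turbines$y[k])),
    properties = list(id = turbines$id[k], heightM = turbines$heightM[k])))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
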