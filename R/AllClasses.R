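#' @import methods
NULL

## ---------------------------------------------------------------------------
## AnalysisGrid
## ---------------------------------------------------------------------------

#' Planar analysis grid
#'
#' A regular square-cell grid in a planar, equal-area projected CRS (meters).
#' Cell `(i, j)` (0-based, column `i` from the left, row `j` from the bottom)
#' covers the half-open square
#' `[x0 + i*s, x0 + (i+1)*s) x [y0 + j*s, y0 + (j+1)*s)`, so a point on a
#' shared edge belongs to exactly one cell.
#'
#' @slot origin numeric(2), planar coordinates of the lower-left corner (m).
#' @slot cellSize positive cell side length (m); 1000 m throughout the
#'   corridor analysis so one cell is 100 ha.
#' @slot nCols,nRows grid dimensions.
#' @export
setClass("AnalysisGrid",
  representation(origin = "numeric", cellSize = "numeric",
                 nCols = "integer", nRows = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 2L || !all(is.finite(object@origin)))
      msg <- c(msg, "origin must be two finite coordinates")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (object@nCols < 1L || object@nRows < 1L)
      msg <- c(msg, "grid must have at least one column and one row")
    if (length(msg)) msg else TRUE
  })

#' Construct an analysis grid
#'
#' @param origin numeric(2) lower-left corner (m).
#' @param cellSize cell side length in meters (default 1000).
#' @param nCols,nRows number of columns / rows.
#' @return An [AnalysisGrid-class] object.
#' @examples
#' g <- analysisGrid(c(0, 0), 1000, 10, 8)
#' cellArea(g)  # m^2
#' @export
analysisGrid <- function(origin, cellSize = 1000, nCols, nRows) {
  new("AnalysisGrid", origin = as.numeric(origin),
      cellSize = as.numeric(cellSize),
      nCols = as.integer(nCols), nRows = as.integer(nRows))
}

#' @describeIn analysisGrid cell area in square meters.
#' @param grid an `AnalysisGrid`.
#' @export
cellArea <- function(grid) grid@cellSize^2

#' @describeIn analysisGrid cell side length in meters.
#' @export
cellSize <- function(grid) grid@cellSize

#' @describeIn analysisGrid lower-left corner of the grid.
#' @export
gridOrigin <- function(grid) grid@origin

#' @describeIn analysisGrid `c(nCols, nRows)`.
#' @export
gridDim <- function(grid) c(grid@nCols, grid@nRows)

#' @describeIn analysisGrid x coordinates of cell centers (length `nCols`).
#' @export
cellCentersX <- function(grid)
  grid@origin[1] + (seq_len(grid@nCols) - 0.5) * grid@cellSize

#' @describeIn analysisGrid y coordinates of cell centers (length `nRows`).
#' @export
cellCentersY <- function(grid)
  grid@origin[2] + (seq_len(grid@nRows) - 0.5) * grid@cellSize

## 0-based column/row index of points; NA outside the extent.
## Half-open convention: floor((x - x0) / s).
cellIndexOf <- function(grid, x, y) {
  i <- floor((x - grid@origin[1]) / grid@cellSize)
  j <- floor((y - grid@origin[2]) / grid@cellSize)
  bad <- i < 0 | i >= grid@nCols | j < 0 | j >= grid@nRows
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(col = as.integer(i), row = as.integer(j))
}

sameGrid <- function(a, b, tol = 1e-9) {
  a@nCols == b@nCols && a@nRows == b@nRows &&
    isTRUE(all.equal(a@cellSize, b@cellSize, tolerance = tol)) &&
    isTRUE(all.equal(a@origin, b@origin, tolerance = tol))
}

setMethod("show", "AnalysisGrid", function(object) {
  cat(sprintf("AnalysisGrid: %d x %d cells of %g m, origin (%g, %g)\n",
              object@nCols, object@nRows, object@cellSize,
              object@origin[1], object@origin[2]))
})

## ---------------------------------------------------------------------------
## TelemetryTrack
## ---------------------------------------------------------------------------

#' GPS telemetry track for one individual
#'
#' Ordered GPS fixes for a single animal: UTC timestamp, planar position in
#' meters, and the per-fix location-error SD (18 m for the GPS transmitters
#' the corridor analysis was designed around).
#'
#' @slot individualId identifier of the tracked animal.
#' @slot fixes `data.frame` with columns `t` (POSIXct, UTC, strictly
#'   increasing), `x`, `y` (planar meters) and `errSd` (meters, >= 0).
#' @export
setClass("TelemetryTrack",
  representation(individualId = "character", fixes = "data.frame"),
  validity = function(object) {
    f <- object@fixes
    msg <- character()
    need <- c("t", "x", "y", "errSd")
    if (!all(need %in% names(f)))
      return(paste("fixes must have columns", paste(need, collapse = ", ")))
    if (nrow(f)) {
      if (!inherits(f$t, "POSIXct")) msg <- c(msg, "t must be POSIXct")
      else if (any(diff(as.numeric(f$t)) <= 0))
        msg <- c(msg, "timestamps must be strictly increasing")
      if (!all(is.finite(f$x)) || !all(is.finite(f$y)))
        msg <- c(msg, "coordinates must be finite")
      if (any(f$errSd < 0)) msg <- c(msg, "errSd must be >= 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a telemetry track
#'
#' Fixes are sorted by time; the validity check then requires strictly
#' increasing timestamps (deduplicate before construction).
#'
#' @param individualId animal identifier.
#' @param t POSIXct UTC timestamps.
#' @param x,y planar coordinates (m).
#' @param errSd per-fix location-error SD in meters (recycled; default 18).
#' @return A [TelemetryTrack-class].
#' @export
telemetryTrack <- function(individualId, t, x, y, errSd = 18) {
  o <- order(t)
  f <- data.frame(t = t[o], x = as.numeric(x)[o], y = as.numeric(y)[o],
                  errSd = rep_len(as.numeric(errSd), length(t))[o])
  attr(f$t, "tzone") <- "UTC"
  new("TelemetryTrack", individualId = as.character(individualId), fixes = f)
}

#' @describeIn telemetryTrack number of fixes.
#' @param track a `TelemetryTrack`.
#' @export
nFixes <- function(track) nrow(track@fixes)

#' @describeIn telemetryTrack the fix table (`t`, `x`, `y`, `errSd`).
#' @export
trackFixes <- function(track) track@fixes

#' @describeIn telemetryTrack the individual identifier.
#' @export
individualId <- function(track) track@individualId

setMethod("show", "TelemetryTrack", function(object) {
  f <- object@fixes
  cat(sprintf("TelemetryTrack '%s': %d fixes", object@individualId, nrow(f)))
  if (nrow(f))
    cat(sprintf(" [%s .. %s UTC]",
                format(f$t[1], "%Y-%m-%d %H:%M"),
                format(f$t[nrow(f)], "%Y-%m-%d %H:%M")))
  cat("\n")
})

## ---------------------------------------------------------------------------
## MigrationSegment
## ---------------------------------------------------------------------------

#' Directional migration segment of a track
#'
#' A contiguous slice of a parent track identified as a continuous
#' directional (north or south) movement of at least the minimum net
#' north-south displacement, with an optional padded range extending about
#' 24 h beyond the core movement.
#'
#' @slot trackId parent track identifier.
#' @slot direction `"north"` or `"south"`.
#' @slot coreStart,coreEnd 1-based fix indices of the core directional run.
#' @slot padStart,padEnd fix indices after padding (superset of the core).
#' @slot netKm signed net north-south displacement of the core run (km;
#'   positive north).
#' @export
setClass("MigrationSegment",
  representation(trackId = "character", direction = "character",
                 coreStart = "integer", coreEnd = "integer",
                 padStart = "integer", padEnd = "integer",
                 netKm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@direction %in% c("north", "south"))
      msg <- c(msg, "direction must be 'north' or 'south'")
    if (object@coreStart > object@coreEnd)
      msg <- c(msg, "coreStart must be <= coreEnd")
    if (object@padStart > object@coreStart || object@padEnd < object@coreEnd)
      msg <- c(msg, "padded range must contain the core range")
    if (length(msg)) msg else TRUE
  })

#' @describeIn findMigrationSegments number of fixes in the padded range.
#' @param segment a `MigrationSegment`.
#' @export
segmentNFixes <- function(segment) segment@padEnd - segment@padStart + 1L

#' @describeIn findMigrationSegments fix table of the padded segment.
#' @export
segmentFixes <- function(segment, track) {
  stopifnot(identical(segment@trackId, track@individualId))
  track@fixes[segment@padStart:segment@padEnd, , drop = FALSE]
}

setMethod("show", "MigrationSegment", function(object) {
  cat(sprintf(
    "MigrationSegment (%s) of '%s': core fixes %d-%d, padded %d-%d, net %.1f km\n",
    object@direction, object@trackId, object@coreStart, object@coreEnd,
    object@padStart, object@padEnd, object@netKm))
})

## ---------------------------------------------------------------------------
## VarianceProfile
## ---------------------------------------------------------------------------

#' Per-interval Brownian motion variance profile
#'
#' One motion-variance value sigma2 (m^2/s) per consecutive fix pair of a
#' segment, as estimated by the sliding-window changepoint scheme, plus the
#' number of windows that informed each interval.
#'
#' @slot sigma2 numeric, length `nFixes - 1`, all >= 0.
#' @slot nWindows integer, how many window assignments each interval received
#'   (0 for edge intervals that inherited a neighbour's value).
#' @slot breakFraction fraction of windows in which a one-breakpoint model
#'   beat the single-variance model by BIC.
#' @export
setClass("VarianceProfile",
  representation(sigma2 = "numeric", nWindows = "integer",
                 breakFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(!is.finite(object@sigma2)) || any(object@sigma2 < 0))
      msg <- c(msg, "sigma2 must be finite and >= 0")
    if (length(object@nWindows) != length(object@sigma2))
      msg <- c(msg, "nWindows must match sigma2 in length")
    if (length(msg)) msg else TRUE
  })

#' @describeIn dynamicVariance per-interval motion variance (m^2/s).
#' @param profile a `VarianceProfile`.
#' @export
motionVariance <- function(profile) profile@sigma2

#' @describeIn dynamicVariance fraction of windows preferring a breakpoint.
#' @export
breakFraction <- function(profile) profile@breakFraction

setMethod("show", "VarianceProfile", function(object) {
  cat(sprintf(
    "VarianceProfile: %d intervals, sigma2 range [%.4g, %.4g] m^2/s, %.0f%% breakpoint windows\n",
    length(object@sigma2), min(object@sigma2), max(object@sigma2),
    100 * object@breakFraction))
})

## ---------------------------------------------------------------------------
## UDRaster
## ---------------------------------------------------------------------------

#' Gridded utilization distribution
#'
#' A nonnegative probability surface on an [AnalysisGrid-class]; after
#' normalization cell values sum to 1. `nFixes` records how many fixes shaped
#' the surface and is the weight used when combining segments into the
#' population UD.
#'
#' @slot grid the analysis grid.
#' @slot values numeric matrix `nRows x nCols`; row 1 is the bottom row.
#' @slot nFixes fix count behind the surface.
#' @export
setClass("UDRaster",
  representation(grid = "AnalysisGrid", values = "matrix", nFixes = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      msg <- c(msg, "values must be nRows x nCols")
    if (any(object@values < 0, na.rm = TRUE))
      msg <- c(msg, "UD values must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a UD raster
#'
#' @param grid an [AnalysisGrid-class].
#' @param values `nRows x nCols` matrix of nonnegative cell values, row 1 at
#'   the bottom of the grid.
#' @param nFixes number of fixes behind the surface (combination weight).
#' @param normalize divide by the total so cells sum to 1 (default TRUE).
#' @return A [UDRaster-class].
#' @export
udRaster <- function(grid, values, nFixes = 0L, normalize = TRUE) {
  values <- as.matrix(values)
  if (normalize) {
    tot <- sum(values)
    if (tot <= 0) stop("cannot normalize a UD with zero total mass")
    values <- values / tot
  }
  new("UDRaster", grid = grid, values = values, nFixes = as.integer(nFixes))
}

#' @describeIn udRaster the cell-value matrix (row 1 = bottom row).
#' @param ud a `UDRaster`.
#' @export
udValues <- function(ud) ud@values

#' @describeIn udRaster the underlying grid.
#' @export
udGrid <- function(ud) ud@grid

#' @describeIn udRaster fix count behind the surface.
#' @export
udNFixes <- function(ud) ud@nFixes

setMethod("show", "UDRaster", function(object) {
  cat(sprintf(
    "UDRaster: %d x %d cells (%g m), sum %.6f, n_fixes %d\n",
    object@grid@nCols, object@grid@nRows, object@grid@cellSize,
    sum(object@values), object@nFixes))
})

## ---------------------------------------------------------------------------
## CategoryMap
## ---------------------------------------------------------------------------

#' Integer class raster (wind power classes)
#'
#' A categorical raster on an [AnalysisGrid-class]; here wind power classes
#' 1-7 (50 m AGL wind power density rating; classes >= 3 are commercially
#' viable for utility-scale wind).
#'
#' @slot grid the analysis grid.
#' @slot classes integer matrix `nRows x nCols` (row 1 = bottom row), values
#'   1-7 or NA.
#' @export
setClass("ClassRaster",
  representation(grid = "AnalysisGrid", classes = "matrix"),
  validity = function(object) {
    d <- dim(object@classes)
    msg <- character()
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      msg <- c(msg, "classes must be nRows x nCols")
    v <- object@classes[!is.na(object@classes)]
    if (length(v) && (!all(v == as.integer(v)) || any(v < 1) || any(v > 7)))
      msg <- c(msg, "classes must be integers in 1..7")
    if (length(msg)) msg else TRUE
  })

#' Construct a class raster
#'
#' @param grid an [AnalysisGrid-class].
#' @param classes integer matrix `nRows x nCols`, values 1-7 or NA.
#' @return A [ClassRaster-class].
#' @export
classRaster <- function(grid, classes) {
  m <- as.matrix(classes)
  storage.mode(m) <- "integer"
  new("ClassRaster", grid = grid, classes = m)
}

#' @describeIn classRaster the integer class matrix.
#' @param wpc a `ClassRaster`.
#' @export
classValues <- function(wpc) wpc@classes

setMethod("show", "ClassRaster", function(object) {
  cat(sprintf("ClassRaster: %d x %d cells (%g m), classes %s\n",
              object@grid@nCols, object@grid@nRows, object@grid@cellSize,
              paste(sort(unique(as.vector(object@classes))), collapse = ",")))
})

#' UD use-category map
#'
#' Ordination of UD cells into disjoint use categories labelled 20 (highest
#' use) through 100 (lowest use); cells below the nonzero threshold are
#' background (`NA`).
#'
#' @slot grid the analysis grid.
#' @slot categories integer matrix `nRows x nCols` with values in
#'   `c(20, 40, 60, 80, 100)` or `NA` for background.
#' @slot mode `"count"` (equal cell counts per bin) or `"volume"`
#'   (probability-mass quantiles).
#' @export
setClass("CategoryMap",
  representation(grid = "AnalysisGrid", categories = "matrix",
                 mode = "character"),
  validity = function(object) {
    d <- dim(object@categories)
    msg <- character()
    if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
      msg <- c(msg, "categories must be nRows x nCols")
    vals <- object@categories[!is.na(object@categories)]
    if (length(vals) && !all(vals %in% c(20L, 40L, 60L, 80L, 100L)))
      msg <- c(msg, "categories must be in {20, 40, 60, 80, 100} or NA")
    if (!object@mode %in% c("count", "volume"))
      msg <- c(msg, "mode must be 'count' or 'volume'")
    if (length(msg)) msg else TRUE
  })

#' @describeIn categorizeUD the integer category matrix (NA = background).
#' @param map a `CategoryMap`.
#' @export
categoryValues <- function(map) map@categories

#' @describeIn categorizeUD the underlying grid.
#' @export
categoryGrid <- function(map) map@grid

setMethod("show", "CategoryMap", function(object) {
  tab <- table(factor(object@categories, levels = c(20, 40, 60, 80, 100)))
  cat(sprintf("CategoryMap (%s mode): %d x %d cells; cells per category: %s\n",
              object@mode, object@grid@nCols, object@grid@nRows,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = " ")))
})
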