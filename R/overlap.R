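## Hazard overlap: turbines and wind-power-class cells overlaid on the UD
## category map, and the tabular report with headline percentages.

#' Assign turbines to UD categories
#'
#' Turbines at or above the height threshold are assigned to the category of
#' their containing cell (half-open cell convention, so an edge point lands
#' in exactly one cell). Turbines outside the grid extent are flagged, not
#' dropped; turbines with missing height are excluded from the height-filter
#' set and reported.
#'
#' @param map a [CategoryMap-class].
#' @param turbines data.frame with `x`, `y`, `heightM` (and optionally `id`).
#' @param minHeightM height filter in m AGL (default 100).
#' @return data.frame of the turbines passing the filter with a `category`
#'   column (`"20"`..`"100"`, `"background"`, or `"out_of_extent"`).
#' @export
assignTurbines <- function(map, turbines, minHeightM = 100) {
  if (anyNA(turbines$heightM))
    message(sum(is.na(turbines$heightM)),
            " turbine(s) with missing height excluded from the height filter")
  keep <- !is.na(turbines$heightM) & turbines$heightM >= minHeightM
  tb <- turbines[keep, , drop = FALSE]
  if (!"id" %in% names(tb)) tb$id <- sprintf("T%04d", seq_len(nrow(tb)))
  ij <- cellIndexOf(map@grid, tb$x, tb$y)
  cat <- rep("out_of_extent", nrow(tb))
  inext <- !is.na(ij[, "col"])
  cc <- map@categories[cbind(ij[inext, "row"] + 1L, ij[inext, "col"] + 1L)]
  cat[inext] <- ifelse(is.na(cc), "background", as.character(cc))
  tb$category <- cat
  tb
}

#' Count turbines per UD category
#'
#' @inheritParams assignTurbines
#' @return named integer vector over `"20"`, `"40"`, `"60"`, `"80"`,
#'   `"100"`, `"background"`, `"out_of_extent"`; sums to the number of
#'   turbines passing the height filter.
#' @export
countTurbines <- function(map, turbines, minHeightM = 100) {
  asg <- assignTurbines(map, turbines, minHeightM)
  lev <- c("20", "40", "60", "80", "100", "background", "out_of_extent")
  tab <- table(factor(asg$category, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Resample a class raster onto another grid (nearest neighbour)
#'
#' Each target cell takes the class of the source cell containing its
#' center; target cells outside the source extent become `NA`. Nearest
#' neighbour is the only sensible choice for categorical classes.
#'
#' @param wpc a [ClassRaster-class].
#' @param grid target [AnalysisGrid-class].
#' @return A [ClassRaster-class] on `grid`.
#' @export
resampleNearest <- function(wpc, grid) {
  cx <- cellCentersX(grid); cy <- cellCentersY(grid)
  pts <- cbind(x = rep(cx, each = grid@nRows),
               y = rep(cy, times = grid@nCols))
  ij <- cellIndexOf(wpc@grid, pts[, "x"], pts[, "y"])
  out <- rep(NA_integer_, nrow(pts))
  ok <- !is.na(ij[, "col"])
  out[ok] <- wpc@classes[cbind(ij[ok, "row"] + 1L, ij[ok, "col"] + 1L)]
  classRaster(grid, matrix(out, grid@nRows, grid@nCols))
}

#' Wind-power-class overlap per UD category
#'
#' Hectares of cells in each category whose wind power class is at least
#' `minClass` (class 3 is the usual threshold of commercial viability).
#'
#' @param map a [CategoryMap-class].
#' @param wpc a [ClassRaster-class] on the identical grid (resample first
#'   with [resampleNearest()]).
#' @param minClass minimum viable class (default 3).
#' @return named numeric vector of hectares for categories 20..100.
#' @export
wpcOverlap <- function(map, wpc, minClass = 3) {
  if (!sameGrid(map@grid, wpc@grid))
    stop("wpc raster grid does not match the category grid; resample first")
  viable <- !is.na(wpc@classes) & wpc@classes >= minClass
  lev <- c(20L, 40L, 60L, 80L, 100L)
  ha <- vapply(lev, function(k)
    sum(viable & !is.na(map@categories) & map@categories == k) *
      cellArea(map@grid) / 1e4, numeric(1))
  stats::setNames(ha, as.character(lev))
}

#' Build the overlap report
#'
#' Assembles the per-category table — UD area, viable-wind overlap area,
#' installed turbines — plus the derived percentages: turbines in each
#' category as a share of all turbines passing the height filter, and
#' overlap area as a share of the category area. Percentages are rounded
#' half-away-from-zero to integers, the convention used when quoting them.
#'
#' @param categoryAreasHa data.frame from [categoryAreas()] (or any with
#'   `category` and `hectares`).
#' @param wpcOverlapHa named vector from [wpcOverlap()].
#' @param turbineCounts named vector from [countTurbines()] (extra names
#'   beyond the five categories, e.g. background, are allowed).
#' @param totalTurbines denominator for the turbine percentages; defaults to
#'   `sum(turbineCounts)`.
#' @return data.frame with columns `category`, `udHectares`,
#'   `wpcOverlapHectares`, `installedTurbines`, `pctTurbines`,
#'   `pctWpcOverlap`.
#' @export
buildReport <- function(categoryAreasHa, wpcOverlapHa, turbineCounts,
                        totalTurbines = sum(turbineCounts)) {
  lev <- c("20", "40", "60", "80", "100")
  ud <- categoryAreasHa$hectares[match(as.integer(lev),
                                       categoryAreasHa$category)]
  ov <- as.numeric(wpcOverlapHa[lev])
  tc <- as.numeric(turbineCounts[lev])
  data.frame(
    category = as.integer(lev),
    udHectares = ud,
    wpcOverlapHectares = ov,
    installedTurbines = as.integer(tc),
    pctTurbines = roundHalfAway(100 * tc / totalTurbines),
    pctWpcOverlap = ifelse(ud > 0, roundHalfAway(100 * ov / ud), 0))
}
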