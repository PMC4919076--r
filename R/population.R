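## Population-level UD: weighted combination of per-segment surfaces and
## ordination of cells into use categories.

#' Combine per-segment UDs into a population surface
#'
#' Weighted mean of the normalized per-segment surfaces with weights equal
#' to the number of fixes behind each surface, renormalized to sum to 1 —
#' i.e. segments with more locations contribute proportionally more to the
#' population probability of each cell.
#'
#' @param uds nonempty list of [UDRaster-class] on an identical grid, each
#'   normalized.
#' @param weights optional numeric weights overriding each UD's fix count.
#' @return A [UDRaster-class]; `nFixes` is the summed fix count.
#' @export
combineUDs <- function(uds, weights = NULL) {
  if (!length(uds)) stop("empty UD list")
  g <- uds[[1]]@grid
  for (u in uds[-1]) if (!sameGrid(g, u@grid))
    stop("all UDs must share an identical grid")
  w <- weights %||% vapply(uds, udNFixes, numeric(1))
  if (any(w <= 0)) stop("weights must be positive")
  acc <- matrix(0, g@nRows, g@nCols)
  for (k in seq_along(uds)) acc <- acc + w[k] * uds[[k]]@values
  udRaster(g, acc / sum(w), nFixes = sum(vapply(uds, udNFixes, numeric(1))),
           normalize = TRUE)
}

#' Ordinate UD cells into use categories
#'
#' Nonzero cells (above `nonzeroThreshold`) are ranked by UD value in
#' decreasing order, ties broken by row-major cell index so maps are
#' deterministic, and binned into the disjoint categories 20 (highest use)
#' through 100 (lowest use):
#' \describe{
#'   \item{count mode (default)}{the top 20\% of nonzero *cells* are
#'     category 20, the next 20\% category 40, and so on; per-category cell
#'     counts differ from exact fifths by at most one cell.}
#'   \item{volume mode}{categories are probability-mass quantiles: a cell is
#'     in category 20 if less than 20\% of total mass lies in higher-ranked
#'     cells (so the top cell is always category 20), in category 40 if less
#'     than 40\% does, etc. A 1e-9 tolerance absorbs floating-point dust at
#'     the bin edges.}
#' }
#'
#' @param ud a normalized [UDRaster-class].
#' @param mode `"count"` or `"volume"`.
#' @param nonzeroThreshold cells at or below this value are background;
#'   default `1e-12 * max(values)`.
#' @return A [CategoryMap-class].
#' @export
categorizeUD <- function(ud, mode = c("count", "volume"),
                         nonzeroThreshold = NULL) {
  mode <- match.arg(mode)
  v <- as.vector(ud@values)  # column-major; a fixed, documented cell order
  thr <- nonzeroThreshold %||% (1e-12 * max(v))
  nz <- which(v > thr)
  cat <- rep(NA_integer_, length(v))
  if (!length(nz)) {
    warning("all cells are background (zero UD)")
  } else {
    o <- nz[order(-v[nz], nz)]   # decreasing value, ties by cell index
    if (mode == "count") {
      r <- seq_along(o)
      bin <- ceiling(5 * r / length(o))
    } else {
      cumPrev <- c(0, cumsum(v[o] / sum(v[o])))[seq_along(o)]
      bin <- findInterval(cumPrev, c(0.2, 0.4, 0.6, 0.8) - 1e-9) + 1L
    }
    cat[o] <- c(20L, 40L, 60L, 80L, 100L)[bin]
  }
  new("CategoryMap", grid = ud@grid,
      categories = matrix(cat, ud@grid@nRows, ud@grid@nCols),
      mode = mode)
}

#' Per-category areas
#'
#' @param map a [CategoryMap-class].
#' @return data.frame with `category`, `cells` and `hectares`
#'   (cells x cell area / 1e4; 100 ha per cell at the default 1 km size).
#' @export
categoryAreas <- function(map) {
  lev <- c(20L, 40L, 60L, 80L, 100L)
  cells <- vapply(lev, function(k) sum(map@categories == k, na.rm = TRUE),
                  numeric(1))
  data.frame(category = lev, cells = as.integer(cells),
             hectares = cells * cellArea(map@grid) / 1e4)
}
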