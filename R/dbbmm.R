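## Dynamic Brownian bridge movement model: time-varying motion variance
## estimated by a sliding-window leave-one-out likelihood with BIC
## changepoint selection, then bridge densities integrated onto the
## analysis grid.

#' Bridge / likelihood parameters
#'
#' @param window sliding-window size in fixes; odd (default 17, the maximum
#'   number of fixes received per day under the hourly-daylight sampling
#'   design).
#' @param margin minimum fixes per side of a candidate breakpoint
#'   (default 7).
#' @param locErrorSd default location-error SD in meters (default 18),
#'   used when a fix carries none.
#' @param cellSize analysis cell size in meters (default 1000).
#' @param substeps integration points per inter-fix interval (default 10).
#' @param sigmaSearch `c(lo, hi, n)`: log-spaced search grid for the motion
#'   variance in m^2/s (default 1e-4 .. 1e4, 200 points), refined by Brent
#'   minimization on the bracketing interval.
#' @param allowBreaks consider one-breakpoint models within each window
#'   (default TRUE); FALSE reduces the dynamic model to a constant-variance
#'   Brownian bridge.
#' @return A validated list of class `BridgeParams`.
#' @export
bridgeParams <- function(window = 17, margin = 7, locErrorSd = 18,
                         cellSize = 1000, substeps = 10,
                         sigmaSearch = c(1e-4, 1e4, 200),
                         allowBreaks = TRUE) {
  window <- as.integer(window); margin <- as.integer(margin)
  if (window %% 2L == 0L) stop("window must be odd")
  if (margin < 3L) stop("margin must be >= 3")
  if (window < margin) stop("window must be >= margin")
  if (substeps < 1L) stop("substeps must be >= 1")
  if (length(sigmaSearch) != 3 || sigmaSearch[1] <= 0 ||
      sigmaSearch[2] <= sigmaSearch[1] || sigmaSearch[3] < 10)
    stop("sigmaSearch must be c(lo, hi, n) with 0 < lo < hi, n >= 10")
  structure(list(window = window, margin = margin, locErrorSd = locErrorSd,
                 cellSize = cellSize, substeps = as.integer(substeps),
                 sigmaSearch = sigmaSearch, allowBreaks = isTRUE(allowBreaks)),
            class = "BridgeParams")
}

#' Brownian bridge mean and variance at an interior time
#'
#' For a bridge between observed fixes `zi` at `ti` and `zj` at `tj` with
#' motion variance `sigma2` (m^2/s) and per-fix location-error SDs, the
#' position at time `t` is circular bivariate normal with, writing
#' `alpha = (t - ti) / (tj - ti)` and `T = tj - ti`:
#' mean `(1 - alpha) zi + alpha zj` and per-coordinate variance
#' `T alpha (1 - alpha) sigma2 + (1 - alpha)^2 errI^2 + alpha^2 errJ^2`.
#'
#' @param zi,zj numeric(2) planar endpoints (m).
#' @param ti,tj,t endpoint and evaluation times (seconds or POSIXct);
#'   `ti <= t <= tj`, `ti < tj`.
#' @param sigma2 motion variance (m^2/s), >= 0.
#' @param errI,errJ endpoint location-error SDs (m).
#' @return list with `mean` (numeric(2)) and `var` (per-coordinate, m^2).
#' @examples
#' bridgeMoments(c(0, 0), c(0, 0), 0, 3600, 1800, 0.5, 18, 18)$var
#' # 3600 * 0.25 * 0.5 + 0.25 * 324 + 0.25 * 324 = 612
#' @export
bridgeMoments <- function(zi, zj, ti, tj, t, sigma2, errI = 0, errJ = 0) {
  ti <- as.numeric(ti); tj <- as.numeric(tj); t <- as.numeric(t)
  if (tj <= ti) stop("tj must be > ti")
  if (t < ti || t > tj) stop("t outside [ti, tj]")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  T <- tj - ti
  alpha <- (t - ti) / T
  list(mean = (1 - alpha) * zi + alpha * zj,
       var = T * alpha * (1 - alpha) * sigma2 +
         (1 - alpha)^2 * errI^2 + alpha^2 * errJ^2)
}

## Leave-one-out terms for a window slice: for each left-out fix j
## (every 2nd fix, so its neighbours are retained), the bridge variance is
## a * sigma2 + b and the squared residual to the bridge mean is r2.
## The left-out fix's own error variance is part of b: the left-out point is
## an observation with error, and omitting it biases sigma upward at small
## time gaps.
looTerms <- function(fx) {
  n <- nrow(fx)
  if (n < 3L) stop("need >= 3 fixes for leave-one-out estimation")
  j <- seq(2L, n - 1L, by = 2L)
  tn <- as.numeric(fx$t)
  T <- tn[j + 1L] - tn[j - 1L]
  alpha <- (tn[j] - tn[j - 1L]) / T
  mx <- (1 - alpha) * fx$x[j - 1L] + alpha * fx$x[j + 1L]
  my <- (1 - alpha) * fx$y[j - 1L] + alpha * fx$y[j + 1L]
  list(a = T * alpha * (1 - alpha),
       b = (1 - alpha)^2 * fx$errSd[j - 1L]^2 +
         alpha^2 * fx$errSd[j + 1L]^2 + fx$errSd[j]^2,
       r2 = (fx$x[j] - mx)^2 + (fx$y[j] - my)^2,
       j = j, n = length(j))
}

subsetTerms <- function(tm, keep)
  list(a = tm$a[keep], b = tm$b[keep], r2 = tm$r2[keep],
       j = tm$j[keep], n = sum(keep))

#' Leave-one-out negative log-likelihood of the motion variance
#'
#' Alternating fixes (2nd, 4th, ...) are treated as observations of the
#' Brownian bridge spanned by their neighbours; each contributes the
#' negative log of a circular bivariate normal density whose variance is the
#' bridge variance at its time plus its own location-error variance.
#'
#' @param fixes data.frame slice with columns `t`, `x`, `y`, `errSd`
#'   (>= 3 rows).
#' @param sigma2 candidate motion variance (m^2/s).
#' @return The summed negative log-likelihood (scalar).
#' @export
looNegLogLik <- function(fixes, sigma2) {
  tm <- looTerms(fixes)
  s <- pmax(tm$a * sigma2 + tm$b, 1e-300)
  sum(log(2 * pi * s) + tm$r2 / (2 * s))
}

## Minimize the LOO NLL over sigma2: log-grid scan then Brent refinement on
## the bracketing interval. Deterministic.
fitSigmaTerms <- function(tm, sigmaSearch) {
  if (all(tm$r2 == 0) && all(tm$b == 0)) {
    warning("degenerate window: identical positions with zero error; sigma2 = 0")
    return(list(sigma2 = 0, nll = Inf))
  }
  grid <- exp(seq(log(sigmaSearch[1]), log(sigmaSearch[2]),
                  length.out = sigmaSearch[3]))
  s <- outer(tm$a, grid) + tm$b
  s[s < 1e-300] <- 1e-300
  nll <- colSums(log(2 * pi * s) + tm$r2 / (2 * s))
  k <- which.min(nll)
  f <- function(u) {
    si <- pmax(tm$a * exp(u) + tm$b, 1e-300)
    sum(log(2 * pi * si) + tm$r2 / (2 * si))
  }
  lo <- log(grid[max(k - 1L, 1L)]); hi <- log(grid[min(k + 1L, length(grid))])
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-10)
  if (opt$objective <= nll[k]) list(sigma2 = exp(opt$minimum),
                                    nll = opt$objective)
  else list(sigma2 = grid[k], nll = nll[k])
}

#' Fit the motion variance of a window slice
#'
#' @param fixes data.frame slice (`t`, `x`, `y`, `errSd`), >= 3 rows.
#' @param params a [bridgeParams()] object.
#' @return The fitted motion variance (m^2/s).
#' @export
fitSigma <- function(fixes, params = bridgeParams()) {
  fitSigmaTerms(looTerms(fixes), params$sigmaSearch)$sigma2
}

#' Sliding-window BIC changepoint estimation of the variance profile
#'
#' Slides a window of `params$window` fixes one fix at a time. Within each
#' window a single-variance model (k = 1) is compared by BIC against models
#' with one breakpoint at fix `b` leaving at least `params$margin` fixes on
#' each side (k = 2). Both models are scored on the *same* left-out
#' observation set: the breakpoint model partitions the window's left-out
#' fixes by side and fits one variance per side, so the likelihoods are
#' directly comparable and the one-breakpoint family nests the single
#' model. `BIC = 2 NLL + k log(n_loo)` with `n_loo` the number of left-out
#' fixes in the window. The winning model's variances are assigned to the window's
#' central (non-margin) intervals; each interval's profile value is the mean
#' of all assignments it received, and never-assigned edge intervals inherit
#' the nearest assigned value. If the margin leaves no assignable central
#' interval (e.g. a single whole-track window), each window assigns to all
#' its intervals, which reduces the scheme to the static fit.
#'
#' @param fixes data.frame of segment fixes (`t`, `x`, `y`, `errSd`),
#'   >= `params$window` rows.
#' @param params a [bridgeParams()] object.
#' @return A [VarianceProfile-class] of length `nrow(fixes) - 1`.
#' @export
dynamicVariance <- function(fixes, params = bridgeParams()) {
  n <- nrow(fixes)
  w <- params$window; m <- params$margin
  if (n < w)
    stop("segment has ", n, " fixes, fewer than the window size ", w,
         " (should have been excluded)")
  nInt <- n - 1L
  ssum <- numeric(nInt); cnt <- integer(nInt)

  ## central intervals of a window: both endpoint fixes non-margin
  ctr <- seq.int(m + 1L, w - m - 1L)
  ctr <- ctr[ctr >= 1L & ctr <= w - 1L]
  fallback <- length(ctr) == 0L
  target <- if (fallback) seq_len(w - 1L) else ctr

  breaks <- if (params$allowBreaks) seq.int(m, w - m) else integer()

  starts <- seq_len(n - w + 1L)
  nBreak <- 0L
  for (s0 in starts) {
    sl <- fixes[s0:(s0 + w - 1L), , drop = FALSE]
    tmAll <- looTerms(sl)
    fit1 <- fitSigmaTerms(tmAll, params$sigmaSearch)
    best <- list(k = 1L, b = NA_integer_, sig = c(fit1$sigma2, fit1$sigma2),
                 bic = 2 * fit1$nll + log(tmAll$n))
    for (b in breaks) {
      left <- tmAll$j <= b
      if (!any(left) || all(left)) next
      fl <- fitSigmaTerms(subsetTerms(tmAll, left), params$sigmaSearch)
      fr <- fitSigmaTerms(subsetTerms(tmAll, !left), params$sigmaSearch)
      ## 3 parameters: two variances plus the breakpoint location
      bic2 <- 2 * (fl$nll + fr$nll) + 3 * log(tmAll$n)
      if (bic2 < best$bic)
        best <- list(k = 2L, b = b, sig = c(fl$sigma2, fr$sigma2), bic = bic2)
    }
    if (best$k == 2L) nBreak <- nBreak + 1L
    for (i in target) {
      val <- if (best$k == 1L) best$sig[1]
             else if (i + 1L <= best$b) best$sig[1]
             else if (i >= best$b + 1L) best$sig[2]
             else mean(best$sig)       # interval spanning the breakpoint
      g <- s0 - 1L + i
      ssum[g] <- ssum[g] + val
      cnt[g] <- cnt[g] + 1L
    }
  }

  sig <- ifelse(cnt > 0L, ssum / pmax(cnt, 1L), NA_real_)
  if (anyNA(sig)) {
    assigned <- which(!is.na(sig))
    for (g in which(is.na(sig))) {
      nearest <- assigned[which.min(abs(assigned - g))]
      sig[g] <- sig[nearest]
    }
  }
  new("VarianceProfile", sigma2 = sig, nWindows = cnt,
      breakFraction = nBreak / length(starts))
}

#' Locate the variance-profile changepoint
#'
#' The changepoint is the largest jump of the profile on the log scale —
#' the motion variance is a scale parameter, so regime changes are ratios,
#' and the log scale keeps within-regime estimation noise (which is
#' multiplicative) from dominating an additive comparison.
#'
#' @param profile a [VarianceProfile-class] or numeric sigma2 vector.
#' @param floor variances are clamped below at this value before taking
#'   logs (default 1e-8 m^2/s).
#' @return The fix index just after the largest jump (the first fix of the
#'   new regime).
#' @export
profileChangepoint <- function(profile, floor = 1e-8) {
  sig <- if (is(profile, "VarianceProfile")) profile@sigma2 else profile
  which.max(abs(diff(log(pmax(sig, floor))))) + 1L
}

#' Default analysis grid for a segment
#'
#' Bounding box of the fixes buffered by `max(bufferMinM, 3 x max bridge
#' SD)`, snapped to cell-size multiples, so at least 99.7% of every bridge's
#' mass falls inside the grid.
#'
#' @param fixes segment fix data.frame (or several row-bound together).
#' @param profile a [VarianceProfile-class] (or a numeric sigma2 vector) used
#'   to size the buffer; `NULL` uses `bufferMinM` alone.
#' @param params a [bridgeParams()] object (cell size).
#' @param bufferMinM minimum buffer (default 30 km).
#' @return An [AnalysisGrid-class].
#' @export
trackGrid <- function(fixes, profile = NULL, params = bridgeParams(),
                      bufferMinM = 30000) {
  buf <- bufferMinM
  if (!is.null(profile)) {
    sig <- if (is(profile, "VarianceProfile")) profile@sigma2 else profile
    tn <- as.numeric(fixes$t)
    T <- abs(diff(tn))
    sig <- rep_len(sig, length(T))
    maxVar <- max(sig * T / 4 + max(fixes$errSd)^2)
    buf <- max(buf, 3 * sqrt(maxVar))
  }
  cs <- params$cellSize
  x0 <- floor((min(fixes$x) - buf) / cs) * cs
  y0 <- floor((min(fixes$y) - buf) / cs) * cs
  analysisGrid(c(x0, y0), cs,
               ceiling((max(fixes$x) + buf - x0) / cs),
               ceiling((max(fixes$y) + buf - y0) / cs))
}

#' Integrate the bridge density onto the analysis grid
#'
#' For each inter-fix interval the circular normal bridge density is
#' evaluated at `params$substeps` equally spaced interior times (midpoint
#' rule), each evaluation weighted by `dt / substeps`, the density taken at
#' cell centers times cell area, then the surface is normalized to sum to 1.
#'
#' @param fixes segment fix data.frame (`t`, `x`, `y`, `errSd`).
#' @param profile a [VarianceProfile-class] (length `nrow(fixes) - 1`) or a
#'   numeric vector of per-interval motion variances.
#' @param grid an [AnalysisGrid-class] containing the 3-SD envelope of every
#'   bridge (hard error otherwise).
#' @param params a [bridgeParams()] object.
#' @return A [UDRaster-class] with `nFixes = nrow(fixes)`.
#' @export
computeUD <- function(fixes, profile, grid, params = bridgeParams()) {
  sig <- if (is(profile, "VarianceProfile")) profile@sigma2 else profile
  n <- nrow(fixes)
  if (length(sig) != n - 1L)
    stop("profile length must be nrow(fixes) - 1")
  tn <- as.numeric(fixes$t)
  cs <- grid@cellSize
  cx <- cellCentersX(grid); cy <- cellCentersY(grid)
  xmin <- grid@origin[1]; ymin <- grid@origin[2]
  xmax <- xmin + grid@nCols * cs; ymax <- ymin + grid@nRows * cs
  vals <- matrix(0, grid@nRows, grid@nCols)
  area <- cellArea(grid)
  sub <- params$substeps

  for (i in seq_len(n - 1L)) {
    T <- tn[i + 1L] - tn[i]
    wgt <- T / sub
    e1 <- fixes$errSd[i]; e2 <- fixes$errSd[i + 1L]
    for (k in seq_len(sub)) {
      alpha <- (k - 0.5) / sub
      mx <- (1 - alpha) * fixes$x[i] + alpha * fixes$x[i + 1L]
      my <- (1 - alpha) * fixes$y[i] + alpha * fixes$y[i + 1L]
      s <- T * alpha * (1 - alpha) * sig[i] +
        (1 - alpha)^2 * e1^2 + alpha^2 * e2^2
      sd3 <- 3 * sqrt(s)
      if (mx - sd3 < xmin || mx + sd3 > xmax ||
          my - sd3 < ymin || my + sd3 > ymax)
        stop("grid does not contain the 3-SD envelope of a bridge; ",
             "enlarge the extent (see trackGrid())")
      if (s < 1e-12) {
        ## degenerate bridge: all mass in the containing cell
        ij <- cellIndexOf(grid, mx, my)
        vals[ij[1, "row"] + 1L, ij[1, "col"] + 1L] <-
          vals[ij[1, "row"] + 1L, ij[1, "col"] + 1L] + wgt
        next
      }
      rad <- 5 * sqrt(s)
      c1 <- max(1L, floor((mx - rad - xmin) / cs) + 1L)
      c2 <- min(grid@nCols, floor((mx + rad - xmin) / cs) + 1L)
      r1 <- max(1L, floor((my - rad - ymin) / cs) + 1L)
      r2 <- min(grid@nRows, floor((my + rad - ymin) / cs) + 1L)
      if (c2 < c1 || r2 < r1) next
      ex <- exp(-(cx[c1:c2] - mx)^2 / (2 * s))
      ey <- exp(-(cy[r1:r2] - my)^2 / (2 * s))
      vals[r1:r2, c1:c2] <- vals[r1:r2, c1:c2] +
        (wgt * area / (2 * pi * s)) * outer(ey, ex)
    }
  }
  udRaster(grid, vals, nFixes = n, normalize = TRUE)
}
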