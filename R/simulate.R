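## Synthetic telemetry, turbine fields and wind-power-class rasters with
## known ground truth. The generator emulates the sampling design of GPS
## transmitters that record hourly daylight fixes plus one midnight fix with
## ~18 m location error, and mixed resident/migratory behaviour with
## piecewise Brownian motion variance.

#' Simulation configuration
#'
#' Defines the behavioural schedule and observation model for one synthetic
#' individual. The true path is Brownian motion with a piecewise-constant
#' motion variance around a drift: zero drift while resident, along-corridor
#' drift at `migrationSpeed` while migrating. Observations add isotropic
#' Gaussian location error.
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param nIndividuals number of animals to simulate.
#' @param corridor two-column matrix of planar points (m), the migration
#'   polyline from the wintering end to the summering end. Default a due-north
#'   600 km corridor.
#' @param residentCenter starting point (m); default the corridor start.
#' @param migrationSpeed net migration drift in m/day (default 1e5, i.e.
#'   100 km/day, a realistic migration pace for a large soaring raptor).
#' @param phases data.frame with columns `label`
#'   (`resident` / `migrating-north` / `migrating-south`) and `days`; `NA`
#'   days for a migrating phase are derived from corridor length and speed.
#'   The default schedule is residence, a northward migration up the full
#'   corridor, a 60-day residence, a southward return, and a final residence.
#' @param sigmaRegimes data.frame with columns `durationHours` and `sigma2`
#'   (m^2/s), the piecewise motion-variance schedule from the start of the
#'   simulation. `NULL` (default) derives one regime per phase:
#'   `residentSigma2` while resident and `migratingSigma2` while migrating.
#' @param residentSigma2,migratingSigma2 default motion variances (m^2/s)
#'   used when `sigmaRegimes` is `NULL`.
#' @param locErrorSd location-error SD in meters (default 18).
#' @param dayStart,dayEnd first and last daylight fix hour (default 06:00 and
#'   19:00 UTC, i.e. 14 hourly daylight fixes).
#' @param nightFix add one fix at midnight (default TRUE).
#' @param startTime POSIXct start of the simulation (default 2008-03-01 UTC).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nIndividuals = 1L,
                      corridor = rbind(c(0, 0), c(0, 6e5)),
                      residentCenter = corridor[1, ],
                      migrationSpeed = 1e5,
                      phases = NULL,
                      sigmaRegimes = NULL,
                      residentSigma2 = 0.2, migratingSigma2 = 5,
                      locErrorSd = 18,
                      dayStart = 6L, dayEnd = 19L, nightFix = TRUE,
                      startTime = as.POSIXct("2008-03-01 00:00:00",
                                             tz = "UTC")) {
  corridor <- as.matrix(corridor)
  if (ncol(corridor) != 2 || nrow(corridor) < 2 || !all(is.finite(corridor)))
    stop("corridor must be a 2-column matrix of >= 2 finite points")
  if (!is.finite(locErrorSd) || locErrorSd < 0)
    stop("locErrorSd must be >= 0")
  if (migrationSpeed <= 0) stop("migrationSpeed must be positive")
  if (is.null(phases)) {
    phases <- data.frame(
      label = c("resident", "migrating-north", "resident",
                "migrating-south", "resident"),
      days = c(7, NA, 60, NA, 7))
  }
  if (!all(phases$label %in% c("resident", "migrating-north",
                               "migrating-south")))
    stop("phase labels must be resident / migrating-north / migrating-south")
  corLen <- sum(sqrt(rowSums(diff(corridor)^2)))
  mig <- is.na(phases$days)
  phases$days[mig] <- corLen / migrationSpeed
  if (any(phases$days <= 0)) stop("phase durations must be positive")
  if (is.null(sigmaRegimes)) {
    sigmaRegimes <- data.frame(
      durationHours = phases$days * 24,
      sigma2 = ifelse(phases$label == "resident",
                      residentSigma2, migratingSigma2))
  }
  if (nrow(sigmaRegimes) == 0) stop("sigmaRegimes must not be empty")
  if (any(!is.finite(sigmaRegimes$sigma2)) || any(sigmaRegimes$sigma2 < 0))
    stop("sigma2 must be finite and >= 0")
  structure(list(seed = as.integer(seed), nIndividuals = as.integer(nIndividuals),
                 corridor = corridor, residentCenter = as.numeric(residentCenter),
                 migrationSpeed = migrationSpeed, phases = phases,
                 sigmaRegimes = sigmaRegimes, locErrorSd = locErrorSd,
                 dayStart = as.integer(dayStart), dayEnd = as.integer(dayEnd),
                 nightFix = isTRUE(nightFix), startTime = startTime),
            class = "SimConfig")
}

## Fix times for one simulated deployment: per day, optionally one midnight
## fix plus hourly fixes dayStart..dayEnd, for nDays days.
fixTimes <- function(config, nDays) {
  hours <- c(if (config$nightFix) 0L, config$dayStart:config$dayEnd)
  offs <- as.vector(outer(hours * 3600, (seq_len(nDays) - 1L) * 86400, "+"))
  config$startTime + sort(offs)
}

## Piecewise-constant schedule lookup: value active on [start_k, start_{k+1}).
## starts in seconds from simulation start; returns integrated value * dt and
## also supports querying the active index.
scheduleStarts <- function(durationsHours)
  c(0, cumsum(durationsHours * 3600))

## Integrate a piecewise-constant rate over [t0, t1] (seconds from start).
integrateSchedule <- function(starts, values, t0, t1) {
  if (t1 <= t0) return(0)
  tot <- 0
  for (k in seq_along(values)) {
    lo <- max(t0, starts[k])
    hi <- min(t1, starts[k + 1])
    if (hi > lo) tot <- tot + values[k] * (hi - lo)
  }
  ## time past the last regime keeps the last value
  if (t1 > starts[length(starts)])
    tot <- tot + values[length(values)] *
      (t1 - max(t0, starts[length(starts)]))
  tot
}

## Corridor geometry: cumulative vertex distances and the unit tangent at a
## given arc-length position.
corridorTangent <- function(corridor, pos) {
  seglen <- sqrt(rowSums(diff(corridor)^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  pos <- min(max(pos, 0), L)
  k <- findInterval(pos, cum, rightmost.closed = TRUE)
  k <- min(max(k, 1L), nrow(corridor) - 1L)
  d <- corridor[k + 1L, ] - corridor[k, ]
  d / sqrt(sum(d^2))
}

#' Simulate one telemetry track with ground truth
#'
#' Draws the true path as drifted Brownian motion under the configured phase
#' and variance schedules, samples it at hourly daylight times plus one
#' midnight fix, and adds isotropic Gaussian location error. Everything
#' needed for recovery tests is returned alongside the observed track.
#'
#' @param config a [simConfig()] object.
#' @param individual index used to derive the per-animal seed and id.
#' @return A list with elements
#'   `track` (a [TelemetryTrack-class] of observed fixes),
#'   `truth` (list: `trueX`, `trueY` per fix; `sigma2` — effective true
#'   motion variance per inter-fix interval; `phase` — label per fix;
#'   `changePoints` — POSIXct times where the variance regime changes).
#' @examples
#' cfg <- simConfig(seed = 7, locErrorSd = 0, residentSigma2 = 0,
#'                  migratingSigma2 = 0)
#' sim <- simulateTrack(cfg)
#' sim$track
#' @export
simulateTrack <- function(config, individual = 1L) {
  stopifnot(inherits(config, "SimConfig"))
  withSeed(config$seed + 7919L * (as.integer(individual) - 1L), {
    nDays <- ceiling(sum(config$phases$days))
    tt <- fixTimes(config, nDays)
    secs <- as.numeric(tt) - as.numeric(config$startTime)
    n <- length(tt)

    phStarts <- scheduleStarts(config$phases$days * 24)
    phIdx <- function(s) min(findInterval(s, phStarts,
                                          rightmost.closed = TRUE),
                             nrow(config$phases))
    regStarts <- scheduleStarts(config$sigmaRegimes$durationHours)
    regVals <- config$sigmaRegimes$sigma2

    ## drift rate (m/s along corridor, signed) is piecewise by phase
    driftSign <- ifelse(config$phases$label == "migrating-north", 1,
                        ifelse(config$phases$label == "migrating-south", -1, 0))

    trueX <- trueY <- numeric(n)
    pos <- config$residentCenter
    prog <- 0  # arc-length progress along the corridor
    trueX[1] <- pos[1]; trueY[1] <- pos[2]
    sig2eff <- numeric(n - 1L)
    for (i in seq_len(n - 1L)) {
      t0 <- secs[i]; t1 <- secs[i + 1L]
      ## split the gap at phase boundaries so drift follows the schedule
      cuts <- sort(unique(c(t0, t1, phStarts[phStarts > t0 & phStarts < t1])))
      for (k in seq_len(length(cuts) - 1L)) {
        a <- cuts[k]; b <- cuts[k + 1L]
        ph <- phIdx(a)
        sgn <- driftSign[ph]
        if (sgn != 0) {
          step <- config$migrationSpeed * (b - a) / 86400
          u <- corridorTangent(config$corridor, prog)
          pos <- pos + sgn * step * u
          prog <- prog + sgn * step
          seglen <- sqrt(rowSums(diff(config$corridor)^2))
          prog <- min(max(prog, 0), sum(seglen))
        }
      }
      v <- integrateSchedule(regStarts, regVals, t0, t1)  # m^2 per coordinate
      sig2eff[i] <- v / (t1 - t0)
      if (v > 0) pos <- pos + stats::rnorm(2, 0, sqrt(v))
      if (!all(is.finite(pos))) stop("non-finite simulated coordinates")
      trueX[i + 1L] <- pos[1]; trueY[i + 1L] <- pos[2]
    }

    obsX <- trueX; obsY <- trueY
    if (config$locErrorSd > 0) {
      obsX <- obsX + stats::rnorm(n, 0, config$locErrorSd)
      obsY <- obsY + stats::rnorm(n, 0, config$locErrorSd)
    }
    phase <- config$phases$label[vapply(secs, phIdx, integer(1))]
    cps <- config$startTime +
      regStarts[-c(1, length(regStarts))]

    id <- sprintf("sim-%02d", as.integer(individual))
    list(track = telemetryTrack(id, tt, obsX, obsY, config$locErrorSd),
         truth = list(trueX = trueX, trueY = trueY, sigma2 = sig2eff,
                      phase = phase, changePoints = cps))
  })
}

#' Simulate a clustered turbine field
#'
#' Poisson-cluster point process emulating ridgeline wind farms: cluster
#' centers uniform in the extent, turbines scattered around each center with
#' an isotropic Gaussian (redrawn until inside the extent), each carrying a
#' total height drawn uniformly in `heightRangeM`.
#'
#' @param seed RNG seed.
#' @param nClusters number of wind farms.
#' @param turbinesPerCluster turbines in each farm.
#' @param clusterSdM within-farm scatter SD (m).
#' @param extent `c(xmin, xmax, ymin, ymax)` in meters.
#' @param heightRangeM `c(min, max)` turbine total height (m AGL).
#' @return data.frame with columns `id`, `x`, `y`, `heightM`, `cluster`.
#' @export
simulateTurbines <- function(seed, nClusters, turbinesPerCluster,
                             clusterSdM = 2000,
                             extent, heightRangeM = c(80, 150)) {
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("degenerate extent: need c(xmin, xmax, ymin, ymax) with positive spans")
  n <- nClusters * turbinesPerCluster
  if (n == 0)
    return(data.frame(id = character(), x = numeric(), y = numeric(),
                      heightM = numeric(), cluster = integer()))
  withSeed(seed, {
    cx <- stats::runif(nClusters, extent[1], extent[2])
    cy <- stats::runif(nClusters, extent[3], extent[4])
    xs <- ys <- numeric(n)
    cl <- rep(seq_len(nClusters), each = turbinesPerCluster)
    for (i in seq_len(n)) {
      for (tries in 1:1000) {
        p <- c(cx[cl[i]], cy[cl[i]]) + stats::rnorm(2, 0, clusterSdM)
        if (p[1] >= extent[1] && p[1] < extent[2] &&
            p[2] >= extent[3] && p[2] < extent[4]) break
      }
      xs[i] <- p[1]; ys[i] <- p[2]
    }
    h <- stats::runif(n, heightRangeM[1], heightRangeM[2])
    data.frame(id = sprintf("T%04d", seq_len(n)), x = xs, y = ys,
               heightM = h, cluster = cl)
  })
}

#' Simulate a smooth wind-power-class raster
#'
#' Smooths white noise with a circular Gaussian kernel (via FFT) to obtain a
#' spatially coherent latent field, then assigns classes 1-7 by rank so the
#' marginal class frequencies match `classProbs` up to integer rounding.
#'
#' @param seed RNG seed.
#' @param grid an [AnalysisGrid-class].
#' @param smoothness Gaussian kernel SD in cells (default 5).
#' @param classProbs length-7 nonnegative vector summing to 1 (tolerance
#'   1e-9); marginal probability of each wind power class.
#' @return A [ClassRaster-class] on `grid`.
#' @export
simulateWpcRaster <- function(seed, grid, smoothness = 5,
                              classProbs = rep(1 / 7, 7)) {
  if (length(classProbs) != 7 || any(classProbs < 0))
    stop("classProbs must be 7 nonnegative probabilities")
  if (abs(sum(classProbs) - 1) > 1e-9)
    stop("classProbs must sum to 1 (tolerance 1e-9)")
  nr <- grid@nRows; nc <- grid@nCols
  withSeed(seed, {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (smoothness > 0) {
      gk <- function(n) {
        d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
        k <- exp(-d^2 / (2 * smoothness^2))
        k / sum(k)
      }
      K <- outer(gk(nr), gk(nc))
      z <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) /
        (nr * nc)
    }
    ## rank-based thresholding: exact marginal frequencies up to rounding
    r <- rank(z, ties.method = "first")
    cum <- cumsum(classProbs)[1:6]
    cls <- findInterval((r - 0.5) / length(r), cum) + 1L
    classRaster(grid, matrix(cls, nr, nc))
  })
}
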