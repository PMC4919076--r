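## Migration-segment extraction: continuous directional north/south
## movements with at least 100 km net north-south displacement, padded by
## ~24 h of extra fixes, and excluded when shorter than the model window.

## Per-UTC-day net northing displacement (m) and bounding fix indices.
dailyDisplacement <- function(fixes) {
  day <- as.Date(fixes$t, tz = "UTC")
  idx <- split(seq_len(nrow(fixes)), day)
  data.frame(day = as.Date(names(idx)),
             first = vapply(idx, `[`, integer(1), 1L),
             last = vapply(idx, function(i) i[length(i)], integer(1)),
             dy = vapply(idx, function(i)
               fixes$y[i[length(i)]] - fixes$y[i[1]], numeric(1)),
             row.names = NULL)
}

#' Find directional migration segments in a track
#'
#' Operationalizes "continuous directional movement north or south" at the
#' day level: days whose net north-south displacement exceeds
#' `minDailyKm` with a consistent sign form runs, tolerating up to
#' `maxStopoverDays` consecutive interior days below threshold (stopovers).
#' Runs whose total net north-south displacement reaches `minKm` are
#' returned as segments; repeated migrations within a season yield separate
#' segments. Direction is the sign of the net change in projected northing.
#'
#' @param track a [TelemetryTrack-class].
#' @param minKm minimum |net N-S displacement| of the whole run (km;
#'   default 100).
#' @param minDailyKm daily displacement threshold for a "travel day"
#'   (default 20 km).
#' @param maxStopoverDays tolerated consecutive interior non-travel days
#'   (default 1).
#' @return list of [MigrationSegment-class] (padded range initially equal to
#'   the core; see [padSegment()]).
#' @export
findMigrationSegments <- function(track, minKm = 100, minDailyKm = 20,
                                  maxStopoverDays = 1) {
  f <- trackFixes(track)
  if (!nrow(f)) stop("empty track")
  dd <- dailyDisplacement(f)
  thr <- minDailyKm * 1000
  sgn <- ifelse(dd$dy >= thr, 1L, ifelse(dd$dy <= -thr, -1L, 0L))

  segs <- list()
  n <- nrow(dd)
  i <- 1L
  while (i <= n) {
    if (sgn[i] == 0L) { i <- i + 1L; next }
    dir <- sgn[i]
    j <- i
    gap <- 0L
    last <- i
    while (j < n) {
      nxt <- sgn[j + 1L]
      if (nxt == dir) { j <- j + 1L; last <- j; gap <- 0L }
      else if (nxt == 0L && gap < maxStopoverDays) { j <- j + 1L; gap <- gap + 1L }
      else break
    }
    a <- dd$first[i]; b <- dd$last[last]
    net <- f$y[b] - f$y[a]
    if (abs(net) >= minKm * 1000 && sign(net) == dir) {
      segs[[length(segs) + 1L]] <- new(
        "MigrationSegment", trackId = individualId(track),
        direction = if (dir > 0) "north" else "south",
        coreStart = a, coreEnd = b, padStart = a, padEnd = b,
        netKm = net / 1000)
    }
    i <- last + 1L
  }
  segs
}

#' Pad a segment with ~24 h of flanking fixes
#'
#' Extends the segment's fix range to include all parent-track fixes within
#' `padHours` before the first core fix and after the last one, so the whole
#' migration movement is inside the modelled track. Never exceeds the track
#' bounds.
#'
#' @param segment a [MigrationSegment-class] from `track`.
#' @param track the parent [TelemetryTrack-class].
#' @param padHours padding window in hours (default 24).
#' @return The segment with an updated padded range.
#' @export
padSegment <- function(segment, track, padHours = 24) {
  stopifnot(identical(segment@trackId, individualId(track)))
  f <- trackFixes(track)
  t0 <- as.numeric(f$t[segment@coreStart]) - padHours * 3600
  t1 <- as.numeric(f$t[segment@coreEnd]) + padHours * 3600
  tn <- as.numeric(f$t)
  segment@padStart <- min(which(tn >= t0))
  segment@padEnd <- max(which(tn <= t1))
  validObject(segment)
  segment
}

#' Apply the minimum-length exclusion rule
#'
#' Segments whose padded fix count is below the model window size cannot be
#' fitted and are excluded (with the reason reported via `message()`).
#'
#' @param segments list of [MigrationSegment-class].
#' @param window model window size in fixes (default 17).
#' @return list with elements `kept` and `excluded`.
#' @export
applyExclusion <- function(segments, window = 17) {
  short <- vapply(segments, function(s) segmentNFixes(s) < window, logical(1))
  if (any(short))
    message(sum(short), " segment(s) excluded: fewer than ", window,
            " fixes after padding")
  list(kept = segments[!short], excluded = segments[short])
}

#' Segment summary table
#'
#' @param segments list of [MigrationSegment-class].
#' @param tracks list of parent [TelemetryTrack-class] (for timestamps).
#' @param excluded logical flag recorded for every row.
#' @return data.frame: track id, direction, start/end time, net km, fix
#'   count, excluded flag.
#' @export
segmentTable <- function(segments, tracks, excluded = FALSE) {
  ids <- vapply(tracks, individualId, character(1))
  rows <- lapply(segments, function(s) {
    f <- trackFixes(tracks[[match(s@trackId, ids)]])
    data.frame(trackId = s@trackId, direction = s@direction,
               start = f$t[s@padStart], end = f$t[s@padEnd],
               netKm = s@netKm, nFixes = segmentNFixes(s),
               excluded = excluded)
  })
  if (!length(rows))
    return(data.frame(trackId = character(), direction = character(),
                      start = as.POSIXct(character()),
                      end = as.POSIXct(character()), netKm = numeric(),
                      nFixes = integer(), excluded = logical()))
  do.call(rbind, rows)
}
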