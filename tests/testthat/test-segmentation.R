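# Toy track with two fixes per day (06:00 and 18:00 UTC) whose daily net
# northing displacements are given in km.
dailyTrack <- function(dailyKm, id = "toy") {
  y0 <- cumsum(c(0, dailyKm * 1000))
  tt <- x <- y <- c()
  for (d in seq_along(dailyKm)) {
    base <- as.POSIXct("2008-03-01", tz = "UTC") + (d - 1) * 86400
    tt <- c(tt, base + c(6, 18) * 3600)
    y <- c(y, y0[d], y0[d + 1])
    x <- c(x, 0, 0)
  }
  telemetryTrack(id, as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                 x, y, errSd = 18)
}

test_that("a sustained northward run above both thresholds becomes one segment", {
  tr <- dailyTrack(c(40, 40, 40, 40, 40, 0, 0, 0))
  segs <- findMigrationSegments(tr)
  expect_length(segs, 1)
  expect_equal(segs[[1]]@direction, "north")
  expect_equal(segs[[1]]@netKm, 200, tolerance = 1e-9)
})

test_that("runs under the 100 km total threshold are rejected", {
  expect_length(findMigrationSegments(dailyTrack(c(20, 20, 20))), 0)
})

test_that("stopover tolerance joins runs; longer pauses split them", {
  # one interior rest day within tolerance -> single segment
  tr1 <- dailyTrack(c(40, 40, 0, 40, 40))
  expect_length(findMigrationSegments(tr1), 1)
  # two consecutive rest days exceed maxStopoverDays = 1 -> split; each half
  # is 80 km and fails the 100 km rule
  tr2 <- dailyTrack(c(40, 40, 0, 0, 40, 40))
  expect_length(findMigrationSegments(tr2), 0)
  # direction flip splits immediately: two opposite segments
  tr3 <- dailyTrack(c(60, 60, -60, -60))
  segs <- findMigrationSegments(tr3)
  expect_equal(vapply(segs, function(s) s@direction, character(1)),
               c("north", "south"))
})

test_that("mirroring y swaps direction labels but preserves boundaries", {
  tr <- dailyTrack(c(40, 40, 40, 0, -30, 40, 40, 40))
  f <- trackFixes(tr)
  trM <- telemetryTrack("m", f$t, f$x, -f$y, f$errSd)
  s1 <- findMigrationSegments(tr)
  s2 <- findMigrationSegments(trM)
  expect_equal(length(s1), length(s2))
  for (k in seq_along(s1)) {
    expect_equal(s1[[k]]@coreStart, s2[[k]]@coreStart)
    expect_equal(s1[[k]]@coreEnd, s2[[k]]@coreEnd)
    expect_equal(s1[[k]]@netKm, -s2[[k]]@netKm)
    expect_false(s1[[k]]@direction == s2[[k]]@direction)
  }
})

test_that("segments are contiguous ordered slices of the parent track", {
  sim <- simulateTrack(simConfig(seed = 21))
  segs <- findMigrationSegments(sim$track)
  for (s in segs) {
    f <- segmentFixes(padSegment(s, sim$track), sim$track)
    expect_true(all(diff(as.numeric(f$t)) > 0))
    expect_equal(nrow(f), segmentNFixes(padSegment(s, sim$track)))
  }
})

test_that("simulated north + 60-day residence + south is recovered as two segments", {
  ok <- 0L
  for (s in 1:50) {
    sim <- simulateTrack(simConfig(seed = 1000L + s))
    segs <- findMigrationSegments(sim$track)
    dirs <- vapply(segs, function(x) x@direction, character(1))
    if (identical(dirs, c("north", "south"))) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.95)
})

test_that("padding adds up to 24 h of flanking fixes and respects bounds", {
  tr <- dailyTrack(c(0, 0, 40, 40, 40, 0, 0))
  seg <- findMigrationSegments(tr)[[1]]
  p <- padSegment(seg, tr, padHours = 24)
  f <- trackFixes(tr)
  expect_lte(as.numeric(f$t[seg@coreStart]) - as.numeric(f$t[p@padStart]),
             24 * 3600)
  expect_true(p@padStart <= seg@coreStart && p@padEnd >= seg@coreEnd)
  # identity at zero padding
  p0 <- padSegment(seg, tr, padHours = 0)
  expect_equal(c(p0@padStart, p0@padEnd), c(seg@coreStart, seg@coreEnd))
  # hourly fixes: 24 h of padding adds at most 24 fixes per side
  th <- as.POSIXct("2008-03-01", tz = "UTC") + 3600 * (0:199)
  trh <- telemetryTrack("h", th, rep(0, 200),
                        c(rep(0, 72), seq(0, 2e5, length.out = 56),
                          rep(2e5, 72)), 18)
  sh <- findMigrationSegments(trh)[[1]]
  ph <- padSegment(sh, trh, padHours = 24)
  expect_lte(sh@coreStart - ph@padStart, 24)
  expect_lte(ph@padEnd - sh@coreEnd, 24)
  # segment starting at the first fix gets no left padding
  tr0 <- dailyTrack(c(40, 40, 40, 0))
  s0 <- findMigrationSegments(tr0)[[1]]
  expect_equal(padSegment(s0, tr0)@padStart, 1L)
})

test_that("the window-size exclusion removes exactly the short segments", {
  mkseg <- function(n) new("MigrationSegment", trackId = "t",
                           direction = "north", coreStart = 1L,
                           coreEnd = as.integer(n), padStart = 1L,
                           padEnd = as.integer(n), netKm = 150)
  segs <- c(lapply(rep(34, 132), mkseg), list(mkseg(16L)))
  expect_message(res <- applyExclusion(segs, window = 17), "excluded")
  expect_length(res$kept, 132)
  expect_length(res$excluded, 1)
  # boundary: exactly 17 fixes is kept
  res2 <- applyExclusion(list(mkseg(17L)), window = 17)
  expect_length(res2$kept, 1)
})
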