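test_that("all three generators are deterministic under a fixed seed", {
  cfg <- simConfig(seed = 11)
  s1 <- simulateTrack(cfg); s2 <- simulateTrack(cfg)
  expect_identical(trackFixes(s1$track), trackFixes(s2$track))
  expect_identical(s1$truth, s2$truth)

  ext <- c(0, 5e4, 0, 5e4)
  t1 <- simulateTurbines(3, 4, 10, 2000, ext)
  t2 <- simulateTurbines(3, 4, 10, 2000, ext)
  expect_identical(t1, t2)

  g <- analysisGrid(c(0, 0), 1000, 40, 40)
  w1 <- simulateWpcRaster(5, g); w2 <- simulateWpcRaster(5, g)
  expect_identical(classValues(w1), classValues(w2))
})

test_that("noise-free resident track sits exactly at the resident center", {
  cfg <- simConfig(seed = 2, locErrorSd = 0, residentSigma2 = 0,
                   migratingSigma2 = 0,
                   phases = data.frame(label = "resident", days = 3),
                   residentCenter = c(1234, -567))
  fx <- trackFixes(simulateTrack(cfg)$track)
  expect_true(all(fx$x == 1234))
  expect_true(all(fx$y == -567))
  # 15 fixes per day: midnight + hourly 06:00-19:00
  expect_equal(nrow(fx), 45)
  expect_equal(sort(unique(as.integer(format(fx$t, "%H")))),
               c(0L, 6:19))
})

test_that("migration drift accumulates the configured speed (100 km/day x 3 days)", {
  nets <- vapply(1:20, function(s) {
    cfg <- simConfig(seed = s, migrationSpeed = 1e5, locErrorSd = 0,
                     corridor = rbind(c(0, 0), c(0, 4e5)),
                     phases = data.frame(label = "migrating-north", days = 3),
                     migratingSigma2 = 0.5)
    fx <- trackFixes(simulateTrack(cfg)$track)
    span <- as.numeric(fx$t[nrow(fx)]) - as.numeric(fx$t[1])
    c(net = fx$y[nrow(fx)] - fx$y[1], drift = 1e5 * span / 86400)
  }, numeric(2))
  # net northing ~ 300 km within 10%, allowing for Brownian wander and the
  # fix schedule ending at 19:00 on the last day
  expect_true(all(abs(nets["net", ] / 3e5 - 1) < 0.1))
  # and the mean matches the exact accumulated drift over the fix span
  expect_lt(abs(mean(nets["net", ] / nets["drift", ]) - 1), 0.02)
})

test_that("observation errors have the configured SD and Brownian scaling holds", {
  cfg <- simConfig(seed = 4, locErrorSd = 18, residentSigma2 = 2,
                   migratingSigma2 = 2,
                   phases = data.frame(label = "resident", days = 700))
  sim <- simulateTrack(cfg)
  fx <- trackFixes(sim$track)
  expect_gte(nrow(fx), 1e4)
  res <- c(fx$x - sim$truth$trueX, fx$y - sim$truth$trueY)
  expect_lt(abs(sd(res) / 18 - 1), 0.05)

  # per-coordinate squared displacement of the true path over each gap has
  # mean sigma2 * dt (pure Brownian regime, zero drift)
  dt <- diff(as.numeric(fx$t))
  dx2 <- diff(sim$truth$trueX)^2 / dt
  dy2 <- diff(sim$truth$trueY)^2 / dt
  expect_gte(length(dx2), 1e3)
  expect_lt(abs(mean(c(dx2, dy2)) / 2 - 1), 0.1)
})

test_that("truth records phases and strictly increasing change points", {
  sim <- simulateTrack(simConfig(seed = 9))
  expect_equal(length(sim$truth$phase), nFixes(sim$track))
  expect_true(all(sim$truth$phase %in%
                    c("resident", "migrating-north", "migrating-south")))
  expect_true(all(diff(as.numeric(sim$truth$changePoints)) > 0))
  expect_equal(length(sim$truth$sigma2), nFixes(sim$track) - 1L)
})

test_that("turbine fields honour counts, extent and degenerate inputs", {
  expect_equal(nrow(simulateTurbines(1, 0, 10, 500, c(0, 1e4, 0, 1e4))), 0)
  tb <- simulateTurbines(7, 5, 20, 1500, c(0, 2e4, -1e4, 1e4),
                         heightRangeM = c(90, 140))
  expect_equal(nrow(tb), 100)
  expect_true(all(tb$x >= 0 & tb$x < 2e4 & tb$y >= -1e4 & tb$y < 1e4))
  expect_true(all(tb$heightM >= 90 & tb$heightM <= 140))
  expect_error(simulateTurbines(1, 2, 5, 100, c(0, 0, 0, 1e4)), "extent")
})

test_that("wind-power-class raster matches requested class frequencies", {
  g <- analysisGrid(c(0, 0), 1000, 350, 350)  # >= 1e5 cells
  w <- simulateWpcRaster(12, g, smoothness = 4)
  freq <- as.vector(table(factor(classValues(w), levels = 1:7))) / (350 * 350)
  expect_true(all(abs(freq - 1 / 7) < 0.02))

  w1 <- simulateWpcRaster(1, analysisGrid(c(0, 0), 1000, 20, 20),
                          classProbs = c(1, 0, 0, 0, 0, 0, 0))
  expect_true(all(classValues(w1) == 1L))
  expect_error(simulateWpcRaster(1, g, classProbs = rep(0.15, 7)),
               "sum to 1")
})
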