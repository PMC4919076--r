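test_that("bridge moments match the closed form at endpoints and midpoints", {
  # endpoint limit: all weight on the first fix, variance = its error
  m0 <- bridgeMoments(c(1, 2), c(9, 9), 0, 3600, 0, 0.5, 18, 7)
  expect_equal(m0$mean, c(1, 2))
  expect_equal(m0$var, 324)
  # degenerate: no motion variance, no error -> a point on the chord
  md <- bridgeMoments(c(0, 0), c(100, 0), 0, 100, 25, 0, 0, 0)
  expect_equal(md$mean, c(25, 0))
  expect_equal(md$var, 0)
  # direct substitution: T = 3600, alpha = 0.5, sigma2 = 0.5, err = 18
  mm <- bridgeMoments(c(0, 0), c(0, 0), 0, 3600, 1800, 0.5, 18, 18)
  expect_equal(mm$var, 450 + 81 + 81)
  expect_error(bridgeMoments(c(0, 0), c(0, 0), 0, 3600, 4000, 1), "outside")
})

test_that("three-fix likelihood has its optimum at the closed-form sigma2 = 2", {
  fx <- threeFixTrack()
  # independent check: fine grid search over the exported likelihood
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 20000))
  nll <- vapply(grid, function(s) looNegLogLik(fx, s), numeric(1))
  expect_equal(grid[which.min(nll)], 2, tolerance = 1e-3)
  # the fitted optimizer agrees within 1%
  expect_equal(fitSigma(fx), 2, tolerance = 0.01)
  # likelihood decays monotonically beyond the optimum
  far <- vapply(c(10, 100, 1000, 10000), function(s) looNegLogLik(fx, s),
                numeric(1))
  expect_true(all(diff(far) > 0))
})

test_that("fitted sigma2 scales as c^2 when coordinates scale by c", {
  fx <- brownianTrack(17, 60, 1.5)
  s1 <- fitSigma(fx)
  fx3 <- fx; fx3$x <- 3 * fx$x; fx3$y <- 3 * fx$y
  expect_equal(fitSigma(fx3), 9 * s1, tolerance = 1e-6)
})

test_that("stationary noisy fixes yield a near-zero motion variance", {
  meds <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 40
    fx <- data.frame(t = 3600 * (0:(n - 1)), x = rnorm(n, 0, 18),
                     y = rnorm(n, 0, 18), errSd = 18)
    fitSigma(fx)
  }, numeric(1))
  expect_lte(median(meds), 1e-3)
})

test_that("degenerate identical positions return zero with a warning", {
  fx <- data.frame(t = 3600 * (0:9), x = 0, y = 0, errSd = 0)
  expect_warning(s <- fitSigma(fx), "degenerate")
  expect_equal(s, 0)
})

test_that("constant-sigma tracks rarely select breakpoints and the profile is unbiased", {
  profs <- vapply(1:20, function(s) {
    p <- dynamicVariance(brownianTrack(s, 120, 2))
    c(breakFraction(p), motionVariance(p))
  }, numeric(120))
  expect_lt(mean(profs[1, ]), 0.2)
  avg <- rowMeans(profs[-1, , drop = FALSE])
  expect_true(all(abs(avg / 2 - 1) < 0.2))
})

test_that("a sharp variance regime change is localized by the profile jump", {
  fx <- twoRegimeTrack(105, n = 300, s1 = 0.2, s2 = 5, cp = 150)
  prof <- dynamicVariance(fx)
  expect_lte(abs(profileChangepoint(prof) - 150), 3)
  # the two plateaus bracket their regimes
  sig <- motionVariance(prof)
  expect_lt(median(sig[1:130]), 0.5)
  expect_gt(median(sig[170:299]), 2.5)
})

test_that("with breakpoints disabled a single window reduces to the static fit", {
  fx <- brownianTrack(31, 17, 1)
  p <- dynamicVariance(fx, bridgeParams(window = 17,
                                        allowBreaks = FALSE))
  expect_identical(unique(motionVariance(p)), fitSigma(fx))
  g <- trackGrid(fx, p, bridgeParams(cellSize = 200))
  udDyn <- computeUD(fx, p, g, bridgeParams(cellSize = 200))
  udStat <- computeUD(fx, rep(fitSigma(fx), 16), g,
                      bridgeParams(cellSize = 200))
  expect_identical(udValues(udDyn), udValues(udStat))
})

test_that("UD surfaces normalize, mirror and translate exactly", {
  fx <- data.frame(t = c(0, 1800, 3600), x = c(0, 600, 0),
                   y = c(0, 400, -100), errSd = 50)
  bp <- bridgeParams(cellSize = 100)
  g <- analysisGrid(c(-2000, -2000), 100, 46, 42)
  ud <- computeUD(fx, c(20, 20), g, bp)
  expect_equal(sum(udValues(ud)), 1, tolerance = 1e-6)

  # mirror about the x axis on a y-symmetric grid
  fxm <- fx; fxm$y <- -fx$y
  gm <- analysisGrid(c(-2000, -2200), 100, 46, 42)  # mirror of g's y-extent
  udm <- computeUD(fxm, c(20, 20), gm, bp)
  expect_equal(udValues(udm), udValues(ud)[nrow(udValues(ud)):1, ],
               tolerance = 1e-12)

  # translation equivariance
  sh <- c(12345, -6789)
  fxt <- fx; fxt$x <- fx$x + sh[1]; fxt$y <- fx$y + sh[2]
  gt <- analysisGrid(c(-2000 + sh[1], -2000 + sh[2]), 100, 46, 42)
  udt <- computeUD(fxt, c(20, 20), gt, bp)
  expect_lt(max(abs(udValues(udt) - udValues(ud))) / max(udValues(ud)),
            1e-9)

  # a grid that cannot hold the 3-SD envelope is a hard error
  gsmall <- analysisGrid(c(-100, -100), 100, 8, 6)
  expect_error(computeUD(fx, c(20, 20), gsmall, bp), "3-SD envelope")
})

test_that("the default integration matches a fine-discretization oracle", {
  fx <- data.frame(t = c(0, 1800, 3600), x = c(0, 600, 0),
                   y = c(0, 400, 0), errSd = 200)
  bp <- bridgeParams(cellSize = 100)
  g <- trackGrid(fx, c(30, 30), bp, bufferMinM = 1500)
  ud <- computeUD(fx, c(30, 30), g, bp)
  orc <- oracleUD(fx, g, c(30, 30))
  expect_lte(max(abs(udValues(ud) - orc)) / max(orc), 0.02)
})

test_that("parameter validation rejects malformed bridge settings", {
  expect_error(bridgeParams(window = 16), "odd")
  expect_error(bridgeParams(margin = 2), "margin")
  expect_error(bridgeParams(substeps = 0), "substeps")
  fx <- brownianTrack(1, 10, 1)
  expect_error(dynamicVariance(fx, bridgeParams(window = 17)), "excluded")
})
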