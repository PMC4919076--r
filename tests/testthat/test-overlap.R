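# A 10 x 10 category map with two cells per category laid out along the
# bottom rows and the rest background.
fixtureMap <- function() {
  g <- analysisGrid(c(0, 0), 1000, 10, 10)
  m <- matrix(NA_integer_, 10, 10)
  m[1, 1:10] <- rep(c(20L, 40L, 60L, 80L, 100L), each = 2)
  new("CategoryMap", grid = g, categories = m, mode = "count")
}

test_that("turbine counting filters height, respects cell edges and conserves totals", {
  cm <- fixtureMap()
  tb <- data.frame(
    x = c(500, 1000, 2500, 99999, 500, 500),
    y = c(500, 500, 500, 500, 5500, 500),
    heightM = c(120, 150, 130, 101, 110, 99))
  counts <- countTurbines(cm, tb)
  # the 99 m turbine is excluded everywhere
  expect_equal(sum(counts), 5)
  # the turbine exactly on the cell edge x = 1000 belongs to column 1 (cat 20)
  expect_equal(unname(counts["20"]), 2L)
  expect_equal(unname(counts["40"]), 1L)
  expect_equal(unname(counts["out_of_extent"]), 1L)
  expect_equal(unname(counts["background"]), 1L)
  # conservation: categories + background + out-of-extent = filtered total
  expect_equal(sum(counts), sum(tb$heightM >= 100))
  # missing heights are excluded and reported
  tbNA <- rbind(tb, data.frame(x = 500, y = 500, heightM = NA))
  expect_message(c2 <- countTurbines(cm, tbNA), "missing height")
  expect_equal(sum(c2), 5)
})

test_that("turbines placed inside category-20 cells are all counted there", {
  cm <- fixtureMap()
  set.seed(8)
  tb <- data.frame(x = runif(100, 0, 2000), y = runif(100, 0, 1000),
                   heightM = runif(100, 100, 150))
  counts <- countTurbines(cm, tb)
  expect_equal(unname(counts["20"]), 100L)
})

test_that("wind-class overlap saturates, vanishes and halves as constructed", {
  cm <- fixtureMap()
  g <- cm@grid
  # all class 1: no overlap anywhere
  expect_true(all(wpcOverlap(cm, classRaster(g, matrix(1L, 10, 10))) == 0))
  # all class 7: overlap equals each category's area (200 ha)
  ov7 <- wpcOverlap(cm, classRaster(g, matrix(7L, 10, 10)))
  expect_equal(unname(ov7), rep(200, 5))
  # checkerboard 3/1 over 2-cell categories: half the area each
  chk <- matrix(3L, 10, 10)
  chk[(row(chk) + col(chk)) %% 2 == 1] <- 1L
  ovc <- wpcOverlap(cm, classRaster(g, chk))
  expect_true(all(abs(ovc - 100) <= 100))  # within one cell of half
  expect_equal(sum(ovc), 500)
  # overlap never exceeds the category area
  areas <- categoryAreas(cm)$hectares
  expect_true(all(ov7 <= areas + 1e-9))
  # mismatched grids are a hard error
  g2 <- analysisGrid(c(0, 0), 500, 10, 10)
  expect_error(wpcOverlap(cm, classRaster(g2, matrix(3L, 10, 10))),
               "resample")
})

test_that("nearest-neighbour resampling preserves classes cell-for-cell", {
  src <- classRaster(analysisGrid(c(0, 0), 2000, 5, 5),
                     matrix(sample(1:7, 25, TRUE), 5, 5))
  tgt <- analysisGrid(c(0, 0), 1000, 10, 10)
  rs <- resampleNearest(src, tgt)
  # each 2x2 block of the target inherits its source cell's class
  expect_equal(classValues(rs)[1, 1], classValues(src)[1, 1])
  expect_equal(classValues(rs)[2, 2], classValues(src)[1, 1])
  expect_equal(classValues(rs)[3, 3], classValues(src)[2, 2])
  # identical grids: identity
  same <- resampleNearest(src, src@grid)
  expect_identical(classValues(same), classValues(src))
  # outside the source extent -> NA
  big <- analysisGrid(c(-2000, -2000), 1000, 3, 3)
  expect_true(is.na(classValues(resampleNearest(src, big))[1, 1]))
})

test_that("report percentages recompute from its own raw columns", {
  set.seed(3)
  areas <- data.frame(category = c(20L, 40L, 60L, 80L, 100L),
                      hectares = c(5e5, 4e5, 3e5, 2e5, 1e5))
  ov <- setNames(c(1e4, 3e4, 2e4, 5e3, 0), c("20", "40", "60", "80", "100"))
  tc <- setNames(c(50L, 30L, 10L, 5L, 0L), c("20", "40", "60", "80", "100"))
  rep <- buildReport(areas, ov, tc, totalTurbines = 120)
  expect_equal(rep$pctTurbines,
               floor(100 * rep$installedTurbines / 120 + 0.5))
  expect_equal(rep$pctWpcOverlap,
               floor(100 * rep$wpcOverlapHectares / rep$udHectares + 0.5))
  expect_true(all(rep$wpcOverlapHectares <= rep$udHectares))
})

test_that("percentages round half away from zero like quoted figures", {
  areas <- data.frame(category = c(20L, 40L, 60L, 80L, 100L),
                      hectares = rep(1000, 5))
  ov <- setNames(c(25, 35, 0, 0, 0), c("20", "40", "60", "80", "100"))
  tc <- setNames(c(1L, 0L, 0L, 0L, 0L), c("20", "40", "60", "80", "100"))
  rep <- buildReport(areas, ov, tc, totalTurbines = 40)  # 2.5% of turbines
  expect_equal(rep$pctTurbines[1], 3)  # 2.5 -> 3, not banker's 2
  expect_equal(rep$pctWpcOverlap[1:2], c(3, 4))  # 2.5 -> 3, 3.5 -> 4
})
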