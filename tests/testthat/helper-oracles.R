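# Independent fixtures and oracles used across test files. Everything here
# is deliberately written against the model definitions directly (plain
# loops, fine discretization), not by calling the package's own code paths.

# Pure Brownian track with constant motion variance (no drift), hourly gaps.
brownianTrack <- function(seed, n, sigma2, dt = 3600, err = 0) {
  set.seed(seed)
  tt <- cumsum(c(0, rep(dt, n - 1)))
  x <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  y <- cumsum(c(0, rnorm(n - 1, 0, sqrt(sigma2 * dt))))
  if (err > 0) { x <- x + rnorm(n, 0, err); y <- y + rnorm(n, 0, err) }
  data.frame(t = tt, x = x, y = y, errSd = err)
}

# Two-regime Brownian track: sigma2 jumps from s1 to s2 at increment `cp`
# (so fix cp + 1 is the first fix of the new regime).
twoRegimeTrack <- function(seed, n = 300, s1 = 0.2, s2 = 5, cp = 150,
                           dt = 3600) {
  set.seed(seed)
  tt <- cumsum(c(0, rep(dt, n - 1)))
  sig <- c(rep(s1, cp - 1), rep(s2, n - cp))
  data.frame(t = tt,
             x = cumsum(c(0, rnorm(n - 1, 0, sqrt(sig * dt)))),
             y = cumsum(c(0, rnorm(n - 1, 0, sqrt(sig * dt)))),
             errSd = 0)
}

# The closed-form fixture: z1 = z3 = (0,0) at t = 0, 3600; z2 = (60,0) at
# t = 1800, no location error. The single left-out observation has bridge
# variance s = 900 sigma2 and squared residual r2 = 3600; the stationary
# point of log(2 pi s) + r2 / (2 s) is s = r2 / 2 = 1800, i.e. sigma2 = 2.
threeFixTrack <- function() {
  data.frame(t = c(0, 1800, 3600), x = c(0, 60, 0), y = c(0, 0, 0),
             errSd = 0)
}

# Brute-force UD: fine temporal discretization (sub steps) and per-cell
# integration by nsub x nsub subsampling of each cell.
oracleUD <- function(fx, g, sig2, sub = 1000, nsub = 5) {
  cs <- cellSize(g)
  offs <- (seq_len(nsub) - (nsub + 1) / 2) * cs / nsub
  fineX <- as.vector(vapply(cellCentersX(g), function(c) c + offs,
                            numeric(nsub)))
  fineY <- as.vector(vapply(cellCentersY(g), function(c) c + offs,
                            numeric(nsub)))
  acc <- matrix(0, length(fineY), length(fineX))
  for (i in seq_len(nrow(fx) - 1)) {
    T <- fx$t[i + 1] - fx$t[i]
    for (k in seq_len(sub)) {
      a <- (k - 0.5) / sub
      mx <- (1 - a) * fx$x[i] + a * fx$x[i + 1]
      my <- (1 - a) * fx$y[i] + a * fx$y[i + 1]
      s <- T * a * (1 - a) * sig2[i] +
        (1 - a)^2 * fx$errSd[i]^2 + a^2 * fx$errSd[i + 1]^2
      acc <- acc + (T / sub) / (2 * pi * s) *
        outer(exp(-(fineY - my)^2 / (2 * s)),
              exp(-(fineX - mx)^2 / (2 * s)))
    }
  }
  nr <- gridDim(g)[2]; nc <- gridDim(g)[1]
  cellv <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    cellv[r, c] <- mean(acc[(nsub * (r - 1) + 1):(nsub * r),
                            (nsub * (c - 1) + 1):(nsub * c)])
  cellv / sum(cellv)
}

# Table-1-shaped inputs used by the report tests: per-category UD areas,
# viable-wind overlap areas and installed-turbine counts (US portion), plus
# the study-area-wide per-category turbine counts and total.
reportFixture <- function() {
  list(
    areasHa = data.frame(category = c(20L, 40L, 60L, 80L, 100L),
                         hectares = c(18779858, 12657002, 5536982,
                                      491701, 767)),
    overlapHa = c(`20` = 374334, `40` = 501646, `60` = 259996,
                  `80` = 120335, `100` = 379),
    usCounts = c(`20` = 568, `40` = 517, `60` = 300, `80` = 20, `100` = 0),
    studyCounts = c(`20` = 1185, `40` = 971, `60` = 0, `80` = 0, `100` = 0),
    usTotal = 1405, caTotal = 1718, studyTotal = 3123)
}
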