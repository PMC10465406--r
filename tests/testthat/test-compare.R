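# Comparison protocol: magnitudes, phase alignment, rigid co-registration,
# slicing, ROI binning, regression and component statistics.

test_that("in-plane magnitude follows the two-component Pythagorean form", {
  expect_equal(inplaneMagnitude(0, 0), 0)
  expect_equal(inplaneMagnitude(0.3, 0.4), 0.5)
  # components of the apex-adjacent reference ROI
  expect_equal(inplaneMagnitude(-0.196, -0.192), 0.2744, tolerance = 5e-4)
})

test_that("phase alignment recovers a known circular shift modulo the period", {
  nx <- 8; nz <- 8; nt <- 76; dt <- 0.01
  mkStack <- function(lagSamples) {
    g <- array(0, c(nx, nz, nt))
    for (k in seq_len(nt)) {
      th <- 2 * pi * ((k - 1 - lagSamples) %% nt) / nt
      phase <- sin(th) + 0.4 * sin(2 * th + 1)   # asymmetric cyclic signal
      g[, , k] <- phase * outer(seq_len(nx), seq_len(nz), "+") / 10
    }
    g
  }
  expect_equal(alignPhase(mkStack(0), mkStack(0), dt = dt), 0)
  d <- alignPhase(mkStack(0), mkStack(10), dt = dt)
  expect_lt(min(abs(d - 0.10), abs(d - 0.10 - nt * dt)), dt + 1e-12)
  # modulo the period: shifting by a full cycle is no shift
  expect_equal(alignPhase(mkStack(0), mkStack(nt), dt = dt), 0)
  expect_warning(alignPhase(array(1, c(4, 4, 6)), array(1, c(4, 4, 6)),
                            dt = 0.01), "zero delay")
})

test_that("rigid landmark alignment is its own inverse", {
  set.seed(21)
  A <- matrix(runif(12, -20, 20), 6, 2)
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  B <- applyRigid(A, R, c(3, -2))
  est <- rigidAlign(A, B)
  expect_equal(est$R, R, tolerance = 1e-10)
  expect_equal(est$t, c(3, -2), tolerance = 1e-10)
  expect_lt(est$rmsd, 1e-10)
  # applying the found transform and re-estimating gives the identity
  A2 <- applyRigid(A, est$R, est$t)
  est2 <- rigidAlign(A2, B)
  expect_lt(max(abs(est2$R - diag(2))), 0.1 * pi / 180)
  expect_lt(max(abs(est2$t)), 0.1)
})

test_that("slicing a solved field onto the common grid preserves the flow", {
  ff <- fxPhantomRun()
  rec <- sliceFlow(ff, pixel = 1, dtOut = 0.01)
  expect_s4_class(rec, "PlanarRecord")
  expect_equal(diff(rec@times[1:2]), 0.01)
  expect_equal(diff(rec@x[1:2]), 1)
  # record values agree with direct evaluation at a stored step
  kStep <- which(ff@cycle == max(ff@cycle))[5]
  tCyc <- cardiocfd:::flowStepGeometry(ff, kStep)$tCyc
  kOut <- which.min(abs(rec@times - tCyc))
  pts <- as.matrix(expand.grid(rec@x, rec@z))
  direct <- evalFlow(ff, kStep, pts)
  inB <- !is.na(direct[, 1]) & as.vector(rec@g[, , kOut] > 0)
  expect_gt(sum(inB), 100)
  expect_lt(max(abs(as.vector(rec@u[, , kOut])[inB] - direct[inB, 1])), 5e-3)
})

test_that("slicing an analytic field is equivariant under joint rigid rotation", {
  flow <- function(pts, t) cbind(0.02 * pts[, 3], 0, -0.01 * pts[, 1])
  base <- list(origin = c(0, 0, 0), inPlaneX = c(1, 0, 0),
               inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0),
               xlim = c(-10, 10), zlim = c(-10, 10), id = 1L)
  recA <- renderVfiPlanes(flow, list(base), pixel = 1, dt = 0.05,
                          duration = 0.1)[[1]]
  th <- 0.7
  R <- rbind(c(cos(th), 0, -sin(th)), c(0, 1, 0), c(sin(th), 0, cos(th)))
  rot <- base
  rot$inPlaneX <- as.vector(R %*% base$inPlaneX)
  rot$inPlaneZ <- as.vector(R %*% base$inPlaneZ)
  rot$normal <- as.vector(R %*% base$normal)
  flowRot <- function(pts, t) flow(pts %*% R, t) %*% t(R)
  recB <- renderVfiPlanes(flowRot, list(rot), pixel = 1, dt = 0.05,
                          duration = 0.1)[[1]]
  expect_lt(max(abs(recA@u - recB@u)), 1e-8)
  expect_lt(max(abs(recA@w - recB@w)), 1e-8)
})

test_that("ROI binning averages constants exactly and partitions the cycle", {
  rec <- constantRecord(u = 0.2, w = 0, nx = 20, nz = 20, nt = 76)
  rois <- data.frame(id = 1:3, x = c(5, 10, 15), z = c(5, 10, 15),
                     radius = 2.5)
  rb <- roiBins(rec, rois, nBins = 11)
  expect_equal(dim(rb$bins), c(3L, 11L))
  expect_equal(unname(as.vector(rb$bins)), rep(0.2, 33))
  # bin edges tile [0, T) with equal widths; counts differ by at most 1
  expect_equal(rb$binEdges[1], 0)
  expect_equal(diff(rb$binEdges), rep(0.76 / 11, 11))
  cnt <- table(findInterval(rec@times, rb$binEdges,
                            rightmost.closed = FALSE))
  expect_lte(diff(range(cnt)), 1)
  # an ROI that never enters the mask is excluded with a report
  rec2 <- rec
  rec2@g[1:4, 1:4, ] <- 0
  rois2 <- rbind(rois, data.frame(id = 4, x = 1, z = 1, radius = 1))
  rb2 <- roiBins(rec2, rois2)
  expect_equal(rb2$excluded, 4)
})

test_that("16 ROIs x 11 bins give 176 paired values", {
  ff <- fxPhantomRun()
  rec <- sliceFlow(ff, pixel = 1, dtOut = 0.01)
  rois <- defaultRois(rec, n = 16, radius = 2.5)
  rb <- roiBins(rec, rois, nBins = 11)
  expect_equal(length(rb$bins), 176L)
  expect_true(all(is.finite(rb$bins)))
})

test_that("sinusoidal ROI series bin to the analytic interval means", {
  nt <- 760; dt <- 0.001; period <- 0.76
  tms <- (seq_len(nt) - 1) * dt
  amp <- 0.1; base <- 0.2
  sig <- base + amp * sin(2 * pi * tms / period)
  rec <- constantRecord(u = 0, w = 0, nx = 8, nz = 8, nt = nt, dt = dt)
  for (k in seq_len(nt)) rec@u[, , k] <- sig[k]
  rois <- data.frame(id = 1, x = 3, z = 3, radius = 2)
  rb <- roiBins(rec, rois, nBins = 11)
  edges <- rb$binEdges
  exact <- vapply(seq_len(11), function(b) {
    om <- 2 * pi / period
    base + amp * (cos(om * edges[b]) - cos(om * edges[b + 1])) /
      (om * (edges[b + 1] - edges[b]))
  }, 0)
  expect_equal(unname(rb$bins[1, ]), exact, tolerance = 0.01 * amp)
})

test_that("regression recovers exact and noisy linear relations", {
  x <- matrix(seq(0.05, 0.4, length.out = 176), 16, 11)
  regSelf <- regressBins(x, x)
  expect_equal(regSelf@slope, 1)
  expect_equal(regSelf@intercept, 0)
  expect_equal(regSelf@r2, 1)
  expect_equal(regSelf@residualSD, 0, tolerance = 1e-12)
  reg2 <- regressBins(2 * x + 0.1, x)
  expect_equal(reg2@slope, 2)
  expect_equal(reg2@intercept, 0.1)
  expect_equal(reg2@r2, 1)
  set.seed(5)
  y <- x + matrix(rnorm(176, sd = 0.05), 16, 11)
  regN <- regressBins(y, x)
  expect_lt(abs(regN@slope - 1), 0.2)
  expect_error(regressBins(x[1, 1:2, drop = FALSE], x[1, 1:2, drop = FALSE]),
               "3")
  # ROI exclusion drops whole rows
  regE <- regressBins(y, x, exclude = c(3L, 7L))
  expect_equal(regE@n, 154L)
  expect_equal(regE@excluded, c(3L, 7L))
})

test_that("component statistics report the out-of-plane share", {
  expect_equal(outOfPlanePct(-0.327, 0.026, 0.019), 7.95, tolerance = 0.02)
  expect_equal(outOfPlanePct(0.097, 0.064, -0.043), 66.0, tolerance = 0.05)
  expect_equal(outOfPlanePct(0.119, -0.095, -0.159), 59.8, tolerance = 0.1)
  expect_equal(outOfPlanePct(0.2, 0, 0.1), 0)
  rec <- constantRecord(u = -0.327, w = 0.019, v = 0.026, nx = 10, nz = 10)
  cs <- componentStats(rec, list(x = 5, z = 5, radius = 3))
  expect_equal(cs$u, -0.327)
  expect_equal(cs$v, 0.026)
  expect_equal(cs$outOfPlanePct, 7.95, tolerance = 0.02)
})
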