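# Synthetic phantom: waveform, analytic motion, image rendering, emulated
# planar vector-flow records.

test_that("compression waveform follows the squared-sine programme", {
  w <- motionWaveform(Cd = 10, Tprog = 0.8)
  expect_equal(compressionWaveform(0, w), 0)
  expect_equal(compressionWaveform(0.4, w), 10)      # peak compression
  expect_equal(compressionWaveform(0.2, w), 5)       # sin^2(pi/4) = 1/2
  expect_true(all(compressionWaveform(seq(0, 5, by = 0.013), w) >= 0))
  # periodicity at 100 random times
  set.seed(42)
  t <- runif(100, 0, 10)
  expect_equal(compressionWaveform(t, w), compressionWaveform(t + w@Tprog, w))
  wBad <- motionWaveform()
  wBad@Tprog <- -1                        # bypass the constructor validity
  expect_error(compressionWaveform(0.1, wBad), "positive")
  expect_error(motionWaveform(Tprog = -0.8), "positive")
})

test_that("realized waveform completes a full cycle in the measured period", {
  w <- motionWaveform()
  expect_equal(realizedCompression(0, w), 0)
  expect_equal(realizedCompression(0.76, w), 0, tolerance = 1e-12)
  expect_equal(realizedCompression(0.38, w), 10)
  set.seed(7)
  t <- runif(100, 0, 5)
  expect_equal(realizedCompression(t, w), realizedCompression(t + 0.76, w))
})

test_that("analytic deformation is axial, apex-maximal and zero on static boundaries", {
  g <- fxGeometry3D(); w <- fxWaveform()
  pts <- rbind(apexPoint(g), c(0, 0, 0), c(10, 0, -5), c(-12, 0, -10))
  expect_equal(analyticDeformation(g, w, 0, pts),
               matrix(0, 4, 3))                       # c(0) = 0
  d <- analyticDeformation(g, w, w@Tmeas / 2, pts)
  expect_equal(d[1, 3], -w@Cd)                        # full stroke at apex
  expect_equal(d[2:4, ], matrix(0, 3, 3))             # base plate and tubes
  expect_equal(d[, 1:2], matrix(0, 4, 2))             # purely axial
  # non-moving boundaries at random times
  set.seed(3)
  for (t in runif(5, 0, 0.76)) {
    dd <- analyticDeformation(g, w, t, cbind(runif(20, -15, 15),
                                             runif(20, -10, 10),
                                             runif(20, -15, 0)))
    expect_equal(max(abs(dd)), 0)
  }
})

test_that("cavity volume shrinks to a mid-cycle minimum and is cyclic", {
  g <- fxGeometry3D(); w <- fxWaveform()
  tms <- seq(0, 0.76, length.out = 9)
  V <- analyticVolumeSeries(g, w, tms)
  expect_lt(V[5], V[1])                               # V(T/2) < V(0)
  expect_equal(which.min(V), 5L)                      # minimum at T/2
  expect_equal(V[1], V[9], tolerance = 1e-12)         # T-periodic
  expect_gt(V[1], 50)                                 # plausible cavity [mL]
})

test_that("rendered sequences have the CTA-like layout and are deterministic", {
  s <- fxSequence2D()
  expect_s4_class(s, "ImageSequence")
  expect_equal(nPhases(s), 20L)
  tms <- vapply(s@volumes, function(v) v@time, 0)
  expect_equal(diff(tms), rep(0.038, 19))             # volume-sample period
  # zero-noise rendering is deterministic
  g <- fxGeometry2D(); w <- fxWaveform()
  a <- renderImageSequence(g, w, nPhases = 3, spacing = c(3, 3), noiseSd = 0)
  b <- renderImageSequence(g, w, nPhases = 3, spacing = c(3, 3), noiseSd = 0)
  expect_identical(getVolume(a, 2)@data, getVolume(b, 2)@data)
  # same seed, same noise
  a <- renderImageSequence(g, w, nPhases = 2, spacing = c(3, 3),
                           noiseSd = 10, seed = 5)
  b <- renderImageSequence(g, w, nPhases = 2, spacing = c(3, 3),
                           noiseSd = 10, seed = 5)
  expect_identical(getVolume(a, 1)@data, getVolume(b, 1)@data)
  expect_error(renderImageSequence(g, w, spacing = c(-1, 1)), "positive")
  expect_error(renderImageSequence(g, w, nPhases = 1), "at least 2")
})

test_that("phase-0 vs mid-cycle image difference concentrates in the moving half", {
  s <- fxSequence2D()
  v0 <- getVolume(s, 1); v10 <- getVolume(s, 11)
  dimg <- abs(v0@data - v10@data)
  zidx <- v0@origin[2] + (seq_len(ncol(dimg)) - 1) * v0@spacing[2]
  moving <- zidx > 30                                 # apex half
  expect_gt(mean(dimg[, moving]), 10 * mean(dimg[, !moving]))
})

test_that("emulated planar records project out the normal component", {
  g <- fxGeometry3D()
  planes <- vfiPlanePoses(g, n = 2, planeSpacing = 5)
  uni <- function(pts, t) cbind(0.2, 0, 0.1)[rep(1, nrow(pts)), ]
  recs <- renderVfiPlanes(uni, planes, pixel = 2, dt = 0.05, duration = 0.2)
  r <- recs[[1]]
  expect_equal(max(abs(inplaneMagnitude(r@u, r@w) - sqrt(0.2^2 + 0.1^2))), 0)
  # flow along the plane normal leaves no in-plane signal
  nrm <- function(pts, t) cbind(0, 0.3, 0)[rep(1, nrow(pts)), ]
  rn <- renderVfiPlanes(nrm, planes, pixel = 2, dt = 0.05, duration = 0.2)[[1]]
  expect_equal(max(abs(inplaneMagnitude(rn@u, rn@w))), 0)
  expect_equal(max(abs(rn@v - 0.3)), 0)               # retained for reference
})

test_that("a mid-plane chord through emulated Poiseuille tube flow is parabolic", {
  R <- 10; Vmax <- 0.4
  pois <- function(pts, t) {
    r2 <- pts[, 1]^2 + pts[, 2]^2
    cbind(0, 0, Vmax * pmax(1 - r2 / R^2, 0))
  }
  plane <- list(origin = c(0, 0, 0), inPlaneX = c(1, 0, 0),
                inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0),
                xlim = c(-R, R), zlim = c(0, 5), id = 1L)
  rec <- renderVfiPlanes(pois, list(plane), pixel = 0.5, dt = 0.05,
                         duration = 0.1)[[1]]
  prof <- rec@w[, 1, 1]
  expect_equal(prof, Vmax * (1 - rec@x^2 / R^2), tolerance = 1e-12)
  # noisy rendering stays parabolic within noise
  recN <- renderVfiPlanes(pois, list(plane), pixel = 0.5, dt = 0.05,
                          duration = 0.1, noiseSd = 0.01, seed = 3)[[1]]
  expect_lt(max(abs(recN@w[, 1, 1] - prof)), 0.05)
})

test_that("planes outside the domain yield an empty-record warning, not an error", {
  g <- fxGeometry3D()
  plane <- list(origin = c(0, 200, 0), inPlaneX = c(1, 0, 0),
                inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0),
                xlim = c(-5, 5), zlim = c(0, 5), id = 9L)
  geomFun <- function(pts, t) as.numeric(abs(pts[, 2]) < 50)
  expect_warning(
    recs <- renderVfiPlanes(function(pts, t) cbind(0.1, 0, 0),
                            list(plane), pixel = 2, dt = 0.05,
                            duration = 0.1, geometry = geomFun),
    "outside")
  expect_null(recs[[1]])
})
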