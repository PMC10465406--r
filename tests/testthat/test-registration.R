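# Diffeomorphic demons registration, cyclic assembly, temporal smoothing
# and displacement sampling.

smallParams <- demonsParams(levels = 3, iters = c(30, 20, 10))

test_that("registering identical volumes yields a near-zero field", {
  f <- getVolume(fxSequence2D(), 1)
  fld <- registerPair(f, f, smallParams)
  maxVox <- max(abs(sweep(matrix(fld@d[[1]], ncol = 2), 2, f@spacing, "/")))
  expect_lt(maxVox, 0.05)
})

test_that("a synthetic two-voxel axial shift is recovered within half a voxel", {
  f <- getVolume(fxSequence2D(), 1)
  arr <- f@data
  mv <- arr
  mv[, 3:ncol(arr)] <- arr[, 1:(ncol(arr) - 2)]       # +2 voxels axially
  moving <- imageVolume(mv, f@spacing, f@origin, time = 0.1)
  fld <- registerPair(f, moving, demonsParams())
  axes <- lapply(seq_along(dim(arr)), function(k)
    f@origin[k] + (seq_len(dim(arr)[k]) - 1) * f@spacing[k])
  lum <- cardiocfd:::lumenIndicator(fxGeometry2D(), as.matrix(expand.grid(axes)))
  trueD <- 2 * f@spacing[2]
  dz <- fld@d[[1]][, , 2][matrix(lum, nrow(arr))]
  epeVox <- mean(abs(dz - trueD)) / f@spacing[2]      # endpoint error
  expect_lt(epeVox, 0.5)
})

test_that("registration is invariant to a global additive intensity offset", {
  s <- fxSequence2D()
  f <- getVolume(s, 1); m <- getVolume(s, 4)
  f2 <- imageVolume(f@data + 137, f@spacing, f@origin, time = f@time)
  m2 <- imageVolume(m@data + 137, m@spacing, m@origin, time = m@time)
  p <- demonsParams(levels = 2, iters = c(10, 5))
  expect_equal(registerPair(f, m, p)@d[[1]],
               registerPair(f2, m2, p)@d[[1]], tolerance = 1e-8)
})

test_that("warping with the recovered field halves the intensity mismatch", {
  s <- fxSequence2D()
  f <- getVolume(s, 1); m <- getVolume(s, 6)
  fld <- registerPair(f, m, smallParams)
  mse0 <- mean((f@data - m@data)^2)
  phi <- lapply(1:2, function(k) fld@d[[1]][, , k] / f@spacing[k])
  warped <- cardiocfd:::warpByField(m@data, phi)
  expect_lt(mean((f@data - warped)^2), 0.5 * mse0)
})

test_that("recovered apex motion tracks the analytic waveform within a voxel", {
  s <- fxSequence2D()
  g <- fxGeometry2D(); w <- fxWaveform()
  f <- getVolume(s, 1); m <- getVolume(s, 11)         # phase 1 -> 11
  fld <- registerPair(f, m, demonsParams())
  # probe just inside the apex where the stroke is near-maximal
  probe <- apexPoint(g) - c(0, 6)
  dz <- cardiocfd:::interpVector(fld@d[[1]], matrix(probe, 1), f@spacing, f@origin)[, 2]
  trueDz <- analyticDeformation(g, w, m@time, matrix(probe, 1))[, 2]
  expect_lt(abs(dz - trueDz), max(f@spacing))
})

test_that("grid mismatch is an error", {
  f <- getVolume(fxSequence2D(), 1)
  other <- imageVolume(f@data[-1, ], f@spacing, f@origin)
  expect_error(registerPair(f, other), "grid")
})

test_that("cyclic assembly produces n+2 instances with zero ends", {
  dims <- c(5, 6)
  mk <- function(t, val) new("DisplacementField",
                             d = list(array(val, c(dims, 2))), times = t,
                             spacing = c(1, 1), origin = c(0, 0))
  flds <- lapply(1:19, function(i) mk(i * 0.038, i / 100))
  cyc <- assembleCyclic(flds, period = 0.76)
  expect_length(cyc@d, 21L)                           # 19 + two zero ends
  expect_equal(cyc@times[1], 0)
  expect_equal(cyc@times[21], 0.76)
  expect_equal(max(abs(cyc@d[[1]])), 0)
  expect_equal(cyc@d[[1]], cyc@d[[21]])               # t = 0 equals t = T
  # all-zero inputs give an all-zero cyclic field
  z <- assembleCyclic(lapply(1:19, function(i) mk(i * 0.038, 0)), 0.76)
  expect_equal(max(vapply(z@d, function(a) max(abs(a)), 0)), 0)
  dup <- c(flds[1], flds[1])
  expect_error(assembleCyclic(dup, 0.76), "duplicate|ordered")
})

test_that("temporal smoothing preserves zero ends and equalises seam derivatives", {
  dims <- c(4, 4)
  n <- 21L
  tms <- seq(0, 0.76, length.out = n)
  # single-frequency sinusoid per voxel (zero at both ends)
  mk <- function(i) array(sin(2 * pi * tms[i] / 0.76), c(dims, 2))
  f <- new("DisplacementField", d = lapply(seq_len(n), mk), times = tms,
           spacing = c(1, 1), origin = c(0, 0))
  sm <- smoothTemporal(f, penalty = 0.3)
  expect_equal(max(abs(sm@d[[1]])), 0, tolerance = 1e-9)    # zeros preserved
  expect_equal(max(abs(sm@d[[n]])), 0, tolerance = 1e-9)
  # seam derivative continuity of the sampled field
  pt <- matrix(c(1, 1), 1)
  eps <- 1e-5
  dA <- (sampleDisplacement(sm, pt, eps) - sampleDisplacement(sm, pt, 0)) / eps
  dB <- (sampleDisplacement(sm, pt, 0.76) -
           sampleDisplacement(sm, pt, 0.76 - eps)) / eps
  expect_equal(dA, dB, tolerance = 1e-3)
  # penalty 0 is the identity
  expect_identical(smoothTemporal(f, 0), f)
  # constant-in-time unique samples stay constant under the smoother
  fc <- new("DisplacementField",
            d = rep(list(array(0.5, c(dims, 2))), n), times = tms,
            spacing = c(1, 1), origin = c(0, 0))
  smc <- smoothTemporal(fc, penalty = 1)
  expect_equal(smc@d[[3]], fc@d[[3]], tolerance = 1e-12)
  expect_error(smoothTemporal(new("DisplacementField",
                                  d = fc@d[1:3], times = tms[1:3],
                                  spacing = c(1, 1), origin = c(0, 0)), 1),
               "at least 4")
})

test_that("displacement sampling is exact at instances and cyclic in time", {
  s <- fxSequence2D()
  g <- fxGeometry2D(); w <- fxWaveform()
  f <- groundTruthField(g, w, s)
  pt <- matrix(c(0, 50), 1)
  expect_equal(sampleDisplacement(f, pt, 0), matrix(0, 1, 2))
  # exact reproduction of a stored instance at a grid node
  v1 <- getVolume(s, 1)
  node <- matrix(c(v1@origin[1] + 10 * v1@spacing[1],
                   v1@origin[2] + 30 * v1@spacing[2]), 1)
  d5 <- sampleDisplacement(f, node, f@times[5])
  expect_equal(as.vector(d5), f@d[[5]][11, 31, ], tolerance = 1e-12)
  # periodic wrap
  expect_equal(sampleDisplacement(f, pt, 0.2),
               sampleDisplacement(f, pt, 0.2 + 0.76), tolerance = 1e-10)
  # mid-instance query against the analytic motion (dense-truth oracle)
  tq <- 0.25
  expect_equal(sampleDisplacement(f, pt, tq),
               analyticDeformation(g, w, tq, pt), tolerance = 0.05)
  expect_warning(sampleDisplacement(f, matrix(c(500, 500), 1), 0.1),
                 "clamped")
})

test_that("volumetric (3D) demons recovers an axial shift", {
  g <- fxGeometry3D(); w <- fxWaveform()
  s3 <- renderImageSequence(g, w, nPhases = 2, spacing = c(4, 4, 4),
                            noiseSd = 0)
  f <- getVolume(s3, 1)
  arr <- f@data
  mv <- arr
  mv[, , 2:dim(arr)[3]] <- arr[, , 1:(dim(arr)[3] - 1)]   # +1 voxel axially
  moving <- imageVolume(mv, f@spacing, f@origin, time = 0.1)
  fld <- registerPair(f, moving, demonsParams(levels = 2, iters = c(25, 15)))
  axes <- lapply(1:3, function(k)
    f@origin[k] + (seq_len(dim(arr)[k]) - 1) * f@spacing[k])
  lum <- array(cardiocfd:::lumenIndicator(g, as.matrix(expand.grid(axes))), dim(arr))
  dz <- fld@d[[1]][, , , 3][lum] / f@spacing[3]
  expect_lt(mean(abs(dz - 1)), 0.5)
  expect_lt(max(abs(fld@d[[1]][, , , 1][lum])) / f@spacing[1], 1)
})
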