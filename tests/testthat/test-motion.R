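# Moving-mesh construction: advection, interior extension, volumes and
# mesh velocities.

test_that("phantom cross-section mesh is valid with tagged boundaries", {
  msh <- phantomMesh2D(fxGeometry2D(), h = 4)
  expect_true(all(cardiocfd:::triangleAreas(msh@nodes, msh@elements) > 0))
  expect_setequal(unique(msh@boundaryTag), c("inlet", "outlet", "wall", "base"))
  expect_gt(min(elementQuality(msh)), 0.1)
})

test_that("surface advection closes the cycle and respects static patches", {
  g <- fxGeometry2D(); w <- fxWaveform()
  msh <- phantomMesh2D(g, h = 4.5)
  f <- groundTruthField(g, w, fxSequence2D())
  tr <- advectSurface(msh, f, step = 0.019)
  expect_length(tr$times, 41L)                        # 0.76 / 0.019 + 1
  expect_equal(tr$positions[1, , ], tr$positions[41, , ])   # cyclic closure
  # tube and base nodes never move
  stat <- msh@nodes[tr$bnodes, 2] <= 0
  moved <- apply(tr$positions[, stat, , drop = FALSE], c(2, 3), function(x)
    max(abs(x - x[1])))
  expect_lt(max(moved), 1e-9)
  # apex excursion within one voxel of the programmed stroke
  apexN <- which.max(msh@nodes[tr$bnodes, 2])
  exc <- max(tr$positions[1, apexN, 2] - tr$positions[, apexN, 2])
  expect_lt(abs(exc - w@Cd), 1.5)
  # zero field keeps everything fixed
  z <- f; z@d <- lapply(z@d, function(a) array(0, dim(a)))
  trz <- advectSurface(msh, z, step = 0.038)
  expect_equal(max(abs(sweep(trz$positions, c(2, 3),
                             trz$positions[1, , ]))), 0)
  expect_error(advectSurface(msh, f, step = 0.017), "divide")
})

test_that("interior extension reproduces affine motion and rejects inversion", {
  msh <- phantomMesh2D(fxGeometry2D(), h = 5)
  bnodes <- sort(unique(as.vector(msh@boundary)))
  nst <- 5L
  tms <- seq(0, 0.76, length.out = nst)
  mkTraj <- function(shift) {
    pos <- array(0, c(nst, length(bnodes), 2))
    for (k in seq_len(nst))
      pos[k, , ] <- sweep(msh@nodes[bnodes, ], 2, shift[k, ], "+")
    list(times = tms, positions = pos, bnodes = bnodes)
  }
  # rigid translation (cyclically closed)
  sh <- cbind(2.5 * sin(pi * (tms / 0.76))^2, 0)
  sh[nst, ] <- sh[1, ]
  for (method in c("elastic", "harmonic")) {
    mm <- extendInterior(mkTraj(sh), msh, method = method)
    expect_equal(mm@trajectories[2, , ],
                 sweep(msh@nodes, 2, sh[2, ], "+"), tolerance = 1e-8)
  }
  # zero boundary motion is the identity
  mm0 <- extendInterior(mkTraj(matrix(0, nst, 2)), msh)
  expect_equal(mm0@trajectories[3, , ], msh@nodes, tolerance = 1e-12)
})

test_that("phantom compression keeps element quality above 0.1 at all steps", {
  mm <- fxMovingMesh()
  qmin <- min(vapply(seq_along(mm@times), function(k)
    min(elementQuality(mm@mesh, mm@trajectories[k, , ])), 0))
  expect_gt(qmin, 0.1)
})

test_that("cavity measure is exact, cyclic and consistent with boundary flux", {
  # unit square: area 1
  unitMesh <- channelMesh2D(L = 1, H = 1, h = 0.25)
  mmU <- fxRigidMovingMesh(unitMesh, nSteps = 4)
  expect_equal(cavityVolumeSeries(mmU), rep(1, 5))
  mm <- fxMovingMesh()
  V <- cavityVolumeSeries(mm)
  expect_equal(V[1], V[length(V)], tolerance = 1e-12)     # cyclic closure
  expect_lt(min(V), V[1])                                 # compression
  # dV/dt from finite differences vs the mesh-velocity boundary flux
  fem <- cardiocfd:::p2Structure(mm@mesh)
  sp <- cardiocfd:::meshSpline(mm)
  areaAt <- function(t)
    sum(abs(cardiocfd:::triangleAreas(meshPositions(mm, t, sp),
                                      mm@mesh@elements))) * 1e-6    # m^2
  ks <- seq(2, length(mm@times) - 1)
  fluxes <- dVdts <- numeric(length(ks))
  h <- 1e-4
  for (i in seq_along(ks)) {
    t <- mm@times[ks[i]]
    wv <- meshVelocity(mm, t, sp)
    wN <- rbind(wv, (wv[fem$edges[, 1], ] + wv[fem$edges[, 2], ]) / 2)
    fluxes[i] <- cardiocfd:::boundaryFlux(fem,
                                          mm@trajectories[ks[i], , ] * 1e-3,
                                          wN,
                                          c("inlet", "outlet", "wall", "base"))
    dVdts[i] <- (areaAt(t + h) - areaAt(t - h)) / (2 * h)
  }
  expect_lt(max(abs(fluxes - dVdts)), 0.01 * max(abs(fluxes)))
  # open surface errors
  open <- mm@mesh
  open@boundary <- open@boundary[-1, , drop = FALSE]
  open@boundaryTag <- open@boundaryTag[-1]
  mmOpen <- mm; mmOpen@mesh <- open
  expect_error(cavityVolumeSeries(mmOpen), "open")
})

test_that("mesh velocity is zero on static patches and integrates to zero", {
  mm <- fxMovingMesh()
  sp <- cardiocfd:::meshSpline(mm)
  stat <- mm@mesh@nodes[, 2] <= 0
  w1 <- meshVelocity(mm, 0.21, sp)
  expect_equal(max(abs(w1[stat, ])), 0)
  # stationary mesh: identically zero
  mmR <- fxRigidMovingMesh(channelMesh2D(10, 5, 2))
  expect_equal(max(abs(meshVelocity(mmR, 0.3))), 0)
  # periodicity: apex velocity integrates to ~zero displacement
  apexN <- which.max(mm@mesh@nodes[, 2])
  ts <- seq(0, 0.76, length.out = 401)
  vz <- vapply(ts, function(t) meshVelocity(mm, t, sp)[apexN, 2], 0)
  intD <- sum((vz[-1] + vz[-length(vz)]) / 2 * diff(ts)) * 1e3   # mm
  expect_lt(abs(intD), 1e-6)
  # peak apex speed consistent with the analytic derivative within 5%
  g <- fxGeometry2D(); w <- fxWaveform()
  sProf <- cardiocfd:::axialProfile(g, mm@mesh@nodes[apexN, 2])
  peakAnalytic <- w@Cd * pi / w@Tmeas * sProf * 1e-3         # m/s
  expect_equal(max(abs(vz)), peakAnalytic, tolerance = 0.05)
})

test_that("stored motion is reused identically across cycles", {
  mm <- fxMovingMesh()
  sp <- cardiocfd:::meshSpline(mm)
  t0 <- 0.21
  expect_equal(meshPositions(mm, t0, sp), meshPositions(mm, t0 + 0.76, sp),
               tolerance = 1e-12)
  expect_equal(meshPositions(mm, mm@times[4]), mm@trajectories[4, , ])
})
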