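# Flow solver: stationary ramp, Poiseuille benchmark, ALE properties,
# cycle convergence and mesh independence.

test_that("zero inlet target gives the zero stationary state", {
  msh <- channelMesh2D(L = 20, H = 10, h = 4)
  res <- rampInitialize(msh, 0)
  expect_equal(max(abs(res$U)), 0)
  expect_equal(max(abs(res$p)), 0)
  expect_lt(res$div, 1e-8)
})

test_that("steady channel flow reproduces the plane Poiseuille parabola", {
  msh <- channelMesh2D(L = 40, H = 10, h = 2.5)
  H <- 0.01; Um <- 0.1
  res <- rampInitialize(msh, Um, nRamp = 3, dirichletFun = channelParabolicBC(H))
  XP2 <- cardiocfd:::p2Coords(res$fem, msh@nodes * 1e-3)
  uex <- 6 * Um * (XP2[, 2] / H) * (1 - XP2[, 2] / H)
  relL2 <- sqrt(mean((res$U[, 1] - uex)^2)) / sqrt(mean(uex^2))
  expect_lt(relL2, 0.02)
  expect_equal(max(res$U[, 1]), 1.5 * Um, tolerance = 0.001)  # centreline
  expect_lt(res$div, 1e-8)                       # incompressibility
  expect_lt(max(abs(res$U[, 2])), 1e-10)
})

test_that("a plug inlet develops towards the parabolic profile at low Re", {
  # Re ~ 25: development length well inside the channel
  msh <- channelMesh2D(L = 60, H = 10, h = 2)
  Um <- 0.01
  res <- rampInitialize(msh, Um, nRamp = 3)
  XP2 <- cardiocfd:::p2Coords(res$fem, msh@nodes * 1e-3)
  out <- which(abs(XP2[, 1] - 0.06) < 1e-9)
  expect_equal(max(res$U[out, 1]), 1.5 * Um, tolerance = 0.02)
})

test_that("moving rigid frame with co-moving boundary data preserves the flow", {
  # oscillating rigid translation; all boundaries carry U0 + mesh velocity;
  # the discrete solution must stay spatially uniform (transported exactly)
  msh <- channelMesh2D(L = 20, H = 10, h = 3)
  period <- 0.76; nst <- 8L
  tms <- seq(0, period, length.out = nst + 1L)
  amp <- 4                                            # mm
  shift <- amp * sin(pi * tms / period)^2
  pos <- array(0, c(nst + 1L, nrow(msh@nodes), 2))
  for (k in seq_len(nst + 1L))
    pos[k, , ] <- sweep(msh@nodes, 2, c(shift[k], 0), "+")
  mm <- new("MovingMesh", mesh = msh, trajectories = pos, times = tms,
            step = tms[2] - tms[1])
  U0 <- c(0.05, 0)
  allDirichlet <- function(fem, XP2, wN, Uin) {
    vals <- matrix(NA_real_, fem$nP2, 2)
    ids <- unique(c(as.vector(fem$mesh@boundary), fem$bmid))
    vals[ids, 1] <- wN[ids, 1] + U0[1]
    vals[ids, 2] <- wN[ids, 2] + U0[2]
    vals
  }
  ff <- solveCycles(mm, function(t) 0, dt = mm@step, nCycles = 1,
                    dirichletFun = allDirichlet, pinPressure = TRUE)
  sp <- cardiocfd:::meshSpline(mm)
  for (k in seq_along(ff@times)) {
    wv <- meshVelocity(mm, ff@times[k], sp)
    expect_lt(max(abs(sweep(ff@U[k, , ], 2, U0 + wv[1, ]))), 1e-6)
    # uniformity: all nodes share one velocity vector
    expect_lt(max(apply(ff@U[k, , ], 2, function(x) diff(range(x)))), 1e-6)
  }
})

test_that("rigid mesh with steady inlet relaxes to the stationary solution", {
  msh <- channelMesh2D(L = 30, H = 10, h = 3)
  Um <- 0.05
  stat <- rampInitialize(msh, Um, nRamp = 3)
  mm <- fxRigidMovingMesh(msh, period = 0.8, nSteps = 10L)
  ff <- solveCycles(mm, function(t) Um, dt = 0.08, nCycles = 2)
  uEnd <- ff@U[dim(ff@U)[1], , ]
  expect_lt(max(abs(uEnd - stat$U)) / max(abs(stat$U)), 0.005)
})

test_that("a closed-inlet compressing cavity pushes its volume change out the outlet", {
  mm <- fxMovingMesh()
  ff <- suppressWarnings(solveCycles(mm, function(t) 0, dt = 0.038,
                                     nCycles = 1, tol = 1e-6, maxIter = 10))
  fem <- cardiocfd:::p2Structure(mm@mesh)
  sp <- cardiocfd:::meshSpline(mm)
  areaAt <- function(t)
    sum(abs(cardiocfd:::triangleAreas(meshPositions(mm, t, sp),
                                      mm@mesh@elements))) * 1e-6
  outflux <- dVdt <- numeric(length(ff@times))
  for (k in seq_along(ff@times)) {
    gs <- cardiocfd:::flowStepGeometry(ff, k)
    outflux[k] <- cardiocfd:::boundaryFlux(fem, gs$X, ff@U[k, , ], "outlet")
    h <- 1e-4
    dVdt[k] <- (areaAt(gs$tCyc + h) - areaAt(gs$tCyc - h)) / (2 * h)
  }
  expect_lt(max(abs(outflux + dVdt)), 0.01 * max(abs(dVdt)))
})

test_that("kinetic energy decays with zero inflow and static walls", {
  msh <- channelMesh2D(L = 30, H = 10, h = 3)
  stat <- rampInitialize(msh, 0.05, nRamp = 3)        # initial swirl-free state
  mm <- fxRigidMovingMesh(msh, period = 0.4, nSteps = 10L)
  ff <- solveCycles(mm, function(t) 0, dt = 0.04, nCycles = 1,
                    uInit = stat$U)
  fem <- cardiocfd:::p2Structure(msh)
  geo <- cardiocfd:::elemGeometry(fem, msh@nodes * 1e-3)
  grads <- cardiocfd:::p2Gradients(fem, geo)
  M <- cardiocfd:::femMatrices(fem, geo, grads)$M
  ke <- vapply(seq_along(ff@times), function(k) {
    u <- ff@U[k, , ]
    as.numeric(t(u[, 1]) %*% M %*% u[, 1] + t(u[, 2]) %*% M %*% u[, 2])
  }, 0)
  expect_true(all(diff(ke) < 0))
})

test_that("repeated runs are bitwise identical", {
  msh <- channelMesh2D(L = 20, H = 10, h = 4)
  mm <- fxRigidMovingMesh(msh, period = 0.4, nSteps = 5L)
  f1 <- solveCycles(mm, function(t) 0.03, dt = 0.08, nCycles = 1)
  f2 <- solveCycles(mm, function(t) 0.03, dt = 0.08, nCycles = 1)
  expect_identical(f1@U, f2@U)
  expect_identical(f1@p, f2@p)
})

test_that("cycle convergence reporting matches hand-built fields", {
  msh <- channelMesh2D(L = 20, H = 10, h = 4)
  mm <- fxRigidMovingMesh(msh, period = 0.4, nSteps = 4L)
  fem <- cardiocfd:::p2Structure(msh)
  nst <- 4L; nCyc <- 3L
  U <- array(0, c(nst * nCyc, fem$nP2, 2))
  U[, , 1] <- 0.1
  # cycle 3 uniformly 0.01 m/s faster than cycle 2
  U[(2 * nst + 1):(3 * nst), , 1] <- 0.11
  ff <- new("FlowField", mmesh = mm, edges = fem$edges,
            times = (1:(nst * nCyc)) * 0.1,
            cycle = rep(1:3, each = nst), U = U,
            p = matrix(0, nst * nCyc, fem$nv))
  cc <- cycleConvergence(ff, probes = as.matrix(expand.grid(
    seq(2, 18, by = 4), seq(2, 8, by = 3))))
  expect_equal(unname(cc$velDiff[, 1]), rep(0, cc$nProbes))      # identical
  expect_equal(unname(cc$velDiff[, 2]), rep(-0.01, cc$nProbes))  # built gap
  expect_equal(cc$summary$median, c(0, -0.01))
})

test_that("mesh independence flags agreement with the finest mesh", {
  runner <- function(h) {
    msh <- channelMesh2D(L = 30, H = 10, h = h)
    mm <- fxRigidMovingMesh(msh, period = 0.4, nSteps = 4L)
    solveCycles(mm, function(t) 0.03, dt = 0.1, nCycles = 1)
  }
  tab <- meshIndependence(c(5, 3.4, 2.5), runner)
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$dof) > 0) || all(diff(tab$h) < 0))
  finest <- which.min(tab$h)
  expect_true(tab$withinBand[finest])                 # self-comparison
  expect_equal(tab$deviation[finest], 0)
  # deviations shrink with refinement
  expect_lt(tab$deviation[2], tab$deviation[1])
  # identical meshes give identical metrics
  tab2 <- meshIndependence(c(4, 4), runner)
  expect_equal(tab2$metric[1], tab2$metric[2])
})
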