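# Shared fixtures, memoised so the heavier runs (the coarse phantom flow
# solve, rendered sequences) are computed once per test session.

.fx <- new.env()

fxWaveform <- function() motionWaveform()
fxGeometry2D <- function() phantomGeometry(dim = 2)
fxGeometry3D <- function() phantomGeometry(dim = 3)

# coarse noiseless 2D image sequence (shared by phantom/registration tests)
fxSequence2D <- function() {
  if (is.null(.fx$seq2d))
    .fx$seq2d <- renderImageSequence(fxGeometry2D(), fxWaveform(),
                                     nPhases = 20, spacing = c(1.5, 1.5),
                                     noiseSd = 0, seed = 1)
  .fx$seq2d
}

# coarse 2D phantom moving mesh from analytic ground-truth motion
fxMovingMesh <- function() {
  if (is.null(.fx$mm)) {
    msh <- phantomMesh2D(fxGeometry2D(), h = 4.5)
    .fx$mm <- analyticMovingMesh(msh, fxGeometry2D(), fxWaveform(),
                                 step = 0.038)
  }
  .fx$mm
}

# the coarse phantom flow run: 4 cycles at the default fluid properties and
# inlet waveform (the run behind the mass-balance, cycle-convergence and
# closure checks)
fxPhantomRun <- function() {
  if (is.null(.fx$ff)) {
    .fx$ff <- suppressWarnings(
      solveCycles(fxMovingMesh(), defaultInlet(fxGeometry2D(), fxWaveform()),
                  dt = 0.038, nCycles = 4, tol = 1e-5, maxIter = 10))
  }
  .fx$ff
}

# small rigid "moving" mesh (constant trajectories) over one cycle
fxRigidMovingMesh <- function(mesh, period = 0.76, nSteps = 8L) {
  tms <- seq(0, period, length.out = nSteps + 1L)
  pos <- array(0, c(nSteps + 1L, nrow(mesh@nodes), ncol(mesh@nodes)))
  for (k in seq_len(nSteps + 1L)) pos[k, , ] <- mesh@nodes
  new("MovingMesh", mesh = mesh, trajectories = pos, times = tms,
      step = tms[2] - tms[1])
}

# parabolic-inlet Dirichlet data for the plane channel benchmark
channelParabolicBC <- function(H) {
  force(H)
  function(fem, XP2, wN, Uin) {
    vals <- matrix(NA_real_, fem$nP2, 2)
    for (tg in c("inlet", "wall")) {
      sel <- fem$mesh@boundaryTag == tg
      ed <- fem$mesh@boundary[sel, , drop = FALSE]
      ids <- unique(c(as.vector(ed), fem$bmid[sel]))
      if (tg == "wall") vals[ids, ] <- 0
      else {
        y <- XP2[ids, 2]
        vals[ids, 1] <- 6 * Uin * (y / H) * (1 - y / H)
        vals[ids, 2] <- 0
      }
    }
    vals
  }
}

# constant-velocity planar record fixture
constantRecord <- function(u, w, v = 0, nx = 12, nz = 12, nt = 10,
                           pixel = 1, dt = 0.01) {
  xs <- (seq_len(nx) - 1) * pixel
  zs <- (seq_len(nz) - 1) * pixel
  tms <- (seq_len(nt) - 1) * dt
  mk <- function(val) array(val, c(nx, nz, nt))
  new("PlanarRecord", x = xs, z = zs, times = tms, u = mk(u), w = mk(w),
      v = mk(v), g = mk(1), planeId = 1L,
      pose = list(origin = c(0, 0, 0), inPlaneX = c(1, 0, 0),
                  inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0)))
}
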