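# Incompressible Navier-Stokes on the moving mesh in ALE form:
# stationary ramp initialisation, implicit-Euler multi-cycle time stepping
# with Picard-linearised convection, cycle-convergence and mesh-independence
# reporting. Mixed P2/P1 elements, sparse direct linear solves.

#' Fluid properties
#'
#' Defaults are those of a blood-mimicking fluid: density 1037 kg/m^3,
#' dynamic viscosity 4.1 mPa s (Newtonian).
#'
#' @param rho density [kg/m^3]
#' @param mu dynamic viscosity [Pa s]
#' @return a validated property list
#' @export
fluidProperties <- function(rho = 1037, mu = 4.1e-3) {
  stopifnot(rho > 0, mu > 0)
  list(rho = rho, mu = mu)
}

# Default Dirichlet data: plug inlet along the inward normal, no-slip
# (= mesh velocity) on wall and base, natural (zero-traction) outlet.
# Returns an nP2 x 2 matrix of values with NA on unconstrained nodes.
defaultDirichlet <- function(fem, X, wNodes, Uin) {
  vals <- matrix(NA_real_, fem$nP2, 2)
  for (tg in c("wall", "base", "inlet")) {
    sel <- fem$mesh@boundaryTag == tg
    if (!any(sel)) next
    ed <- fem$mesh@boundary[sel, , drop = FALSE]
    mid <- fem$bmid[sel]
    ids <- unique(c(as.vector(ed), mid))
    if (tg == "inlet") {
      p1 <- X[ed[, 1], , drop = FALSE]; p2 <- X[ed[, 2], , drop = FALSE]
      dv <- p2 - p1
      nrm <- cbind(dv[, 2], -dv[, 1]) / sqrt(rowSums(dv^2))
      inward <- -colMeans(nrm)                  # plug along inward normal
      vals[ids, 1] <- Uin * inward[1]
      vals[ids, 2] <- Uin * inward[2]
    } else {
      vals[ids, ] <- wNodes[ids, ]
    }
  }
  # walls win over inlet at patch junctions: re-impose no-slip last
  for (tg in c("wall", "base")) {
    sel <- fem$mesh@boundaryTag == tg
    if (!any(sel)) next
    ed <- fem$mesh@boundary[sel, , drop = FALSE]
    ids <- unique(c(as.vector(ed), fem$bmid[sel]))
    vals[ids, ] <- wNodes[ids, ]
  }
  vals
}

# One Picard-linearised solve of the (possibly unsteady) saddle system.
# Returns list(U, p, div). uStar: convective iterate; uOld: previous step
# (NULL for stationary); all nP2 x 2 in m/s.
nsSolveLinear <- function(fem, geo, grads, mats, Dmats, props, dt,
                          uStar, uOld, wNodes, dirich, pinP = FALSE) {
  nP2 <- fem$nP2
  a <- uStar - wNodes
  cm <- femMatrices(fem, geo, grads, aNodes = a, nu = props$mu / props$rho)
  A <- props$mu * mats$K + props$rho * cm$C + props$rho * cm$S
  rhs <- numeric(2 * nP2 + fem$nv)
  if (!is.null(uOld)) {
    A <- A + (props$rho / dt) * mats$M
    rhs[seq_len(nP2)] <- as.vector((props$rho / dt) * (mats$M %*% uOld[, 1]))
    rhs[nP2 + seq_len(nP2)] <- as.vector((props$rho / dt) * (mats$M %*% uOld[, 2]))
  }
  Z <- Matrix::Matrix(0, nP2, nP2, sparse = TRUE)
  Amat <- rbind(
    cbind(A, Z, -Matrix::t(Dmats$Dx)),
    cbind(Z, A, -Matrix::t(Dmats$Dy)),
    cbind(Dmats$Dx, Dmats$Dy,
          Matrix::Matrix(0, fem$nv, fem$nv, sparse = TRUE)))
  cdof <- which(!is.na(dirich))           # column-major: x dofs then y dofs
  cvals <- dirich[cdof]
  if (pinP) {                             # gauge for all-Dirichlet cases
    cdof <- c(cdof, 2L * nP2 + 1L)
    cvals <- c(cvals, 0)
  }
  sys <- applyDirichlet(Amat, rhs, cdof, cvals)
  sol <- as.vector(Matrix::solve(sys$A, sys$rhs))
  U <- cbind(sol[seq_len(nP2)], sol[nP2 + seq_len(nP2)])
  p <- sol[2 * nP2 + seq_len(fem$nv)]
  div <- sqrt(sum((Dmats$Dx %*% U[, 1] + Dmats$Dy %*% U[, 2])^2))
  list(U = U, p = p, div = div)
}

# Picard iteration with adaptive under-relaxation: the relaxation factor is
# halved whenever the update grows, which keeps the fixed point attractive
# at convection-dominated stationary solves.
nsSolveNonlinear <- function(fem, geo, grads, mats, Dmats, props, dt,
                             uInit, uOld, wNodes, dirich,
                             tol = 1e-8, maxIter = 25, context = "solve",
                             pinP = FALSE, relax = 1) {
  u <- uInit
  res <- NULL
  deltaPrev <- Inf
  delta <- Inf
  for (it in seq_len(maxIter)) {
    res <- nsSolveLinear(fem, geo, grads, mats, Dmats, props, dt,
                         u, uOld, wNodes, dirich, pinP = pinP)
    if (any(!is.finite(res$U)))
      stop(sprintf("nonlinear solve diverged (%s, iteration %d)", context, it))
    delta <- max(abs(res$U - u))
    if (delta > deltaPrev && relax > 0.1) relax <- relax / 2
    u <- u + relax * (res$U - u)
    deltaPrev <- delta
    if (delta < tol * max(1e-6, max(abs(u)))) break
  }
  if (relax < 1) {          # make the returned state the relaxed iterate
    res <- nsSolveLinear(fem, geo, grads, mats, Dmats, props, dt,
                         u, uOld, wNodes, dirich, pinP = pinP)
    delta <- max(abs(res$U - u))
  }
  # warn only on substantive non-convergence; sub-permille residual updates
  # are routine for warm-started transient steps
  if (delta >= max(tol, 1e-3) * max(1e-6, max(abs(res$U))) && maxIter > 2)
    warning(sprintf("Picard iteration did not fully converge (%s): delta %.3g",
                    context, delta))
  res
}

#' Stationary ramp initialisation
#'
#' Computes a well-posed initial condition: a sequence of stationary
#' Navier-Stokes solves on the reference (undeformed) geometry with the
#' inlet speed stepped linearly from 0 to the target, each solve
#' warm-started from the previous one.
#'
#' @param mesh a \linkS4class{SimplexMesh}
#' @param Uin target inlet plug speed [m/s]
#' @param props fluid properties from \code{\link{fluidProperties}}
#' @param nRamp number of ramp steps
#' @param dirichletFun optional override of the boundary data (signature of
#'   the internal default; used by benchmark cases, e.g. a parabolic inlet)
#' @param tol,maxIter Picard controls
#' @return list: \code{U} (nP2 x 2 [m/s]), \code{p} [Pa], \code{fem}
#'   workspace, \code{div} discrete divergence norm
#' @export
rampInitialize <- function(mesh, Uin, props = fluidProperties(), nRamp = 5,
                           dirichletFun = NULL, tol = 1e-8, maxIter = 25,
                           pinPressure = FALSE) {
  fem <- p2Structure(mesh)
  X <- mesh@nodes * 1e-3
  geo <- elemGeometry(fem, X)
  grads <- p2Gradients(fem, geo)
  mats <- femMatrices(fem, geo, grads)
  Dmats <- femDivMatrices(fem, geo, grads)
  wNodes <- matrix(0, fem$nP2, 2)
  u <- matrix(0, fem$nP2, 2)
  res <- list(U = u, p = numeric(fem$nv), div = 0)
  targets <- if (Uin == 0) 0 else seq(Uin / nRamp, Uin, length.out = nRamp)
  XP2 <- p2Coords(fem, X)
  for (s in seq_along(targets)) {
    dirich <- if (is.null(dirichletFun))
      defaultDirichlet(fem, X, wNodes, targets[s])
    else dirichletFun(fem, XP2, wNodes, targets[s])
    res <- nsSolveNonlinear(fem, geo, grads, mats, Dmats, props, dt = NULL,
                            uInit = u, uOld = NULL, wNodes = wNodes,
                            dirich = dirich, tol = tol, maxIter = maxIter,
                            context = sprintf("ramp step %d", s),
                            pinP = pinPressure)
    u <- res$U
  }
  list(U = res$U, p = res$p, fem = fem, div = res$div)
}

#' Solve the flow over multiple cycles on the moving mesh
#'
#' Implicit-Euler ALE time stepping: at each step the system is assembled
#' on the deformed geometry at the new time level, the convective velocity
#' is the fluid velocity minus the mesh velocity (both interpolated from
#' the stored motion solution via periodic splines), and the motion
#' solution is reused for every cycle. No-slip walls move with the mesh;
#' the outlet is a natural zero-traction (0 Pa gauge) boundary; the inlet
#' is a plug profile from the inlet waveform.
#'
#' @param mmesh a \linkS4class{MovingMesh}
#' @param inlet an \linkS4class{InletWaveform}, or a function(t) -> plug
#'   speed [m/s]
#' @param props fluid properties
#' @param dt solver time step [s]; must not exceed the mesh-motion step and
#'   must divide the cycle period
#' @param nCycles number of cycles to run
#' @param uInit optional initial velocity (nP2 x 2); default: stationary
#'   ramp solution at the t = 0 inlet speed
#' @param dirichletFun optional boundary-data override (benchmarks)
#' @param tol,maxIter Picard controls
#' @param laminarRe warn if the peak cell Reynolds estimate exceeds this
#' @param verbose print per-cycle progress
#' @return a \linkS4class{FlowField} (one stored step per dt, all cycles)
#' @export
solveCycles <- function(mmesh, inlet, props = fluidProperties(),
                        dt = mmesh@step, nCycles = 6, uInit = NULL,
                        dirichletFun = NULL, tol = 1e-8, maxIter = 25,
                        laminarRe = 2300, pinPressure = FALSE,
                        verbose = FALSE) {
  if (dt > mmesh@step + 1e-12) stop("dt must not exceed the mesh-motion step")
  period <- tail(mmesh@times, 1)
  nsteps <- round(period / dt)
  if (abs(nsteps * dt - period) > 1e-9) stop("dt must divide the cycle period")
  UinFun <- if (is(inlet, "InletWaveform")) {
    ps <- periodicSpline(c(inlet@times, inlet@times[1] + period),
                         c(inlet@U, inlet@U[1]))
    function(t) as.vector(evalPeriodicSpline(ps, t))
  } else inlet
  fem <- p2Structure(mmesh@mesh)
  sp <- meshSpline(mmesh)
  np <- nrow(mmesh@mesh@nodes)
  getX <- function(t) meshPositions(mmesh, t, sp) * 1e-3
  getW <- function(t) {
    wv <- meshVelocity(mmesh, t, sp)
    rbind(wv, (wv[fem$edges[, 1], , drop = FALSE] +
                 wv[fem$edges[, 2], , drop = FALSE]) / 2)
  }
  if (is.null(uInit)) {
    init <- rampInitialize(mmesh@mesh, UinFun(0), props,
                           dirichletFun = dirichletFun, tol = tol,
                           maxIter = maxIter, pinPressure = pinPressure)
    uInit <- init$U
  }
  ntot <- nsteps * nCycles
  U <- array(0, c(ntot, fem$nP2, 2))
  p <- matrix(0, ntot, fem$nv)
  times <- numeric(ntot)
  cycles <- integer(ntot)
  divs <- numeric(ntot)
  uOld <- uInit
  peakRe <- 0
  hmin <- sqrt(min(abs(triangleAreas(mmesh@mesh@nodes * 1e-3,
                                     mmesh@mesh@elements))))
  for (k in seq_len(ntot)) {
    tGlob <- k * dt
    tCyc <- ((k - 1) %% nsteps + 1) * dt        # position within the cycle
    X <- getX(tCyc)
    geo <- elemGeometry(fem, X)
    grads <- p2Gradients(fem, geo)
    mats <- femMatrices(fem, geo, grads)
    Dmats <- femDivMatrices(fem, geo, grads)
    wN <- getW(tCyc)
    dirich <- if (is.null(dirichletFun))
      defaultDirichlet(fem, X, wN, UinFun(tCyc))
    else dirichletFun(fem, p2Coords(fem, X), wN, UinFun(tCyc))
    res <- nsSolveNonlinear(fem, geo, grads, mats, Dmats, props, dt,
                            uInit = uOld, uOld = uOld, wNodes = wN,
                            dirich = dirich, tol = tol, maxIter = maxIter,
                            context = sprintf("t = %.4g s", tGlob),
                            pinP = pinPressure)
    U[k, , ] <- res$U
    p[k, ] <- res$p
    times[k] <- tGlob
    cycles[k] <- as.integer((k - 1L) %/% nsteps + 1L)
    divs[k] <- res$div
    peakRe <- max(peakRe, props$rho * max(sqrt(rowSums(res$U^2))) * hmin /
                    props$mu)
    uOld <- res$U
    if (verbose && k %% nsteps == 0)
      message(sprintf("cycle %d / %d done (max |U| = %.3g m/s)",
                      cycles[k], nCycles, max(sqrt(rowSums(res$U^2)))))
  }
  if (peakRe > laminarRe)
    warning(sprintf("peak cell Reynolds estimate %.0f exceeds laminar threshold %d",
                    peakRe, laminarRe))
  ff <- new("FlowField", mmesh = mmesh, edges = fem$edges, times = times,
            cycle = cycles, U = U, p = p)
  attr(ff, "divNorm") <- divs
  attr(ff, "peakRe") <- peakRe
  ff
}

# FEM workspace and deformed vertex positions for a stored step of a field.
flowStepGeometry <- function(ff, k) {
  period <- tail(ff@mmesh@times, 1)
  tCyc <- ff@times[k] %% period
  if (tCyc < 1e-12) tCyc <- period
  X <- meshPositions(ff@mmesh, tCyc) * 1e-3
  list(X = X, tCyc = tCyc)
}

#' Evaluate a stored flow step at arbitrary points
#'
#' @param ff a \linkS4class{FlowField}
#' @param k stored step index
#' @param pts n x 2 world points [mm]
#' @return n x 2 velocities [m/s]; NA outside the domain
#' @export
evalFlow <- function(ff, k, pts) {
  fem <- p2Structure(ff@mmesh@mesh)
  gs <- flowStepGeometry(ff, k)
  loc <- locatePoints(ff@mmesh@mesh, gs$X * 1e3, matrix(pts, ncol = 2))
  evalP2(fem, ff@U[k, , ], loc)
}

#' Mass-balance report for a moving-mesh flow solution
#'
#' At every stored step, compares the net outward flux through the open
#' boundaries (inlet + outlet) with the negative rate of domain volume
#' change, normalised by the peak inlet flow magnitude. For an
#' incompressible flow with no-slip walls the two must agree.
#'
#' @param ff a \linkS4class{FlowField}
#' @return data.frame: time, openFlux, dVdt, inletFlux, residual (fraction
#'   of the peak inlet flux)
#' @export
massBalance <- function(ff) {
  fem <- p2Structure(ff@mmesh@mesh)
  sp <- meshSpline(ff@mmesh)
  period <- tail(ff@mmesh@times, 1)
  n <- length(ff@times)
  open <- dv <- qin <- numeric(n)
  for (k in seq_len(n)) {
    gs <- flowStepGeometry(ff, k)
    U <- ff@U[k, , ]
    open[k] <- boundaryFlux(fem, gs$X, U, c("inlet", "outlet"))
    qin[k] <- boundaryFlux(fem, gs$X, U, "inlet")
    # dV/dt from the mesh velocity flux over the whole boundary
    wv <- meshVelocity(ff@mmesh, gs$tCyc, sp)
    wN <- rbind(wv, (wv[fem$edges[, 1], , drop = FALSE] +
                       wv[fem$edges[, 2], , drop = FALSE]) / 2)
    dv[k] <- boundaryFlux(fem, gs$X, wN, c("inlet", "outlet", "wall", "base"))
  }
  qref <- max(abs(qin))
  if (qref == 0) qref <- max(abs(dv), 1e-300)
  data.frame(time = ff@times, openFlux = open, dVdt = dv, inletFlux = qin,
             residual = abs(open + dv) / qref)
}

#' Cycle-convergence report
#'
#' Difference in velocity magnitude between consecutive cycles,
#' \code{Vel_diff = |U_i| - |U_(i+1)|}, evaluated at probe points at the
#' last step of each cycle. Probes outside the domain at the evaluation
#' time are dropped and counted.
#'
#' @param ff a \linkS4class{FlowField} with at least 2 cycles
#' @param probes n x 2 probe points [mm]; default: an even grid over the
#'   reference domain
#' @return list: \code{velDiff} (nprobe x npairs matrix), \code{summary}
#'   data.frame (pair, median, q1, q3, maxAbs), \code{dropped} count
#' @export
cycleConvergence <- function(ff, probes = NULL) {
  nCyc <- max(ff@cycle)
  if (nCyc < 2) stop("cycle convergence needs at least 2 cycles")
  if (is.null(probes)) probes <- probeGrid(ff@mmesh)
  probes <- matrix(probes, ncol = 2)
  fem <- p2Structure(ff@mmesh@mesh)
  lastIdx <- vapply(seq_len(nCyc), function(cy) max(which(ff@cycle == cy)), 1L)
  gs <- flowStepGeometry(ff, lastIdx[1])     # same phase every cycle
  loc <- locatePoints(ff@mmesh@mesh, gs$X * 1e3, probes)
  keep <- !is.na(loc$element)
  mag <- vapply(lastIdx, function(k) {
    sqrt(rowSums(evalP2(fem, ff@U[k, , ], loc)^2))
  }, numeric(nrow(probes)))
  mag <- mag[keep, , drop = FALSE]
  vd <- mag[, -ncol(mag), drop = FALSE] - mag[, -1, drop = FALSE]
  summ <- data.frame(
    pair = sprintf("%d-%d", seq_len(nCyc - 1L), 2:nCyc),
    median = apply(vd, 2, median),
    q1 = apply(vd, 2, quantile, 0.25),
    q3 = apply(vd, 2, quantile, 0.75),
    medianAbs = apply(abs(vd), 2, median),
    maxAbs = apply(abs(vd), 2, max))
  list(velDiff = vd, summary = summ, dropped = sum(!keep),
       nProbes = sum(keep))
}

#' Evenly spaced probe points inside the reference domain
#'
#' @param mmesh a \linkS4class{MovingMesh}
#' @param n approximate number of probes
#' @return matrix of points [mm]
#' @export
probeGrid <- function(mmesh, n = 400) {
  nd <- mmesh@mesh@nodes
  bb <- apply(nd, 2, range)
  sp <- sqrt(prod(bb[2, ] - bb[1, ]) / n)
  xs <- seq(bb[1, 1] + sp / 2, bb[2, 1], by = sp)
  zs <- seq(bb[1, 2] + sp / 2, bb[2, 2], by = sp)
  pts <- as.matrix(expand.grid(xs, zs))
  loc <- locatePoints(mmesh@mesh, nd, pts)
  pts[!is.na(loc$element), , drop = FALSE]
}

#' Volume-and-cycle-averaged velocity magnitude
#'
#' The mesh-independence metric: |U| integrated over the domain and
#' averaged over the stored steps of the last cycle, divided by the domain
#' measure.
#'
#' @param ff a \linkS4class{FlowField}
#' @return scalar [m/s]
#' @export
volumeAverageSpeed <- function(ff) {
  fem <- p2Structure(ff@mmesh@mesh)
  lastCycle <- which(ff@cycle == max(ff@cycle))
  vals <- vapply(lastCycle, function(k) {
    gs <- flowStepGeometry(ff, k)
    geo <- elemGeometry(fem, gs$X)
    N <- fem$basis$N
    spd <- sqrt(rowSums(ff@U[k, , ]^2))
    se <- matrix(spd[fem$elem6], nrow(fem$elem6))
    tot <- 0
    for (q in seq_along(fem$quad$w))
      tot <- tot + sum(fem$quad$w[q] * geo$area * (se %*% N[q, ]))
    c(tot, sum(geo$area))
  }, numeric(2))
  sum(vals[1, ]) / sum(vals[2, ])
}

#' Mesh-independence study
#'
#' Runs a case at several mesh sizes and reports degrees of freedom and the
#' volume-and-cycle-averaged velocity magnitude; meshes whose metric lies
#' within \code{band} (default 0.5\%) of the finest mesh are flagged.
#'
#' @param hs element sizes [mm], any order; the smallest is the reference
#' @param runner function(h) -> \linkS4class{FlowField}
#' @param band relative agreement band (default 0.005)
#' @return data.frame: h, dof, metric, deviation, withinBand, failed
#' @export
meshIndependence <- function(hs, runner, band = 0.005) {
  res <- lapply(hs, function(h) {
    ff <- tryCatch(runner(h), error = function(e) e)
    if (inherits(ff, "error"))
      return(data.frame(h = h, dof = NA, metric = NA, failed = TRUE))
    fem <- p2Structure(ff@mmesh@mesh)
    data.frame(h = h, dof = 2L * fem$nP2 + fem$nv,
               metric = volumeAverageSpeed(ff), failed = FALSE)
  })
  tab <- do.call(rbind, res)
  refIdx <- which(!tab$failed)[which.min(tab$h[!tab$failed])]
  ref <- tab$metric[refIdx]
  tab$deviation <- abs(tab$metric - ref) / ref
  tab$withinBand <- !tab$failed & tab$deviation <= band
  tab
}
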