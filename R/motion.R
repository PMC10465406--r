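# Moving-mesh construction: advect the boundary with the registered
# displacement field, extend the motion to interior nodes by an elastic (or
# harmonic) smoothing solve, and report cavity volume and mesh velocity.

#' Advect boundary nodes along the displacement field
#'
#' Samples the cyclic displacement field at every boundary node at fixed
#' time steps over one cycle. Because the field's first and last instances
#' are identically zero, the trajectories close exactly (first and last
#' stored positions coincide), and nodes in regions of zero displacement
#' (base plate, tube walls) remain stationary.
#'
#' @param mesh a \linkS4class{SimplexMesh}
#' @param f a cyclic \linkS4class{DisplacementField}
#' @param step fixed time step [s] (default 0.019 s; T/step must be integer)
#' @return list: \code{times} (stored step times, 0..T inclusive),
#'   \code{positions} (nsteps x nBoundaryNodes x d [mm]), \code{bnodes}
#'   (boundary node ids)
#' @export
advectSurface <- function(mesh, f, step = 0.019) {
  period <- tail(f@times, 1)
  K <- round(period / step)
  if (abs(K * step - period) > 1e-9)
    stop("step must divide the cycle period")
  tms <- (0:K) * step
  bnodes <- sort(unique(as.vector(mesh@boundary)))
  X <- mesh@nodes[bnodes, , drop = FALSE]
  pos <- array(0, c(K + 1L, length(bnodes), ncol(X)))
  for (k in seq_along(tms)) {
    d <- sampleDisplacement(f, X, tms[k])
    if (any(!is.finite(d))) stop("displacement sampling failed at a node")
    pos[k, , ] <- X + d
  }
  # exact cyclic closure (both end instances of f are identically zero)
  pos[K + 1L, , ] <- pos[1L, , ]
  list(times = tms, positions = pos, bnodes = bnodes)
}

# P1 stiffness for the vector extension problem on simplices.
# method "harmonic": component-wise Laplace; "elastic": Navier-Cauchy form
# mu (grad u, grad v) + (lam + mu)(div u, div v). Jacobian stiffening scales
# each element matrix by (Vref / V)^chi.
extensionMatrix <- function(nodes, elements, method = c("elastic", "harmonic"),
                            chi = 1, poisson = 0.3) {
  method <- match.arg(method)
  d <- ncol(nodes)
  np <- nrow(nodes)
  nel <- nrow(elements)
  nvert <- d + 1L
  vol <- abs(triangleAreas(nodes, elements))
  vref <- mean(vol)
  stiff <- (vref / pmax(vol, 1e-12))^chi
  mu <- 1
  lam <- if (method == "elastic") 2 * mu * poisson / (1 - 2 * poisson) else 0
  ii <- jj <- xx <- vector("list", nel)
  for (e in seq_len(nel)) {
    vid <- elements[e, ]
    X <- nodes[vid, , drop = FALSE]
    # gradients of barycentric coordinates
    Jm <- t(X[-1, , drop = FALSE]) - X[1, ]
    Jinv <- solve(Jm)
    G <- rbind(-colSums(Jinv), Jinv)        # nvert x d, rows = grad lambda_i
    Ke <- matrix(0, nvert * d, nvert * d)
    lap <- (G %*% t(G)) * vol[e]
    for (c_ in seq_len(d)) {
      id <- (c_ - 1L) * nvert + seq_len(nvert)
      Ke[id, id] <- Ke[id, id] + mu * lap
    }
    if (method == "elastic") {
      for (c1 in seq_len(d)) for (c2 in seq_len(d)) {
        id1 <- (c1 - 1L) * nvert + seq_len(nvert)
        id2 <- (c2 - 1L) * nvert + seq_len(nvert)
        Ke[id1, id2] <- Ke[id1, id2] +
          (lam + mu) * outer(G[, c1], G[, c2]) * vol[e]
      }
    }
    Ke <- Ke * stiff[e]
    gid <- as.vector(outer(vid, (seq_len(d) - 1L) * np, "+"))
    ii[[e]] <- rep(gid, times = nvert * d)
    jj[[e]] <- rep(gid, each = nvert * d)
    xx[[e]] <- as.vector(Ke)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(np * d, np * d))
}

#' Extend boundary motion to the mesh interior
#'
#' Solves a linear smoothing-extension problem (elastic by default,
#' harmonic as an alternative) for the interior node displacement at every
#' stored step, with the advected boundary trajectories as Dirichlet data.
#' The system matrix is assembled on the reference mesh and factorised
#' once, so the extension is deterministic and fast. Affine boundary motion
#' (e.g. a rigid translation) is reproduced exactly up to solver tolerance.
#'
#' @param traj boundary trajectories from \code{\link{advectSurface}}
#' @param mesh the reference \linkS4class{SimplexMesh}
#' @param method "elastic" (default) or "harmonic"
#' @param chi Jacobian stiffening exponent (0 disables)
#' @return a \linkS4class{MovingMesh}
#' @export
extendInterior <- function(traj, mesh, method = c("elastic", "harmonic"),
                           chi = 1) {
  method <- match.arg(method)
  d <- ncol(mesh@nodes)
  np <- nrow(mesh@nodes)
  K <- extensionMatrix(mesh@nodes, mesh@elements, method, chi)
  bnd <- traj$bnodes
  bdof <- as.vector(outer(bnd, (seq_len(d) - 1L) * np, "+"))
  idof <- setdiff(seq_len(np * d), bdof)
  Kii <- K[idof, idof, drop = FALSE]
  Kib <- K[idof, bdof, drop = FALSE]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kii))
  nst <- length(traj$times)
  pos <- array(0, c(nst, np, d))
  for (k in seq_len(nst)) {
    ub <- as.vector(traj$positions[k, , ] - mesh@nodes[bnd, , drop = FALSE])
    ui <- as.vector(Matrix::solve(fac, -Kib %*% ub))
    u <- numeric(np * d)
    u[bdof] <- ub
    u[idof] <- ui
    pos[k, , ] <- mesh@nodes + matrix(u, np, d)
    ar <- triangleAreas(pos[k, , ], mesh@elements)
    if (any(ar <= 0))
      stop(sprintf("element inversion at step %d (worst element %d, area %.3g)",
                   k, which.min(ar), min(ar)))
  }
  pos[nst, , ] <- pos[1L, , ]
  new("MovingMesh", mesh = mesh, trajectories = pos, times = traj$times,
      step = traj$times[2] - traj$times[1])
}

#' Moving mesh directly from analytic ground-truth motion
#'
#' Bypasses registration: applies the analytic phantom deformation to every
#' mesh node at the fixed steps. Used for ablation and for ground-truth
#' pipeline runs.
#'
#' @param mesh a \linkS4class{SimplexMesh} (2D cross-section)
#' @param g,w phantom geometry and waveform
#' @param step fixed time step [s]
#' @return a \linkS4class{MovingMesh}
#' @export
analyticMovingMesh <- function(mesh, g, w, step = 0.019) {
  period <- w@Tmeas
  K <- round(period / step)
  if (abs(K * step - period) > 1e-9) stop("step must divide the cycle period")
  tms <- (0:K) * step
  np <- nrow(mesh@nodes)
  pos <- array(0, c(K + 1L, np, ncol(mesh@nodes)))
  for (k in seq_along(tms))
    pos[k, , ] <- mesh@nodes + analyticDeformation(g, w, tms[k], mesh@nodes)
  pos[K + 1L, , ] <- pos[1L, , ]
  new("MovingMesh", mesh = mesh, trajectories = pos, times = tms, step = step)
}

#' Cavity volume (2D: area) per stored step of a moving mesh
#'
#' Divergence-theorem measure of the deformed domain at each stored step.
#' In 3D the result is in mL; in 2D mode it is the cross-section area in
#' mm^2. Errors if the boundary is open (a facet of some element is shared
#' by more than two elements or the boundary does not close).
#'
#' @param m a \linkS4class{MovingMesh}
#' @return numeric vector, one measure per stored step
#' @export
cavityVolumeSeries <- function(m) {
  ed <- m@mesh@boundary
  ring <- sort(unique(as.vector(ed)))
  cnt <- table(as.vector(ed))
  if (any(cnt != 2L)) stop("open surface: boundary facets do not close")
  vapply(seq_along(m@times), function(k) {
    sum(abs(triangleAreas(m@trajectories[k, , ], m@mesh@elements)))
  }, 0) / ifelse(ncol(m@mesh@nodes) == 3L, 1000, 1)
}

# periodic spline of the trajectories; cached on first use
meshSpline <- function(m) {
  nst <- length(m@times)
  Y <- matrix(m@trajectories, nst)
  periodicSpline(m@times, Y)
}

#' Mesh node positions at an arbitrary time
#'
#' Periodic cubic-spline interpolation of the stored trajectories; exact at
#' stored steps.
#'
#' @param m a \linkS4class{MovingMesh}
#' @param t time [s] (wrapped into the cycle)
#' @param spline optional precomputed spline from repeated calls
#' @return nnodes x d matrix [mm]
#' @export
meshPositions <- function(m, t, spline = NULL) {
  k <- which(abs(m@times - t) < 1e-12)
  if (length(k) == 1L) return(m@trajectories[k, , ])
  if (is.null(spline)) spline <- meshSpline(m)
  matrix(evalPeriodicSpline(spline, t), nrow(m@mesh@nodes),
         ncol(m@mesh@nodes))
}

#' Mesh node velocities at an arbitrary time
#'
#' Time derivative of the periodic spline through the node trajectories.
#' Nodes with constant trajectories (non-moving patches) get exactly zero
#' velocity. Returned in m/s (trajectories are stored in mm).
#'
#' @param m a \linkS4class{MovingMesh}
#' @param t time [s]
#' @param spline optional precomputed spline
#' @return nnodes x d matrix [m/s]
#' @export
meshVelocity <- function(m, t, spline = NULL) {
  if (is.null(spline)) spline <- meshSpline(m)
  matrix(evalPeriodicSpline(spline, t, deriv = 1), nrow(m@mesh@nodes),
         ncol(m@mesh@nodes)) * 1e-3
}
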