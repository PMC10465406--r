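# Taylor-Hood (P2 velocity / P1 pressure) finite elements on triangles:
# mesh-derived P2 structure, quadrature, vectorised assembly, Dirichlet
# elimination, boundary flux integration and solution evaluation.
# Positions enter in metres; all assembled quantities are SI.

# Degree-5 7-point triangle quadrature (barycentric coords, weights sum 1).
triQuadrature <- function() {
  a <- 0.059715871789770; b <- 0.470142064105115
  c_ <- 0.797426985353087; d <- 0.101286507323456
  L <- rbind(c(1/3, 1/3, 1/3),
             c(a, b, b), c(b, a, b), c(b, b, a),
             c(c_, d, d), c(d, c_, d), c(d, d, c_))
  w <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  list(L = L, w = w)
}

# P2 basis and barycentric derivatives at quadrature points.
# N: nq x 6; dNdL: 6 x 3 x nq (d phi_i / d L_j).
p2Basis <- function(L) {
  nq <- nrow(L)
  N <- matrix(0, nq, 6)
  dNdL <- array(0, c(6, 3, nq))
  for (q in seq_len(nq)) {
    l <- L[q, ]
    N[q, ] <- c(l * (2 * l - 1), 4 * l[1] * l[2], 4 * l[2] * l[3],
                4 * l[3] * l[1])
    for (i in 1:3) dNdL[i, i, q] <- 4 * l[i] - 1
    dNdL[4, 1, q] <- 4 * l[2]; dNdL[4, 2, q] <- 4 * l[1]
    dNdL[5, 2, q] <- 4 * l[3]; dNdL[5, 3, q] <- 4 * l[2]
    dNdL[6, 3, q] <- 4 * l[1]; dNdL[6, 1, q] <- 4 * l[3]
  }
  list(N = N, dNdL = dNdL)
}

# P2 node structure: vertex nodes then one node per unique edge.
p2Structure <- function(mesh) {
  tri <- mesh@elements
  nv <- nrow(mesh@nodes)
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- !duplicated(key)
  edges <- ed[uk, , drop = FALSE]
  eid <- match(key, key[uk])
  elem6 <- cbind(tri, matrix(eid, nrow(tri), 3) + nv)
  bkey <- paste(pmin(mesh@boundary[, 1], mesh@boundary[, 2]),
                pmax(mesh@boundary[, 1], mesh@boundary[, 2]))
  bmid <- match(bkey, key[uk]) + nv
  qd <- triQuadrature()
  bas <- p2Basis(qd$L)
  list(mesh = mesh, nv = nv, edges = edges, nP2 = nv + nrow(edges),
       elem6 = elem6, bmid = bmid, quad = qd, basis = bas)
}

# P2 node coordinates for given vertex positions (midpoints = averages).
p2Coords <- function(fem, X) {
  rbind(X, (X[fem$edges[, 1], , drop = FALSE] +
              X[fem$edges[, 2], , drop = FALSE]) / 2)
}

# Element geometry at vertex positions X [m]: barycentric gradients and
# areas. gradL: nel x 3 x 2, area: nel.
elemGeometry <- function(fem, X) {
  tri <- fem$mesh@elements
  p1 <- X[tri[, 1], , drop = FALSE]
  p2 <- X[tri[, 2], , drop = FALSE]
  p3 <- X[tri[, 3], , drop = FALSE]
  d2 <- p2 - p1; d3 <- p3 - p1
  det <- d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1]
  if (any(det <= 0)) stop("element inversion during assembly")
  # inverse-transpose of J = [d2 d3]: gradients of reference coords
  g2 <- cbind(d3[, 2], -d3[, 1]) / det
  g3 <- cbind(-d2[, 2], d2[, 1]) / det
  gradL <- array(0, c(nrow(tri), 3, 2))
  gradL[, 2, ] <- g2
  gradL[, 3, ] <- g3
  gradL[, 1, ] <- -(g2 + g3)
  list(gradL = gradL, area = det / 2)
}

# Physical P2 gradients at each quadrature point.
# Returns list over q of list(Gx = nel x 6, Gy = nel x 6).
p2Gradients <- function(fem, geo) {
  nq <- length(fem$quad$w)
  lapply(seq_len(nq), function(q) {
    dn <- fem$basis$dNdL[, , q]          # 6 x 3
    Gx <- geo$gradL[, , 1] %*% t(dn)     # nel x 6
    Gy <- geo$gradL[, , 2] %*% t(dn)
    list(Gx = Gx, Gy = Gy)
  })
}

# Triplet indices for nel x nb x nb element blocks flattened in (e, i, j)
# order: row = conn[e, i], col = conn[e, j].
blockTriplets <- function(conn) {
  nb <- ncol(conn)
  list(i = rep(as.vector(conn), times = nb),
       j = as.vector(conn[, rep(seq_len(nb), each = nb)]))
}

# Viscous stiffness, mass, convection and streamline-upwind matrices on the
# current geometry. aNodes: nP2 x 2 convective velocity (fluid - mesh) or
# NULL. The SU term tau (a.grad u, a.grad v) stabilises convection-dominated
# elements; tau follows the classic cell-Peclet switch and vanishes as
# |a| h / (2 nu) -> 0. It is inactive wherever a.grad u = 0, so developed
# Poiseuille profiles and uniform (Galilean) fields are unaffected.
femMatrices <- function(fem, geo, grads, aNodes = NULL, nu = NULL) {
  nel <- nrow(fem$mesh@elements)
  w <- fem$quad$w
  N <- fem$basis$N
  Kacc <- array(0, c(nel, 6, 6))
  Macc <- array(0, c(nel, 6, 6))
  Cacc <- if (!is.null(aNodes)) array(0, c(nel, 6, 6)) else NULL
  Sacc <- if (!is.null(aNodes) && !is.null(nu)) array(0, c(nel, 6, 6)) else NULL
  if (!is.null(aNodes)) {
    ax <- matrix(aNodes[fem$elem6, 1], nel)   # nel x 6 nodal values
    ay <- matrix(aNodes[fem$elem6, 2], nel)
    if (!is.null(Sacc)) {
      he <- sqrt(2 * geo$area)
      amag <- sqrt(rowMeans(ax)^2 + rowMeans(ay)^2)
      pe <- amag * he / (2 * nu)
      tau <- ifelse(amag > 1e-12,
                    he / (2 * amag) * pmin(pe / 3, 1), 0)
    }
  }
  for (q in seq_along(w)) {
    Gx <- grads[[q]]$Gx; Gy <- grads[[q]]$Gy
    wq <- w[q] * geo$area
    if (!is.null(aNodes)) {
      axq <- as.vector(ax %*% N[q, ])         # nel
      ayq <- as.vector(ay %*% N[q, ])
    }
    for (i in 1:6) for (j in 1:6) {
      Kacc[, i, j] <- Kacc[, i, j] + wq * (Gx[, i] * Gx[, j] + Gy[, i] * Gy[, j])
      Macc[, i, j] <- Macc[, i, j] + wq * N[q, i] * N[q, j]
      if (!is.null(aNodes)) {
        adGj <- axq * Gx[, j] + ayq * Gy[, j]
        Cacc[, i, j] <- Cacc[, i, j] + wq * N[q, i] * adGj
        if (!is.null(Sacc))
          Sacc[, i, j] <- Sacc[, i, j] +
            wq * tau * (axq * Gx[, i] + ayq * Gy[, i]) * adGj
      }
    }
  }
  tp <- blockTriplets(fem$elem6)
  mk <- function(acc)
    Matrix::sparseMatrix(i = tp$i, j = tp$j, x = as.vector(acc),
                         dims = c(fem$nP2, fem$nP2))
  list(K = mk(Kacc), M = mk(Macc),
       C = if (!is.null(aNodes)) mk(Cacc) else NULL,
       S = if (!is.null(Sacc)) mk(Sacc) else NULL)
}

# Pressure-velocity coupling D_c[p1 node, p2 node] = int L_p d(phi)/dx_c.
femDivMatrices <- function(fem, geo, grads) {
  nel <- nrow(fem$mesh@elements)
  w <- fem$quad$w
  L <- fem$quad$L
  Dx <- array(0, c(nel, 3, 6))
  Dy <- array(0, c(nel, 3, 6))
  for (q in seq_along(w)) {
    wq <- w[q] * geo$area
    for (i in 1:3) for (j in 1:6) {
      Dx[, i, j] <- Dx[, i, j] + wq * L[q, i] * grads[[q]]$Gx[, j]
      Dy[, i, j] <- Dy[, i, j] + wq * L[q, i] * grads[[q]]$Gy[, j]
    }
  }
  tri <- fem$mesh@elements
  i3 <- rep(as.vector(tri), times = 6)
  j6 <- as.vector(fem$elem6[, rep(seq_len(6), each = 3)])
  mk <- function(acc)
    Matrix::sparseMatrix(i = i3, j = j6, x = as.vector(acc),
                         dims = c(fem$nv, fem$nP2))
  list(Dx = mk(Dx), Dy = mk(Dy))
}

# Apply Dirichlet conditions on velocity DOFs by symmetric elimination.
applyDirichlet <- function(Amat, rhs, dofs, vals) {
  n <- nrow(Amat)
  rhs <- rhs - as.vector(Amat[, dofs, drop = FALSE] %*% vals)
  keep <- rep(1, n); keep[dofs] <- 0
  Z <- Matrix::Diagonal(n, keep)
  pin <- Matrix::sparseMatrix(i = dofs, j = dofs, x = 1, dims = c(n, n))
  Amat <- Z %*% Amat %*% Z + pin
  rhs[dofs] <- vals
  list(A = Amat, rhs = rhs)
}

# Boundary flux of the P2 velocity through facets with the given tag.
# Simpson on each straight edge (exact for quadratic traces). Positive =
# out of the domain. X: vertex positions [m]; U: nP2 x 2 [m/s].
boundaryFlux <- function(fem, X, U, tags) {
  sel <- fem$mesh@boundaryTag %in% tags
  if (!any(sel)) return(0)
  ed <- fem$mesh@boundary[sel, , drop = FALSE]
  mid <- fem$bmid[sel]
  p1 <- X[ed[, 1], , drop = FALSE]
  p2 <- X[ed[, 2], , drop = FALSE]
  dvec <- p2 - p1
  len <- sqrt(rowSums(dvec^2))
  nrm <- cbind(dvec[, 2], -dvec[, 1]) / len    # outward for CCW interior-left
  f1 <- rowSums(U[ed[, 1], , drop = FALSE] * nrm)
  f2 <- rowSums(U[ed[, 2], , drop = FALSE] * nrm)
  fm <- rowSums(U[mid, , drop = FALSE] * nrm)
  sum(len / 6 * (f1 + 4 * fm + f2))
}

# Locate points in triangles (deformed positions X); returns element index
# (NA outside) and barycentric coordinates.
locatePoints <- function(mesh, X, pts, tol = 1e-9) {
  npts <- nrow(pts)
  el <- rep(NA_integer_, npts)
  bc <- matrix(NA_real_, npts, 3)
  rem <- seq_len(npts)
  tri <- mesh@elements
  for (e in seq_len(nrow(tri))) {
    if (!length(rem)) break
    p1 <- X[tri[e, 1], ]; p2 <- X[tri[e, 2], ]; p3 <- X[tri[e, 3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    dx <- pts[rem, 1] - p1[1]; dy <- pts[rem, 2] - p1[2]
    l2 <- (dx * (p3[2] - p1[2]) - dy * (p3[1] - p1[1])) / det
    l3 <- (dy * (p2[1] - p1[1]) - dx * (p2[2] - p1[2])) / det
    l1 <- 1 - l2 - l3
    inE <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (any(inE)) {
      hit <- rem[inE]
      el[hit] <- e
      bc[hit, ] <- cbind(l1[inE], l2[inE], l3[inE])
      rem <- rem[!inE]
    }
  }
  list(element = el, bary = bc)
}

# Evaluate the P2 velocity (and P1 pressure) at located points.
evalP2 <- function(fem, U, loc, p = NULL) {
  ok <- !is.na(loc$element)
  out <- matrix(NA_real_, length(loc$element), ncol(U))
  pout <- rep(NA_real_, length(loc$element))
  if (any(ok)) {
    l <- loc$bary[ok, , drop = FALSE]
    N <- cbind(l * (2 * l - 1), 4 * l[, 1] * l[, 2], 4 * l[, 2] * l[, 3],
               4 * l[, 3] * l[, 1])
    conn <- fem$elem6[loc$element[ok], , drop = FALSE]
    for (c_ in seq_len(ncol(U))) {
      vals <- matrix(U[conn, c_], nrow(conn))
      out[ok, c_] <- rowSums(N * vals)
    }
    if (!is.null(p)) {
      tri <- fem$mesh@elements[loc$element[ok], , drop = FALSE]
      pout[ok] <- rowSums(l * matrix(p[tri], nrow(tri)))
    }
  }
  if (is.null(p)) out else list(U = out, p = pout)
}
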