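# Simplex mesh generation for the desk-scale 2D (long-axis cross-section)
# mode: the phantom cavity with inlet/outlet channels, and plain channel
# meshes for solver benchmarks. Structured block meshing with node merging.

# Merge coincident nodes (coordinate hash) and remap connectivity.
mergeNodes <- function(nodes, tol = 1e-8) {
  dimnames(nodes) <- NULL
  key <- apply(round(nodes / tol) * tol, 1, paste, collapse = "_")
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  list(nodes = nodes[uid, , drop = FALSE], map = map)
}

# Triangulate a structured quad block given node id matrix [ni x nj];
# alternating diagonals for isotropy.
triangulateBlock <- function(ids) {
  ni <- nrow(ids); nj <- ncol(ids)
  tris <- vector("list", (ni - 1) * (nj - 1))
  n <- 0L
  for (j in seq_len(nj - 1)) for (i in seq_len(ni - 1)) {
    a <- ids[i, j]; b <- ids[i + 1, j]; c_ <- ids[i + 1, j + 1]; d <- ids[i, j + 1]
    n <- n + 1L
    if ((i + j) %% 2 == 0)
      tris[[n]] <- rbind(c(a, b, c_), c(a, c_, d))
    else
      tris[[n]] <- rbind(c(a, b, d), c(b, c_, d))
  }
  do.call(rbind, tris)
}

# Signed areas of triangles (positive = counter-clockwise).
triangleAreas <- function(nodes, tri) {
  p1 <- nodes[tri[, 1], , drop = FALSE]
  p2 <- nodes[tri[, 2], , drop = FALSE]
  p3 <- nodes[tri[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

# Extract boundary edges (facets used by exactly one triangle), oriented so
# the interior lies on the left (outward normal = (dy, -dx) rotated).
boundaryEdges <- function(nodes, tri) {
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  ed[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

#' 2D long-axis cross-section mesh of the phantom
#'
#' Builds a triangulated cross-section: a truncated-ellipse cavity (base at
#' z = 0, slightly flattened apex cap at z = zc + Rz) with two straight
#' channels (inlet and outlet) above the base plane. Boundary facets are
#' tagged \code{inlet} (top of the inlet channel), \code{outlet},
#' \code{base} (static base segments at z = 0) and \code{wall}.
#'
#' @param g a \linkS4class{PhantomGeometry} (its 2D cross-section is used)
#' @param h target element size [mm]
#' @param apexFrac width of the flat apex cap as a fraction of Rx
#' @return a \linkS4class{SimplexMesh}
#' @export
phantomMesh2D <- function(g, h = 4, apexFrac = 0.25) {
  za <- g@zc + g@Rz
  tubes <- lapply(g@tubeX, function(xt) c(xt - g@tubeD / 2, xt + g@tubeD / 2))
  # x stations at the base: uniform grid plus exact channel edges
  nx <- max(8L, 2L * ceiling(g@Rx / h))
  xsU <- seq(-g@Rx, g@Rx, length.out = nx + 1L)
  edges <- unlist(tubes)
  # drop uniform stations that crowd an exact channel edge, then union
  keep <- vapply(xsU, function(x) all(abs(x - edges) > h / 4), TRUE)
  xs <- sort(unique(c(xsU[keep], edges)))
  xi <- xs / g@Rx
  nz <- max(6L, ceiling(za / h))
  # cluster axial stations towards the narrowing apex to keep aspect ratios
  zeta <- sin(pi / 2 * seq(0, 1, length.out = nz + 1L))
  width <- g@Rx * sqrt(1 - (1 - apexFrac^2) * zeta^2)
  cavNodes <- do.call(rbind, lapply(seq_along(zeta), function(j)
    cbind(xi * width[j], zeta[j] * za)))
  cavIds <- matrix(seq_len(length(xi) * length(zeta)), length(xi))
  nodes <- cavNodes
  tri <- triangulateBlock(cavIds)
  # channel blocks share the z = 0 nodes of the cavity
  ntz <- max(3L, ceiling(g@tubeL / h))
  zt <- seq(-g@tubeL, 0, length.out = ntz + 1L)
  for (tb in tubes) {
    xt <- xs[xs >= tb[1] - 1e-9 & xs <= tb[2] + 1e-9]
    ids <- matrix(0L, length(xt), length(zt))
    for (j in seq_along(zt)) {
      ids[, j] <- nrow(nodes) + seq_along(xt)
      nodes <- rbind(nodes, cbind(xt, zt[j]))
    }
    tri <- rbind(tri, triangulateBlock(ids))
  }
  mg <- mergeNodes(nodes)
  tri <- matrix(mg$map[tri], ncol = 3)
  # enforce counter-clockwise orientation
  ar <- triangleAreas(mg$nodes, tri)
  tri[ar < 0, ] <- tri[ar < 0, c(1, 3, 2)]
  bed <- boundaryEdges(mg$nodes, tri)
  mid <- (mg$nodes[bed[, 1], , drop = FALSE] +
            mg$nodes[bed[, 2], , drop = FALSE]) / 2
  tag <- rep("wall", nrow(bed))
  atBottom <- abs(mid[, 2] + g@tubeL) < 1e-6
  inT1 <- mid[, 1] > tubes[[1]][1] - 1e-6 & mid[, 1] < tubes[[1]][2] + 1e-6
  inT2 <- mid[, 1] > tubes[[2]][1] - 1e-6 & mid[, 1] < tubes[[2]][2] + 1e-6
  tag[atBottom & inT1] <- "inlet"
  tag[atBottom & inT2] <- "outlet"
  tag[abs(mid[, 2]) < 1e-6] <- "base"
  new("SimplexMesh", nodes = mg$nodes, elements = tri, boundary = bed,
      boundaryTag = tag)
}

#' Rectangular channel mesh (solver benchmark geometry)
#'
#' A straight 2D channel x in [0, L], y in [0, H]; boundary tags:
#' \code{inlet} at x = 0, \code{outlet} at x = L, \code{wall} at y = 0, H.
#'
#' @param L channel length [mm]
#' @param H channel height [mm]
#' @param h target element size [mm]
#' @return a \linkS4class{SimplexMesh}
#' @export
channelMesh2D <- function(L = 40, H = 10, h = 2) {
  nxm <- max(4L, ceiling(L / h)); nym <- max(4L, ceiling(H / h))
  xs <- seq(0, L, length.out = nxm + 1L)
  ys <- seq(0, H, length.out = nym + 1L)
  nodes <- as.matrix(expand.grid(xs, ys))
  dimnames(nodes) <- NULL
  ids <- matrix(seq_len(nrow(nodes)), length(xs))
  tri <- triangulateBlock(ids)
  ar <- triangleAreas(nodes, tri)
  tri[ar < 0, ] <- tri[ar < 0, c(1, 3, 2)]
  bed <- boundaryEdges(nodes, tri)
  mid <- (nodes[bed[, 1], ] + nodes[bed[, 2], ]) / 2
  tag <- rep("wall", nrow(bed))
  tag[abs(mid[, 1]) < 1e-9] <- "inlet"
  tag[abs(mid[, 1] - L) < 1e-9] <- "outlet"
  colnames(nodes) <- NULL
  new("SimplexMesh", nodes = nodes, elements = tri, boundary = bed,
      boundaryTag = tag)
}

#' Triangle shape quality
#'
#' Ratio of twice the inradius to the circumradius (1 for equilateral,
#' towards 0 for degenerate elements).
#'
#' @param mesh a \linkS4class{SimplexMesh} (2D)
#' @param nodes optional deformed node positions
#' @return quality per element in (0, 1]
#' @export
elementQuality <- function(mesh, nodes = mesh@nodes) {
  tri <- mesh@elements
  a <- sqrt(rowSums((nodes[tri[, 2], ] - nodes[tri[, 3], ])^2))
  b <- sqrt(rowSums((nodes[tri[, 1], ] - nodes[tri[, 3], ])^2))
  c_ <- sqrt(rowSums((nodes[tri[, 1], ] - nodes[tri[, 2], ])^2))
  s <- (a + b + c_) / 2
  area <- abs(triangleAreas(nodes, tri))
  rin <- area / s
  rcirc <- a * b * c_ / (4 * pmax(area, 1e-300))
  pmin(2 * rin / rcirc, 1)
}
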