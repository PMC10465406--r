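# Synthetic dynamic phantom: programmed compression waveform, parametric
# cavity geometry, analytic ground-truth deformation and cavity surfaces.

#' Programmed compression waveform c(t)
#'
#' Axial compression applied to the phantom apex:
#' \deqn{c(t) = C_d \sin^2(\pi (t + t_0) / T_{prog})}
#' Non-negative, \code{Tprog}-periodic, zero at t = 0 and t = T.
#'
#' @param t time(s) [s]
#' @param w a \linkS4class{MotionWaveform}
#' @return axial displacement [mm], same length as \code{t}
#' @examples
#' w <- motionWaveform(Cd = 10, Tprog = 0.8)
#' compressionWaveform(c(0, 0.2, 0.4), w)  # 0, 5, 10 mm
#' @export
compressionWaveform <- function(t, w) {
  stopifnot(is(w, "MotionWaveform"))
  if (w@Tprog <= 0) stop("invalid parameter: period must be positive")
  w@Cd * sin(pi * (t + w@phaseOffset) / w@Tprog)^2
}

#' Realized compression waveform
#'
#' The cycle period realized by the phantom differs from the programmed one
#' (0.76 s measured vs 0.8 s programmed); the realized motion keeps the
#' squared-sine shape but completes a full cycle in \code{Tmeas}. This is
#' the waveform the synthetic phantom actually moves with, so rendered
#' sequences are exactly \code{Tmeas}-periodic.
#'
#' @inheritParams compressionWaveform
#' @return axial displacement [mm]
#' @export
realizedCompression <- function(t, w) {
  stopifnot(is(w, "MotionWaveform"))
  if (w@Tmeas <= 0) stop("invalid parameter: period must be positive")
  w@Cd * sin(pi * (t + w@phaseOffset) / w@Tmeas)^2
}

#' Apex point of the phantom cavity
#' @param g a \linkS4class{PhantomGeometry}
#' @return world coordinates [mm] (length 2 or 3)
#' @export
apexPoint <- function(g) {
  za <- g@zc + g@Rz
  if (g@dim == 2L) c(0, za) else c(0, 0, za)
}

# Axial motion ramp: 0 for z <= rampStart (base plate and tubes), smoothstep
# to 1 at the apex. Purely axial, so tube walls (z < 0) are exactly static.
axialProfile <- function(g, z) {
  za <- g@zc + g@Rz
  smoothstep((z - g@rampStart) / (za - g@rampStart))
}

# Lumen indicator in the reference configuration. pts: n x dim world [mm].
# grow: dilate the shape by this margin [mm] (used to rasterise the wall).
lumenIndicator <- function(g, pts, grow = 0) {
  pts <- matrix(pts, ncol = g@dim)
  x <- pts[, 1]
  z <- pts[, g@dim]
  r2 <- if (g@dim == 3L) {
    y <- pts[, 2]
    (x / (g@Rx + grow))^2 + (y / (g@Ry + grow))^2
  } else (x / (g@Rx + grow))^2
  inCavity <- z >= -grow &
    r2 + ((z - g@zc) / (g@Rz + grow))^2 <= 1
  inTube <- rep(FALSE, nrow(pts))
  for (xt in g@tubeX) {
    rt2 <- if (g@dim == 3L) (x - xt)^2 + pts[, 2]^2 else (x - xt)^2
    inTube <- inTube | (rt2 <= (g@tubeD / 2 + grow)^2 &
                          z >= -g@tubeL - grow & z <= 0)
  }
  inCavity | inTube
}

#' Ground-truth displacement of the analytic phantom motion
#'
#' The phantom motion is a pure axial compression: material points move by
#' \code{-c(t) * s(z)} along the long axis, where \code{s} ramps smoothly
#' (C1) from 0 at the base plane to 1 at the apex and is identically zero on
#' the base plate and the inlet/outlet tube walls. The realized period
#' \code{Tmeas} governs the motion (see \code{\link{realizedCompression}}).
#'
#' @param g a \linkS4class{PhantomGeometry}
#' @param w a \linkS4class{MotionWaveform}
#' @param t a single time [s]
#' @param pts n x dim matrix of reference points [mm]
#' @return n x dim matrix of displacements [mm]
#' @export
analyticDeformation <- function(g, w, t, pts) {
  pts <- matrix(pts, ncol = g@dim)
  d <- matrix(0, nrow(pts), g@dim)
  d[, g@dim] <- -realizedCompression(t, w) * axialProfile(g, pts[, g@dim])
  d
}

# Inverse of the axial map z' = z - c * s(z) for a vector of deformed z'.
# Monotone for c * max s' < 1; solved by bisection (vectorised).
invertAxialMap <- function(g, cval, zprime) {
  if (cval == 0) return(zprime)
  lo <- zprime              # z >= z' since displacement is <= 0... z' = z - c s(z) <= z
  hi <- zprime + cval       # s <= 1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f <- mid - cval * axialProfile(g, mid) - zprime
    up <- f < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

#' Closed triangulated cavity surface
#'
#' Triangulates the truncated-ellipsoid cavity (3D) capped by a flat base
#' disk, producing a watertight, consistently oriented (outward) surface.
#' Nodes on the base cap are flagged non-moving. Tubes are not part of this
#' surface: they attach above the base plane and never move.
#'
#' @param g a 3D \linkS4class{PhantomGeometry}
#' @param nTheta azimuthal resolution
#' @param nZ axial resolution
#' @return list: \code{nodes} (n x 3 [mm]), \code{triangles} (m x 3),
#'   \code{moving} logical per node
#' @export
cavitySurface <- function(g, nTheta = 24, nZ = 16) {
  stopifnot(g@dim == 3L)
  za <- g@zc + g@Rz
  # axial stations from base (z = 0) towards the apex, last ring before apex
  zs <- seq(0, za, length.out = nZ + 1L)[1:nZ]
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[1:nTheta]
  fr <- sqrt(pmax(1 - ((zs - g@zc) / g@Rz)^2, 0))
  nodes <- do.call(rbind, lapply(seq_along(zs), function(i)
    cbind(g@Rx * fr[i] * cos(th), g@Ry * fr[i] * sin(th), zs[i])))
  apexId <- nrow(nodes) + 1L
  baseId <- nrow(nodes) + 2L
  nodes <- rbind(nodes, apexPoint(g), c(0, 0, 0))
  tri <- list()
  ring <- function(i) (i - 1L) * nTheta + seq_len(nTheta)
  nxt <- c(2:nTheta, 1L)
  for (i in seq_len(nZ - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    # outward orientation (counter-clockwise seen from outside)
    tri[[length(tri) + 1L]] <- cbind(a, b, a[nxt])
    tri[[length(tri) + 1L]] <- cbind(a[nxt], b, b[nxt])
  }
  top <- ring(nZ)
  tri[[length(tri) + 1L]] <- cbind(top, apexId, top[nxt])     # apex fan
  bot <- ring(1L)
  tri[[length(tri) + 1L]] <- cbind(bot, bot[nxt], baseId)     # base cap
  triangles <- do.call(rbind, tri)
  # orient outward: flip winding if the signed volume comes out negative
  if (surfaceVolume(nodes, triangles) < 0)
    triangles <- triangles[, c(1L, 3L, 2L)]
  moving <- axialProfile(g, nodes[, 3]) > 0
  list(nodes = nodes, triangles = triangles, moving = moving)
}

#' Volume enclosed by a closed triangulated surface
#'
#' Divergence-theorem volume: sum of signed tetrahedron volumes against the
#' origin. Requires a consistently outward-oriented watertight surface.
#'
#' @param nodes n x 3 vertex coordinates [mm]
#' @param triangles m x 3 connectivity
#' @return enclosed volume [mL]
#' @export
surfaceVolume <- function(nodes, triangles) {
  a <- nodes[triangles[, 1], , drop = FALSE]
  b <- nodes[triangles[, 2], , drop = FALSE]
  c_ <- nodes[triangles[, 3], , drop = FALSE]
  v6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(v6) / 6 / 1000          # mm^3 -> mL
}

#' Cavity volume over time from the analytically deformed surface
#'
#' @param g a 3D \linkS4class{PhantomGeometry}
#' @param w a \linkS4class{MotionWaveform}
#' @param times evaluation times [s]
#' @param nTheta,nZ surface resolution
#' @return numeric vector of volumes [mL]
#' @export
analyticVolumeSeries <- function(g, w, times, nTheta = 48, nZ = 32) {
  surf <- cavitySurface(g, nTheta, nZ)
  vapply(times, function(t) {
    nd <- surf$nodes + analyticDeformation(g, w, t, surf$nodes)
    surfaceVolume(nd, surf$triangles)
  }, 0)
}
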