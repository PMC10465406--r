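#' @import methods
#' @importFrom stats splinefun lm coef fft rnorm sd median quantile approx
#' @importFrom utils head tail write.csv read.csv
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Programmed cyclic compression waveform
#'
#' Describes the periodic long-axis compression applied to the dynamic
#' phantom: \eqn{c(t) = C_d \sin^2(\pi t / T_{prog})}. The programmed period
#' (the waveform driving the actuator) and the realized period measured from
#' the imaging data are kept separately, since the two were observed to
#' differ (0.8 s programmed vs 0.76 s realized).
#'
#' @slot Cd peak compression amplitude [mm]
#' @slot Tprog programmed period of the drive waveform [s]
#' @slot Tmeas realized (measured) cycle period [s]
#' @slot phaseOffset temporal offset added to \code{t} [s]
#' @export
setClass("MotionWaveform",
  representation(Cd = "numeric", Tprog = "numeric", Tmeas = "numeric",
                 phaseOffset = "numeric"),
  prototype(Cd = 10, Tprog = 0.8, Tmeas = 0.76, phaseOffset = 0))

setValidity("MotionWaveform", function(object) {
  msg <- character()
  if (length(object@Cd) != 1 || !is.finite(object@Cd) || object@Cd < 0)
    msg <- c(msg, "Cd must be a single non-negative number [mm]")
  if (length(object@Tprog) != 1 || !is.finite(object@Tprog) || object@Tprog <= 0)
    msg <- c(msg, "Tprog must be a single positive period [s]")
  if (length(object@Tmeas) != 1 || !is.finite(object@Tmeas) || object@Tmeas <= 0)
    msg <- c(msg, "Tmeas must be a single positive period [s]")
  if (length(msg)) msg else TRUE
})

#' Construct a compression waveform
#'
#' @param Cd peak compression [mm] (default 10 mm)
#' @param Tprog programmed period [s] (default 0.8 s)
#' @param Tmeas measured cycle period [s] (default 0.76 s)
#' @param phaseOffset phase offset [s]
#' @return a \linkS4class{MotionWaveform}
#' @examples
#' w <- motionWaveform()
#' compressionWaveform(0.4, w)   # peak compression, 10 mm
#' @export
motionWaveform <- function(Cd = 10, Tprog = 0.8, Tmeas = 0.76, phaseOffset = 0) {
  new("MotionWaveform", Cd = Cd, Tprog = Tprog, Tmeas = Tmeas,
      phaseOffset = phaseOffset)
}

#' @export
setMethod("show", "MotionWaveform", function(object) {
  cat(sprintf("MotionWaveform: c(t) = %.3g mm * sin^2(pi t / %.3g s)\n",
              object@Cd, object@Tprog))
  cat(sprintf("  realized period Tmeas = %.3g s, phase offset %.3g s\n",
              object@Tmeas, object@phaseOffset))
})

#' Parametric phantom geometry
#'
#' A ventricle-like cavity: an axis-aligned truncated ellipsoid (long axis =
#' z, base plane at z = 0, apex pointing towards +z) with two cylindrical
#' tubes (inlet and outlet) attached above the base plane (z < 0). The base
#' plane and the tube walls are flagged non-moving; the compression acts
#' along the long axis only, ramping smoothly from zero at the base to the
#' full amplitude at the apex.
#'
#' In 2D mode (\code{dim = 2}) the same parameters describe the long-axis
#' cross-section in the (x, z) plane; y is the out-of-plane direction.
#'
#' @slot dim 2 or 3
#' @slot Rx,Ry cavity semi-axes at the equator [mm] (Ry ignored in 2D)
#' @slot Rz cavity semi-axis along the long axis [mm]
#' @slot zc offset of the ellipsoid centre below the base plane [mm];
#'   the cavity is the part of the ellipsoid with z >= 0 and the apex sits
#'   at z = zc + Rz
#' @slot tubeD tube (inlet/outlet) diameter [mm]
#' @slot tubeL tube length [mm]
#' @slot tubeX signed x offsets of the inlet and outlet tube axes [mm]
#' @slot wall wall thickness for image rendering [mm]
#' @slot rampStart z below which no motion occurs [mm]
#' @export
setClass("PhantomGeometry",
  representation(dim = "integer", Rx = "numeric", Ry = "numeric",
                 Rz = "numeric", zc = "numeric", tubeD = "numeric",
                 tubeL = "numeric", tubeX = "numeric", wall = "numeric",
                 rampStart = "numeric"))

setValidity("PhantomGeometry", function(object) {
  msg <- character()
  if (!(object@dim %in% c(2L, 3L))) msg <- c(msg, "dim must be 2 or 3")
  for (s in c("Rx", "Ry", "Rz", "tubeD", "tubeL", "wall"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (length(object@tubeX) != 2) msg <- c(msg, "tubeX must give two tube offsets")
  if (object@zc < 0 || object@zc >= object@Rz)
    msg <- c(msg, "zc must lie in [0, Rz)")
  rb <- object@Rx * sqrt(1 - (object@zc / object@Rz)^2)
  if (any(abs(object@tubeX) + object@tubeD / 2 > rb))
    msg <- c(msg, "tubes must attach inside the base cross-section")
  if (object@rampStart < 0) msg <- c(msg, "rampStart must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom geometry
#'
#' Defaults give a cavity of roughly 100 mL (3D) with apex 55 mm from the
#' base and 8 mm tubes, a desk-scale stand-in for a right-ventricle lumen.
#'
#' @param dim 2 for the long-axis cross-section, 3 for the full cavity
#' @param Rx,Ry,Rz ellipsoid semi-axes [mm]
#' @param zc centre offset below the base plane [mm]
#' @param tubeD tube diameter [mm]
#' @param tubeL tube length [mm]
#' @param tubeX x offsets of the two tube axes [mm]
#' @param wall rendered wall thickness [mm]
#' @param rampStart z where the axial motion ramp begins [mm]
#' @return a \linkS4class{PhantomGeometry}
#' @export
phantomGeometry <- function(dim = 3, Rx = 25, Ry = 25, Rz = 60, zc = 5,
                            tubeD = 8, tubeL = 15, tubeX = c(-12, 12),
                            wall = 4, rampStart = 5) {
  new("PhantomGeometry", dim = as.integer(dim), Rx = Rx, Ry = Ry, Rz = Rz,
      zc = zc, tubeD = tubeD, tubeL = tubeL, tubeX = tubeX, wall = wall,
      rampStart = rampStart)
}

#' @export
setMethod("show", "PhantomGeometry", function(object) {
  cat(sprintf("PhantomGeometry (%dD): ellipsoid %g x %g x %g mm, apex at z = %g mm\n",
              object@dim, object@Rx, object@Ry, object@Rz, apexPoint(object)[object@dim]))
  cat(sprintf("  tubes: D = %g mm, L = %g mm at x = %g, %g mm; wall %g mm\n",
              object@tubeD, object@tubeL, object@tubeX[1], object@tubeX[2],
              object@wall))
})

#' A single image volume (or 2D slice) of the phantom sequence
#'
#' @slot data intensity array (2D or 3D), HU-like arbitrary units
#' @slot spacing voxel spacing per axis [mm]
#' @slot origin world coordinate of the centre of voxel (1,1[,1]) [mm]
#' @slot phase 0-based phase index within the cycle
#' @slot time time stamp [s]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 phase = "integer", time = "numeric"))

setValidity("ImageVolume", function(object) {
  nd <- length(dim(object@data))
  msg <- character()
  if (!(nd %in% c(2L, 3L))) msg <- c(msg, "data must be a 2D or 3D array")
  if (length(object@spacing) != nd || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be strictly positive, one entry per axis")
  if (length(object@origin) != nd) msg <- c(msg, "origin length must match dim")
  if (length(msg)) msg else TRUE
})

#' @export
imageVolume <- function(data, spacing, origin = rep(0, length(dim(data))),
                        phase = 0L, time = 0) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), phase = as.integer(phase), time = time)
}

#' @export
setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("ImageVolume: %s voxels, spacing %s mm, phase %d, t = %.4g s\n",
              paste(dim(object@data), collapse = "x"),
              paste(signif(object@spacing, 3), collapse = "x"),
              object@phase, object@time))
})

#' A cyclic sequence of image volumes on a shared grid
#'
#' @slot volumes list of \linkS4class{ImageVolume} sharing grid and spacing
#' @slot period cycle period [s]
#' @export
setClass("ImageSequence",
  representation(volumes = "list", period = "numeric"))

setValidity("ImageSequence", function(object) {
  msg <- character()
  if (length(object@volumes) < 2) msg <- c(msg, "need at least 2 phases")
  if (!all(vapply(object@volumes, is, TRUE, "ImageVolume")))
    msg <- c(msg, "volumes must all be ImageVolume")
  if (length(object@volumes) >= 2) {
    d1 <- dim(object@volumes[[1]]@data); s1 <- object@volumes[[1]]@spacing
    o1 <- object@volumes[[1]]@origin
    same <- vapply(object@volumes, function(v)
      identical(dim(v@data), d1) && isTRUE(all.equal(v@spacing, s1)) &&
        isTRUE(all.equal(v@origin, o1)), TRUE)
    if (!all(same)) msg <- c(msg, "all volumes must share grid, spacing and origin")
  }
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ImageSequence", function(object) {
  cat(sprintf("ImageSequence: %d phases, grid %s, period %.4g s\n",
              length(object@volumes),
              paste(dim(object@volumes[[1]]@data), collapse = "x"),
              object@period))
})

#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))
#' @export
setMethod("nPhases", "ImageSequence", function(x) length(x@volumes))
#' @export
setGeneric("getVolume", function(x, i) standardGeneric("getVolume"))
#' @export
setMethod("getVolume", "ImageSequence", function(x, i) x@volumes[[i]])

#' Cyclic voxel-wise displacement field
#'
#' Displacement (in mm, world units) from the reference phase to each time
#' instance, stored per instance as an array with a trailing component axis.
#' Cyclicity: the first and last instances are identically zero and the
#' instance count is \code{n_phases + 1}.
#'
#' @slot d list of arrays, each of dim c(grid dims, ndim) [mm]
#' @slot times instance time stamps [s], strictly increasing, t[1] = 0
#' @slot spacing,origin grid metadata shared with the image sequence
#' @export
setClass("DisplacementField",
  representation(d = "list", times = "numeric", spacing = "numeric",
                 origin = "numeric"))

setValidity("DisplacementField", function(object) {
  msg <- character()
  n <- length(object@d)
  if (n < 1) msg <- c(msg, "need at least one instance")
  if (length(object@times) != n) msg <- c(msg, "times length must match instances")
  if (n > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "time stamps must be strictly increasing")
  if (!all(vapply(object@d, function(a) all(is.finite(a)), TRUE)))
    msg <- c(msg, "displacement values must be finite")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "DisplacementField", function(object) {
  dd <- dim(object@d[[1]])
  cat(sprintf("DisplacementField: %d instances on a %s grid (%d components)\n",
              length(object@d), paste(head(dd, -1), collapse = "x"), tail(dd, 1)))
  mx <- max(vapply(object@d, function(a) max(abs(a)), 0))
  cat(sprintf("  t in [%.4g, %.4g] s, max |d| = %.4g mm\n",
              object@times[1], tail(object@times, 1), mx))
})

#' Simplex mesh with tagged boundary
#'
#' @slot nodes n x d node coordinates [mm]
#' @slot elements m x (d+1) 1-based simplex connectivity
#' @slot boundary b x d boundary facet connectivity (edges in 2D)
#' @slot boundaryTag character tag per boundary facet: inlet/outlet/wall/base
#' @export
setClass("SimplexMesh",
  representation(nodes = "matrix", elements = "matrix", boundary = "matrix",
                 boundaryTag = "character"))

setValidity("SimplexMesh", function(object) {
  d <- ncol(object@nodes)
  msg <- character()
  if (ncol(object@elements) != d + 1)
    msg <- c(msg, "elements must be simplices with d+1 vertices")
  if (nrow(object@boundary) != length(object@boundaryTag))
    msg <- c(msg, "one tag per boundary facet required")
  if (max(object@elements) > nrow(object@nodes))
    msg <- c(msg, "element connectivity out of range")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "SimplexMesh", function(object) {
  cat(sprintf("SimplexMesh: %d nodes, %d elements (%dD), %d boundary facets\n",
              nrow(object@nodes), nrow(object@elements), ncol(object@nodes),
              nrow(object@boundary)))
  print(table(object@boundaryTag))
})

#' Moving mesh: node trajectories at fixed time steps
#'
#' Element connectivity is constant over time; trajectories store node
#' positions at \code{times[k]}; cyclic closure means first and last stored
#' positions coincide. Temporal interpolation between steps uses a periodic
#' cubic spline, so the mesh velocity is continuous across the cycle seam.
#'
#' @slot mesh the reference \linkS4class{SimplexMesh}
#' @slot trajectories array nsteps x nnodes x d of positions [mm]
#' @slot times stored step times [s], t[1] = 0, t[end] = T
#' @slot step fixed step size [s]
#' @export
setClass("MovingMesh",
  representation(mesh = "SimplexMesh", trajectories = "array",
                 times = "numeric", step = "numeric"))

setValidity("MovingMesh", function(object) {
  msg <- character()
  dt <- dim(object@trajectories)
  if (length(dt) != 3) msg <- c(msg, "trajectories must be steps x nodes x dim")
  else {
    if (dt[2] != nrow(object@mesh@nodes)) msg <- c(msg, "node count mismatch")
    if (dt[1] != length(object@times)) msg <- c(msg, "step count mismatch")
    gap <- max(abs(object@trajectories[1, , ] - object@trajectories[dt[1], , ]))
    if (gap > 1e-9) msg <- c(msg, sprintf("cyclic closure violated (gap %.3g mm)", gap))
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "MovingMesh", function(object) {
  cat(sprintf("MovingMesh: %d nodes over %d steps (step %.4g s, T = %.4g s)\n",
              nrow(object@mesh@nodes), length(object@times), object@step,
              tail(object@times, 1)))
})

#' Inlet boundary waveform
#'
#' @slot times sample times over one cycle [s]
#' @slot Q volume flow [m^3/s]
#' @slot U plug mean velocity [m/s] (positive into the domain)
#' @slot D inlet diameter [mm]
#' @slot area inlet cross-section area [m^2]
#' @slot ratio off-axis chord correction ratio in (0, 1]
#' @slot offset additive velocity offset [m/s]
#' @export
setClass("InletWaveform",
  representation(times = "numeric", Q = "numeric", U = "numeric",
                 D = "numeric", area = "numeric", ratio = "numeric",
                 offset = "numeric"))

setValidity("InletWaveform", function(object) {
  msg <- character()
  if (length(object@Q) != length(object@times) ||
      length(object@U) != length(object@times))
    msg <- c(msg, "Q, U and times must have equal length")
  if (object@area <= 0) msg <- c(msg, "area must be positive")
  if (object@ratio <= 0 || object@ratio > 1)
    msg <- c(msg, "correction ratio must lie in (0, 1]")
  err <- max(abs(abs(object@U) * object@area - abs(object@Q)))
  if (err > 1e-9 * max(abs(object@Q), 1e-12))
    msg <- c(msg, "Q(t) must equal |U(t)| * area")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "InletWaveform", function(object) {
  cat(sprintf("InletWaveform: D = %g mm, peak Q = %.4g L/min, offset %.3g m/s\n",
              object@D, max(abs(object@Q)) * 60000, object@offset))
})

#' Time-resolved mixed finite-element flow solution on a moving mesh
#'
#' Velocity lives on P2 (vertex + edge-midpoint) nodes, pressure on P1
#' vertices. One row of \code{U}/\code{p} per stored solver step.
#'
#' @slot mmesh the \linkS4class{MovingMesh} the flow was solved on
#' @slot edges e x 2 vertex pairs defining the P2 midpoint nodes
#' @slot times solver step times [s] (global, over all cycles)
#' @slot cycle 1-based cycle index per step
#' @slot U array nsteps x nP2 x d velocity [m/s]
#' @slot p matrix nsteps x nVertices pressure [Pa]
#' @export
setClass("FlowField",
  representation(mmesh = "MovingMesh", edges = "matrix", times = "numeric",
                 cycle = "integer", U = "array", p = "matrix"))

setValidity("FlowField", function(object) {
  msg <- character()
  if (dim(object@U)[1] != length(object@times)) msg <- c(msg, "step count mismatch")
  if (length(object@cycle) != length(object@times))
    msg <- c(msg, "cycle index per step required")
  if (!all(is.finite(object@U)) || !all(is.finite(object@p)))
    msg <- c(msg, "flow solution must be finite")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: %d steps over %d cycle(s), %d velocity nodes, peak |U| = %.3g m/s\n",
              length(object@times), max(object@cycle), dim(object@U)[2],
              sqrt(max(rowSums(aperm(object@U, c(2, 1, 3))^2)))))
})

#' Planar velocity record on the common comparison grid
#'
#' Shared container for emulated vector-flow measurements and sliced CFD
#' fields: pixel grid (default 0.5 x 0.5 mm), sample period (default 0.01 s),
#' in-plane components u (x) and w (z), the out-of-plane component v stored
#' separately, and a geometry channel g (B-mode proxy or domain mask).
#'
#' @slot x,z pixel centre coordinates in the plane [mm]
#' @slot times sample times [s]
#' @slot u,w arrays nx x nz x nt of in-plane velocity [m/s]
#' @slot v out-of-plane component, same shape, or NULL
#' @slot g geometry channel nx x nz x nt (or nx x nz), >0 inside the domain
#' @slot planeId integer plane identifier
#' @slot pose list: origin [mm], inPlaneX, inPlaneZ, normal (unit vectors)
#' @export
setClass("PlanarRecord",
  representation(x = "numeric", z = "numeric", times = "numeric",
                 u = "array", w = "array", v = "arrayOrNULL", g = "array",
                 planeId = "integer", pose = "list"))

setValidity("PlanarRecord", function(object) {
  msg <- character()
  dimOK <- identical(dim(object@u), dim(object@w)) &&
    dim(object@u)[1] == length(object@x) && dim(object@u)[2] == length(object@z)
  if (!dimOK) msg <- c(msg, "u and w must be nx x nz x nt arrays")
  if (sum(object@g > 0) == 0) msg <- c(msg, "geometry mask must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PlanarRecord", function(object) {
  cat(sprintf("PlanarRecord: plane %d, %d x %d px, %d samples, dt = %.3g s\n",
              object@planeId, length(object@x), length(object@z),
              length(object@times),
              if (length(object@times) > 1) diff(object@times[1:2]) else NA))
})

#' Regression of CFD on measured bin velocities
#'
#' @slot r2 coefficient of determination
#' @slot slope,intercept fitted line (CFD on the vertical axis)
#' @slot residualSD standard deviation of residuals [m/s]
#' @slot n number of points used
#' @slot excluded ROI ids excluded before fitting
#' @export
setClass("RegressionResult",
  representation(r2 = "numeric", slope = "numeric", intercept = "numeric",
                 residualSD = "numeric", n = "integer", excluded = "integer"))

setValidity("RegressionResult", function(object) {
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12)
    "R^2 must lie in [0, 1]" else TRUE
})

#' @export
setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: R^2 = %.3f, slope = %.3f, intercept = %.4f m/s, SD = %.4f m/s (n = %d)\n",
              object@r2, object@slope, object@intercept, object@residualSD,
              object@n))
  if (length(object@excluded))
    cat("  excluded ROIs:", paste(object@excluded, collapse = ", "), "\n")
})
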