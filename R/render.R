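# Rendering of the synthetic phantom: 4D image sequences with CTA-like
# contrast, and emulated planar vector-flow records of a known flow.

#' Render the cyclic 4D image sequence of the moving phantom
#'
#' Rasterises the analytically deformed phantom onto a fixed voxel grid at
#' \code{nPhases} evenly spaced phases of the realized cycle (sample period
#' \code{Tmeas / nPhases}; 0.038 s at the default 20 phases / 0.76 s).
#' Intensities emulate contrast-enhanced CT: bright lumen, dimmer wall,
#' zero background, a Gaussian partial-volume blur, and optional additive
#' Gaussian noise. With \code{noiseSd = 0} the output is a deterministic
#' function of (geometry, waveform, grid).
#'
#' @param g a \linkS4class{PhantomGeometry} (2D or 3D)
#' @param w a \linkS4class{MotionWaveform}
#' @param nPhases number of phases per cycle (default 20)
#' @param spacing voxel spacing [mm]; default 0.6 x 0.6 x 0.5 (3D)
#' @param noiseSd additive Gaussian noise sd [intensity units]
#' @param seed RNG seed for the noise
#' @param intensities named vector: lumen, wall, background
#' @param blurSigma partial-volume blur sd [voxels]
#' @param margin grid margin beyond the phantom [mm]
#' @return an \linkS4class{ImageSequence}
#' @export
renderImageSequence <- function(g, w, nPhases = 20L,
                                spacing = if (g@dim == 3L) c(0.6, 0.6, 0.5)
                                          else c(0.6, 0.5),
                                noiseSd = 0, seed = 1L,
                                intensities = c(lumen = 300, wall = 80,
                                                background = 0),
                                blurSigma = 0.5, margin = 3) {
  stopifnot(is(g, "PhantomGeometry"), is(w, "MotionWaveform"))
  if (nPhases < 2) stop("nPhases must be at least 2")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  ext <- g@wall + margin
  za <- g@zc + g@Rz
  lim <- if (g@dim == 3L)
    list(c(-g@Rx - ext, g@Rx + ext), c(-g@Ry - ext, g@Ry + ext),
         c(-g@tubeL - margin, za + ext))
  else
    list(c(-g@Rx - ext, g@Rx + ext), c(-g@tubeL - margin, za + ext))
  axes <- lapply(seq_len(g@dim), function(k)
    seq(lim[[k]][1], lim[[k]][2], by = spacing[k]))
  dims <- vapply(axes, length, 1L)
  origin <- vapply(axes, `[`, 0, 1L)
  grid <- as.matrix(expand.grid(axes))
  tms <- (seq_len(nPhases) - 1L) * w@Tmeas / nPhases
  vols <- withSeed(seed, lapply(seq_len(nPhases), function(k) {
    cval <- realizedCompression(tms[k], w)
    ref <- grid
    # the axial map is 1D: invert once per unique grid z and broadcast
    zq <- invertAxialMap(g, cval, axes[[g@dim]])
    ref[, g@dim] <- zq[match(grid[, g@dim], axes[[g@dim]])]
    img <- rep(intensities[["background"]], nrow(grid))
    inWall <- lumenIndicator(g, ref, grow = g@wall)
    img[inWall] <- intensities[["wall"]]
    img[lumenIndicator(g, ref)] <- intensities[["lumen"]]
    dim(img) <- dims
    if (blurSigma > 0) img <- gaussianSmooth(img, blurSigma)
    if (noiseSd > 0) img <- img + array(rnorm(length(img), sd = noiseSd), dims)
    imageVolume(img, spacing, origin, phase = k - 1L, time = tms[k])
  }))
  new("ImageSequence", volumes = vols, period = w@Tmeas)
}

#' Ground-truth displacement field of the rendered sequence
#'
#' Samples the analytic deformation on the image grid at each phase time,
#' then appends the cyclic zero instance at t = T, yielding the
#' \code{nPhases + 1} instance layout that registration produces.
#'
#' @param g,w geometry and waveform used for rendering
#' @param seq_ the rendered \linkS4class{ImageSequence} (provides the grid)
#' @return a \linkS4class{DisplacementField}
#' @export
groundTruthField <- function(g, w, seq_) {
  v1 <- getVolume(seq_, 1L)
  dims <- dim(v1@data)
  axes <- lapply(seq_along(dims), function(k)
    v1@origin[k] + (seq_len(dims[k]) - 1L) * v1@spacing[k])
  grid <- as.matrix(expand.grid(axes))
  tms <- vapply(seq_@volumes, function(v) v@time, 0)
  mk <- function(t) {
    d <- analyticDeformation(g, w, t, grid)
    array(d, c(dims, g@dim))
  }
  flds <- lapply(tms, mk)
  flds[[length(flds) + 1L]] <- array(0, c(dims, g@dim))
  new("DisplacementField", d = flds, times = c(tms, seq_@period),
      spacing = v1@spacing, origin = v1@origin)
}

#' Default parallel measurement-plane poses
#'
#' Eight parallel long-axis planes with 5 mm inter-plane spacing, centred on
#' the phantom axis; in-plane axes are world x and z, the out-of-plane
#' normal is world y.
#'
#' @param g a 3D \linkS4class{PhantomGeometry}
#' @param n number of planes
#' @param planeSpacing inter-plane distance [mm]
#' @return list of pose lists (origin, inPlaneX, inPlaneZ, normal, xlim, zlim)
#' @export
vfiPlanePoses <- function(g, n = 8L, planeSpacing = 5) {
  offs <- (seq_len(n) - (n + 1) / 2) * planeSpacing
  za <- g@zc + g@Rz
  lapply(seq_len(n), function(i)
    list(origin = c(0, offs[i], 0), inPlaneX = c(1, 0, 0),
         inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0),
         xlim = c(-g@Rx, g@Rx), zlim = c(-g@tubeL, za), id = i))
}

#' Emulate planar 2D vector-flow records of a known 3D flow
#'
#' Samples a ground-truth velocity field on parallel planes at pixel
#' resolution and discards the out-of-plane component from the measured
#' channels, emulating 2D vector flow imaging. Gaussian noise is added
#' independently to each in-plane velocity sample. The true out-of-plane
#' component is retained in the \code{v} slot for reference only.
#'
#' @param truthFlow function(pts, t) -> n x 3 velocities [m/s] at world
#'   points pts (n x 3 [mm])
#' @param planes list of plane poses (see \code{\link{vfiPlanePoses}})
#' @param pixel pixel size [mm] (default 0.5)
#' @param dt temporal sample period [s] (default 0.01)
#' @param duration record duration [s]
#' @param noiseSd velocity noise sd [m/s]
#' @param seed RNG seed
#' @param geometry optional function(pts, t) -> numeric geometry channel
#'   (domain indicator or B-mode proxy); default: all inside
#' @return list of \linkS4class{PlanarRecord} (NULL, with a warning, for
#'   planes that never intersect the domain)
#' @export
renderVfiPlanes <- function(truthFlow, planes, pixel = 0.5, dt = 0.01,
                            duration = 0.76, noiseSd = 0, seed = 1L,
                            geometry = NULL) {
  if (pixel <= 0) stop("pixel size must be positive")
  tms <- seq(0, duration - dt / 2, by = dt)
  withSeed(seed, lapply(planes, function(pl) {
    xs <- seq(pl$xlim[1], pl$xlim[2], by = pixel)
    zs <- seq(pl$zlim[1], pl$zlim[2], by = pixel)
    pts <- matrix(pl$origin, length(xs) * length(zs), 3, byrow = TRUE) +
      outer(as.vector(outer(xs, rep(1, length(zs)))), pl$inPlaneX) +
      outer(as.vector(outer(rep(1, length(xs)), zs)), pl$inPlaneZ)
    nx <- length(xs); nz <- length(zs); nt <- length(tms)
    u <- w_ <- v <- array(0, c(nx, nz, nt))
    gch <- array(1, c(nx, nz, nt))
    for (k in seq_len(nt)) {
      V <- truthFlow(pts, tms[k])
      u[, , k] <- V %*% pl$inPlaneX
      w_[, , k] <- V %*% pl$inPlaneZ
      v[, , k] <- V %*% pl$normal
      if (!is.null(geometry)) gch[, , k] <- geometry(pts, tms[k])
    }
    if (all(gch <= 0)) {
      warning(sprintf("plane %d lies outside the domain; empty record",
                      pl$id))
      return(NULL)
    }
    if (noiseSd > 0) {
      u <- u + array(rnorm(length(u), sd = noiseSd), dim(u))
      w_ <- w_ + array(rnorm(length(w_), sd = noiseSd), dim(w_))
    }
    new("PlanarRecord", x = xs, z = zs, times = tms, u = u, w = w_, v = v,
        g = gch, planeId = as.integer(pl$id), pose = pl)
  }))
}
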