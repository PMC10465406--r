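# CFD-vs-measurement comparison protocol: phase alignment by the geometry
# channel, rigid landmark co-registration, slicing the flow solution onto
# the common planar grid, in-plane magnitudes, ROI time binning, linear
# regression with outlier exclusion, and out-of-plane component statistics.

#' In-plane velocity magnitude
#'
#' The quantitative comparison metric: |U| = sqrt(u^2 + w^2) from the two
#' in-plane components.
#'
#' @param u,w in-plane velocity components [m/s]
#' @return magnitudes [m/s]
#' @examples
#' inplaneMagnitude(0.3, 0.4)   # 0.5
#' @export
inplaneMagnitude <- function(u, w) sqrt(u^2 + w^2)

# Frame-wise displacement metric of a geometry-channel stack: mean absolute
# difference of each frame from the temporal mean frame. The reference frame
# is circular-shift invariant, so the metric of a phase-shifted cyclic
# sequence is exactly the shifted metric.
frameMetric <- function(g) {
  nt <- dim(g)[3]
  ref <- apply(g, c(1, 2), mean)
  vapply(seq_len(nt), function(k) mean(abs(g[, , k] - ref)), 0)
}

#' Phase alignment of two cyclic records by their geometry channels
#'
#' Reduces each geometry-channel stack to a frame-wise displacement metric
#' (mean absolute difference from the temporal mean frame) and finds the
#' circular
#' lag maximising the normalised cross-correlation. The delay is reported
#' modulo the record period; if the correlation peak is below
#' \code{threshold} a warning is given and zero delay returned.
#'
#' @param reference,target \linkS4class{PlanarRecord}s (or plain
#'   nx x nz x nt arrays) with equal sample periods
#' @param dt sample period [s] (taken from the records when available)
#' @param threshold minimum acceptable correlation peak
#' @return time delay [s] to add to the target's time stamps
#' @export
alignPhase <- function(reference, target, dt = NULL, threshold = 0.2) {
  gR <- if (is(reference, "PlanarRecord")) reference@g else reference
  gT <- if (is(target, "PlanarRecord")) target@g else target
  if (is.null(dt))
    dt <- if (is(reference, "PlanarRecord")) diff(reference@times[1:2])
          else stop("dt required for plain arrays")
  mR <- frameMetric(gR)
  mT <- frameMetric(gT)
  n <- min(length(mR), length(mT))
  mR <- mR[seq_len(n)] - mean(mR[seq_len(n)])
  mT <- mT[seq_len(n)] - mean(mT[seq_len(n)])
  denom <- sqrt(sum(mR^2) * sum(mT^2))
  if (denom == 0) {
    warning("flat geometry metric; returning zero delay")
    return(0)
  }
  cc <- vapply(seq_len(n) - 1L, function(lag) {
    idx <- ((seq_len(n) - 1L + lag) %% n) + 1L
    sum(mR * mT[idx]) / denom
  }, 0)
  if (max(cc) < threshold) {
    warning(sprintf("correlation peak %.2f below threshold; returning zero delay",
                    max(cc)))
    return(0)
  }
  (which.max(cc) - 1L) * dt
}

#' Rigid landmark co-registration (Kabsch)
#'
#' Least-squares rigid transform (rotation + translation, no scaling)
#' mapping landmark set A onto landmark set B.
#'
#' @param A,B n x d matrices of paired landmarks [mm]
#' @return list: \code{R} (d x d rotation), \code{t} (translation),
#'   \code{rmsd} residual [mm]
#' @export
rigidAlign <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(rep(1, ncol(A) - 1), d))
  R <- sv$v %*% D %*% t(sv$u)
  tv <- cb - as.vector(R %*% ca)
  rmsd <- sqrt(mean(rowSums((applyRigid(A, R, tv) - B)^2)))
  list(R = R, t = tv, rmsd = rmsd)
}

#' Apply a rigid transform to points
#' @param pts n x d points
#' @param R rotation matrix
#' @param t translation vector
#' @return transformed points
#' @export
applyRigid <- function(pts, R, t) {
  sweep(as.matrix(pts) %*% t(R), 2, t, "+")
}

#' Slice a flow solution onto the common planar grid
#'
#' Interpolates the last cycle of a 2D flow solution onto the comparison
#' grid (default 0.5 x 0.5 mm pixels, 0.01 s sample period). Velocities are
#' evaluated on the deformed mesh at each stored solver step and resampled
#' in time with a periodic spline. The geometry channel is the domain
#' membership of each pixel (1 inside, 0 outside); pixels outside the
#' domain at a given step carry zero velocity and mask 0.
#'
#' For analytic 3D fields use \code{\link{renderVfiPlanes}} with
#' \code{noiseSd = 0}, which implements the same projection.
#'
#' @param ff a \linkS4class{FlowField} (2D solver field)
#' @param pixel pixel size [mm]
#' @param dtOut output sample period [s]
#' @param planeId plane identifier stored in the record
#' @return a \linkS4class{PlanarRecord} (v slot zero: the 2D mode has no
#'   out-of-plane component)
#' @export
sliceFlow <- function(ff, pixel = 0.5, dtOut = 0.01, planeId = 1L) {
  mesh <- ff@mmesh@mesh
  fem <- p2Structure(mesh)
  period <- tail(ff@mmesh@times, 1)
  lastCycle <- which(ff@cycle == max(ff@cycle))
  bb <- apply(mesh@nodes, 2, range)
  xs <- seq(bb[1, 1], bb[2, 1], by = pixel)
  zs <- seq(bb[1, 2], bb[2, 2], by = pixel)
  pts <- as.matrix(expand.grid(xs, zs))
  nx <- length(xs); nz <- length(zs)
  nSteps <- length(lastCycle)
  uS <- wS <- gS <- array(0, c(nx, nz, nSteps))
  tS <- numeric(nSteps)
  for (j in seq_len(nSteps)) {
    k <- lastCycle[j]
    gs <- flowStepGeometry(ff, k)
    loc <- locatePoints(mesh, gs$X * 1e3, pts)
    V <- evalP2(fem, ff@U[k, , ], loc)
    inside <- !is.na(loc$element)
    V[is.na(V)] <- 0
    uS[, , j] <- matrix(V[, 1], nx)
    wS[, , j] <- matrix(V[, 2], nx)
    gS[, , j] <- matrix(as.numeric(inside), nx)
    tS[j] <- gs$tCyc
  }
  if (nrow(as.matrix(pts)) == 0 || all(gS == 0))
    stop("plane does not intersect the domain")
  # periodic temporal resampling (cycle phase 0 == phase T)
  tKnots <- c(0, tS)                       # tS runs dt..T; prepend phase 0
  tOut <- seq(0, period - dtOut / 2, by = dtOut)
  resample <- function(arr) {
    Ymat <- t(matrix(arr, nx * nz, nSteps))          # steps x pixels
    Y <- rbind(Ymat[nSteps, , drop = FALSE], Ymat)   # phase 0 = phase T
    ps <- periodicSpline(tKnots, Y)
    array(t(evalPeriodicSpline(ps, tOut)), c(nx, nz, length(tOut)))
  }
  uO <- resample(uS)
  wO <- resample(wS)
  dtStep <- tS[2] - tS[1]
  jNear <- round(tOut / dtStep)
  jNear[jNear == 0L] <- nSteps                       # phase 0 geometry = T
  jNear <- pmin(jNear, nSteps)
  gO <- gS[, , jNear, drop = FALSE]
  new("PlanarRecord", x = xs, z = zs, times = tOut, u = uO, w = wO,
      v = array(0, dim(uO)), g = gO, planeId = as.integer(planeId),
      pose = list(origin = c(0, 0, 0), inPlaneX = c(1, 0, 0),
                  inPlaneZ = c(0, 0, 1), normal = c(0, 1, 0)))
}

#' Default stationary circular ROIs over a planar record
#'
#' Picks \code{n} well-spread pixel centres inside the geometry mask (on a
#' coarse grid over the mask's bounding box) as ROI centres.
#'
#' @param record a \linkS4class{PlanarRecord}
#' @param n number of ROIs
#' @param radius ROI radius [mm]
#' @return data.frame: id, x, z, radius
#' @export
defaultRois <- function(record, n = 16L, radius = 2.5) {
  mask <- apply(record@g > 0, c(1, 2), all)
  idx <- which(mask, arr.ind = TRUE)
  px <- cbind(record@x[idx[, 1]], record@z[idx[, 2]])
  # greedy farthest-point sampling for even spread, deterministic start
  ctr <- colMeans(px)
  sel <- integer(n)
  sel[1] <- which.min(rowSums(sweep(px, 2, ctr)^2))
  dmin <- rowSums(sweep(px, 2, px[sel[1], ])^2)
  for (i in seq_len(n - 1L)) {
    sel[i + 1L] <- which.max(dmin)
    dmin <- pmin(dmin, rowSums(sweep(px, 2, px[sel[i + 1L], ])^2))
  }
  data.frame(id = seq_len(n), x = px[sel, 1], z = px[sel, 2],
             radius = radius)
}

#' ROI time series and time-bin means
#'
#' For each stationary circular ROI: the spatial mean of the in-plane
#' velocity magnitude per sample (over mask pixels inside the ROI), an
#' optional average over full cycles, and the temporal mean within each of
#' \code{nBins} equal-width, left-closed/right-open bins partitioning the
#' cycle. ROIs that never contain a mask pixel are excluded and reported.
#'
#' @param record a \linkS4class{PlanarRecord}
#' @param rois data.frame from \code{\link{defaultRois}}
#' @param nBins number of non-overlapping time bins (default 11)
#' @param nAvgCycles cycles to average (default 1; use 5 for
#'   measurement-side records spanning several cycles)
#' @param period cycle period [s] (default: record duration / nAvgCycles)
#' @return list: \code{series} (nROI x nSamples), \code{bins}
#'   (nROI x nBins), \code{binEdges}, \code{excluded} ROI ids,
#'   \code{rois}
#' @export
roiBins <- function(record, rois, nBins = 11L, nAvgCycles = 1L,
                    period = NULL) {
  nt <- length(record@times)
  dt <- diff(record@times[1:2])
  if (is.null(period)) period <- nt * dt / nAvgCycles
  perCycle <- round(period / dt)
  mag <- inplaneMagnitude(record@u, record@w)
  nR <- nrow(rois)
  series <- matrix(NA_real_, nR, nt)
  for (r in seq_len(nR)) {
    dx <- outer(record@x - rois$x[r], rep(1, length(record@z)))
    dz <- outer(rep(1, length(record@x)), record@z - rois$z[r])
    inR <- dx^2 + dz^2 <= rois$radius[r]^2
    if (!any(inR)) next
    for (k in seq_len(nt)) {
      sel <- inR & record@g[, , min(k, dim(record@g)[3])] > 0
      if (any(sel)) series[r, k] <- mean(mag[, , k][sel])
    }
  }
  excluded <- rois$id[rowSums(!is.na(series)) == 0]
  # cycle averaging
  nCycAvail <- nt %/% perCycle
  nAvg <- min(nAvgCycles, max(1L, nCycAvail))
  cyc <- matrix(NA_real_, nR, perCycle)
  for (c_ in seq_len(nAvg)) {
    idx <- (c_ - 1L) * perCycle + seq_len(perCycle)
    idx <- idx[idx <= nt]
    block <- series[, idx, drop = FALSE]
    if (c_ == 1L) cyc[, seq_along(idx)] <- block
    else cyc[, seq_along(idx)] <- cyc[, seq_along(idx), drop = FALSE] + block
  }
  cyc <- cyc / nAvg
  tCyc <- (seq_len(perCycle) - 1L) * dt
  edges <- seq(0, period, length.out = nBins + 1L)
  binIdx <- findInterval(tCyc, edges, rightmost.closed = FALSE,
                         left.open = FALSE)
  binIdx[binIdx > nBins] <- nBins
  bins <- t(vapply(seq_len(nR), function(r)
    vapply(seq_len(nBins), function(b) {
      v <- cyc[r, binIdx == b]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0), numeric(nBins)))
  list(series = series, cycleMean = cyc, bins = bins, binEdges = edges,
       excluded = excluded, rois = rois)
}

#' Linear regression of CFD bin velocities on measured bin velocities
#'
#' Ordinary least squares with the CFD values on the vertical axis (so a
#' systematic CFD underestimation appears as a negative intercept).
#' Optionally excludes whole ROIs before fitting.
#'
#' @param cfdBins,vfiBins nROI x nBins matrices from \code{\link{roiBins}}
#' @param exclude integer ROI ids to exclude
#' @return a \linkS4class{RegressionResult}
#' @export
regressBins <- function(cfdBins, vfiBins, exclude = integer(0)) {
  stopifnot(all(dim(cfdBins) == dim(vfiBins)))
  keep <- setdiff(seq_len(nrow(cfdBins)), exclude)
  y <- as.vector(cfdBins[keep, , drop = FALSE])
  x <- as.vector(vfiBins[keep, , drop = FALSE])
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("regression needs at least 3 paired bin values")
  fit <- lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  # self-comparisons fit exactly; the perfect-fit note is expected there
  ss <- suppressWarnings(summary(fit))
  new("RegressionResult",
      r2 = ss$r.squared,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      residualSD = ss$sigma,
      n = as.integer(sum(ok)),
      excluded = as.integer(exclude))
}

#' Cycle-averaged velocity components and out-of-plane share within an ROI
#'
#' Averages each velocity component over one cycle and the ROI area, and
#' reports the out-of-plane share as 100 |<v>| / max(|<u>|, |<w>|).
#'
#' @param record a \linkS4class{PlanarRecord} with the \code{v} slot set
#' @param roi list or one-row data.frame with x, z, radius [mm]
#' @return list: u, v, w cycle means [m/s] and \code{outOfPlanePct}
#' @export
componentStats <- function(record, roi) {
  dx <- outer(record@x - roi$x, rep(1, length(record@z)))
  dz <- outer(rep(1, length(record@x)), record@z - roi$z)
  inR <- dx^2 + dz^2 <= roi$radius^2
  if (!any(inR)) stop("ROI contains no pixels")
  avg <- function(a) {
    v <- vapply(seq_len(dim(a)[3]), function(k) {
      sel <- inR & record@g[, , min(k, dim(record@g)[3])] > 0
      if (any(sel)) mean(a[, , k][sel]) else NA_real_
    }, 0)
    mean(v, na.rm = TRUE)
  }
  um <- avg(record@u)
  wm <- avg(record@w)
  vm <- if (!is.null(record@v)) avg(record@v) else 0
  list(u = um, v = vm, w = wm,
       outOfPlanePct = 100 * abs(vm) / max(abs(um), abs(wm)))
}

#' Out-of-plane percentage from cycle-averaged components
#'
#' @param u,v,w cycle-averaged components [m/s]; v is out-of-plane
#' @return percentage 100 |v| / max(|u|, |w|)
#' @examples
#' outOfPlanePct(-0.327, 0.026, 0.019)   # 7.95 %
#' @export
outOfPlanePct <- function(u, v, w) 100 * abs(v) / max(abs(u), abs(w))
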