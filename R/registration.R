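# Intensity-based recovery of the cyclic wall motion: pairwise diffeomorphic
# demons registration against the reference phase, assembly of the cyclic
# 21-instance displacement field, and penalised periodic temporal smoothing.

# -- internal demons machinery (index/voxel units throughout) ---------------

# Block-average downsampling by 2 along every axis (odd sizes keep the tail).
downsample2 <- function(arr) {
  dims <- dim(arr)
  out <- arr
  for (k in seq_along(dims)) {
    n <- dim(out)[k]
    if (n < 2L) next
    idx1 <- seq(1L, n, by = 2L)
    idx2 <- pmin(idx1 + 1L, n)
    perm <- c(k, seq_along(dims)[-k])
    a <- aperm(out, perm)
    da <- dim(a)
    m <- matrix(a, da[1])
    m <- (m[idx1, , drop = FALSE] + m[idx2, , drop = FALSE]) / 2
    dim(m) <- c(length(idx1), da[-1])
    out <- aperm(m, order(perm))
  }
  out
}

# Central-difference gradient in voxel units; list of arrays per axis.
voxelGradient <- function(arr) {
  dims <- dim(arr)
  lapply(seq_along(dims), function(k) {
    n <- dims[k]
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    sc <- (ip - im)
    perm <- c(k, seq_along(dims)[-k])
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, da[1])
    gm <- (m[ip, , drop = FALSE] - m[im, , drop = FALSE]) / sc
    dim(gm) <- da
    aperm(gm, order(perm))
  })
}

# Evaluate array at (identity + disp) in index space; disp = list per axis.
warpByField <- function(arr, disp) {
  dims <- dim(arr)
  nd <- length(dims)
  axes <- lapply(dims, seq_len)
  base <- as.matrix(expand.grid(axes))
  pts <- base
  for (k in seq_len(nd)) pts[, k] <- pts[, k] + as.vector(disp[[k]])
  out <- interpLinear(arr, pts, spacing = rep(1, nd), origin = rep(1, nd))
  dim(out) <- dims
  out
}

# Compose displacement fields: (a after b)(x) = b(x) + a(x + b(x)).
composeFields <- function(a, b) {
  lapply(seq_along(a), function(k) b[[k]] + warpByField(a[[k]], b))
}

# Exponential map of a velocity field by scaling and squaring.
expField <- function(v) {
  mx <- max(vapply(v, function(a) max(abs(a)), 0))
  nsq <- max(0L, ceiling(log2(max(mx, 1e-12) / 0.5)))
  e <- lapply(v, function(a) a / 2^nsq)
  for (i in seq_len(nsq)) e <- composeFields(e, e)
  e
}

demonsLevel <- function(Fimg, Mimg, phi, iters, sigmaFluid, sigmaDiff,
                        sigmaX = 1) {
  dims <- dim(Fimg)
  nd <- length(dims)
  if (is.null(phi)) phi <- lapply(seq_len(nd), function(k) array(0, dims))
  gF <- voxelGradient(Fimg)
  mse <- function(p) mean((Fimg - warpByField(Mimg, p))^2)
  best <- phi
  bestMse <- mse(phi)
  for (it in seq_len(iters)) {
    Mw <- warpByField(Mimg, phi)
    diffI <- Fimg - Mw
    gM <- voxelGradient(Mw)
    J2 <- array(0, dims)
    J <- lapply(seq_len(nd), function(k) (gF[[k]] + gM[[k]]) / 2)
    for (k in seq_len(nd)) J2 <- J2 + J[[k]]^2
    den <- J2 + diffI^2 / sigmaX^2
    fac <- ifelse(den > 1e-9, diffI / den, 0)
    upd <- lapply(seq_len(nd), function(k) {
      u <- fac * J[[k]]
      gaussianSmooth(u, sigmaFluid)
    })
    phi <- composeFields(phi, expField(upd))
    phi <- lapply(phi, gaussianSmooth, sigma = sigmaDiff)
    m <- mse(phi)
    if (m < bestMse) { bestMse <- m; best <- phi }
  }
  list(phi = best, mse = bestMse)
}

# Linear upsampling of a coarse field (values doubled) to target dims.
upsampleField <- function(phi, targetDims) {
  nd <- length(targetDims)
  axes <- lapply(targetDims, seq_len)
  pts <- as.matrix(expand.grid(axes))
  # fine index i maps to coarse index (i + 0.5) / 2 under block averaging
  for (k in seq_len(nd)) pts[, k] <- (pts[, k] + 0.5) / 2
  lapply(phi, function(a) {
    out <- 2 * interpLinear(a, pts, spacing = rep(1, nd), origin = rep(1, nd))
    dim(out) <- targetDims
    out
  })
}

#' Default demons registration parameters
#'
#' Symmetric-forces diffeomorphic demons with a 3-level multi-resolution
#' pyramid; iterations per level are coarse-to-fine.
#'
#' @param levels pyramid levels
#' @param iters iterations per level (coarse to fine)
#' @param sigmaFluid update-field Gaussian smoothing sd [voxels]
#' @param sigmaDiff total-field Gaussian smoothing sd [voxels]
#' @return parameter list
#' @export
demonsParams <- function(levels = 3L, iters = c(50L, 30L, 15L),
                         sigmaFluid = 2, sigmaDiff = 1) {
  list(levels = as.integer(levels),
       iters = rep(as.integer(iters), length.out = levels),
       sigmaFluid = sigmaFluid, sigmaDiff = sigmaDiff)
}

#' Pairwise diffeomorphic demons registration
#'
#' Registers \code{moving} to \code{fixed} (same grid) and returns the
#' displacement field mapping fixed coordinates to moving coordinates, in
#' world millimetres. The similarity metric is the mean squared intensity
#' difference; the best-so-far field is kept, so the warped similarity is
#' never worse than before registration. The update is composed through the
#' exponential map (scaling and squaring), giving a diffeomorphic total
#' field; the metric is invariant to a global additive intensity offset.
#'
#' @param fixed,moving \linkS4class{ImageVolume}s on the same grid
#' @param params list from \code{\link{demonsParams}}
#' @return a single-instance \linkS4class{DisplacementField} (time stamp
#'   taken from \code{moving})
#' @export
registerPair <- function(fixed, moving, params = demonsParams()) {
  stopifnot(is(fixed, "ImageVolume"), is(moving, "ImageVolume"))
  if (!identical(dim(fixed@data), dim(moving@data)) ||
      !isTRUE(all.equal(fixed@spacing, moving@spacing)) ||
      !isTRUE(all.equal(fixed@origin, moving@origin)))
    stop("fixed and moving volumes must share the same grid")
  dims <- dim(fixed@data)
  nd <- length(dims)
  # build pyramid
  pyrF <- list(fixed@data)
  pyrM <- list(moving@data)
  for (l in seq_len(params$levels - 1L)) {
    pyrF[[l + 1L]] <- downsample2(pyrF[[l]])
    pyrM[[l + 1L]] <- downsample2(pyrM[[l]])
  }
  phi <- NULL
  for (l in rev(seq_len(params$levels))) {
    if (!is.null(phi)) phi <- upsampleField(phi, dim(pyrF[[l]]))
    res <- demonsLevel(pyrF[[l]], pyrM[[l]], phi,
                       iters = params$iters[l],
                       sigmaFluid = params$sigmaFluid,
                       sigmaDiff = params$sigmaDiff)
    phi <- res$phi
  }
  mse0 <- mean((fixed@data - moving@data)^2)
  if (res$mse > mse0) {
    warning("registration did not improve similarity; returning zero field")
    phi <- lapply(seq_len(nd), function(k) array(0, dims))
  }
  # voxel-index displacement -> world mm per axis
  dmm <- matrix(0, prod(dims), nd)
  for (k in seq_len(nd)) dmm[, k] <- as.vector(phi[[k]]) * fixed@spacing[k]
  dim(dmm) <- c(dims, nd)
  new("DisplacementField", d = list(dmm), times = moving@time,
      spacing = fixed@spacing, origin = fixed@origin)
}

#' Register a full cyclic sequence against its first phase
#'
#' Performs the 19 independent pairwise registrations (first phase versus
#' every other phase) and assembles the cyclic field.
#'
#' @param seq_ an \linkS4class{ImageSequence}
#' @param params demons parameters
#' @param verbose print per-phase progress
#' @return a cyclic \linkS4class{DisplacementField} with
#'   \code{nPhases + 1} instances
#' @export
registerSequence <- function(seq_, params = demonsParams(), verbose = FALSE) {
  n <- nPhases(seq_)
  fixed <- getVolume(seq_, 1L)
  flds <- vector("list", n - 1L)
  for (i in 2:n) {
    if (verbose) message(sprintf("registering phase %d / %d", i, n))
    flds[[i - 1L]] <- registerPair(fixed, getVolume(seq_, i), params)
  }
  assembleCyclic(flds, period = seq_@period)
}

#' Assemble pairwise fields into the cyclic displacement field
#'
#' Prepends the identically zero instance at t = 0 (the reference phase) and
#' appends a zero instance at t = T (cyclic closure), so 19 pairwise fields
#' become 21 time instances.
#'
#' @param fields list of single-instance \linkS4class{DisplacementField}s,
#'   ordered by phase time
#' @param period cycle period T [s]
#' @return a cyclic \linkS4class{DisplacementField}
#' @export
assembleCyclic <- function(fields, period) {
  stopifnot(length(fields) >= 1)
  tms <- vapply(fields, function(f) f@times[1], 0)
  if (anyDuplicated(c(0, tms, period)))
    stop("duplicate time stamps in pairwise fields")
  if (any(diff(tms) <= 0)) stop("fields must be ordered by phase time")
  f1 <- fields[[1]]
  zero <- array(0, dim(f1@d[[1]]))
  d <- c(list(zero), lapply(fields, function(f) f@d[[1]]), list(zero))
  new("DisplacementField", d = d, times = c(0, tms, period),
      spacing = f1@spacing, origin = f1@origin)
}

#' Penalised periodic temporal smoothing of a cyclic field
#'
#' Smooths each voxel component over time with a periodic (circulant)
#' fourth-difference penalty, solved exactly per frequency with the FFT.
#' The zero instances at t = 0 and t = T are preserved exactly via a
#' rank-one constraint correction, so cyclicity survives smoothing, and the
#' downstream periodic-spline interpolation gives equal first derivatives
#' at the cycle seam (equal rates of volume change at start and end).
#'
#' @param f a cyclic \linkS4class{DisplacementField} (uniformly spaced)
#' @param penalty non-negative smoothing weight; 0 returns \code{f}
#' @return smoothed \linkS4class{DisplacementField}
#' @export
smoothTemporal <- function(f, penalty = 0.5) {
  n <- length(f@d)
  if (n < 4) stop("temporal smoothing requires at least 4 instances")
  if (penalty == 0) return(f)
  m <- n - 1L                                  # unique cyclic samples
  dims <- dim(f@d[[1]])
  Y <- vapply(f@d[seq_len(m)], as.vector, numeric(prod(dims)))
  Y <- t(Y)                                    # m x nvox
  j <- 0:(m - 1)
  mu <- (2 * cos(2 * pi * j / m) - 2)^2        # circulant penalty spectrum
  gain <- 1 / (1 + penalty * mu)
  S <- Re(stats::mvfft(stats::mvfft(Y) * gain, inverse = TRUE)) / m
  # pin the first (zero) instance to its original value exactly
  # (rank-one Sherman-Morrison correction on the circulant smoother)
  k1 <- Re(fft(gain, inverse = TRUE)) / m      # first column of the smoother
  S <- S - outer(k1, S[1, ] - Y[1, ]) / k1[1]
  d <- lapply(seq_len(m), function(i) array(S[i, ], dims))
  d[[n]] <- d[[1L]]
  new("DisplacementField", d = d, times = f@times, spacing = f@spacing,
      origin = f@origin)
}

#' Sample a cyclic displacement field in space and time
#'
#' Multilinear in space, periodic cubic spline in time; exact at stored
#' instances and grid nodes. Query times are wrapped into the cycle. Points
#' outside the grid are clamped to the nearest edge with a warning.
#'
#' @param f a cyclic \linkS4class{DisplacementField}
#' @param points n x d world points [mm]
#' @param t a single query time [s]
#' @return n x d matrix of displacements [mm]
#' @export
sampleDisplacement <- function(f, points, t) {
  nd <- length(dim(f@d[[1]])) - 1L
  points <- matrix(points, ncol = nd)
  nInst <- length(f@d)
  # exact hit on an instance avoids the spline round trip
  hit <- which(abs(f@times - t) < 1e-12)
  if (length(hit) == 1L)
    return(interpVector(f@d[[hit]], points, f@spacing, f@origin, warn = TRUE))
  vals <- vapply(seq_len(nInst), function(i)
    as.vector(interpVector(f@d[[i]], points, f@spacing, f@origin,
                           warn = (i == 1L))),
    numeric(nrow(points) * nd))
  ps <- periodicSpline(f@times, t(vals))
  matrix(evalPeriodicSpline(ps, t), nrow(points), nd)
}
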