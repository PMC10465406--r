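# Shared numerical kernels: n-D linear interpolation on regular grids,
# separable Gaussian smoothing, and vectorised periodic cubic splines.
# These are deliberately dependency-free; grids are small (desk scale).

#' Multilinear interpolation on a regular grid
#'
#' Bilinear (2D) or trilinear (3D) interpolation of a scalar array at world
#' points. Points outside the grid are clamped to the nearest edge.
#'
#' @param arr 2D or 3D numeric array
#' @param pts n x d matrix of world coordinates [mm]
#' @param spacing grid spacing per axis [mm]
#' @param origin world coordinate of the first voxel centre [mm]
#' @param warn warn when points are clamped
#' @return numeric vector of interpolated values
#' @export
interpLinear <- function(arr, pts, spacing, origin = rep(0, length(dim(arr))),
                         warn = FALSE) {
  dims <- dim(arr)
  nd <- length(dims)
  pts <- matrix(pts, ncol = nd)
  # continuous 1-based index coordinates
  idx <- sweep(sweep(pts, 2, origin), 2, spacing, "/") + 1
  clamped <- FALSE
  i0 <- w <- vector("list", nd)
  for (k in seq_len(nd)) {
    xk <- idx[, k]
    if (any(xk < 1 - 1e-9 | xk > dims[k] + 1e-9)) clamped <- TRUE
    xk <- pmin(pmax(xk, 1), dims[k])
    f <- pmin(floor(xk), dims[k] - 1L)
    if (dims[k] == 1L) f <- rep(1L, length(xk))
    i0[[k]] <- as.integer(f)
    w[[k]] <- if (dims[k] == 1L) rep(0, length(xk)) else xk - f
  }
  if (clamped && warn) warning("points outside grid were clamped to the edge")
  out <- numeric(nrow(pts))
  # accumulate over the 2^d corners
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  mult <- cumprod(c(1L, dims[-nd]))
  for (ci in seq_len(nrow(corners))) {
    wt <- rep(1, nrow(pts)); lin <- rep(1, nrow(pts))
    for (k in seq_len(nd)) {
      b <- corners[ci, k]
      ik <- pmin(i0[[k]] + b, dims[k])
      wt <- wt * (if (b == 1) w[[k]] else 1 - w[[k]])
      lin <- lin + (ik - 1L) * mult[k]
    }
    out <- out + wt * arr[lin]
  }
  out
}

# Interpolate each component of a displacement-like array (grid dims +
# trailing component axis) at world points; returns n x d matrix.
interpVector <- function(varr, pts, spacing, origin, warn = FALSE) {
  dd <- dim(varr)
  nd <- length(dd) - 1L
  comp <- dd[nd + 1L]
  pts <- matrix(pts, ncol = nd)
  out <- matrix(0, nrow(pts), comp)
  idx <- lapply(dd[seq_len(nd)], seq_len)
  for (c_ in seq_len(comp)) {
    a <- do.call(`[`, c(list(varr), idx, list(c_), list(drop = FALSE)))
    dim(a) <- dd[seq_len(nd)]
    out[, c_] <- interpLinear(a, pts, spacing, origin,
                              warn = warn && c_ == 1L)
  }
  out
}

# Dense 1D Gaussian smoothing matrix with edge renormalisation.
gaussianMatrix1D <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  i <- seq_len(n)
  W <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  W / rowSums(W)
}

#' Separable Gaussian smoothing of a 2D/3D array
#'
#' @param arr numeric array
#' @param sigma smoothing sd per axis, in voxels (recycled)
#' @return smoothed array of the same shape
#' @export
gaussianSmooth <- function(arr, sigma) {
  dims <- dim(arr)
  nd <- length(dims)
  sigma <- rep(sigma, length.out = nd)
  out <- arr
  for (k in seq_len(nd)) {
    if (sigma[k] <= 0 || dims[k] == 1L) next
    W <- gaussianMatrix1D(dims[k], sigma[k])
    perm <- c(k, seq_len(nd)[-k])
    a <- aperm(out, perm)
    da <- dim(a)
    a <- W %*% matrix(a, dims[k])
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

#' Periodic cubic spline through a matrix of cyclic series
#'
#' Builds natural periodic cubic splines (C2 across the seam, so the first
#' derivatives at t[1] and t[end] agree) for many series at once, sharing one
#' factorisation of the cyclic tridiagonal system. The last sample must equal
#' the first.
#'
#' @param times strictly increasing knots [s]; times[1] and times[end] span
#'   one period
#' @param Y length(times) x nseries matrix (or vector) with Y[1, ] == Y[end, ]
#' @return an object for \code{\link{evalPeriodicSpline}}
#' @export
periodicSpline <- function(times, Y) {
  Y <- as.matrix(Y)
  n <- length(times)
  stopifnot(n >= 4, nrow(Y) == n, all(diff(times) > 0))
  if (max(abs(Y[n, ] - Y[1, ])) > 1e-8 * max(1, max(abs(Y))))
    stop("periodic spline requires Y[end, ] == Y[1, ]")
  m <- n - 1L                       # unique knots
  h <- diff(times)                  # m interval widths
  # second-derivative unknowns M_1..M_m (M_{m+1} = M_1), cyclic tridiagonal
  A <- matrix(0, m, m)
  rhs <- matrix(0, m, ncol(Y))
  for (i in seq_len(m)) {
    im <- if (i == 1L) m else i - 1L
    ip <- if (i == m) 1L else i + 1L
    hm <- h[im]; hp <- h[i]
    A[i, im] <- A[i, im] + hm / 6
    A[i, i] <- A[i, i] + (hm + hp) / 3
    A[i, ip] <- A[i, ip] + hp / 6
    rhs[i, ] <- (Y[ip, ] - Y[i, ]) / hp - (Y[i, ] - Y[im, ]) / hm
  }
  M <- solve(A, rhs)
  M <- rbind(M, M[1L, , drop = FALSE])
  structure(list(times = times, Y = Y, M = M, period = times[n] - times[1]),
            class = "periodicSpline")
}

#' Evaluate a periodic spline (or its time derivative)
#'
#' @param ps object from \code{\link{periodicSpline}}
#' @param t evaluation times [s]; wrapped into the period
#' @param deriv 0 for values, 1 for the first time derivative
#' @return length(t) x nseries matrix
#' @export
evalPeriodicSpline <- function(ps, t, deriv = 0) {
  tt <- ps$times
  tw <- tt[1] + (t - tt[1]) %% ps$period
  iv <- findInterval(tw, tt, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), length(tt) - 1L)
  h <- tt[iv + 1L] - tt[iv]
  a <- (tt[iv + 1L] - tw) / h
  b <- (tw - tt[iv]) / h
  Y0 <- ps$Y[iv, , drop = FALSE]; Y1 <- ps$Y[iv + 1L, , drop = FALSE]
  M0 <- ps$M[iv, , drop = FALSE]; M1 <- ps$M[iv + 1L, , drop = FALSE]
  if (deriv == 0) {
    a * Y0 + b * Y1 +
      ((a^3 - a) * M0 + (b^3 - b) * M1) * h^2 / 6
  } else if (deriv == 1) {
    (Y1 - Y0) / h + ((3 * b^2 - 1) * M1 - (3 * a^2 - 1) * M0) * h / 6
  } else stop("deriv must be 0 or 1")
}

# Smoothstep (C1) ramp on [0, 1].
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# One seeded RNG scope: evaluate expr with a local seed without disturbing
# the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}
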