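# Inlet boundary condition construction: chord-sampled mean velocity from
# planar records, the parabolic off-axis correction, volume flow, and the
# plug inlet waveform with additive offset.

#' Spatial mean speed along a measurement chord
#'
#' Samples the in-plane speed of a planar record along a straight chord at
#' pixel resolution (bilinear interpolation) and returns the arithmetic
#' mean over samples inside the geometry mask.
#'
#' @param record a \linkS4class{PlanarRecord}
#' @param chord list(p0, p1): chord endpoints in plane coordinates [mm]
#' @param t sample time [s] (nearest record sample is used)
#' @return mean in-plane speed [m/s]
#' @export
chordMean <- function(record, chord, t = record@times[1]) {
  k <- which.min(abs(record@times - t))
  px <- min(diff(record@x)[1], diff(record@z)[1])
  len <- sqrt(sum((chord$p1 - chord$p0)^2))
  ns <- max(2L, ceiling(len / px) + 1L)
  s <- seq(0, 1, length.out = ns)
  pts <- cbind(chord$p0[1] + s * (chord$p1[1] - chord$p0[1]),
               chord$p0[2] + s * (chord$p1[2] - chord$p0[2]))
  sp <- c(diff(record@x)[1], diff(record@z)[1])
  or <- c(record@x[1], record@z[1])
  uI <- interpLinear(record@u[, , k], pts, sp, or)
  wI <- interpLinear(record@w[, , k], pts, sp, or)
  gI <- interpLinear(record@g[, , min(k, dim(record@g)[3])], pts, sp, or)
  inGrid <- pts[, 1] >= min(record@x) & pts[, 1] <= max(record@x) &
    pts[, 2] >= min(record@z) & pts[, 2] <= max(record@z)
  inside <- gI > 0.5 & inGrid
  if (!any(inside)) stop("chord lies fully outside the geometry mask")
  mean(sqrt(uI[inside]^2 + wI[inside]^2))
}

#' Off-axis chord correction ratio for parabolic flow
#'
#' For fully developed Poiseuille flow, the line-averaged velocity along a
#' chord at perpendicular offset d from the axis is (4V/3)(1 - d^2/R^2),
#' while the chord length is 2 sqrt(R^2 - d^2). The ratio of the off-centre
#' chord mean to the centred (diameter) chord mean is therefore the squared
#' chord-length fraction: a chord spanning 89.4\% of the diameter reads
#' 80\% of the true (diameter) mean.
#'
#' @param chordFraction chord length as a fraction of the diameter, (0, 1]
#' @return ratio of off-centre to centred chord-mean velocity
#' @examples
#' offAxisRatio(0.894)   # ~0.80
#' @export
offAxisRatio <- function(chordFraction) {
  if (any(chordFraction <= 0 | chordFraction > 1))
    stop("chord fraction must lie in (0, 1]")
  chordFraction^2
}

#' Chord fraction whose mean reads a given fraction of the diameter mean
#'
#' Inverse of \code{\link{offAxisRatio}}: the chord length (as a percentage
#' of the diameter) at which the line-averaged parabolic velocity equals
#' \code{ratio} times the centred value.
#'
#' @param ratio target mean-velocity ratio in (0, 1]
#' @return chord length as a percentage of the diameter
#' @examples
#' chordFractionForRatio(0.8)   # 89.44 %
#' @export
chordFractionForRatio <- function(ratio) {
  stopifnot(ratio > 0, ratio <= 1)
  100 * sqrt(ratio)
}

#' Volume flow through a circular inlet
#'
#' Q(t) = |U(t)| * pi (D/2)^2, assuming a circular inlet cross-section.
#'
#' @param Umean mean speed time series [m/s]
#' @param D inlet diameter [mm]
#' @return list: \code{m3s} [m^3/s] and \code{Lmin} [L/min]
#' @examples
#' volumeFlow(0.5, 20)   # 1.5708e-4 m^3/s = 9.4248 L/min
#' @export
volumeFlow <- function(Umean, D) {
  if (D <= 0) stop("diameter must be positive")
  area <- pi * (D / 2000)^2
  q <- abs(Umean) * area
  list(m3s = q, Lmin = q * 60000)
}

#' Build the plug inlet waveform
#'
#' U_inlet(t) = Q(t)/area + offset, prescribed as a spatially uniform
#' boundary-normal plug. The offset is the additive correction applied to
#' compensate the off-axis chord underestimation (0.386 m/s in the default
#' configuration). Negative resulting speeds (back-flow) are allowed with a
#' warning.
#'
#' @param times sample times over one cycle [s] (exclusive of T)
#' @param Q volume flow series [m^3/s]
#' @param D inlet diameter [mm] (defines the area)
#' @param offset additive speed offset [m/s]
#' @param ratio off-axis correction ratio recorded with the waveform
#' @return an \linkS4class{InletWaveform}
#' @export
buildInlet <- function(times, Q, D, offset = 0, ratio = 1) {
  if (D <= 0) stop("inlet area must be positive")
  area <- pi * (D / 2000)^2
  U <- Q / area + offset
  if (any(U < 0)) warning("inlet waveform contains back-flow (negative speed)")
  new("InletWaveform", times = times, Q = abs(U) * area, U = U, D = D,
      area = area, ratio = ratio, offset = offset)
}

#' Default phantom inlet volume-flow waveform
#'
#' A smooth single-lobed cyclic flow with the configured peak (default
#' 2.21 L/min, the peak volume flow measured at the phantom inlet) and a
#' non-zero baseline, peaking mid-diastole. This is the synthetic stand-in
#' for the measured flow-rate curve; its peak value and period are
#' configuration defaults, not physics.
#'
#' @param times sample times [s]; default 40 samples over one cycle
#' @param period cycle period [s]
#' @param QpeakLmin peak volume flow [L/min]
#' @param baseline baseline fraction of the peak
#' @param tPeakFrac time of peak flow as a fraction of the cycle
#' @return list: \code{times}, \code{Q} [m^3/s]
#' @export
defaultInletFlow <- function(times = NULL, period = 0.76, QpeakLmin = 2.21,
                             baseline = 0.15, tPeakFrac = 0.55) {
  if (is.null(times)) times <- (0:39) * period / 40
  Qpk <- QpeakLmin / 60000
  phase <- pi * (times - tPeakFrac * period) / period
  Q <- Qpk * (baseline + (1 - baseline) * cos(phase)^2)
  list(times = times, Q = Q)
}

#' Default corrected inlet waveform for the phantom run
#'
#' Applies the off-axis correction (a chord at 89.4\% of the diameter reads
#' 80\% of the true mean) to the measured-equivalent flow and adds the
#' additive offset, yielding the plug waveform prescribed to the CFD inlet.
#'
#' @param g a \linkS4class{PhantomGeometry} (provides the inlet diameter)
#' @param w a \linkS4class{MotionWaveform} (provides the period)
#' @param QpeakLmin peak flow [L/min]
#' @param offset additive speed correction [m/s]
#' @return an \linkS4class{InletWaveform}
#' @export
defaultInlet <- function(g, w, QpeakLmin = 2.21, offset = 0) {
  fl <- defaultInletFlow(period = w@Tmeas, QpeakLmin = QpeakLmin)
  buildInlet(fl$times, fl$Q, D = g@tubeD, offset = offset,
             ratio = offAxisRatio(0.894))
}
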