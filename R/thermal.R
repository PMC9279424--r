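# Thermal unfolding: tryptophan 350/330 fluorescence intensity ratio (FIR)
# melt curves, Savitzky-Golay smoothed first derivative, Tm and onset.

#' Construct a MeltCurve
#'
#' Either both fluorescence channels or a precomputed ratio must be given.
#'
#' @param temperature strictly increasing grid, degrees C.
#' @param f350,f330 tryptophan emission intensities at 350/330 nm.
#' @param fir precomputed 350/330 fluorescence intensity ratio.
#' @param label condition label (e.g. "pH 4.3").
#' @return A [MeltCurve-class].
#' @export
meltCurve <- function(temperature, f350 = NULL, f330 = NULL, fir = NULL,
                      label = "") {
  if (is.null(fir)) {
    if (is.null(f350) || is.null(f330))
      stop("supply either fir or both f350 and f330")
    fir <- computeFIR(f350, f330)
  }
  d <- data.frame(temperature = temperature,
                  f350 = if (is.null(f350)) NA_real_ else f350,
                  f330 = if (is.null(f330)) NA_real_ else f330,
                  fir = fir)
  new("MeltCurve", data = d, label = label)
}

#' @rdname meltCurve
#' @param x a MeltCurve.
#' @export
meltData <- function(x) x@data

#' Fluorescence intensity ratio
#'
#' Elementwise F350/F330.
#'
#' @param f350,f330 intensity vectors; f330 must be positive throughout.
#' @return numeric ratio vector.
#' @export
computeFIR <- function(f350, f330) {
  if (any(f330 <= 0)) stop("f330 must be positive wherever the ratio is taken")
  f350 / f330
}

#' Smoothed first derivative of a melt curve
#'
#' Savitzky-Golay (local quadratic) smoothing differentiation of FIR with
#' respect to temperature on the original grid. Requires a (near-)uniform
#' temperature grid, as produced by a linear thermal ramp.
#'
#' @param curve a [MeltCurve-class] with at least 5 points.
#' @param smoothWindow window width in degrees C (default 2.5); must be at
#'   least twice the grid spacing.
#' @return data.frame with columns `temperature` and `dfir` (per degree C).
#' @export
meltDerivative <- function(curve, smoothWindow = 2.5) {
  d <- curve@data
  n <- nrow(d)
  if (n < 5L) stop("need at least 5 points to differentiate a melt curve")
  dT <- diff(d$temperature)
  if ((max(dT) - min(dT)) / mean(dT) > 0.02)
    stop("temperature grid must be uniform (linear ramp) within 2%")
  h <- mean(dT)
  if (smoothWindow < 2 * h)
    stop("smoothWindow must be at least twice the grid spacing")
  w <- round(smoothWindow / h) + 1
  if (w %% 2 == 0) w <- w + 1
  w <- max(5, min(w, if (n %% 2 == 1) n else n - 1))
  dfir <- signal::sgolayfilt(d$fir, p = 2, n = w, m = 1, ts = h)
  data.frame(temperature = d$temperature, dfir = dfir)
}

# Topographic prominence of interior local maxima of y; returns a data.frame
# with peak index, height and prominence.
.peaks <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[y[idx] > pmax(y[idx - 1L], y[idx + 1L])]
  if (!length(idx)) return(data.frame(index = integer(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    right <- y[seq.int(i + 1L, n)]
    higherL <- which(left > h)
    higherR <- which(right > h)
    baseL <- min(left[seq.int(if (length(higherL)) max(higherL) else 1L,
                              i - 1L)])
    baseR <- min(right[seq_len(if (length(higherR)) min(higherR)
                               else length(right))])
    h - max(baseL, baseR)
  }, numeric(1))
  data.frame(index = idx, height = y[idx], prominence = prom)
}

# parabolic sub-grid refinement of a peak position on a uniform grid
.refinePeak <- function(t, y, i) {
  if (i <= 1L || i >= length(y)) return(t[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(t[i])
  dt <- (t[i + 1L] - t[i - 1L]) / 2
  t[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * dt
}

#' Melting temperature from the FIR derivative peak
#'
#' Tm is the temperature of the global positive peak of the smoothed FIR
#' derivative, refined to sub-grid precision by a parabola through the peak
#' and its neighbors. Qualifying transitions are interior local maxima with
#' positive height and topographic prominence at least `minProminence`
#' times the global peak height; curves with several qualifying peaks return
#' all of them in `allTm`. The onset is the lowest temperature at which the
#' smoothed derivative first exceeds `onsetThreshold` times the peak height
#' on the way up to Tm.
#'
#' @param curve a [MeltCurve-class].
#' @param smoothWindow degrees C, passed to [meltDerivative()].
#' @param minProminence fraction of peak height (default 0.25).
#' @param onsetThreshold fraction of peak height (default 0.1).
#' @param sign +1 if unfolding increases FIR (tryptophan red shift,
#'   default), -1 for the opposite.
#' @return A [TmResult-class].
#' @export
findTm <- function(curve, smoothWindow = 2.5, minProminence = 0.25,
                   onsetThreshold = 0.1, sign = 1) {
  dv <- meltDerivative(curve, smoothWindow)
  y <- sign * dv$dfir
  # numerical floor: roundoff ripple on flat curves must not count as a peak
  h <- mean(diff(dv$temperature))
  floorH <- 1e3 * .Machine$double.eps *
    max(abs(curve@data$fir), 1e-300) / h
  pk <- .peaks(y)
  pk <- pk[pk$height > floorH, , drop = FALSE]
  if (nrow(pk) == 0L)
    stop("no transition: derivative has no qualifying peak")
  pk <- pk[pk$prominence >= minProminence * max(pk$height), , drop = FALSE]
  if (nrow(pk) == 0L)
    stop("no transition: derivative has no qualifying peak")
  main <- pk[which.max(pk$height), ]
  tm <- .refinePeak(dv$temperature, y, main$index)
  before <- seq_len(main$index)
  above <- which(y[before] >= onsetThreshold * main$height)
  onset <- if (length(above)) dv$temperature[min(above)] else NA_real_
  if (is.finite(onset)) onset <- min(onset, tm)
  allTm <- vapply(pk$index, function(i) .refinePeak(dv$temperature, y, i),
                  numeric(1))
  new("TmResult", tm = tm, onset = onset,
      derivativePeakHeight = main$height, allTm = sort(allTm),
      spread = NA_real_)
}

#' @rdname findTm
#' @return `findOnset`: the onset temperature in degrees C.
#' @export
findOnset <- function(curve, smoothWindow = 2.5, minProminence = 0.25,
                      onsetThreshold = 0.1, sign = 1) {
  findTm(curve, smoothWindow, minProminence, onsetThreshold, sign)@onset
}

#' @rdname findTm
#' @param x a TmResult.
#' @export
tmValue <- function(x) x@tm

#' @rdname findTm
#' @export
tmOnset <- function(x) x@onset

#' Combine replicate Tm determinations
#'
#' Replicates are reported as mean plus/minus the difference from the mean
#' (half-range), the convention used for duplicate capillaries.
#'
#' @param results list of [TmResult-class] objects, or a numeric vector of
#'   Tm values.
#' @return A [TmResult-class] with `tm` the mean and `spread` the
#'   half-range.
#' @export
summarizeTmReplicates <- function(results) {
  if (is.list(results)) {
    tms <- vapply(results, function(r) r@tm, numeric(1))
    onsets <- vapply(results, function(r) r@onset, numeric(1))
    heights <- vapply(results, function(r) r@derivativePeakHeight, numeric(1))
  } else {
    tms <- as.numeric(results)
    onsets <- NA_real_
    heights <- NA_real_
  }
  new("TmResult", tm = mean(tms),
      onset = if (all(is.finite(onsets))) mean(onsets) else NA_real_,
      derivativePeakHeight = mean(heights), allTm = sort(tms),
      spread = (max(tms) - min(tms)) / 2)
}
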