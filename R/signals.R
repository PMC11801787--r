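#' Parcellated region-by-time series
#'
#' Container for an N-regions x T-timepoints real matrix of parcel signals
#' sampled every \code{tr} seconds. Rows are regions.
#'
#' @param data numeric matrix, N x T, all entries finite; N >= 2, T >= 3.
#' @param tr sampling interval (repetition time) in seconds, > 0.
#' @param region_labels optional character vector of length N.
#' @return An object of class \code{region_ts}.
#' @export
region_ts <- function(data, tr, region_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 3L)
    stop("region_ts requires at least 2 regions and 3 timepoints, got ",
         nrow(data), " x ", ncol(data))
  if (!all(is.finite(data)))
    stop("region_ts data must be finite (found NA/NaN/Inf)")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a single positive number of seconds")
  if (!is.null(region_labels)) {
    region_labels <- as.character(region_labels)
    if (length(region_labels) != nrow(data))
      stop("region_labels length (", length(region_labels),
           ") does not match number of regions (", nrow(data), ")")
    rownames(data) <- region_labels
  }
  structure(list(data = data, tr = as.numeric(tr),
                 region_labels = region_labels),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat("<region_ts> ", nrow(x$data), " regions x ", ncol(x$data),
      " timepoints, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$data)

#' Instantaneous phase series
#'
#' Phases (radians, wrapped to (-pi, pi]) and instantaneous amplitudes of a
#' recording, as produced by \code{\link{analytic_phase}}.
#'
#' @param theta numeric N x T matrix of phases in (-pi, pi].
#' @param tr sampling interval, seconds.
#' @param amplitude optional N x T matrix of non-negative amplitudes.
#' @return An object of class \code{phase_series}.
#' @export
phase_series <- function(theta, tr, amplitude = NULL) {
  theta <- as.matrix(theta)
  if (!all(is.finite(theta))) stop("phases must be finite")
  if (any(theta > pi | theta <= -pi)) theta <- wrap_phase(theta)
  if (!is.null(amplitude)) {
    amplitude <- as.matrix(amplitude)
    stopifnot(identical(dim(amplitude), dim(theta)))
  }
  structure(list(theta = theta, amplitude = amplitude, tr = as.numeric(tr)),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat("<phase_series> ", nrow(x$theta), " regions x ", ncol(x$theta),
      " timepoints, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector or matrix of angles in radians.
#' @return Angles mapped into the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor maps +pi to -pi; put the boundary back on +pi
  w[w <= -pi] <- pi
  w
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every region's signal with a second-order Butterworth bandpass
#' applied forward and backward (\code{signal::filtfilt}), i.e. zero phase
#' distortion and effective order 4. Rows are demeaned first so the passband
#' is not contaminated by the DC offset.
#'
#' @param ts a \code{\link{region_ts}}.
#' @param low_hz,high_hz band edges in Hz; 0 < low_hz < high_hz < Nyquist,
#'   where Nyquist = 1/(2 tr).
#' @return A filtered \code{region_ts} of identical shape.
#' @export
bandpass <- function(ts, low_hz, high_hz) {
  stopifnot(inherits(ts, "region_ts"))
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band [", low_hz, ", ", high_hz, "] Hz: need 0 < low < high < ",
         "Nyquist (", signif(nyq, 4), " Hz at TR = ", ts$tr, " s)")
  # filtfilt padding needs a few filter lengths of data
  if (ncol(ts$data) < 12L)
    stop("series too short (T = ", ncol(ts$data), ") for order-4 zero-phase ",
         "filtering; need at least 12 timepoints")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(ts$data, 1L, function(row) {
    signal::filtfilt(bf, row - mean(row))
  }))
  region_ts(out, ts$tr, ts$region_labels)
}

# Analytic signal of one real vector via the frequency-domain construction:
# null negative frequencies, double positive ones, keep DC and (even n) Nyquist.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phases via the analytic (Hilbert) representation
#'
#' Builds the analytic signal x + i H\{x\} of each demeaned region signal by
#' the FFT construction (periodic assumption) and returns its argument as the
#' instantaneous phase and its modulus as the instantaneous amplitude. Input
#' rows should be approximately narrowband (see \code{\link{bandpass}}) for
#' the phase to be physically meaningful.
#'
#' @param ts a \code{\link{region_ts}}.
#' @param edge_trim number of frames to drop from each end of the series
#'   (Hilbert edge effects); default 0.
#' @return A \code{\link{phase_series}} with phases in (-pi, pi].
#' @export
analytic_phase <- function(ts, edge_trim = 0L) {
  stopifnot(inherits(ts, "region_ts"))
  edge_trim <- as.integer(edge_trim)
  X <- ts$data
  vr <- apply(X, 1L, stats::var)
  if (any(vr == 0))
    stop("constant (zero-variance) signal in row(s): ",
         paste(which(vr == 0), collapse = ", "))
  A <- t(apply(X, 1L, function(row) analytic_signal(row - mean(row))))
  if (edge_trim > 0L) {
    keep <- (edge_trim + 1L):(ncol(A) - edge_trim)
    if (length(keep) < 1L) stop("edge_trim leaves no frames")
    A <- A[, keep, drop = FALSE]
  }
  phase_series(wrap_phase(Arg(A)), ts$tr, amplitude = Mod(A))
}
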