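#' Construct a synchronized three-channel recording
#'
#' @param ecg,ppg,bcg Numeric vectors of equal length: ECG, PPG and
#'   head-to-foot BCG acceleration (mg). The head-to-foot channel is
#'   supplied by the caller; no automatic axis inference is attempted.
#' @param fs_hz Common sampling rate in Hz (nominally 1000).
#' @return An object of class `bcg_recording`.
#' @export
recording <- function(ecg, ppg, bcg, fs_hz = 1000) {
  stopifnot(is.numeric(ecg), is.numeric(ppg), is.numeric(bcg), fs_hz > 0)
  if (length(ecg) != length(ppg) || length(ecg) != length(bcg)) {
    stop("recording(): all three channels must have equal length")
  }
  structure(list(fs_hz = fs_hz, ecg = as.numeric(ecg),
                 ppg = as.numeric(ppg), bcg = as.numeric(bcg),
                 length = length(ecg)),
            class = "bcg_recording")
}

#' @export
print.bcg_recording <- function(x, ...) {
  cat(sprintf("<bcg_recording> %d samples @ %g Hz (%.1f s)\n", x$length,
              x$fs_hz, x$length / x$fs_hz))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass with zero phase distortion and the
#' same output length as the input. The forward-backward (squared
#' magnitude) response of the design is applied in the frequency domain
#' on an odd-extended signal; this is equivalent to transient-free
#' forward-backward recursion and stays numerically exact even for very
#' narrow normalized bands such as 0.5-20 Hz at a 1 kHz rate, where
#' time-domain transfer-function recursion loses precision. The pass
#' bands used by the pipeline are 0.5-100 Hz for ECG and 0.5-20 Hz for
#' PPG and BCG.
#'
#' @param x Numeric signal (length >= 2).
#' @param low_hz,high_hz Band edges; must satisfy
#'   `0 < low_hz < high_hz < fs_hz / 2`.
#' @param fs_hz Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, fs_hz, order = 4L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2)) {
    stop("bandpass_filter(): need 0 < low_hz < high_hz < fs_hz/2 (got ",
         low_hz, ", ", high_hz, " at fs ", fs_hz, ")")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs_hz / 2),
                       type = "pass")
  zerophase_apply(bf$b, bf$a, x)
}

# Apply |H(w)|^2 of the rational design (b, a) in the frequency domain
# after odd extension; returns the zero-phase-filtered interior.
zerophase_apply <- function(b, a, x) {
  n <- length(x)
  stopifnot(n >= 2)
  np <- min(n - 1L, 2000L)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  ext <- c(pre, x, post)
  m <- length(ext)
  z <- exp(2i * pi * (seq_len(m) - 1) / m)
  num <- Reduce(function(acc, k) acc * z + b[k], seq_along(b), accumulate = FALSE,
                init = 0 + 0i)
  den <- Reduce(function(acc, k) acc * z + a[k], seq_along(a), accumulate = FALSE,
                init = 0 + 0i)
  H2 <- Mod(num / den)^2
  y <- Re(stats::fft(stats::fft(ext) * H2, inverse = TRUE)) / m
  y[(np + 1):(np + n)]
}

#' Detect ECG R waves by height threshold with a refractory period
#'
#' Local maxima of the (filtered) ECG exceeding `height_frac` times a
#' robust signal maximum (the 98th percentile) are taken as R-wave
#' candidates; candidates closer than the refractory period to the last
#' accepted R wave are dropped (greedy, left to right), matching the
#' physiological lower bound on RR intervals.
#'
#' @param ecg Filtered ECG signal.
#' @param fs_hz Sampling rate in Hz.
#' @param height_frac Fraction of the robust maximum used as the height
#'   threshold (default 0.6).
#' @param refractory_ms Minimum distance between accepted R waves
#'   (default 250 ms).
#' @return Increasing 1-based sample indices of the R waves; empty for a
#'   flat or sub-threshold signal.
#' @export
detect_r_waves <- function(ecg, fs_hz, height_frac = 0.6,
                           refractory_ms = 250) {
  stopifnot(height_frac > 0, height_frac <= 1)
  n <- length(ecg)
  if (n < 3 || diff(range(ecg)) == 0) return(integer(0))
  d <- diff(ecg)
  # local maxima: derivative changes from >0 to <=0 (plateaus keep the
  # first sample); window boundaries count when they dominate their
  # neighbor, so an R wave at the very first sample is not lost
  peaks <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (ecg[1] > ecg[2]) peaks <- c(1L, peaks)
  if (ecg[n] > ecg[n - 1]) peaks <- c(peaks, n)
  if (!length(peaks)) return(integer(0))
  # robust waveform height: 98th percentile of the peak heights
  robust_max <- as.numeric(stats::quantile(ecg[peaks], 0.98, names = FALSE))
  if (!is.finite(robust_max) || robust_max <= 0) return(integer(0))
  thr <- height_frac * robust_max
  peaks <- peaks[ecg[peaks] > thr]
  if (!length(peaks)) return(integer(0))
  refr <- as.integer(round(refractory_ms * fs_hz / 1000))
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= refr) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

#' Segment a recording into fixed 448-sample beats at the R waves
#'
#' Cuts one window per R wave, starting at the R-wave sample, half-open
#' `[r, r + window)`. A beat is kept only when the window fits before
#' both the next R wave and the end of the recording; short RR intervals
#' are discarded and counted.
#'
#' @param rec A [recording()].
#' @param r_indices Increasing 1-based R-wave sample indices.
#' @param window Window length in samples (default 448).
#' @return A list with `beats` (list of `bcg_beat`, fiducials unset) and
#'   `n_discarded`.
#' @export
segment_beats <- function(rec, r_indices, window = 448L) {
  stopifnot(inherits(rec, "bcg_recording"))
  window <- as.integer(window)
  r_indices <- as.integer(r_indices)
  stopifnot(all(r_indices >= 1), all(r_indices <= rec$length))
  beats <- list()
  n_discarded <- 0L
  for (i in seq_along(r_indices)) {
    r <- r_indices[i]
    rr_ok <- i == length(r_indices) || (r_indices[i + 1] - r) >= window
    fits <- (r + window - 1L) <= rec$length
    if (!rr_ok || !fits) {
      n_discarded <- n_discarded + 1L
      next
    }
    idx <- r:(r + window - 1L)
    beats[[length(beats) + 1L]] <- structure(
      list(beat_id = length(beats) + 1L, fs_hz = rec$fs_hz,
           channels = list(ecg = rec$ecg[idx], ppg = rec$ppg[idx],
                           bcg = rec$bcg[idx]),
           r_index = r, ppg_foot_idx = NA_integer_,
           annotations = NULL, ground_truth_label = NULL, params = NULL),
      class = "bcg_beat")
  }
  list(beats = beats, n_discarded = n_discarded)
}

#' Detect the PPG foot by the intersecting tangent method
#'
#' The foot of the systolic upstroke is the abscissa where the tangent at
#' the steepest point of the upstroke crosses the horizontal line through
#' the preceding minimum. The construction is scale-free: multiplying the
#' beat by a constant leaves the intersection unchanged.
#'
#' @param ppg_beat Numeric PPG window (448 samples in the pipeline).
#' @param fs_hz Sampling rate in Hz.
#' @return A list with `index` (1-based sample, clipped to the window),
#'   `t_ms` (foot latency after window start, possibly fractional) and
#'   `flagged` (TRUE when no upstroke was found, in which case `index`
#'   and `t_ms` are NA).
#' @export
detect_ppg_foot <- function(ppg_beat, fs_hz = 1000) {
  n <- length(ppg_beat)
  if (n < 3 || diff(range(ppg_beat)) == 0) {
    return(list(index = NA_integer_, t_ms = NA_real_, flagged = TRUE))
  }
  d <- diff(ppg_beat)
  i_max <- which.max(d)  # steepest ascent (first sample of that rise)
  slope <- d[i_max]
  if (slope <= 0) {
    return(list(index = NA_integer_, t_ms = NA_real_, flagged = TRUE))
  }
  i_min <- which.min(ppg_beat[1:i_max])
  base <- ppg_beat[i_min]
  # tangent through (i_max, y[i_max]) with the sample-to-sample slope
  t_foot <- i_max - (ppg_beat[i_max] - base) / slope
  t_foot <- min(max(t_foot, 1), n)
  list(index = as.integer(round(t_foot)),
       t_ms = (t_foot - 1) / fs_hz * 1000,
       flagged = FALSE)
}

#' Filter a recording with the standard pass bands
#'
#' Convenience wrapper applying the pipeline's default zero-phase
#' Butterworth bands: 0.5-100 Hz to the ECG and 0.5-20 Hz to PPG and
#' BCG.
#'
#' @param rec A [recording()].
#' @return A filtered `bcg_recording`.
#' @export
filter_recording <- function(rec) {
  stopifnot(inherits(rec, "bcg_recording"))
  recording(bandpass_filter(rec$ecg, 0.5, 100, rec$fs_hz),
            bandpass_filter(rec$ppg, 0.5, 20, rec$fs_hz),
            bandpass_filter(rec$bcg, 0.5, 20, rec$fs_hz),
            fs_hz = rec$fs_hz)
}
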