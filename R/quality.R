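#' Propose the J-wave candidate of a BCG beat
#'
#' The candidate is the largest local maximum of the BCG window strictly
#' before the PPG foot. Its amplitude is the peak value minus the mean of
#' the two flanking local minima (the I- and K-wave troughs; window
#' boundaries serve as flanks when no interior minimum exists), and its
#' width is the full width of the peak at half that amplitude, with
#' linear interpolation at the crossings.
#'
#' @param bcg_beat Numeric BCG window (mg), or a `bcg_beat` whose BCG
#'   channel is used.
#' @param ppg_foot_idx 1-based sample index of the PPG foot within the
#'   window.
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `bcg_jwave_candidate` (fields `index`,
#'   `t_ms`, `amplitude_mg`, `width_ms`), or `NULL` when the window has
#'   no local maximum before the foot.
#' @export
detect_j_candidate <- function(bcg_beat, ppg_foot_idx, fs_hz = 1000) {
  x <- if (inherits(bcg_beat, "bcg_beat")) bcg_beat$channels$bcg else
    as.numeric(bcg_beat)
  n <- length(x)
  if (is.na(ppg_foot_idx) || ppg_foot_idx < 2 || ppg_foot_idx > n) {
    return(NULL)
  }
  d <- diff(x)
  maxima <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  maxima <- maxima[maxima < ppg_foot_idx]
  if (!length(maxima)) return(NULL)
  pk <- maxima[which.max(x[maxima])]
  peak_val <- x[pk]

  minima <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  left_mins <- minima[minima < pk]
  right_mins <- minima[minima > pk]
  left_val <- if (length(left_mins)) x[max(left_mins)] else min(x[1:pk])
  right_val <- if (length(right_mins)) x[min(right_mins)] else min(x[pk:n])
  amplitude <- peak_val - mean(c(left_val, right_val))
  if (amplitude <= 0) return(NULL)

  # full width at half the peak-to-baseline amplitude
  level <- peak_val - amplitude / 2
  li <- pk
  while (li > 1 && x[li - 1] >= level) li <- li - 1
  left_t <- if (li == 1) 1 else
    (li - 1) + (x[li - 1] - level) / (x[li - 1] - x[li])
  ri <- pk
  while (ri < n && x[ri + 1] >= level) ri <- ri + 1
  right_t <- if (ri == n) n else
    ri + (x[ri] - level) / (x[ri] - x[ri + 1])

  structure(
    list(index = pk, t_ms = (pk - 1) / fs_hz * 1000,
         amplitude_mg = amplitude,
         width_ms = (right_t - left_t) / fs_hz * 1000),
    class = "bcg_jwave_candidate")
}

#' @export
print.bcg_jwave_candidate <- function(x, ...) {
  cat(sprintf("<J-wave candidate> t = %.0f ms, amplitude = %.2f mg, width = %.1f ms\n",
              x$t_ms, x$amplitude_mg, x$width_ms))
  invisible(x)
}

#' Label a BCG beat high- or low-quality by the three J-wave rules
#'
#' A beat is high-quality if and only if all three rules pass: (1) a
#' J-wave candidate exists before the PPG foot, (2) its amplitude
#' exceeds `amp_threshold_mg` (strictly; the default 3 mg boundary
#' itself is low-quality), and (3) its width is below
#' `width_threshold_ms` (strictly, default 100 ms). An absent candidate
#' or an absent PPG foot fails rule 1 (and rules 2-3 cannot pass without
#' a candidate).
#'
#' @param candidate A `bcg_jwave_candidate` or `NULL`.
#' @param ppg_foot_idx 1-based PPG foot index, or NA when undetected.
#' @param amp_threshold_mg Amplitude threshold, default 3 mg.
#' @param width_threshold_ms Width threshold, default 100 ms.
#' @return An object of class `bcg_quality_label` with fields `label`
#'   ("high"/"low") and the per-rule booleans `rule1_pass`, `rule2_pass`,
#'   `rule3_pass`.
#' @export
label_beat <- function(candidate, ppg_foot_idx, amp_threshold_mg = 3,
                       width_threshold_ms = 100) {
  stopifnot(amp_threshold_mg > 0, width_threshold_ms > 0)
  rule1 <- !is.null(candidate) && !is.na(ppg_foot_idx) &&
    candidate$index < ppg_foot_idx
  rule2 <- rule1 && candidate$amplitude_mg > amp_threshold_mg
  rule3 <- rule1 && candidate$width_ms < width_threshold_ms
  structure(
    list(label = if (rule1 && rule2 && rule3) "high" else "low",
         rule1_pass = rule1, rule2_pass = rule2, rule3_pass = rule3),
    class = "bcg_quality_label")
}

#' @export
print.bcg_quality_label <- function(x, ...) {
  cat(sprintf("<quality label> %s (rule1 %s, rule2 %s, rule3 %s)\n",
              x$label, x$rule1_pass, x$rule2_pass, x$rule3_pass))
  invisible(x)
}

#' Run candidate detection + rule labeling over segmented beats
#'
#' For each beat: detect the PPG foot if unset, propose the J-wave
#' candidate, and apply the three rules.
#'
#' @param beats List of `bcg_beat` objects.
#' @param amp_threshold_mg,width_threshold_ms Rule thresholds.
#' @param smooth_hz Low-pass corner applied (zero-phase) to the BCG
#'   window before candidate detection, so that broadband noise does not
#'   masquerade as local extrema; 20 Hz matches the recording pass band.
#'   `NULL` disables smoothing.
#' @return Character vector of "high"/"low", one per beat, with the full
#'   `bcg_quality_label` objects in attribute `"details"`.
#' @export
label_beats <- function(beats, amp_threshold_mg = 3,
                        width_threshold_ms = 100, smooth_hz = 20) {
  details <- lapply(beats, function(b) {
    foot <- b$ppg_foot_idx
    if (is.null(foot) || is.na(foot)) {
      foot <- detect_ppg_foot(b$channels$ppg, b$fs_hz)$index
    }
    bcg <- b$channels$bcg
    if (!is.null(smooth_hz)) {
      lp <- signal::butter(4, smooth_hz / (b$fs_hz / 2), type = "low")
      bcg <- zerophase_apply(lp$b, lp$a, bcg)
    }
    cand <- detect_j_candidate(bcg, foot, b$fs_hz)
    label_beat(cand, foot, amp_threshold_mg, width_threshold_ms)
  })
  out <- vapply(details, function(d) d$label, character(1))
  attr(out, "details") <- details
  out
}

#' Balance two label classes by random subsampling
#'
#' Selects an equal number of beats per class by uniform sampling without
#' replacement, deterministic under `seed`. With `per_class_n = "min"`
#' the minority-class count is used, mirroring the balanced design in
#' which 4813 beats per class (9626 total) enter the analysis.
#'
#' @param labels Character/factor vector of "high"/"low" labels.
#' @param per_class_n `"min"` or a positive integer not exceeding either
#'   class count.
#' @param seed Integer seed.
#' @return Sorted integer indices of the selected elements (equal counts
#'   per class).
#' @export
balance_classes <- function(labels, per_class_n = "min", seed = 1L) {
  labels <- as.character(labels)
  idx_high <- which(labels == "high")
  idx_low <- which(labels == "low")
  if (!length(idx_high) || !length(idx_low)) {
    stop("balance_classes(): both classes must be non-empty")
  }
  if (identical(per_class_n, "min")) {
    per_class_n <- min(length(idx_high), length(idx_low))
  }
  per_class_n <- as.integer(per_class_n)
  if (per_class_n > length(idx_high) || per_class_n > length(idx_low)) {
    stop("balance_classes(): per_class_n = ", per_class_n,
         " exceeds a class count (", length(idx_high), " high, ",
         length(idx_low), " low)")
  }
  with_seed(seed, {
    sel <- c(sample(idx_high, per_class_n), sample(idx_low, per_class_n))
  })
  sort(sel)
}
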