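#' Simulation parameters for one synthetic ECG/PPG/BCG beat
#'
#' Collects the ground-truth quantities of a simulated 1 kHz beat
#' triplet. The BCG J wave is a Gaussian bump of peak-to-baseline
#' amplitude `j_amplitude_mg` (milli-gravity; 1 mg = 9.80665e-3 m/s^2)
#' and full width at half maximum `j_width_ms`, centered `j_time_ms`
#' after the gating R wave and flanked by I/K-wave troughs on a damped
#' ~10 Hz oscillation. The PPG is a logistic systolic upstroke whose
#' intersecting-tangent foot falls at `ppg_foot_ms` after the R wave.
#'
#' @param heart_rate_bpm Heart rate in beats per minute (>0).
#' @param j_amplitude_mg J-wave amplitude above the flanking troughs, in
#'   milli-gravity (>=0; 0 removes the J complex entirely).
#' @param j_width_ms Full width at half maximum of the J bump (>0).
#' @param j_time_ms J-peak latency after the R wave, ms.
#' @param ppg_foot_ms PPG foot latency after the R wave, ms.
#' @param noise_sd_mg White-noise standard deviation on the BCG, mg.
#' @param artifact_prob Probability of injecting a low-frequency
#'   (0.5-2 Hz) high-amplitude motion transient into the window.
#' @param seed Integer seed; the same parameters and seed give
#'   bit-identical channels.
#' @return An object of class `bcg_sim_params`.
#' @export
beat_sim_params <- function(heart_rate_bpm = 60, j_amplitude_mg = 6,
                            j_width_ms = 60, j_time_ms = 180,
                            ppg_foot_ms = 260, noise_sd_mg = 0.3,
                            artifact_prob = 0, seed = 1L) {
  stopifnot(heart_rate_bpm > 0, j_amplitude_mg >= 0, j_width_ms > 0,
            j_time_ms > 0, ppg_foot_ms > 0, noise_sd_mg >= 0,
            artifact_prob >= 0, artifact_prob <= 1)
  period_ms <- 60000 / heart_rate_bpm
  if (j_time_ms >= period_ms || ppg_foot_ms >= period_ms) {
    stop("beat_sim_params(): latencies must be below the beat period (",
         round(period_ms, 1), " ms at ", heart_rate_bpm, " bpm)")
  }
  if (j_time_ms >= 448 || ppg_foot_ms >= 448) {
    stop("beat_sim_params(): latencies must fall inside the 448-ms window")
  }
  structure(
    list(heart_rate_bpm = heart_rate_bpm, j_amplitude_mg = j_amplitude_mg,
         j_width_ms = j_width_ms, j_time_ms = j_time_ms,
         ppg_foot_ms = ppg_foot_ms, noise_sd_mg = noise_sd_mg,
         artifact_prob = artifact_prob, seed = as.integer(seed)),
    class = "bcg_sim_params")
}

# Run expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

BEAT_WINDOW_MS <- 448L

#' Simulate one synchronized ECG/PPG/BCG beat at 1 kHz
#'
#' Generates a 448-sample window per channel starting at the gating R
#' wave. The ECG carries an R spike at sample 1 and a small T wave; the
#' PPG is a noise-free-by-default logistic upstroke whose
#' intersecting-tangent foot matches `ppg_foot_ms` to within the sample
#' grid; the BCG superposes the I-J-K complex, a damped 10 Hz
#' oscillation, optional motion artifact and white noise. Ground-truth
#' fiducials and the rule-based quality label implied by the parameters
#' are stored as annotations.
#'
#' @param params A [beat_sim_params()] object.
#' @return An object of class `bcg_beat` with elements `beat_id`,
#'   `fs_hz`, `channels` (list `ecg`, `ppg`, `bcg`, each 448 samples),
#'   `r_index`, `ppg_foot_idx`, `annotations` and `ground_truth_label`.
#' @export
synth_beat <- function(params) {
  stopifnot(inherits(params, "bcg_sim_params"))
  with_seed(params$seed, synth_beat_impl(params))
}

# Internals shared by synth_beat()/synth_dataset(); assumes the RNG is
# already positioned.
synth_beat_impl <- function(params, beat_id = 1L) {
  n <- BEAT_WINDOW_MS
  t_ms <- seq_len(n) - 1  # sample i is t = (i-1) ms

  # ECG: sharp R spike at t = 0 plus a low T wave
  ecg <- exp(-0.5 * (t_ms / 4)^2) + 0.12 * exp(-0.5 * ((t_ms - 280) / 30)^2)

  # PPG: logistic upstroke; the tangent at the steepest point crosses the
  # baseline exactly 2 * slope-scale before the midpoint, so the
  # midpoint is placed at foot + 2 * s_ppg
  s_ppg <- 12
  ppg <- 1 / (1 + exp(-(t_ms - (params$ppg_foot_ms + 2 * s_ppg)) / s_ppg))

  # BCG: I-J-K complex + damped oscillation + artifact + noise, in mg
  a <- params$j_amplitude_mg
  sigma <- params$j_width_ms / (2 * sqrt(2 * log(2)))
  trough <- 0.1 * a
  spread <- 1.2 * params$j_width_ms
  bcg <- (a - trough) * exp(-0.5 * ((t_ms - params$j_time_ms) / sigma)^2) -
    trough * exp(-0.5 * ((t_ms - params$j_time_ms + spread) / sigma)^2) -
    trough * exp(-0.5 * ((t_ms - params$j_time_ms - spread) / sigma)^2)
  bcg <- bcg + 0.4 * exp(-t_ms / 150) * sin(2 * pi * 10 * t_ms / 1000)

  has_artifact <- params$artifact_prob > 0 &&
    stats::runif(1) < params$artifact_prob
  if (has_artifact) {
    f_art <- stats::runif(1, 0.5, 2)
    amp_art <- stats::runif(1, 15, 40)
    # the transient overlaps the scored (pre-foot) region, so a motion
    # artifact always corrupts the J-wave neighborhood it labels
    ctr <- stats::runif(1, 40, params$ppg_foot_ms + 60)
    env_w <- stats::runif(1, 80, 200)
    bcg <- bcg + amp_art * exp(-0.5 * ((t_ms - ctr) / env_w)^2) *
      sin(2 * pi * f_art * (t_ms - ctr) / 1000)
  }
  if (params$noise_sd_mg > 0) {
    bcg <- bcg + stats::rnorm(n, sd = params$noise_sd_mg)
  }

  label <- if (params$j_time_ms < params$ppg_foot_ms &&
               params$j_amplitude_mg > 3 && params$j_width_ms < 100 &&
               !has_artifact) "high" else "low"

  structure(
    list(beat_id = as.integer(beat_id), fs_hz = 1000,
         channels = list(ecg = ecg, ppg = ppg, bcg = bcg),
         r_index = 1L,
         ppg_foot_idx = as.integer(round(params$ppg_foot_ms)) + 1L,
         annotations = list(j_time_ms = params$j_time_ms,
                            j_amplitude_mg = params$j_amplitude_mg,
                            j_width_ms = params$j_width_ms,
                            ppg_foot_ms = params$ppg_foot_ms,
                            artifact = has_artifact),
         ground_truth_label = label,
         params = params),
    class = "bcg_beat")
}

#' @export
print.bcg_beat <- function(x, ...) {
  cat(sprintf("<bcg_beat> id %d, %d samples @ %g Hz, label: %s\n",
              x$beat_id, length(x$channels$bcg), x$fs_hz,
              ifelse(is.null(x$ground_truth_label), "?",
                     x$ground_truth_label)))
  invisible(x)
}

# Draw per-beat simulation parameters for one class.
draw_params <- function(high, difficulty, seed) {
  u <- function(lo, hi) stats::runif(1, lo, hi)
  if (difficulty == "separable") {
    if (high) {
      j_time <- u(120, 220)
      p <- list(j_amplitude_mg = u(5, 9), j_width_ms = u(40, 80),
                j_time_ms = j_time, ppg_foot_ms = j_time + u(60, 120),
                artifact_prob = 0)
    } else {
      mode <- sample.int(4L, 1L)
      j_time <- u(120, 220)
      p <- switch(mode,
        list(j_amplitude_mg = u(0.3, 1.2), j_width_ms = u(40, 80),      # faint J
             j_time_ms = j_time, ppg_foot_ms = j_time + u(60, 120),
             artifact_prob = 0),
        list(j_amplitude_mg = u(5, 9), j_width_ms = u(140, 220),        # broad J
             j_time_ms = j_time, ppg_foot_ms = j_time + u(60, 120),
             artifact_prob = 0),
        {                                                               # late J
          jt <- u(250, 350)
          list(j_amplitude_mg = u(5, 9), j_width_ms = u(40, 80),
               j_time_ms = jt, ppg_foot_ms = jt - u(60, 120),
               artifact_prob = 0)
        },
        list(j_amplitude_mg = u(0.3, 1.5), j_width_ms = u(40, 80),      # motion
             j_time_ms = j_time, ppg_foot_ms = j_time + u(60, 120),     # swamps
             artifact_prob = 1))                                        # faint J
    }
  } else {  # hard: parameters near the 3 mg / 100 ms rule boundaries
    j_time <- u(150, 250)
    if (high) {
      p <- list(j_amplitude_mg = u(3.05, 4.5), j_width_ms = u(60, 99),
                j_time_ms = j_time, ppg_foot_ms = j_time + u(25, 70),
                artifact_prob = 0)
    } else {
      mode <- sample.int(2L, 1L)
      p <- switch(mode,
        list(j_amplitude_mg = u(1.6, 2.95), j_width_ms = u(60, 99),
             j_time_ms = j_time, ppg_foot_ms = j_time + u(25, 70),
             artifact_prob = 0),
        list(j_amplitude_mg = u(3.05, 4.5), j_width_ms = u(101, 140),
             j_time_ms = j_time, ppg_foot_ms = j_time + u(25, 70),
             artifact_prob = 0))
    }
  }
  beat_sim_params(heart_rate_bpm = u(55, 85),
                  j_amplitude_mg = p$j_amplitude_mg,
                  j_width_ms = p$j_width_ms, j_time_ms = p$j_time_ms,
                  ppg_foot_ms = p$ppg_foot_ms, noise_sd_mg = 0.3,
                  artifact_prob = p$artifact_prob, seed = seed)
}

#' Simulate a labeled collection of beats
#'
#' Draws `n_beats` beats with exactly `round(n_beats * high_fraction)`
#' high-quality members. `"separable"` difficulty draws the two classes
#' with a wide margin around the labeling rules (low-quality beats
#' violate at least one rule clearly: faint J, broad J, J after the PPG
#' foot, or motion artifact); `"hard"` draws both classes near the 3 mg
#' amplitude and 100 ms width thresholds so that detection noise
#' matters.
#'
#' @param n_beats Number of beats (>= 2).
#' @param high_fraction Fraction of high-quality beats in [0, 1].
#' @param difficulty `"separable"` or `"hard"`.
#' @param seed Integer seed controlling all draws.
#' @return A list of `bcg_beat` objects; ground-truth labels are in each
#'   beat's `ground_truth_label`.
#' @export
synth_dataset <- function(n_beats, high_fraction = 0.5,
                          difficulty = c("separable", "hard"), seed = 1L) {
  difficulty <- match.arg(difficulty)
  n_beats <- as.integer(n_beats)
  stopifnot(n_beats >= 2, high_fraction >= 0, high_fraction <= 1)
  n_high <- as.integer(round(n_beats * high_fraction))
  is_high <- c(rep(TRUE, n_high), rep(FALSE, n_beats - n_high))
  with_seed(seed, {
    is_high <- sample(is_high)  # interleave the classes
    beats <- vector("list", n_beats)
    for (i in seq_len(n_beats)) {
      prm <- draw_params(is_high[i], difficulty, seed = NA_integer_)
      beats[[i]] <- synth_beat_impl(prm, beat_id = i)
    }
    beats
  })
}

#' Ground-truth labels of a synthetic dataset
#' @param beats List of `bcg_beat` objects.
#' @return Character vector of "high"/"low".
#' @export
ground_truth_labels <- function(beats) {
  vapply(beats, function(b) b$ground_truth_label, character(1))
}

#' Concatenate synthetic beats into one continuous recording
#'
#' Joins beats end to end at their simulated heart-rate periods, giving a
#' continuous three-channel recording whose R waves fall at known sample
#' positions. Used to exercise R-wave detection and beat segmentation
#' round trips.
#'
#' @param beats List of `bcg_beat` objects.
#' @return A list with the `bcg_recording` (`recording`) and the true
#'   1-based R-wave sample indices (`r_indices`).
#' @export
concat_beats <- function(beats) {
  stopifnot(length(beats) >= 1)
  periods <- vapply(beats, function(b)
    as.integer(round(60000 / b$params$heart_rate_bpm)), integer(1))
  periods <- pmax(periods, BEAT_WINDOW_MS)
  total <- sum(periods) + BEAT_WINDOW_MS
  ecg <- ppg <- bcg <- numeric(total)
  r_indices <- integer(length(beats))
  at <- 1L
  for (i in seq_along(beats)) {
    idx <- at:(at + BEAT_WINDOW_MS - 1L)
    ecg[idx] <- beats[[i]]$channels$ecg
    ppg[idx] <- beats[[i]]$channels$ppg
    bcg[idx] <- beats[[i]]$channels$bcg
    r_indices[i] <- at
    at <- at + periods[i]
  }
  list(recording = recording(ecg[1:(at - 1L)], ppg[1:(at - 1L)],
                             bcg[1:(at - 1L)], fs_hz = 1000),
       r_indices = r_indices)
}
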