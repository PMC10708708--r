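test_that("beat simulation is seeded-deterministic and annotates its fiducials", {
  p <- beat_sim_params(j_amplitude_mg = 6, j_width_ms = 60, j_time_ms = 180,
                       ppg_foot_ms = 260, noise_sd_mg = 0.3, seed = 1L)
  b1 <- synth_beat(p)
  b2 <- synth_beat(p)
  expect_identical(b1$channels, b2$channels)
  expect_length(b1$channels$ecg, 448L)
  expect_length(b1$channels$ppg, 448L)
  expect_length(b1$channels$bcg, 448L)
  expect_equal(b1$annotations$j_time_ms, 180)
  expect_identical(b1$ground_truth_label, "high")
  # a different seed moves the noise but not the deterministic parts
  b3 <- synth_beat(beat_sim_params(seed = 2L))
  expect_false(identical(b1$channels$bcg, b3$channels$bcg))
  expect_identical(b1$channels$ppg, b3$channels$ppg)
})

test_that("the simulated J peak is recovered at its annotated position and amplitude", {
  p <- beat_sim_params(j_amplitude_mg = 6, j_width_ms = 60, j_time_ms = 180,
                       ppg_foot_ms = 260, noise_sd_mg = 0.3, seed = 1L)
  b <- synth_beat(p)
  lab <- label_beats(list(b))
  cand <- attr(lab, "details")[[1]]
  expect_identical(lab[[1]], "high")
  sm <- detect_j_candidate(b$channels$bcg, b$ppg_foot_idx)
  # raw peak position: regenerate and measure numerically
  peak_ms <- which.max(b$channels$bcg) - 1
  expect_lt(abs(peak_ms - 180), 5)
  # measured candidate amplitude on the smoothed beat within +/- 1 mg
  lp <- signal::butter(4, 20 / 500, type = "low")
  cand2 <- detect_j_candidate(bcgsq:::zerophase_apply(lp$b, lp$a,
                                                      b$channels$bcg),
                              b$ppg_foot_idx)
  expect_lt(abs(cand2$amplitude_mg - 6), 1)
  expect_lt(abs(cand2$t_ms - 180), 5)
})

test_that("zero J amplitude leaves no peak above the noise floor and labels low", {
  b <- synth_beat(beat_sim_params(j_amplitude_mg = 0, noise_sd_mg = 0.3,
                                  seed = 7L))
  expect_identical(b$ground_truth_label, "low")
  expect_lt(max(b$channels$bcg), 1.5)  # noise + residual oscillation only
  expect_identical(label_beats(list(b))[[1]], "low")
})

test_that("latencies beyond the window or the beat period are rejected", {
  expect_error(beat_sim_params(ppg_foot_ms = 500), "window")
  expect_error(beat_sim_params(j_time_ms = 460), "window")
  expect_error(beat_sim_params(heart_rate_bpm = 200, j_time_ms = 350,
                               ppg_foot_ms = 400), "period")
})

test_that("dataset generation hits the requested class counts exactly", {
  beats <- synth_dataset(100, 0.5, "separable", seed = 3L)
  gt <- ground_truth_labels(beats)
  expect_identical(sum(gt == "high"), 50L)
  expect_identical(sum(gt == "low"), 50L)
  beats2 <- synth_dataset(30, 0.3, "hard", seed = 4L)
  expect_identical(sum(ground_truth_labels(beats2) == "high"), 9L)
  # seeded determinism of whole collections
  beats3 <- synth_dataset(30, 0.3, "hard", seed = 4L)
  expect_identical(beats2[[17]]$channels, beats3[[17]]$channels)
})

test_that("raising the J amplitude never flips a high ground-truth label to low", {
  set.seed(31)
  for (i in 1:25) {
    amp <- runif(1, 3.1, 6)
    base <- beat_sim_params(j_amplitude_mg = amp,
                            j_width_ms = runif(1, 40, 95),
                            j_time_ms = runif(1, 130, 220),
                            ppg_foot_ms = runif(1, 240, 340), seed = i)
    up <- beat_sim_params(j_amplitude_mg = amp + runif(1, 0.5, 4),
                          j_width_ms = base$j_width_ms,
                          j_time_ms = base$j_time_ms,
                          ppg_foot_ms = base$ppg_foot_ms, seed = i)
    lab_base <- synth_beat(base)$ground_truth_label
    lab_up <- synth_beat(up)$ground_truth_label
    if (lab_base == "high") expect_identical(lab_up, "high")
  }
})

test_that("the annotated PPG foot is recovered by the tangent method within 2 ms", {
  for (foot in c(180, 260, 320)) {
    b <- synth_beat(beat_sim_params(ppg_foot_ms = foot, noise_sd_mg = 0,
                                    seed = 5L))
    det <- detect_ppg_foot(b$channels$ppg, 1000)
    expect_false(det$flagged)
    expect_lt(abs(det$t_ms - foot), 2)
  }
})
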