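test_that("band-pass filtering removes out-of-band content and passes the band", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  # DC is annihilated
  dc <- bandpass_filter(rep(2, 3000), 0.5, 20, fs)
  expect_lt(max(abs(dc[500:2500])), 1e-6 * 2)
  # 10 Hz sits inside 0.5-20 Hz: steady-state amplitude within 5% of 1
  f10 <- bandpass_filter(sin(2 * pi * 10 * t), 0.5, 20, fs)
  expect_lt(abs(max(abs(f10[2000:3000])) - 1), 0.05)
  # 0.05 Hz is far below the band
  f005 <- bandpass_filter(sin(2 * pi * 0.05 * t), 0.5, 20, fs)
  expect_lt(max(abs(f005[2000:3000])), 0.1)
  # cutoff order violations are explicit errors
  expect_error(bandpass_filter(rnorm(100), 20, 0.5, fs), "low_hz")
  expect_error(bandpass_filter(rnorm(100), 0.5, 600, fs), "low_hz")
})

test_that("filtering twice changes an in-band sine by less than 5%", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  y1 <- bandpass_filter(sin(2 * pi * 10 * t), 0.5, 20, fs)
  y2 <- bandpass_filter(y1, 0.5, 20, fs)
  a1 <- max(abs(y1[2000:3000]))
  a2 <- max(abs(y2[2000:3000]))
  expect_lt(abs(a2 / a1 - 1), 0.05)
})

test_that("R-wave detection recovers synthetic spike trains without extras", {
  expect_identical(detect_r_waves(rep(0, 2000), 1000), integer(0))
  beats <- synth_dataset(15, 0.5, "separable", seed = 8L)
  cb <- concat_beats(beats)
  r <- detect_r_waves(cb$recording$ecg, cb$recording$fs_hz)
  expect_identical(length(r), 15L)
  expect_true(all(abs(r - cb$r_indices) <= 5))
})

test_that("the refractory period keeps only the first of two close identical peaks", {
  fs <- 1000
  x <- numeric(1500)
  x[300 + (-3:3)] <- c(0.2, 0.5, 0.9, 1, 0.9, 0.5, 0.2)
  x[500 + (-3:3)] <- c(0.2, 0.5, 0.9, 1, 0.9, 0.5, 0.2)  # 200 ms later
  r <- detect_r_waves(x, fs, refractory_ms = 250)
  expect_identical(r, 300L)
})

test_that("beat segmentation keeps fitting windows, discards short RR, and is bit-faithful", {
  beats <- synth_dataset(10, 0.5, "separable", seed = 9L)
  cb <- concat_beats(beats)
  seg <- segment_beats(cb$recording, cb$r_indices)
  expect_identical(length(seg$beats), 10L)
  expect_identical(seg$n_discarded, 0L)
  for (i in c(1L, 5L, 10L)) {
    expect_identical(seg$beats[[i]]$channels$bcg, beats[[i]]$channels$bcg)
    expect_identical(seg$beats[[i]]$channels$ecg, beats[[i]]$channels$ecg)
  }
  # short RR intervals are dropped and counted
  rec <- recording(rnorm(3000), rnorm(3000), rnorm(3000))
  seg2 <- segment_beats(rec, c(1L, 401L, 1000L, 2900L))
  # RR(1->2) = 400 < 448 discarded; beat at 2900 does not fit the end
  expect_identical(seg2$n_discarded, 2L)
  expect_identical(length(seg2$beats), 2L)
  expect_identical(length(seg2$beats) + seg2$n_discarded, 4L)
  # all 800-ms RR windows fit, including the last one
  rec3 <- recording(rnorm(8000), rnorm(8000), rnorm(8000))
  r10 <- seq(1L, by = 800L, length.out = 10L)
  seg3 <- segment_beats(rec3, r10)
  expect_identical(length(seg3$beats), 10L)
})

test_that("the intersecting tangent foot matches its geometric construction", {
  fs <- 1000
  # flat at 0 through t = 200 ms then a linear rise of 1 per ms: the
  # rise extrapolates to zero exactly at the 200-ms sample
  x <- c(rep(0, 201), 1:247)
  det <- detect_ppg_foot(x, fs)
  expect_false(det$flagged)
  expect_equal(det$t_ms, 200)
  # pure ramp from the window start: foot at the first sample
  det2 <- detect_ppg_foot(as.numeric(0:447), fs)
  expect_equal(det2$t_ms, 0)
  # flat beat is flagged, not an error
  det3 <- detect_ppg_foot(rep(1, 448), fs)
  expect_true(det3$flagged)
  expect_true(is.na(det3$index))
})

test_that("foot detection is invariant to amplitude scaling", {
  b <- synth_beat(beat_sim_params(ppg_foot_ms = 260, noise_sd_mg = 0,
                                  seed = 6L))
  f1 <- detect_ppg_foot(b$channels$ppg, 1000)
  f2 <- detect_ppg_foot(b$channels$ppg * 37.5, 1000)
  expect_equal(f1$t_ms, f2$t_ms)
  expect_identical(f1$index, f2$index)
})

test_that("recording construction enforces equal channel lengths", {
  expect_error(recording(rnorm(10), rnorm(9), rnorm(10)), "equal length")
})
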