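test_that("white noise has standard-normal statistics and is reproducible", {
  stim <- generate_white_noise(1e5, 60, seed = 1)
  expect_length(stim$values, 1e5)
  expect_lt(abs(mean(stim$values)), 0.02)
  expect_gt(sd(stim$values), 0.98)
  expect_lt(sd(stim$values), 1.02)
  again <- generate_white_noise(1e5, 60, seed = 1)
  expect_identical(stim$values, again$values)
  other <- generate_white_noise(1e5, 60, seed = 2)
  expect_false(identical(stim$values, other$values))
  # distribution check against the standard normal
  ks <- suppressWarnings(ks.test(stim$values, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate and invalid white-noise arguments are handled", {
  one <- generate_white_noise(1, 60, seed = 0)
  expect_length(one$values, 1L)
  expect_true(is.finite(one$values))
  expect_identical(nrow(one$segments), 1L)
  expect_error(generate_white_noise(0, 60), "positive")
  expect_error(generate_white_noise(10, -1), "positive")
})

test_that("frozen-repeat schedules interleave identical test segments", {
  built <- build_schedule(750, 150, 4, "frozen_repeat", 30, seed = 7)
  expect_length(built$stim$values, 3600L)
  sched <- built$schedule
  expect_identical(nrow(sched$test_intervals), 4L)
  expect_true(all(sched$test_intervals$end - sched$test_intervals$start ==
                    150L))
  segs <- lapply(seq_len(4), function(i) {
    idx <- (sched$test_intervals$start[i] + 1):sched$test_intervals$end[i]
    built$stim$values[idx]
  })
  for (i in 2:4) expect_identical(segs[[i]], segs[[1]])
  # training noise is fresh between blocks
  tr1 <- built$stim$values[1:750]
  tr2 <- built$stim$values[901:1650]
  expect_false(identical(tr1, tr2))
  # intervals cover the trace without overlap
  mask_train <- suppfilt:::intervals_to_mask(sched$train_intervals, 3600L)
  mask_test <- suppfilt:::intervals_to_mask(sched$test_intervals, 3600L)
  expect_true(all(xor(mask_train, mask_test)))
})

test_that("pseudo-trial schedules hold out the final fifth of each trial", {
  built <- build_schedule(1600, 400, 3, "pseudo_trial", 60, seed = 1)
  sched <- built$schedule
  expect_length(built$stim$values, 6000L)
  expect_identical(sched$n_repeats, 1L)
  expect_true(all(sched$test_intervals$end - sched$test_intervals$start ==
                    400L))
  expect_equal(sum(sched$test_intervals$end - sched$test_intervals$start) /
                 length(built$stim$values), 1 / 5)
  # test segments are not repeats of each other
  s1 <- built$stim$values[1601:2000]
  s2 <- built$stim$values[3601:4000]
  expect_false(identical(s1, s2))
})

test_that("degenerate schedules and warnings behave as specified", {
  built <- build_schedule(100, 50, 1, "frozen_repeat", 60, seed = 1)
  expect_identical(nrow(built$schedule$train_intervals), 1L)
  expect_identical(nrow(built$schedule$test_intervals), 1L)
  expect_warning(build_schedule(100, 100, 2, "frozen_repeat", 60, seed = 1),
                 "at least as long")
})

test_that("chirp structure matches the standard segment plan at 60 Hz", {
  chirp <- generate_chirp(60)
  expect_length(chirp$values, 1380L)
  expect_identical(chirp$segments$end - chirp$segments$start,
                   c(120L, 60L, 60L, 60L, 480L, 60L, 480L, 60L))
  ctmu <- attr(chirp, "contrast_to_model_units")
  # steps at +/-100% contrast; background at mean luminance
  expect_equal(unique(chirp$values[suppfilt:::segment_frames(chirp, "step_on")]),
               ctmu)
  expect_equal(unique(chirp$values[suppfilt:::segment_frames(chirp, "step_off")]),
               -ctmu)
  for (i in which(chirp$segments$label == "background")) {
    idx <- (chirp$segments$start[i] + 1):chirp$segments$end[i]
    expect_true(all(chirp$values[idx] == 0))
  }
})

test_that("sweep endpoints and phase continuity hold", {
  # instantaneous frequency ramps 0 -> 15 Hz across the sweep samples
  expect_equal(chirp_sweep_axis(480, "frequency")[1], 0)
  expect_equal(chirp_sweep_axis(480, "frequency")[480], 15)
  expect_equal(chirp_sweep_axis(480, "contrast")[480], 100)
  chirp <- generate_chirp(60)
  ctmu <- attr(chirp, "contrast_to_model_units")
  fs <- chirp$values[suppfilt:::segment_frames(chirp, "frequency_sweep")] / ctmu
  cs <- chirp$values[suppfilt:::segment_frames(chirp, "contrast_sweep")] / ctmu
  # contrast never exceeds 100% before unit conversion
  expect_lte(max(abs(fs)), 1 + 1e-12)
  expect_lte(max(abs(cs)), 1 + 1e-12)
  expect_equal(fs[1], 0)
  expect_equal(cs[1], 0)
  # contrast-sweep envelope reaches 100% at the final sample: the envelope
  # at the last frame is 1, so the value equals sin at the 4 Hz phase there
  t_end <- 479 / 60
  expect_equal(cs[480], sin(2 * pi * 4 * t_end), tolerance = 1e-12)
  # frequency-sweep phase is continuous: per-frame phase step stays below
  # 2*pi*15/frame_rate
  phase <- 2 * pi * (15 / (2 * t_end)) * ((0:479) / 60)^2
  expect_lte(max(diff(phase)), 2 * pi * 15 / 60 + 1e-9)
})

test_that("chirp scales with frame rate and contrast conversion", {
  chirp30 <- generate_chirp(30, contrast_to_model_units = 1)
  expect_length(chirp30$values, 690L)
  expect_equal(max(chirp30$values), 1, tolerance = 1e-9)
})
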