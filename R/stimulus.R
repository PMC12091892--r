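#' Stimulus trace
#'
#' A full-field stimulus as one real value per display frame, in model input
#' units (0 corresponds to mean luminance; white-noise training stimuli are
#' standard normal, i.e. unit SD corresponds to 30% Michelson contrast).
#' Frames are indexed 0-based and segments are half-open `[start, end)`
#' frame intervals.
#'
#' @param values numeric vector, one value per frame; must be finite.
#' @param frame_rate_hz display update rate in Hz (> 0). Common presets are
#'   60 (mouse, marmoset) and 30 (axolotl).
#' @param segments `data.frame` with columns `label`, `start`, `end`
#'   describing non-overlapping half-open frame intervals within
#'   `[0, length(values))`. Defaults to a single unnamed segment.
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(values, frame_rate_hz,
                           segments = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop_invalid("a stimulus needs at least 1 frame")
  if (!all(is.finite(values))) stop_invalid("stimulus values must be finite")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop_invalid("frame_rate_hz must be a single positive number")
  }
  n <- length(values)
  if (is.null(segments)) {
    segments <- data.frame(label = "stimulus", start = 0L, end = n,
                           stringsAsFactors = FALSE)
  }
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (any(segments$start < 0L) || any(segments$end > n) ||
      any(segments$start >= segments$end)) {
    stop_invalid("segments must be non-empty half-open intervals in [0, %d)", n)
  }
  o <- order(segments$start)
  so <- segments[o, , drop = FALSE]
  if (nrow(so) > 1L && any(so$start[-1L] < so$end[-nrow(so)])) {
    stop_invalid("segments must not overlap")
  }
  structure(list(values = values,
                 frame_rate_hz = as.numeric(frame_rate_hz),
                 segments = segments),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %d frames at %g Hz (%.2f s)\n",
              length(x$values), x$frame_rate_hz,
              length(x$values) / x$frame_rate_hz))
  for (i in seq_len(nrow(x$segments))) {
    cat(sprintf("  %-16s [%6d, %6d)\n", x$segments$label[i],
                x$segments$start[i], x$segments$end[i]))
  }
  invisible(x)
}

# Accept a stimulus_trace or a bare numeric vector.
stim_values <- function(stim) {
  if (inherits(stim, "stimulus_trace")) stim$values else as.numeric(stim)
}

#' Generate Gaussian white-noise flicker
#'
#' Draws one intensity value per frame from a standard normal distribution
#' (zero mean, unit SD), the convention used for model fitting: zero is mean
#' luminance and one SD corresponds to 30% contrast.
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_rate_hz display update rate in Hz.
#' @param seed integer seed; the same seed reproduces the same trace.
#' @return A [stimulus_trace()] with a single `"white_noise"` segment.
#' @export
generate_white_noise <- function(n_frames, frame_rate_hz = 60, seed = 1) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1) {
    stop_invalid("n_frames must be a positive integer")
  }
  n_frames <- as.integer(n_frames)
  values <- with_seed(seed, stats::rnorm(n_frames))
  stimulus_trace(values, frame_rate_hz,
                 data.frame(label = "white_noise", start = 0L, end = n_frames,
                            stringsAsFactors = FALSE))
}

#' Train/test schedule
#'
#' Partition of a recording into training and held-out test intervals.
#' `frozen_repeat` mode marks the repeated frozen-noise insertions as test
#' data; `pseudo_trial` mode marks the final fifth (in general, the final
#' `n_frozen` frames) of each pseudo-trial.
#'
#' @param train_intervals,test_intervals data.frames of half-open 0-based
#'   frame intervals (`start`, `end`).
#' @param test_mode `"frozen_repeat"` or `"pseudo_trial"`.
#' @param n_repeats number of frozen repeats (1 for pseudo-trial mode).
#' @return An object of class `train_test_schedule`.
#' @export
train_test_schedule <- function(train_intervals, test_intervals,
                                test_mode = c("frozen_repeat", "pseudo_trial"),
                                n_repeats = 1L) {
  test_mode <- match.arg(test_mode)
  if (test_mode == "frozen_repeat") {
    len <- test_intervals$end - test_intervals$start
    if (length(unique(len)) > 1L) {
      stop_invalid("frozen-repeat test intervals must all have equal length")
    }
  }
  structure(list(train_intervals = train_intervals,
                 test_intervals = test_intervals,
                 test_mode = test_mode,
                 n_repeats = as.integer(n_repeats)),
            class = "train_test_schedule")
}

#' @export
print.train_test_schedule <- function(x, ...) {
  cat(sprintf("<train_test_schedule> mode=%s, %d train / %d test intervals",
              x$test_mode, nrow(x$train_intervals), nrow(x$test_intervals)),
      sprintf("(%d repeats)\n", x$n_repeats))
  invisible(x)
}

#' Build a white-noise recording schedule
#'
#' Emulates the two recording designs used for model fitting: in
#' `frozen_repeat` mode an identical frozen white-noise segment of
#' `n_frozen` frames is inserted after every `n_train_block` frames of fresh
#' noise, repeated `n_blocks` times; in `pseudo_trial` mode the recording is
#' fresh noise throughout and the final `n_frozen` frames of each
#' `n_train_block + n_frozen`-frame pseudo-trial are held out for testing.
#'
#' @param n_train_block frames of fresh training noise per block (>= 1).
#' @param n_frozen frames of frozen/test noise per block (>= 1).
#' @param n_blocks number of blocks (>= 1).
#' @param mode `"frozen_repeat"` or `"pseudo_trial"`.
#' @param frame_rate_hz display update rate in Hz.
#' @param seed integer seed for the noise draws.
#' @return list with elements `stim` ([stimulus_trace()]) and `schedule`
#'   ([train_test_schedule()]).
#' @export
build_schedule <- function(n_train_block, n_frozen, n_blocks,
                           mode = c("frozen_repeat", "pseudo_trial"),
                           frame_rate_hz = 60, seed = 1) {
  mode <- match.arg(mode)
  if (n_train_block < 1 || n_frozen < 1 || n_blocks < 1) {
    stop_invalid("block sizes and n_blocks must be >= 1")
  }
  n_train_block <- as.integer(n_train_block)
  n_frozen <- as.integer(n_frozen)
  n_blocks <- as.integer(n_blocks)
  if (n_frozen >= n_train_block) {
    warning("test block is at least as long as the training block",
            call. = FALSE)
  }
  block_len <- n_train_block + n_frozen
  n_total <- block_len * n_blocks
  values <- with_seed(seed, {
    if (mode == "frozen_repeat") {
      frozen <- stats::rnorm(n_frozen)
      unlist(lapply(seq_len(n_blocks), function(b) {
        c(stats::rnorm(n_train_block), frozen)
      }))
    } else {
      stats::rnorm(n_total)
    }
  })
  starts <- (seq_len(n_blocks) - 1L) * block_len
  train <- make_intervals(starts, starts + n_train_block)
  test <- make_intervals(starts + n_train_block, starts + block_len)
  seg <- data.frame(
    label = rep(c("train", "test"), n_blocks),
    start = as.vector(rbind(train$start, test$start)),
    end = as.vector(rbind(train$end, test$end)),
    stringsAsFactors = FALSE)
  stim <- stimulus_trace(values, frame_rate_hz, seg)
  sched <- train_test_schedule(train, test, test_mode = mode,
                               n_repeats = if (mode == "frozen_repeat")
                                 n_blocks else 1L)
  list(stim = stim, schedule = sched)
}

# Chirp segment plan in seconds; frame counts are round(sec * rate).
chirp_plan <- function() {
  data.frame(
    label = c("background", "step_on", "step_off", "background",
              "frequency_sweep", "background", "contrast_sweep", "background"),
    seconds = c(2, 1, 1, 1, 8, 1, 8, 1),
    stringsAsFactors = FALSE)
}

#' Generate the chirp stimulus
#'
#' Full-field chirp: background (mean luminance), a +100% contrast ON step
#' and a -100% OFF step of 1 s each, a sinusoidal frequency sweep whose
#' instantaneous frequency ramps linearly from 0 to 15 Hz over 8 s at 100%
#' contrast, and a sinusoidal contrast sweep at 4 Hz whose envelope ramps
#' linearly from 0% to 100% contrast over 8 s, with 1-2 s background
#' periods in between.  At 60 Hz the segment lengths are
#' 120/60/60/60/480/60/480/60 frames (1380 frames, 23 s).
#'
#' Contrast (1 = 100%) is converted to model input units by
#' `contrast_to_model_units`; the default 1/0.3 reflects the white-noise
#' training convention that one model unit equals 30% contrast.
#'
#' @param frame_rate_hz display update rate in Hz.
#' @param contrast_to_model_units model input units per unit (100%) contrast.
#' @return A [stimulus_trace()] with labelled segments.
#' @export
generate_chirp <- function(frame_rate_hz = 60,
                           contrast_to_model_units = 1 / 0.3) {
  if (frame_rate_hz <= 0) stop_invalid("frame_rate_hz must be positive")
  plan <- chirp_plan()
  plan$n <- as.integer(round(plan$seconds * frame_rate_hz))
  pieces <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    n <- plan$n[i]
    pieces[[i]] <- switch(
      plan$label[i],
      background = rep(0, n),
      step_on = rep(1, n),
      step_off = rep(-1, n),
      frequency_sweep = chirp_sweep_values(n, frame_rate_hz, "frequency"),
      contrast_sweep = chirp_sweep_values(n, frame_rate_hz, "contrast"))
  }
  values <- unlist(pieces) * contrast_to_model_units
  ends <- cumsum(plan$n)
  seg <- data.frame(label = plan$label,
                    start = c(0L, ends[-length(ends)]),
                    end = ends,
                    stringsAsFactors = FALSE)
  stim <- stimulus_trace(values, frame_rate_hz, seg)
  attr(stim, "contrast_to_model_units") <- contrast_to_model_units
  stim
}

# Sweep sample values in contrast units (1 = 100%).  The sweep parameter
# (instantaneous frequency, or contrast envelope) ramps linearly from 0 at
# the first sampled frame to its maximum at the last sampled frame.
chirp_sweep_values <- function(n, frame_rate_hz, type = c("frequency",
                                                          "contrast")) {
  type <- match.arg(type)
  t <- (seq_len(n) - 1L) / frame_rate_hz
  t_end <- (n - 1L) / frame_rate_hz
  if (type == "frequency") {
    # linear chirp: phi(t) = 2*pi * (f_max / (2*T)) * t^2, sine from phase 0
    f_max <- 15
    sin(2 * pi * (f_max / (2 * t_end)) * t^2)
  } else {
    f <- 4
    (t / t_end) * sin(2 * pi * f * t)
  }
}

#' Per-frame axis values for a chirp sweep
#'
#' For a frequency sweep of `n_frames` frames, the instantaneous frequency
#' in Hz at each frame; for a contrast sweep, the envelope contrast in
#' percent at each frame.  Both ramp linearly from 0 at the first frame to
#' their maximum (15 Hz / 100%) at the last frame.
#'
#' @param n_frames number of frames in the sweep segment.
#' @param sweep `"frequency"` or `"contrast"`.
#' @return numeric vector of length `n_frames`.
#' @export
chirp_sweep_axis <- function(n_frames, sweep = c("frequency", "contrast")) {
  sweep <- match.arg(sweep)
  u <- (seq_len(n_frames) - 1L) / (n_frames - 1L)
  if (sweep == "frequency") 15 * u else 100 * u
}

# Extract the frame index range (1-based) of the first segment with `label`.
segment_frames <- function(stim, label) {
  seg <- stim$segments[stim$segments$label == label, , drop = FALSE]
  if (nrow(seg) == 0L) stop_invalid("no segment labelled '%s'", label)
  (seg$start[1L] + 1L):seg$end[1L]
}
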