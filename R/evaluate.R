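# Evaluation drivers: apply the per-bin metrics to a recording with a
# train/test schedule, and to repeated chirp trials.

schedule_masks <- function(schedule, n, n_taps) {
  base <- default_valid(n, n_taps)
  list(train = base & intervals_to_mask(schedule$train_intervals, n),
       test = base & intervals_to_mask(schedule$test_intervals, n))
}

# Trial-average a per-bin vector over the (equal-length) frozen-test
# intervals: one row per repeat.
frozen_matrix <- function(v, schedule) {
  t(vapply(seq_len(nrow(schedule$test_intervals)), function(i) {
    a <- schedule$test_intervals$start[i]
    b <- schedule$test_intervals$end[i]
    v[(a + 1L):b]
  }, numeric(schedule$test_intervals$end[1L] -
               schedule$test_intervals$start[1L])))
}

#' Evaluate a fitted model on a scheduled recording
#'
#' Computes training and held-out information per spike and, when the
#' schedule carries frozen-noise repeats, the Poisson explained variance of
#' the predicted PSTH.  Stimulus-driven kinds are evaluated from a single
#' deterministic forward pass; the feedback kind is averaged over
#' `n_eval_feedback` free-running evaluations (its rate depends on its own
#' sampled spikes).
#'
#' @param model an [encoding_model()] or [fit_model()] result.
#' @param stim stimulus trace.
#' @param counts observed spike counts per bin.
#' @param schedule a [train_test_schedule()]; `NULL` evaluates all valid
#'   bins as both train and test.
#' @param n_eval_feedback stochastic evaluations for the feedback kind.
#' @param seed integer seed (feedback evaluation only).
#' @return list with `info_train`, `info_test`, `pev_test` (NA without
#'   frozen repeats), `psth_obs`, `psth_pred` (frozen mode only).
#' @export
evaluate_model <- function(model, stim, counts, schedule = NULL,
                           n_eval_feedback = 100L, seed = 1) {
  if (inherits(model, "fit_result")) model <- model$model
  x <- stim_values(stim)
  n <- length(x)
  if (is.null(schedule)) {
    base <- default_valid(n, model$n_taps)
    masks <- list(train = base, test = base)
  } else {
    masks <- schedule_masks(schedule, n, model$n_taps)
  }
  frozen <- !is.null(schedule) && schedule$test_mode == "frozen_repeat" &&
    schedule$n_repeats > 1L

  if (model$kind != "feedback") {
    rate <- forward(model, x)
    info_train <- info_per_spike(counts, rate, masks$train)
    info_test <- info_per_spike(counts, rate, masks$test)
    pred_for_psth <- rate
  } else {
    rates <- lapply(seq_len(n_eval_feedback), function(i) {
      simulate_spikes(model, x, seed = derive_seed(seed, i))$rate
    })
    info_train <- mean(vapply(rates, function(r)
      info_per_spike(counts, r, masks$train), numeric(1)))
    info_test <- mean(vapply(rates, function(r)
      info_per_spike(counts, r, masks$test), numeric(1)))
    pred_for_psth <- Reduce(`+`, rates) / length(rates)
  }

  out <- list(info_train = info_train, info_test = info_test,
              pev_test = NA_real_)
  if (frozen) {
    psth_obs <- colMeans(frozen_matrix(counts, schedule))
    psth_pred <- colMeans(frozen_matrix(pred_for_psth, schedule))
    out$pev_test <- poisson_explained_variance(psth_obs, psth_pred)
    out$psth_obs <- psth_obs
    out$psth_pred <- psth_pred
  }
  out
}

#' Sliding-window generalization profile on a chirp sweep
#'
#' Predicts the response to the chirp stimulus with a model trained on
#' white noise, averages the observed chirp trials into a PSTH, and
#' computes the sliding-window R squared along the requested sweep, with
#' the window axis in contrast percent or instantaneous frequency (Hz).
#'
#' @param model an [encoding_model()] or [fit_model()] result.
#' @param chirp_stim chirp [stimulus_trace()] (from [generate_chirp()]).
#' @param trial_counts trial-by-bin spike count matrix over the chirp.
#' @param sweep `"contrast"` or `"frequency"`.
#' @param window_ms analysis window duration in milliseconds.
#' @param n_eval_feedback free-running passes used to average the feedback
#'   kind's prediction.
#' @param seed integer seed (feedback kind only).
#' @return a `window_profile` data.frame (see [sliding_window_r2()]).
#' @export
evaluate_chirp <- function(model, chirp_stim, trial_counts,
                           sweep = c("contrast", "frequency"),
                           window_ms = 150, n_eval_feedback = 20L,
                           seed = 1) {
  sweep <- match.arg(sweep)
  if (inherits(model, "fit_result")) model <- model$model
  psth <- colMeans(trial_counts)
  pred <- if (model$kind != "feedback") {
    forward(model, chirp_stim)
  } else {
    rates <- lapply(seq_len(n_eval_feedback), function(i) {
      simulate_spikes(model, chirp_stim, seed = derive_seed(seed, i))$rate
    })
    Reduce(`+`, rates) / length(rates)
  }
  idx <- segment_frames(chirp_stim, paste0(sweep, "_sweep"))
  axis <- chirp_sweep_axis(length(idx), sweep)
  sliding_window_r2(psth[idx], pred[idx], axis,
                    frame_rate_hz = chirp_stim$frame_rate_hz,
                    window_ms = window_ms)
}
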