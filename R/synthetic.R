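# Ground-truth cell factory: parametric model cells emulating the fitted
# component shapes seen in retinal data (biphasic temporal filters;
# suppressive filters that are delayed copies of the excitatory filter),
# used to validate every fitting and evaluation path end to end.

# Biphasic temporal filter as a difference of two gamma kernels; tau-order
# (tap 1 = current frame), peak latency in frames.
biphasic_filter <- function(n_taps, t_peak = 3, t_trough = 5.5,
                            trough_gain = 0.7, polarity = c("on", "off")) {
  polarity <- match.arg(polarity)
  tau <- seq_len(n_taps) - 1
  gam <- function(tp, p = 4) {
    g <- (tau / tp)^p * exp(-p * (tau / tp - 1))
    g / max(g)
  }
  k <- gam(t_peak) - trough_gain * gam(t_trough)
  if (polarity == "off") k <- -k
  project_filter(k)
}

# Shift a filter later in time by d frames (delayed suppression), then
# re-project onto the constraint set.
delayed_copy <- function(taps, d) {
  n <- length(taps)
  project_filter(c(rep(0, d), taps[seq_len(n - d)]))
}

synthetic_presets <- function() {
  data.frame(
    name = c("ln_on", "ln_off", "subtractive_off", "divisive_off",
             "feedback_off"),
    kind = c("ln", "ln", "subtractive", "divisive", "feedback"),
    polarity = c("on", "off", "off", "off", "off"),
    sup_delay = c(NA, NA, NA, 2L, NA),
    stringsAsFactors = FALSE)
}

#' Make a synthetic ground-truth cell
#'
#' Builds a constraint-satisfying encoding model from a named preset.  The
#' excitatory filter is a biphasic difference-of-gammas kernel.  The
#' divisive preset's suppressive filter is a copy of the excitatory filter
#' delayed by `sup_delay` frames (2 by default), the configuration
#' typically recovered from fast retinal cells; the subtractive preset
#' uses a kinetically slower, independent suppressive filter with branch
#' nonlinearities of opposite curvature (see the methods vignette for the
#' identifiability rationale); the feedback preset uses a slow, moderate
#' spike-history kernel resembling spike-frequency adaptation.  The
#' rectifier offset `b` is calibrated so that the mean firing rate on
#' white noise matches `target_rate_hz` within a few percent.
#'
#' Presets: `ln_on`, `ln_off` (LN cells), `subtractive_off`,
#' `divisive_off`, `feedback_off`.
#'
#' @param preset preset name (see above).
#' @param n_taps filter length in frames.
#' @param frame_rate_hz stimulus update rate in Hz.
#' @param target_rate_hz mean firing rate to calibrate to (sp/s).
#' @param sup_delay suppressive-filter delay in frames (overrides the
#'   preset default).
#' @param seed integer seed (used by the calibration simulation).
#' @return an [encoding_model()] with attribute `"preset"`.
#' @export
make_cell <- function(preset, n_taps = 15L, frame_rate_hz = 60,
                      target_rate_hz = 10, sup_delay = NULL, seed = 1) {
  presets <- synthetic_presets()
  row <- presets[presets$name == preset, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop_invalid("unknown preset '%s' (available: %s)", preset,
                 paste(presets$name, collapse = ", "))
  }
  kind <- row$kind
  exc_taps <- biphasic_filter(n_taps, polarity = row$polarity)
  knots <- tent_knots()
  # rectifying excitatory nonlinearity, as observed in ganglion cells
  exc_nl <- tent_nonlinearity(pmax(0.5 * softplus(2.5 * (knots - 0.5)),
                                   WEIGHT_FLOOR),
                              "monotone", knots)
  sup_taps <- NULL; sup_nl <- NULL; fb_taps <- NULL
  if (kind == "subtractive") {
    # a slower, kinetically distinct suppressive filter with branch
    # nonlinearities of opposite curvature (strongly convex excitation,
    # saturating suppression): two-branch additive decompositions are only
    # identifiable when the branch nonlinearities are far from quadratic,
    # otherwise filter pairs can rotate along a near-flat likelihood ridge
    sup_taps <- biphasic_filter(n_taps, t_peak = 6, t_trough = 10,
                                polarity = row$polarity)
    exc_nl <- tent_nonlinearity(pmax(0.10 * exp(1.4 * knots), WEIGHT_FLOOR),
                                "monotone", knots)
    sup_nl <- tent_nonlinearity(pmax(3.2 * stats::plogis(2.2 * (knots - 0.2)),
                                     WEIGHT_FLOOR),
                                "monotone", knots)
  } else if (kind == "divisive") {
    d <- if (is.null(sup_delay)) row$sup_delay else as.integer(sup_delay)
    sup_taps <- delayed_copy(exc_taps, d)
    sup_nl <- tent_nonlinearity(pmax(exp(-knots^2 / 2), WEIGHT_FLOOR),
                                "bump", knots)   # unit-variance bump
  } else if (kind == "feedback") {
    # spike-frequency-adaptation-like history kernel: moderate amplitude,
    # slow decay (the per-bin variance of the feedback signal scales with
    # sum(k^2), its stimulus-locked structure with sum(k))
    fb_taps <- project_tail(-0.3 * exp(-(seq_len(n_taps) - 1) / 5))
  }
  model <- encoding_model(kind, exc_taps, exc_nl, sup_taps, sup_nl, fb_taps,
                          softplus_rectifier(a = 1.5, b = 0, c = 0, m = 0.5),
                          frame_rate_hz)
  model <- calibrate_rate(model, target_rate_hz, seed = seed)
  attr(model, "preset") <- preset
  model
}

# Calibrate the rectifier offset b so the mean white-noise firing rate hits
# the target (root finding on b; the rate is monotone in b).
calibrate_rate <- function(model, target_rate_hz, seed = 1,
                           n_calib = 10000L) {
  target <- target_rate_hz / model$frame_rate_hz
  calib <- generate_white_noise(n_calib, model$frame_rate_hz,
                                seed = derive_seed(seed, 9901))
  mean_rate <- function(b) {
    m <- model
    m$rectifier$b <- b
    r <- if (m$kind == "feedback") {
      simulate_spikes(m, calib, seed = derive_seed(seed, 9902))$rate
    } else {
      forward(m, calib)
    }
    mean(r[default_valid(n_calib, m$n_taps)]) - target
  }
  root <- tryCatch(
    stats::uniroot(mean_rate, interval = c(-25, 10), tol = 1e-3),
    error = function(e) {
      stop_invalid("rate calibration failed: %s", conditionMessage(e))
    })
  model$rectifier$b <- root$root
  achieved <- (mean_rate(root$root) + target) * model$frame_rate_hz
  if (abs(achieved - target_rate_hz) > 0.1 * target_rate_hz) {
    stop_invalid("rate calibration missed the target (%.2f vs %.2f sp/s)",
                 achieved, target_rate_hz)
  }
  model
}

#' Simulate a white-noise recording from a model cell
#'
#' Generates the stimulus/response pair that the fitting and evaluation
#' paths consume: a white-noise recording with either interleaved
#' frozen-noise repeats or pseudo-trials (see [build_schedule()]), spikes
#' sampled from the cell (sequentially for a feedback cell), and optionally
#' repeated chirp trials.
#'
#' @param cell an [encoding_model()] (e.g. from [make_cell()]).
#' @param n_train_block,n_frozen,n_blocks,mode schedule layout; the default
#'   gives 18,000 training and 3,600 frozen-test bins at 60 Hz (about 5 + 1
#'   minutes).
#' @param chirp_trials number of repeated chirp trials to simulate (0 for
#'   none).
#' @param contrast_to_model_units chirp unit conversion (see
#'   [generate_chirp()]).
#' @param seed integer seed; stimulus and spike draws use derived seeds.
#' @return list of class `recording`: `cell`, `stim`, `counts`,
#'   `schedule`, and (when requested) `chirp_stim` plus a
#'   `chirp_counts` trial-by-bin matrix.
#' @export
simulate_recording <- function(cell, n_train_block = 1500L, n_frozen = 300L,
                               n_blocks = 12L,
                               mode = c("frozen_repeat", "pseudo_trial"),
                               chirp_trials = 0L,
                               contrast_to_model_units = 1 / 0.3,
                               seed = 1) {
  mode <- match.arg(mode)
  built <- build_schedule(n_train_block, n_frozen, n_blocks, mode,
                          frame_rate_hz = cell$frame_rate_hz,
                          seed = derive_seed(seed, 1L))
  counts <- simulate_spikes(cell, built$stim, seed = derive_seed(seed, 2L))$counts
  out <- list(cell = cell, stim = built$stim, counts = counts,
              schedule = built$schedule)
  if (chirp_trials > 0L) {
    cstim <- generate_chirp(cell$frame_rate_hz, contrast_to_model_units)
    trials <- t(vapply(seq_len(chirp_trials), function(i) {
      simulate_spikes(cell, cstim, seed = derive_seed(seed, 100L + i))$counts
    }, numeric(length(cstim$values))))
    out$chirp_stim <- cstim
    out$chirp_counts <- trials
  }
  class(out) <- "recording"
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s cell, %d bins (%s), %d chirp trials\n",
              x$cell$kind, length(x$counts), x$schedule$test_mode,
              if (is.null(x$chirp_counts)) 0L else nrow(x$chirp_counts)))
  invisible(x)
}

#' Compare a fitted model against its generating cell
#'
#' Reports sign-aligned cosine similarities between matched filters (a
#' sign flip of a filter is absorbed by its nonlinearity, so similarity is
#' reported as `|cos|`), held-out information per spike for the truth and
#' the fitted model, and a constraint audit of the fitted model.
#'
#' @param truth the generating [encoding_model()].
#' @param fitted the fitted [encoding_model()].
#' @param stim,counts,schedule held-out evaluation data (see
#'   [simulate_recording()]).
#' @param n_eval_feedback stochastic evaluations for feedback models.
#' @param seed integer seed.
#' @return list with `cos_exc`, `cos_sup` (NA when either model lacks the
#'   branch), `info_truth`, `info_fitted`, `info_gap`, and
#'   `constraints_ok`.
#' @export
recovery_report <- function(truth, fitted, stim, counts, schedule = NULL,
                            n_eval_feedback = 100L, seed = 1) {
  aligned_cos <- function(a, b) {
    abs(sum(a * b) / (filter_norm(a) * filter_norm(b)))
  }
  cos_exc <- aligned_cos(truth$exc$taps, fitted$exc$taps)
  cos_sup <- if (!is.null(truth$sup) && !is.null(fitted$sup)) {
    aligned_cos(truth$sup$taps, fitted$sup$taps)
  } else NA_real_
  ev_truth <- evaluate_model(truth, stim, counts, schedule,
                             n_eval_feedback = n_eval_feedback, seed = seed)
  ev_fit <- evaluate_model(fitted, stim, counts, schedule,
                           n_eval_feedback = n_eval_feedback,
                           seed = derive_seed(seed, 2L))
  ok <- tryCatch({ validate_model(fitted); TRUE },
                 error = function(e) FALSE)
  list(cos_exc = cos_exc, cos_sup = cos_sup,
       info_truth = ev_truth$info_test, info_fitted = ev_fit$info_test,
       info_gap = ev_truth$info_test - ev_fit$info_test,
       constraints_ok = ok)
}
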