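#' Information per spike
#'
#' Log-likelihood gain of the model prediction over a constant mean-rate
#' predictor, normalized by the total spike count and converted to bits:
#' `(LL(counts, pred) - LL(counts, mean)) / (total spikes * ln 2)`.  The
#' mean rate is the mean of `counts` over the same bins.  Values can be
#' negative on short samples and are not clipped.
#'
#' @param counts observed spike counts per bin.
#' @param rate_pred predicted expected counts per bin.
#' @param valid optional logical mask of bins to evaluate.
#' @return information per spike in bits/spike.
#' @export
info_per_spike <- function(counts, rate_pred, valid = NULL) {
  if (length(counts) != length(rate_pred)) {
    stop_invalid("counts and rate_pred must have equal length")
  }
  if (is.null(valid)) valid <- rep(TRUE, length(counts))
  n_spikes <- sum(counts[valid])
  if (n_spikes < 1) stop_invalid("information per spike undefined without spikes")
  mean_rate <- rep(mean(counts[valid]), length(counts))
  ll_model <- -negative_log_likelihood(rate_pred, counts, valid)
  ll_mean <- -negative_log_likelihood(mean_rate, counts, valid)
  (ll_model - ll_mean) / (n_spikes * log(2))
}

#' Information per spike for the feedback model
#'
#' The feedback model's rate depends on its own stochastically generated
#' spikes, so its performance is averaged across `n_eval` free-running
#' evaluations, each sampling a fresh spike trajectory (with a seed derived
#' from `seed`) and scoring the resulting rate against the observed counts.
#'
#' @param model a feedback-kind [encoding_model()].
#' @param stim stimulus trace or numeric vector.
#' @param counts observed spike counts per bin.
#' @param n_eval number of stochastic evaluations (default 100).
#' @param seed integer seed.
#' @param valid optional logical mask of bins to evaluate.
#' @return mean information per spike in bits/spike, with attribute
#'   `"per_eval"` holding the individual evaluations.
#' @export
info_per_spike_feedback <- function(model, stim, counts, n_eval = 100L,
                                    seed = 1, valid = NULL) {
  if (model$kind != "feedback") {
    stop_invalid("info_per_spike_feedback requires a feedback model")
  }
  vals <- vapply(seq_len(n_eval), function(i) {
    sim <- simulate_spikes(model, stim, seed = derive_seed(seed, i))
    info_per_spike(counts, sim$rate, valid = valid)
  }, numeric(1))
  out <- mean(vals)
  attr(out, "per_eval") <- vals
  out
}

#' Poisson explained variance
#'
#' `1 - dev(r, pred) / dev(r, mean(r))` with the Poisson deviance
#' `dev(r, rhat) = 2 * sum(r * ln(r / rhat) - (r - rhat))` (convention
#' `0 * ln 0 = 0`), computed on a trial-averaged firing-rate profile
#' (PSTH).  Non-positive predictions are floored at 1e-12 with a warning.
#'
#' @param psth trial-averaged spike count per bin.
#' @param pred model-predicted expected count per bin.
#' @return Poisson explained variance (1 for a perfect prediction, 0 for
#'   the mean-rate predictor; can be negative).
#' @export
poisson_explained_variance <- function(psth, pred) {
  if (length(psth) != length(pred)) {
    stop_invalid("psth and pred must have equal length")
  }
  if (any(pred <= 0)) {
    warning("non-positive predictions floored at 1e-12", call. = FALSE)
    pred <- pmax(pred, RATE_FLOOR)
  }
  1 - poisson_deviance(psth, pred) / poisson_deviance(psth, mean(psth))
}

poisson_deviance <- function(r, rhat) {
  rhat <- pmax(rhat, RATE_FLOOR)
  lt <- ifelse(r > 0, r * log(r / rhat), 0)
  2 * sum(lt - (r - rhat))
}

#' Explained variance (R squared)
#'
#' `1 - sum((r - pred)^2) / sum((r - mean(r))^2)` over the analyzed bins.
#' Not clipped; anti-correlated predictions give negative values.  Returns
#' `NA` for a zero-variance window (excluded from sliding-window
#' profiles).
#'
#' @inheritParams poisson_explained_variance
#' @return R squared, or `NA_real_` for a zero-variance window.
#' @export
r_squared <- function(psth, pred) {
  if (length(psth) != length(pred)) {
    stop_invalid("psth and pred must have equal length")
  }
  ss0 <- sum((psth - mean(psth))^2)
  if (ss0 <= 0) return(NA_real_)
  1 - sum((psth - pred)^2) / ss0
}

#' Sliding-window explained variance along a sweep
#'
#' R squared within a sliding window of `window_ms` duration (9 frames at
#' 60 Hz for the default 150 ms), shifted in steps of `step_frames` along a
#' sweep segment.  Each window is labelled by the axis value (contrast in
#' percent, or instantaneous frequency in Hz) at its start frame.
#'
#' @param psth trial-averaged response within the sweep segment.
#' @param pred model prediction within the sweep segment.
#' @param axis per-frame axis values for the segment (see
#'   [chirp_sweep_axis()]).
#' @param frame_rate_hz frame rate in Hz.
#' @param window_ms window duration in milliseconds.
#' @param step_frames shift between consecutive windows, in frames.
#' @return a `window_profile` data.frame with columns `axis` and `r2`
#'   (`NA` for zero-variance windows).
#' @export
sliding_window_r2 <- function(psth, pred, axis, frame_rate_hz = 60,
                              window_ms = 150, step_frames = 1L) {
  n <- length(psth)
  if (length(pred) != n || length(axis) != n) {
    stop_invalid("psth, pred and axis must have equal length")
  }
  w <- as.integer(round(window_ms / 1000 * frame_rate_hz))
  if (n < w) stop_invalid("segment shorter than the analysis window")
  starts <- seq(1L, n - w + 1L, by = step_frames)
  r2 <- vapply(starts, function(s) {
    idx <- s:(s + w - 1L)
    r_squared(psth[idx], pred[idx])
  }, numeric(1))
  out <- data.frame(axis = axis[starts], r2 = r2)
  class(out) <- c("window_profile", "data.frame")
  out
}

#' Performance range of a window profile
#'
#' The range of axis values (contrast or frequency) over which the model
#' explains variance: the span of the longest contiguous run of windows
#' with `r2 > 0` (undefined, `NA`, windows are excluded from the profile
#' and do not break a run).  A contiguous band is used
#' rather than the bare min/max of qualifying windows because on noisy
#' profiles isolated positive windows at the profile's extremes would
#' saturate the min/max span and mask real differences in generalization.
#' With no qualifying window the width is 0 and the bounds are `NA`.
#'
#' @param profile a `window_profile` from [sliding_window_r2()].
#' @return list with `axis_min`, `axis_max`, `width`.
#' @export
performance_range <- function(profile) {
  defined <- !is.na(profile$r2)
  ok <- profile$r2[defined] > 0
  if (!any(ok)) {
    return(list(axis_min = NA_real_, axis_max = NA_real_, width = 0))
  }
  axis <- profile$axis[defined]
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  ax <- axis[starts[best]:ends[best]]
  list(axis_min = min(ax), axis_max = max(ax), width = max(ax) - min(ax))
}

#' Low-frequency performance
#'
#' Mean explained variance over the first 10 windows of a frequency-sweep
#' profile (the first 300 ms of the sweep at the default window step).
#' Undefined (`NA`) windows are excluded; with fewer than 10 windows the
#' mean is taken over the available ones with a warning.
#'
#' @param profile a `window_profile` from [sliding_window_r2()].
#' @param n_windows number of leading windows to average (default 10).
#' @return mean R squared over the leading windows.
#' @export
low_frequency_performance <- function(profile, n_windows = 10L) {
  if (nrow(profile) < n_windows) {
    warning(sprintf("only %d windows available (wanted %d)",
                    nrow(profile), n_windows), call. = FALSE)
    n_windows <- nrow(profile)
  }
  mean(profile$r2[seq_len(n_windows)], na.rm = TRUE)
}

#' Temporal shift between two filters
#'
#' The integer lag (in frames) at which the cross-correlogram between the
#' excitatory and suppressive filter obtains its maximum; positive values
#' mean the suppressive filter lags the excitatory one.
#'
#' @param exc,sup filter tap vectors (tau-order).
#' @return integer lag in frames.
#' @export
filter_shift <- function(exc, sup) {
  nt <- length(exc)
  if (length(sup) != nt) stop_invalid("filters must have equal length")
  lags <- -(nt - 1L):(nt - 1L)
  cc <- vapply(lags, function(L) {
    i <- seq_len(nt)
    j <- i + L
    ok <- j >= 1L & j <= nt
    sum(exc[i[ok]] * sup[j[ok]])
  }, numeric(1))
  lags[which.max(cc)]
}

#' Asymmetry index of a nonlinearity
#'
#' Absolute difference between the sums of the function values over
#' negative and positive inputs, divided by the total sum, evaluated on the
#' knot grid excluding the center knot.  0 for a symmetric bump, 1 when all
#' mass sits on one side.
#'
#' @param nl a [tent_nonlinearity()].
#' @return asymmetry index in \[0, 1\].
#' @export
asymmetry_index <- function(nl) {
  if (nl$shape == "identity") stop_invalid("identity nonlinearity has no weights")
  neg <- sum(nl$weights[nl$knots < 0])
  pos <- sum(nl$weights[nl$knots > 0])
  abs(neg - pos) / (neg + pos)
}

#' Classify step responses as transient or sustained
#'
#' From the PSTH of the contrast-step part of the chirp stimulus: the
#' preferred contrast step (ON or OFF) is the one with the larger peak rate
#' within its first 200 ms; the transiency ratio is the mean rate over the
#' last 700 ms of that step divided by the early peak.  Cells with a ratio
#' strictly below 0.2 are transient, otherwise sustained.
#'
#' @param psth trial-averaged spike counts per bin over the chirp (or any
#'   trace containing the step segments).
#' @param segments segment table with `step_on` and `step_off` rows (e.g.
#'   `generate_chirp(...)$segments`).
#' @param frame_rate_hz frame rate in Hz.
#' @return `"transient"` or `"sustained"`, with attribute `"ratio"`.
#' @export
classify_transiency <- function(psth, segments, frame_rate_hz = 60) {
  early_n <- as.integer(round(0.2 * frame_rate_hz))
  late_n <- as.integer(round(0.7 * frame_rate_hz))
  step_idx <- function(label) {
    seg <- segments[segments$label == label, , drop = FALSE]
    if (nrow(seg) == 0L) stop_invalid("no segment labelled '%s'", label)
    (seg$start[1L] + 1L):seg$end[1L]
  }
  peak_of <- function(idx) max(psth[idx[seq_len(min(early_n, length(idx)))]])
  on_idx <- step_idx("step_on")
  off_idx <- step_idx("step_off")
  idx <- if (peak_of(on_idx) >= peak_of(off_idx)) on_idx else off_idx
  peak <- peak_of(idx)
  sustained <- mean(psth[utils::tail(idx, late_n)])
  ratio <- if (peak > 0) sustained / peak else Inf
  out <- if (ratio < 0.2) "transient" else "sustained"
  attr(out, "ratio") <- ratio
  out
}

#' Detect ON-OFF cells from a U-shaped nonlinearity
#'
#' Fits a least-squares line separately to the nonlinearity values at the
#' negative-input knots (slope `sL`) and the positive-input knots (slope
#' `sR`).  A cell is flagged ON-OFF when `sL / (|sL| + |sR|) < -0.2`, i.e.
#' the function also rises towards negative inputs.
#'
#' @param nl a [tent_nonlinearity()], or a list with numeric `knots` and
#'   `weights` (e.g. a histogram nonlinearity evaluated on a grid).
#' @return logical; attribute `"index"` carries `sL / (|sL| + |sR|)`.
#' @export
detect_on_off <- function(nl) {
  k <- nl$knots
  w <- nl$weights
  fit_slope <- function(side) {
    stats::coef(stats::lm(w[side] ~ k[side]))[[2L]]
  }
  sL <- fit_slope(k < 0)
  sR <- fit_slope(k > 0)
  idx <- sL / (abs(sL) + abs(sR))
  out <- idx < -0.2
  attr(out, "index") <- idx
  out
}

#' Split-half response reliability
#'
#' Trials are split into two equal halves (without replacement; with an odd
#' trial count the halves differ by one trial), a PSTH is computed for each
#' half, and the variance of the first PSTH explained by the second (R
#' squared) is averaged over `n_divisions` random divisions.
#'
#' @param trials matrix of spike counts, one trial per row.
#' @param n_divisions number of random divisions (default 20).
#' @param seed integer seed.
#' @return mean split-half R squared.
#' @export
split_half_reliability <- function(trials, n_divisions = 20L, seed = 1) {
  n_tr <- nrow(trials)
  if (is.null(n_tr) || n_tr < 2L) {
    stop_invalid("split-half reliability needs at least 2 trials")
  }
  half <- n_tr %/% 2L
  vals <- with_seed(seed, {
    vapply(seq_len(n_divisions), function(i) {
      first <- sample.int(n_tr, half)
      r_squared(colMeans(trials[first, , drop = FALSE]),
                colMeans(trials[-first, , drop = FALSE]))
    }, numeric(1))
  })
  mean(vals)
}

#' Unit-selection criteria
#'
#' Applies the five independent selection criteria to a list of per-cell
#' records and reports one boolean per criterion:
#'
#' 1. mean firing rate above the species threshold (2 Hz for axolotl, 5 Hz
#'    for mouse and marmoset);
#' 2. split-half reliability of the repeated-trial PSTH above 0.5
#'    (averaged over 20 random divisions);
#' 3. stationarity: the absolute difference between the mean rates in the
#'    first and last 30% of the white-noise recording below 50% of the
#'    overall mean rate;
#' 4. not an ON-OFF cell per [detect_on_off()];
#' 5. held-out performance at least 60% of the training performance
#'    (information per spike) for all fitted models.
#'
#' Each record is a list with fields `counts` (white-noise binned counts),
#' `frame_rate_hz`, `species` (`"axolotl"`, `"mouse"`, or `"marmoset"`),
#' `trials` (trial x bin count matrix for criterion 2; `NA` result if
#' missing), `nl` (nonlinearity for criterion 4, see [detect_on_off()]),
#' and `info_train` / `info_test` (named numeric vectors over the fitted
#' model kinds).
#'
#' @param cells list of per-cell records.
#' @param seed seed for the random trial divisions of criterion 2.
#' @return logical matrix, one row per cell, columns `rate`,
#'   `reliability`, `stationary`, `not_on_off`, `generalization`.
#' @export
select_units <- function(cells, seed = 1) {
  crit <- t(vapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    fr <- cell$frame_rate_hz
    mean_rate_hz <- mean(cell$counts) * fr
    thr <- if (identical(cell$species, "axolotl")) 2 else 5
    c1 <- mean_rate_hz > thr
    c2 <- if (is.null(cell$trials)) NA else {
      split_half_reliability(cell$trials, seed = derive_seed(seed, i)) > 0.5
    }
    n <- length(cell$counts)
    k <- as.integer(floor(0.3 * n))
    early <- mean(cell$counts[seq_len(k)])
    late <- mean(cell$counts[(n - k + 1L):n])
    c3 <- abs(early - late) < 0.5 * mean(cell$counts)
    c4 <- if (is.null(cell$nl)) NA else !detect_on_off(cell$nl)
    c5 <- if (is.null(cell$info_train)) NA else {
      all(cell$info_test >= 0.6 * cell$info_train)
    }
    c(c1, c2, c3, c4, c5)
  }, logical(5)))
  colnames(crit) <- c("rate", "reliability", "stationary", "not_on_off",
                      "generalization")
  crit
}

#' Remove duplicate units by response correlation
#'
#' Builds a graph over simultaneously recorded units with an edge wherever
#' the zero-lag Pearson correlation between the frame-binned rates exceeds
#' 0.3, finds maximal cliques, and keeps exactly one member (the lowest
#' index) of each clique of size >= 2, resolving overlapping cliques
#' greedily from the largest.
#'
#' @param rates matrix of binned firing rates, one unit per row.
#' @param threshold correlation threshold for an edge (default 0.3).
#' @return sorted integer vector of kept unit indices.
#' @export
dedup_units <- function(rates, threshold = 0.3) {
  rates <- as.matrix(rates)
  n <- nrow(rates)
  if (n < 2L) return(seq_len(n))
  cc <- stats::cor(t(rates))
  adj <- cc > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 2L)
  sizes <- vapply(cliques, length, integer(1))
  removed <- logical(n)
  for (cl in cliques[order(sizes, decreasing = TRUE)]) {
    members <- sort(as.integer(cl))
    alive <- members[!removed[members]]
    if (length(alive) >= 2L) removed[alive[-1L]] <- TRUE
  }
  which(!removed)
}
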