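#' Tent-basis nonlinearity knot grid
#'
#' 15 uniformly spaced knots on \[-3, 3\] (spacing 3/7); the 8th knot sits
#' exactly at zero, so the unity-at-zero constraint of the divisive bump is
#' an equality constraint on a single weight.
#'
#' @param n_knots number of knots.
#' @param range input range covered by the basis.
#' @return numeric vector of knot positions.
#' @export
tent_knots <- function(n_knots = 15L, range = c(-3, 3)) {
  seq(range[1L], range[2L], length.out = n_knots)
}

WEIGHT_FLOOR <- 1e-16

#' Tent-basis nonlinearity
#'
#' A piecewise-linear function parametrized by one weight per knot of a
#' uniform tent (triangular) basis.  Inputs outside the knot range are
#' clamped to the boundary value.  The shape class encodes the optimization
#' constraint: `monotone` weights are nondecreasing with lower bound 1e-16
#' (excitatory branches and the suppressive branch of the subtractive
#' model); `bump` weights rise monotonically up to the center knot (at 0),
#' where the weight equals 1, and decay after, all within \[1e-16, 1\]
#' (suppressive branch of the divisive model); `identity` passes the input
#' through unchanged (feedback branch).
#'
#' @param weights numeric vector, one weight per knot (ignored for
#'   `identity`).
#' @param shape `"monotone"`, `"bump"`, or `"identity"`.
#' @param knots knot positions; defaults to [tent_knots()].
#' @return An object of class `tent_nonlinearity`.
#' @export
tent_nonlinearity <- function(weights = NULL,
                              shape = c("monotone", "bump", "identity"),
                              knots = tent_knots()) {
  shape <- match.arg(shape)
  if (shape != "identity") {
    weights <- as.numeric(weights)
    if (length(weights) != length(knots)) {
      stop_invalid("need one weight per knot (%d)", length(knots))
    }
    if (!all(is.finite(weights))) stop_invalid("weights must be finite")
  } else {
    weights <- NULL
  }
  nl <- structure(list(knots = knots, weights = weights, shape = shape),
                  class = "tent_nonlinearity")
  err <- check_nl_constraints(nl)
  if (!is.null(err)) stop_invalid("invalid %s weights: %s", shape, err)
  nl
}

# NULL if the shape constraints hold (to small numerical tolerance),
# otherwise a message.
check_nl_constraints <- function(nl, tol = 1e-9) {
  if (nl$shape == "identity") return(NULL)
  w <- nl$weights
  if (any(w < WEIGHT_FLOOR * (1 - 1e-6))) return("weight below 1e-16 floor")
  if (nl$shape == "monotone") {
    if (any(diff(w) < -tol)) return("weights not nondecreasing")
  } else {
    ci <- center_knot_index(nl$knots)
    if (abs(w[ci] - 1) > tol) return("center weight != 1")
    if (any(w > 1 + tol)) return("weight above 1")
    if (any(diff(w[seq_len(ci)]) < -tol)) return("left arm not nondecreasing")
    if (any(diff(w[ci:length(w)]) > tol)) return("right arm not nonincreasing")
  }
  NULL
}

center_knot_index <- function(knots) {
  ci <- which.min(abs(knots))
  if (abs(knots[ci]) > 1e-12) {
    stop_invalid("bump nonlinearity requires a knot at 0")
  }
  ci
}

#' Evaluate a tent-basis nonlinearity
#'
#' Piecewise-linear interpolation of the weights over the knots; inputs
#' outside the knot range are clamped to the boundary value.  The identity
#' class returns its input unchanged.
#'
#' @param nl a [tent_nonlinearity()].
#' @param u numeric vector of inputs.
#' @return numeric vector of outputs.
#' @export
eval_nonlinearity <- function(nl, u) {
  if (nl$shape == "identity") return(u)
  stats::approx(nl$knots, nl$weights, xout = u, rule = 2)$y
}

# Derivative of the interpolant w.r.t. its input (0 where clamped; at an
# interior knot the right-interval slope is used).
nl_slope <- function(nl, u) {
  if (nl$shape == "identity") return(rep(1, length(u)))
  k <- nl$knots
  w <- nl$weights
  dx <- k[2L] - k[1L]
  idx <- findInterval(u, k)
  out <- numeric(length(u))
  inside <- idx >= 1L & idx < length(k)
  out[inside] <- (w[idx[inside] + 1L] - w[idx[inside]]) / dx
  out
}

# Tent-basis design matrix: G[t, i] = g_i(clamp(u_t)), so that
# eval_nonlinearity(nl, u) == G %*% weights.
tent_basis_matrix <- function(knots, u) {
  nk <- length(knots)
  dx <- knots[2L] - knots[1L]
  uc <- pmin(pmax(u, knots[1L]), knots[nk])
  idx <- pmin(findInterval(uc, knots), nk - 1L)
  frac <- (uc - knots[idx]) / dx
  G <- matrix(0, length(u), nk)
  G[cbind(seq_along(u), idx)] <- 1 - frac
  G[cbind(seq_along(u), idx + 1L)] <- frac
  G
}

#' Softplus output rectifier
#'
#' The final output nonlinearity `f(x) = m * ln(1 + exp(a*x + b)) + c`,
#' shared by all model kinds.  `a` and `m` are kept positive so the
#' rectifier is nondecreasing.
#'
#' @param a,b,c,m free parameters; `a > 0`, `m > 0`.
#' @return An object of class `softplus_rectifier`.
#' @export
softplus_rectifier <- function(a = 0.1, b = 0, c = 0, m = 10) {
  if (!all(is.finite(c(a, b, c, m)))) stop_invalid("rectifier parameters must be finite")
  if (a <= 0 || m <= 0) stop_invalid("rectifier requires a > 0 and m > 0")
  structure(list(a = a, b = b, c = c, m = m), class = "softplus_rectifier")
}

# Numerically stable softplus: log(1 + exp(v)) -> v for large v.
softplus <- function(v) {
  out <- v
  small <- v < 30
  out[small] <- log1p(exp(v[small]))
  out
}

#' Evaluate the softplus rectifier
#'
#' @param rect a [softplus_rectifier()].
#' @param x numeric vector of inputs.
#' @return `m * ln(1 + exp(a*x + b)) + c`, computed stably for large
#'   `|a*x + b|`.
#' @export
eval_rectifier <- function(rect, x) {
  rect$m * softplus(rect$a * x + rect$b) + rect$c
}

# d f / d x
rectifier_slope <- function(rect, x) {
  rect$m * rect$a * stats::plogis(rect$a * x + rect$b)
}

#' Apply a temporal filter causally
#'
#' Computes `y(t) = sum_{tau=0}^{T-1} k_tau * x(t - tau)` with zero padding
#' for `t' < 0`; tap 1 (`tau = 0`) weights the current frame.  The output
#' has the same length as the input.
#'
#' @param taps numeric vector of filter taps in tau-order (most recent
#'   frame first).
#' @param x numeric input signal (one value per frame), or a
#'   [stimulus_trace()].
#' @return numeric vector, same length as `x`.
#' @export
apply_filter <- function(taps, x) {
  x <- stim_values(x)
  if (length(x) < 1L) stop_invalid("empty input signal")
  taps <- as.numeric(taps)
  nt <- length(taps)
  if (nt == 1L) return(taps * x)
  padded <- c(rep(0, nt - 1L), x)
  y <- stats::filter(padded, taps, method = "convolution", sides = 1)
  as.numeric(y)[nt:(nt + length(x) - 1L)]
}

# Lagged design matrix: row t = (x_t, x_{t-1}, ..., x_{t-T+1}) with zero
# padding, so that Xmat %*% taps == apply_filter(taps, x).
lagged_matrix <- function(x, n_taps) {
  x <- stim_values(x)
  emb <- stats::embed(c(rep(0, n_taps - 1L), x), n_taps)
  emb
}

# Euclidean norm and tail constraint helpers for filter taps.
filter_norm <- function(taps) sqrt(sum(taps^2))

filter_tail_mean <- function(taps, n_tail = 5L) {
  mean(utils::tail(taps, n_tail))
}

# Subtract the mean of the last `n_tail` taps from those taps (linear
# projection onto the tail = 0 constraint).
project_tail <- function(taps, n_tail = 5L) {
  n <- length(taps)
  idx <- (n - n_tail + 1L):n
  taps[idx] <- taps[idx] - mean(taps[idx])
  taps
}

# Project onto the full filter constraint set (tail = 0, then norm = 1).
project_filter <- function(taps, norm = TRUE, n_tail = 5L) {
  taps <- project_tail(taps, n_tail)
  if (norm) {
    nn <- filter_norm(taps)
    if (nn < 1e-12) stop_invalid("cannot normalize a (near) zero filter")
    taps <- taps / nn
  }
  taps
}

#' Encoding model in the unified structure
#'
#' All four model kinds share one master structure: each upstream branch is
#' a temporal stimulus filter followed by a tent-basis nonlinearity; the
#' integrated signal passes through a softplus rectifier whose output is
#' the expected Poisson spike count per bin.
#'
#' * `ln` -- a single excitatory branch: `r = f(E)`.
#' * `subtractive` -- a second monotone branch subtracted before
#'   rectification: `r = f(E - S)`.
#' * `divisive` -- a second, bump-shaped branch in \[0, 1\] multiplying the
#'   excitatory signal: `r = f(E * S)`.
#' * `feedback` -- a filter over the model's own recent spike counts added
#'   to the excitatory signal: `r = f(E + k_fb * spikes)` (the feedback
#'   branch has no nonlinearity and its filter is not norm-constrained).
#'
#' @param kind `"ln"`, `"subtractive"`, `"divisive"`, or `"feedback"`.
#' @param exc_taps excitatory filter taps (tau-order; unit norm, mean of
#'   last five taps zero).
#' @param exc_nl excitatory [tent_nonlinearity()] (monotone).
#' @param sup_taps suppressive filter taps (subtractive/divisive kinds).
#' @param sup_nl suppressive nonlinearity: monotone for subtractive, bump
#'   for divisive.
#' @param fb_taps feedback filter taps (feedback kind; tail constraint
#'   only).
#' @param rectifier a [softplus_rectifier()].
#' @param frame_rate_hz stimulus update rate in Hz (rates are per-bin
#'   expected counts; multiply by `frame_rate_hz` for sp/s).
#' @return An object of class `encoding_model`.
#' @export
encoding_model <- function(kind = c("ln", "subtractive", "divisive",
                                    "feedback"),
                           exc_taps, exc_nl,
                           sup_taps = NULL, sup_nl = NULL,
                           fb_taps = NULL,
                           rectifier = softplus_rectifier(),
                           frame_rate_hz = 60) {
  kind <- match.arg(kind)
  if (!kind %in% c("subtractive", "divisive") &&
      (!is.null(sup_taps) || !is.null(sup_nl))) {
    stop_invalid("%s model must not carry a suppressive branch", kind)
  }
  if (kind != "feedback" && !is.null(fb_taps)) {
    stop_invalid("%s model must not carry a feedback filter", kind)
  }
  model <- structure(
    list(kind = kind,
         exc = list(taps = as.numeric(exc_taps), nl = exc_nl),
         sup = if (kind %in% c("subtractive", "divisive"))
           list(taps = as.numeric(sup_taps), nl = sup_nl) else NULL,
         fb_taps = if (kind == "feedback") as.numeric(fb_taps) else NULL,
         rectifier = rectifier,
         frame_rate_hz = frame_rate_hz,
         n_taps = length(exc_taps)),
    class = "encoding_model")
  validate_model(model)
  model
}

#' Validate encoding-model constraints
#'
#' Checks the structural invariants of the unified model: branch presence
#' matching the kind, unit filter norm and zero filter tail (mean of the
#' last five taps) for stimulus filters, zero tail for the feedback filter,
#' shape-class constraints on the nonlinearity weights, and rectifier
#' parameter signs.
#'
#' @param model an [encoding_model()].
#' @param tol numerical tolerance for the filter constraints.
#' @return `model`, invisibly; errors if a constraint is violated.
#' @export
validate_model <- function(model, tol = 1e-6) {
  kind <- model$kind
  check_filter <- function(taps, label, norm = TRUE) {
    if (!all(is.finite(taps))) stop_invalid("%s taps must be finite", label)
    if (norm && abs(filter_norm(taps) - 1) > tol) {
      stop_invalid("%s filter norm differs from 1", label)
    }
    if (abs(filter_tail_mean(taps)) > tol) {
      stop_invalid("%s filter tail (mean of last 5 taps) differs from 0",
                   label)
    }
  }
  check_filter(model$exc$taps, "excitatory")
  if (model$exc$nl$shape != "monotone") {
    stop_invalid("excitatory nonlinearity must be monotone")
  }
  if (kind %in% c("subtractive", "divisive")) {
    if (is.null(model$sup)) stop_invalid("%s model needs a suppressive branch", kind)
    if (length(model$sup$taps) != model$n_taps) {
      stop_invalid("suppressive filter length differs from excitatory")
    }
    check_filter(model$sup$taps, "suppressive")
    want <- if (kind == "subtractive") "monotone" else "bump"
    if (model$sup$nl$shape != want) {
      stop_invalid("%s model needs a %s suppressive nonlinearity", kind, want)
    }
  } else if (!is.null(model$sup)) {
    stop_invalid("%s model must not carry a suppressive branch", kind)
  }
  if (kind == "feedback") {
    if (is.null(model$fb_taps)) stop_invalid("feedback model needs fb_taps")
    check_filter(model$fb_taps, "feedback", norm = FALSE)
  } else if (!is.null(model$fb_taps)) {
    stop_invalid("%s model must not carry a feedback filter", kind)
  }
  err <- check_nl_constraints(model$exc$nl)
  if (!is.null(err)) stop_invalid("excitatory nonlinearity: %s", err)
  if (!is.null(model$sup)) {
    err <- check_nl_constraints(model$sup$nl)
    if (!is.null(err)) stop_invalid("suppressive nonlinearity: %s", err)
  }
  if (model$rectifier$a <= 0 || model$rectifier$m <= 0) {
    stop_invalid("rectifier requires a > 0 and m > 0")
  }
  invisible(model)
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> kind=%s, %d taps at %g Hz\n",
              x$kind, x$n_taps, x$frame_rate_hz))
  r <- x$rectifier
  cat(sprintf("  rectifier: a=%.4g b=%.4g c=%.4g m=%.4g\n", r$a, r$b, r$c, r$m))
  invisible(x)
}

# Spike counts delayed by one bin: the feedback filter sees strictly past
# spikes (tap 1 weights the previous bin).
delay_one <- function(counts) {
  c(0, counts[-length(counts)])
}

# Upstream branch outputs for the current parameters.
branch_outputs <- function(model, x) {
  y_exc <- apply_filter(model$exc$taps, x)
  E <- eval_nonlinearity(model$exc$nl, y_exc)
  S <- NULL
  if (!is.null(model$sup)) {
    S <- eval_nonlinearity(model$sup$nl, apply_filter(model$sup$taps, x))
  }
  list(E = E, S = S, y_exc = y_exc)
}

#' Expected spike count per bin (forward pass)
#'
#' Evaluates the model's rate (expected Poisson count per bin) for a
#' stimulus.  For the feedback kind a spike history must be supplied
#' (teacher forcing): the feedback filter is applied to the history delayed
#' by one bin, so the rate at bin `t` depends only on spikes in bins
#' `< t`.  For free-running generation, where each bin's count is sampled
#' before the next rate is computed, see [simulate_spikes()].
#'
#' Negative rectifier outputs (possible when `c < 0`) are clipped at zero.
#' The first `n_taps - 1` bins are filter warm-up (zero-padded stimulus);
#' the returned vector carries a `valid_from` attribute with the first
#' fully-valid bin index.
#'
#' @param model an [encoding_model()].
#' @param stim a [stimulus_trace()] or numeric vector.
#' @param spike_history integer counts per bin (required for the feedback
#'   kind).
#' @return numeric rate vector (expected counts per bin), same length as
#'   the stimulus, with attribute `valid_from`.
#' @export
forward <- function(model, stim, spike_history = NULL) {
  x <- stim_values(stim)
  br <- branch_outputs(model, x)
  u <- switch(model$kind,
    ln = br$E,
    subtractive = br$E - br$S,
    divisive = br$E * br$S,
    feedback = {
      if (is.null(spike_history)) {
        stop_invalid(paste("feedback model requires spike_history",
                           "(or use simulate_spikes for free-running mode)"))
      }
      if (length(spike_history) != length(x)) {
        stop_invalid("spike_history length differs from stimulus length")
      }
      br$E + apply_filter(model$fb_taps, delay_one(spike_history))
    })
  rate <- pmax(eval_rectifier(model$rectifier, u), 0)
  attr(rate, "valid_from") <- model$n_taps
  rate
}

#' Draw Poisson spike counts from a rate vector
#'
#' @param rate expected counts per bin (elementwise `>= 0`).
#' @param seed integer seed.
#' @return integer counts per bin.
#' @export
sample_spikes <- function(rate, seed = 1) {
  rate <- as.numeric(rate)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop_invalid("rates must be finite and non-negative")
  }
  with_seed(seed, stats::rpois(length(rate), rate))
}

#' Simulate spiking from a model (free-running)
#'
#' Samples a spike train from the model.  For stimulus-driven kinds this is
#' a Poisson draw from [forward()].  For the feedback kind the bins are
#' generated sequentially: each bin's rate includes the feedback filter
#' applied to the already-sampled spikes of earlier bins, then that bin's
#' count is drawn before moving on.
#'
#' @param model an [encoding_model()].
#' @param stim a [stimulus_trace()] or numeric vector.
#' @param seed integer seed.
#' @return list with `rate` (expected counts per bin along the sampled
#'   trajectory) and `counts` (sampled spike counts).
#' @export
simulate_spikes <- function(model, stim, seed = 1) {
  x <- stim_values(stim)
  if (model$kind != "feedback") {
    rate <- forward(model, x)
    counts <- sample_spikes(rate, seed)
    return(list(rate = rate, counts = counts))
  }
  br <- branch_outputs(model, x)
  E <- br$E
  fb <- model$fb_taps
  nt <- length(fb)
  rect <- model$rectifier
  n <- length(x)
  counts <- numeric(n)
  rate <- numeric(n)
  with_seed(seed, {
    for (t in seq_len(n)) {
      jmax <- min(nt, t - 1L)
      acc <- if (jmax > 0L) {
        sum(fb[seq_len(jmax)] * counts[t - seq_len(jmax)])
      } else 0
      r <- rect$m * softplus(rect$a * (E[t] + acc) + rect$b) + rect$c
      if (r < 0) r <- 0
      rate[t] <- r
      counts[t] <- stats::rpois(1L, r)
    }
  })
  attr(rate, "valid_from") <- model$n_taps
  list(rate = rate, counts = counts)
}
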