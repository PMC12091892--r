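# Independent brute-force oracles and random-model generators used across
# the suite.  The oracles share no code with the package's vectorized
# implementations: plain double loops and per-sample interpolation.

bf_convolve <- function(taps, x) {
  n <- length(x)
  y <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (tau in 0:(length(taps) - 1L)) {
      tp <- t - tau
      if (tp >= 1L) acc <- acc + taps[tau + 1L] * x[tp]
    }
    y[t] <- acc
  }
  y
}

bf_tent <- function(knots, weights, u) {
  nk <- length(knots)
  vapply(u, function(v) {
    if (v <= knots[1L]) return(weights[1L])
    if (v >= knots[nk]) return(weights[nk])
    j <- max(which(knots <= v))
    if (knots[j] == v) return(weights[j])
    frac <- (v - knots[j]) / (knots[j + 1L] - knots[j])
    (1 - frac) * weights[j] + frac * weights[j + 1L]
  }, numeric(1))
}

bf_softplus <- function(rect, u) {
  vapply(u, function(v) {
    z <- rect$a * v + rect$b
    sp <- if (z > 30) z else log(1 + exp(z))
    rect$m * sp + rect$c
  }, numeric(1))
}

# Explicit-loop composition of the master structure for each model kind.
bf_forward <- function(model, x, spike_history = NULL) {
  E <- bf_tent(model$exc$nl$knots, model$exc$nl$weights,
               bf_convolve(model$exc$taps, x))
  u <- switch(model$kind,
    ln = E,
    subtractive = E - bf_tent(model$sup$nl$knots, model$sup$nl$weights,
                              bf_convolve(model$sup$taps, x)),
    divisive = E * bf_tent(model$sup$nl$knots, model$sup$nl$weights,
                           bf_convolve(model$sup$taps, x)),
    feedback = {
      shifted <- c(0, spike_history[-length(spike_history)])
      E + bf_convolve(model$fb_taps, shifted)
    })
  pmax(bf_softplus(model$rectifier, u), 0)
}

random_monotone_weights <- function(nk = 15L) {
  pmax(cumsum(runif(nk, 0, 0.4)), 1e-16)
}

random_bump_weights <- function(knots = tent_knots()) {
  sd <- runif(1, 0.6, 2)
  w <- exp(-knots^2 / (2 * sd^2)) + rnorm(length(knots), sd = 0.05)
  suppfilt:::project_bump_weights(w, suppfilt:::center_knot_index(knots))
}

random_model <- function(kind, n_taps = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  knots <- tent_knots()
  exc <- suppfilt:::project_filter(rnorm(n_taps))
  exc_nl <- tent_nonlinearity(random_monotone_weights(), "monotone", knots)
  rect <- softplus_rectifier(a = runif(1, 0.3, 2), b = rnorm(1, 0, 0.5),
                             c = runif(1, -0.2, 0.5), m = runif(1, 0.2, 3))
  sup_taps <- NULL; sup_nl <- NULL; fb_taps <- NULL
  if (kind == "subtractive") {
    sup_taps <- suppfilt:::project_filter(rnorm(n_taps))
    sup_nl <- tent_nonlinearity(random_monotone_weights(), "monotone", knots)
  } else if (kind == "divisive") {
    sup_taps <- suppfilt:::project_filter(rnorm(n_taps))
    sup_nl <- tent_nonlinearity(random_bump_weights(knots), "bump", knots)
  } else if (kind == "feedback") {
    # suppressive (negative) history filter: positive feedback would make
    # the free-running model unstable
    fb_taps <- suppfilt:::project_tail(-runif(n_taps, 0, 1) *
                                         exp(-(seq_len(n_taps) - 1) / 3))
  }
  encoding_model(kind, exc, exc_nl, sup_taps, sup_nl, fb_taps, rect)
}

all_kinds <- c("ln", "subtractive", "divisive", "feedback")

blocks_of <- function(kind) suppfilt:::model_blocks(kind)

# Natural-space NLL as a function of one block's parameters, for
# finite-difference gradient checks.
nll_of_block <- function(model, block, par, x, counts, valid) {
  m <- suppfilt:::set_block_par(model, block, par)
  hist <- if (m$kind == "feedback") counts else NULL
  rate <- eval_rectifier(m$rectifier, master_drive(m, x, counts))
  negative_log_likelihood(rate, counts, valid)
}

block_par_of <- function(model, block) {
  switch(block,
    exc_filter = model$exc$taps,
    exc_weights = model$exc$nl$weights,
    sup_filter = model$sup$taps,
    sup_weights = model$sup$nl$weights,
    fb_filter = model$fb_taps,
    rectifier = unlist(model$rectifier[c("a", "b", "c", "m")],
                       use.names = FALSE))
}

# Pre-rectifier drive of the full model (teacher-forced for feedback).
master_drive <- function(model, x, counts) {
  E <- eval_nonlinearity(model$exc$nl, apply_filter(model$exc$taps, x))
  switch(model$kind,
    ln = E,
    subtractive = E - eval_nonlinearity(model$sup$nl,
                                        apply_filter(model$sup$taps, x)),
    divisive = E * eval_nonlinearity(model$sup$nl,
                                     apply_filter(model$sup$taps, x)),
    feedback = E + apply_filter(model$fb_taps,
                                c(0, counts[-length(counts)])))
}

# Constraint audit used by the fitting and acceptance tests.
expect_constraints_hold <- function(model, tol = 1e-6) {
  expect_lt(abs(suppfilt:::filter_norm(model$exc$taps) - 1), tol)
  expect_lt(abs(suppfilt:::filter_tail_mean(model$exc$taps)), tol)
  expect_true(all(diff(model$exc$nl$weights) >= -1e-12))
  expect_true(all(model$exc$nl$weights >= 1e-16 * (1 - 1e-9)))
  if (!is.null(model$sup)) {
    expect_lt(abs(suppfilt:::filter_norm(model$sup$taps) - 1), tol)
    expect_lt(abs(suppfilt:::filter_tail_mean(model$sup$taps)), tol)
    w <- model$sup$nl$weights
    if (model$sup$nl$shape == "bump") {
      ci <- suppfilt:::center_knot_index(model$sup$nl$knots)
      expect_identical(w[ci], 1)
      expect_true(all(diff(w[seq_len(ci)]) >= -1e-12))
      expect_true(all(diff(w[ci:length(w)]) <= 1e-12))
      expect_true(all(w <= 1 + 1e-12))
    } else {
      expect_true(all(diff(w) >= -1e-12))
    }
    expect_true(all(w >= 1e-16 * (1 - 1e-9)))
  }
  if (!is.null(model$fb_taps)) {
    expect_lt(abs(suppfilt:::filter_tail_mean(model$fb_taps)), tol)
  }
  expect_gt(model$rectifier$a, 0)
  expect_gt(model$rectifier$m, 0)
}
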