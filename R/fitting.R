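RATE_FLOOR <- 1e-12

#' Poisson negative log-likelihood
#'
#' `-sum_t [n_t * ln r_t - r_t - ln(n_t!)]` over the selected bins, the
#' training objective for all model kinds.  Rates are floored at 1e-12 to
#' avoid `log(0)`.
#'
#' @param rate expected counts per bin.
#' @param counts observed spike counts per bin (non-negative integers).
#' @param valid optional logical mask of bins to include (used to exclude
#'   the filter warm-up and held-out data); default all bins.
#' @return the negative log-likelihood (a single number, always >= 0).
#' @export
negative_log_likelihood <- function(rate, counts, valid = NULL) {
  if (length(rate) != length(counts)) {
    stop_invalid("rate and counts must have equal length")
  }
  if (!is_count_vector(counts)) {
    stop_invalid("counts must be non-negative integers")
  }
  if (is.null(valid)) valid <- rep(TRUE, length(rate))
  r <- pmax(rate[valid], RATE_FLOOR)
  n <- counts[valid]
  sum(r - n * log(r) + lgamma(n + 1))
}

# Unchecked core for the optimizer hot path.
nll_core <- function(rate, counts, valid) {
  r <- pmax(rate[valid], RATE_FLOOR)
  n <- counts[valid]
  sum(r - n * log(r) + lgamma(n + 1))
}

# d(-LL)/d(rate) per bin (0 outside `valid` and where the rate is floored).
nll_drate <- function(rate, counts, valid) {
  g <- numeric(length(rate))
  ok <- valid & rate > RATE_FLOOR
  g[ok] <- 1 - counts[ok] / rate[ok]
  g
}

# Default valid-bin mask: exclude the convolution warm-up so every model
# sees the identical bins.
default_valid <- function(n, n_taps) {
  v <- rep(TRUE, n)
  v[seq_len(min(n_taps - 1L, n))] <- FALSE
  v
}

# Blocks trained per outer iteration, in a fixed canonical order: upstream
# excitatory, upstream suppressive, feedback loop, output rectifier.
model_blocks <- function(kind) {
  switch(kind,
    ln = c("exc_filter", "exc_weights", "rectifier"),
    subtractive = ,
    divisive = c("exc_filter", "exc_weights", "sup_filter", "sup_weights",
                 "rectifier"),
    feedback = c("exc_filter", "exc_weights", "fb_filter", "rectifier"))
}

# Lagged design matrices reused across all blocks of one fit.
fit_cache <- function(x, counts, n_taps, has_fb) {
  list(stim_lag = lagged_matrix(x, n_taps),
       fb_lag = if (has_fb) lagged_matrix(delay_one(counts), n_taps) else NULL)
}

#' Training context for one block of the unified structure
#'
#' For the block under training, the master structure is written as
#' `r(t) = f((sign * B(t) + sign_P * P(t)) * M(t) + A(t))`, where `B` is
#' the output of the branch being updated and `P`, `M`, `A` collect the
#' frozen contributions of the other branches:
#'
#' * LN, exc: `P = 0`, `M = 1`, `A = 0`.
#' * subtractive, exc: `P` = suppressive output (entering negatively);
#'   sup: `P` = excitatory output, the trained branch carries sign `-1`.
#' * divisive, exc: `M` = suppressive (bump) output; sup: `M` = excitatory
#'   output.
#' * feedback, exc: `A` = feedback filter output; fb: source signal `X` =
#'   spike counts (delayed one bin), `A` = excitatory output.
#'
#' @param model an [encoding_model()].
#' @param block_id one of `"exc_filter"`, `"exc_weights"`, `"sup_filter"`,
#'   `"sup_weights"`, `"fb_filter"`, `"rectifier"`.
#' @param stim stimulus trace or numeric vector.
#' @param counts observed spike counts (used by the feedback branch via
#'   teacher forcing).
#' @param valid optional logical mask of bins entering the likelihood.
#' @return list with the frozen terms (`X`, `P`, `M`, `A`, `sign`), the
#'   trained branch's current filter output and design matrix, and the
#'   valid-bin mask.
#' @export
make_block_context <- function(model, block_id, stim, counts, valid = NULL,
                               cache = NULL) {
  x <- stim_values(stim)
  n <- length(x)
  if (length(counts) != n) stop_invalid("counts length differs from stimulus")
  if (is.null(valid)) valid <- default_valid(n, model$n_taps)
  blocks <- c(model_blocks(model$kind))
  if (!block_id %in% blocks) {
    stop_invalid("block '%s' does not exist for the %s model",
                 block_id, model$kind)
  }
  if (is.null(cache)) {
    cache <- fit_cache(x, counts, model$n_taps, model$kind == "feedback")
  }
  E <- eval_nonlinearity(model$exc$nl,
                         as.numeric(cache$stim_lag %*% model$exc$taps))
  S <- if (!is.null(model$sup)) {
    eval_nonlinearity(model$sup$nl,
                      as.numeric(cache$stim_lag %*% model$sup$taps))
  } else NULL
  FB <- if (model$kind == "feedback") {
    as.numeric(cache$fb_lag %*% model$fb_taps)
  } else NULL
  zero <- numeric(n)
  one <- rep(1, n)
  branch <- if (block_id %in% c("sup_filter", "sup_weights")) "sup"
            else if (block_id == "fb_filter") "fb"
            else "exc"
  ctx <- switch(paste(model$kind, branch),
    "ln exc" = list(X = x, P = zero, M = one, A = zero,
                    sign = 1, sign_P = 0),
    "subtractive exc" = list(X = x, P = S, M = one, A = zero,
                             sign = 1, sign_P = -1),
    "subtractive sup" = list(X = x, P = E, M = one, A = zero,
                             sign = -1, sign_P = 1),
    "divisive exc" = list(X = x, P = zero, M = S, A = zero,
                          sign = 1, sign_P = 0),
    "divisive sup" = list(X = x, P = zero, M = E, A = zero,
                          sign = 1, sign_P = 0),
    "feedback exc" = list(X = x, P = zero, M = one, A = FB,
                          sign = 1, sign_P = 0),
    "feedback fb" = list(X = delay_one(counts), P = zero, M = one, A = E,
                         sign = 1, sign_P = 0))
  ctx$block <- block_id
  ctx$kind <- model$kind
  ctx$valid <- valid
  ctx$counts <- counts
  ctx$Xmat <- if (branch == "fb") cache$fb_lag else cache$stim_lag
  br <- switch(branch, exc = model$exc, sup = model$sup,
               fb = list(taps = model$fb_taps,
                         nl = tent_nonlinearity(shape = "identity")))
  ctx$taps <- br$taps
  ctx$nl <- br$nl
  ctx$y <- as.numeric(ctx$Xmat %*% br$taps)
  if (block_id == "rectifier") {
    B <- eval_nonlinearity(ctx$nl, ctx$y)
    ctx$u <- (ctx$sign * B + ctx$sign_P * ctx$P) * ctx$M + ctx$A
  }
  ctx
}

# Objective/gradient pair in the block's natural parameter space.
# Returns list(par, state) where state(par) gives list(value, grad);
# consecutive calls with the identical par are memoized.  Everything in
# the hot path is restricted to the valid (training) bins: the rate at
# excluded bins affects neither the objective nor its gradient.
block_objective <- function(model, block_id, stim, counts, valid = NULL,
                            cache = NULL) {
  ctx <- make_block_context(model, block_id, stim, counts, valid, cache)
  rect <- model$rectifier
  v <- which(ctx$valid)
  cnt <- ctx$counts[v]
  lgam <- sum(lgamma(cnt + 1))
  Mv <- ctx$M[v]
  Pv <- ctx$P[v]
  Av <- ctx$A[v]

  nll_of_rate <- function(r) {
    r <- pmax(r, RATE_FLOOR)
    sum(r - cnt * log(r)) + lgam
  }
  drate <- function(r) {
    g <- 1 - cnt / r
    g[r <= RATE_FLOOR] <- 0
    g
  }

  finish <- function(u, grad_fn) {
    r <- rect$m * softplus(rect$a * u + rect$b) + rect$c
    value <- nll_of_rate(r)
    gu <- drate(pmax(r, RATE_FLOOR)) * rectifier_slope(rect, u)
    list(value = value, grad = grad_fn(gu))
  }

  if (block_id == "rectifier") {
    u <- ctx$u[v]
    state <- function(par) {
      a <- par[1L]; b <- par[2L]; cc <- par[3L]; m <- par[4L]
      z <- a * u + b
      sp <- softplus(z)
      r <- m * sp + cc
      value <- nll_of_rate(r)
      gr_r <- drate(pmax(r, RATE_FLOOR))
      sig <- stats::plogis(z)
      list(value = value,
           grad = c(sum(gr_r * m * sig * u),
                    sum(gr_r * m * sig),
                    sum(gr_r),
                    sum(gr_r * sp)))
    }
    par <- c(rect$a, rect$b, rect$c, rect$m)
  } else if (grepl("_weights$", block_id)) {
    G <- tent_basis_matrix(ctx$nl$knots, ctx$y[v])
    state <- function(w) {
      B <- as.numeric(G %*% w)
      u <- (ctx$sign * B + ctx$sign_P * Pv) * Mv + Av
      finish(u, function(gu) {
        as.numeric(crossprod(G, gu * ctx$sign * Mv))
      })
    }
    par <- ctx$nl$weights
  } else {
    nl <- ctx$nl
    Xmat <- ctx$Xmat[v, , drop = FALSE]
    state <- function(k) {
      y <- as.numeric(Xmat %*% k)
      B <- eval_nonlinearity(nl, y)
      u <- (ctx$sign * B + ctx$sign_P * Pv) * Mv + Av
      finish(u, function(gu) {
        gy <- gu * ctx$sign * Mv * nl_slope(nl, y)
        as.numeric(crossprod(Xmat, gy))
      })
    }
    par <- ctx$taps
  }

  memo_par <- NULL
  memo_val <- NULL
  memo <- function(par) {
    if (!is.null(memo_par) && identical(par, memo_par)) return(memo_val)
    v <- state(par)
    memo_par <<- par
    memo_val <<- v
    v
  }
  list(par = par, state = memo, ctx = ctx)
}

#' Analytic gradient of the training objective for one block
#'
#' Gradient of the Poisson negative log-likelihood with respect to the
#' block's parameters in their natural space (filter taps, nonlinearity
#' weights, or the rectifier parameters `(a, b, c, m)`), obtained by the
#' chain rule through the rectifier, the tent-basis interpolation, and the
#' convolution.  Constraints are not part of this gradient; the optimizer
#' applies them through its parametrization.
#'
#' @inheritParams make_block_context
#' @return numeric gradient vector.
#' @export
nll_gradient <- function(model, block_id, stim, counts, valid = NULL) {
  obj <- block_objective(model, block_id, stim, counts, valid)
  obj$state(obj$par)$grad
}

# ---- constraint-preserving parametrizations ------------------------------

# Filter with norm + tail constraints: k = normalize(project_tail(theta)).
reparam_norm_tail <- function(taps) {
  list(
    theta0 = taps,
    to_par = function(theta) {
      kt <- project_tail(theta)
      nn <- filter_norm(kt)
      if (nn < 1e-10) return(NULL)
      kt / nn
    },
    chain = function(theta, k, gk) {
      nn <- filter_norm(project_tail(theta))
      project_tail((gk - k * sum(k * gk)) / nn)
    })
}

# Feedback filter: tail constraint only.
reparam_tail <- function(taps) {
  list(
    theta0 = taps,
    to_par = function(theta) project_tail(theta),
    chain = function(theta, k, gk) project_tail(gk))
}

# Monotone weights: par = (w_1, increments), box-constrained.
monotone_to_increments <- function(w) {
  c(w[1L], pmax(diff(w), 0))
}

increments_to_monotone <- function(p) {
  cumsum(c(p[1L], p[-1L]))
}

# Bump weights via logistic-ratio parametrization: the center weight is
# fixed at 1 and each neighbour is the previous weight times a sigmoid, so
# the up/down shape and the [0, 1] range hold throughout optimization.
bump_to_theta <- function(w, ci) {
  nk <- length(w)
  ratio_l <- w[seq_len(ci - 1L)] / w[2L:ci]
  ratio_r <- w[(ci + 1L):nk] / w[ci:(nk - 1L)]
  ratio <- pmin(pmax(c(ratio_l, ratio_r), 1e-8), 1 - 1e-8)
  stats::qlogis(ratio)
}

theta_to_bump <- function(theta, ci, nk) {
  sig <- stats::plogis(theta)
  w <- numeric(nk)
  w[ci] <- 1
  for (i in (ci - 1L):1L) w[i] <- w[i + 1L] * sig[i]
  for (i in (ci + 1L):nk) w[i] <- w[i - 1L] * sig[i - 1L]
  w
}

bump_chain <- function(theta, w, gw, ci, nk) {
  sig <- stats::plogis(theta)
  gt <- numeric(length(theta))
  for (j in seq_len(ci - 1L)) {              # theta_j controls w[1..j]
    gt[j] <- sum(gw[seq_len(j)] * w[seq_len(j)]) * (1 - sig[j])
  }
  for (j in ci:(nk - 1L)) {                  # theta_j controls w[(j+1)..nk]
    gt[j] <- sum(gw[(j + 1L):nk] * w[(j + 1L):nk]) * (1 - sig[j])
  }
  gt
}

#' Update one block by constrained descent
#'
#' Takes up to `max_steps` quasi-Newton steps on the block's parameters
#' while every other block stays frozen, honoring the block's constraint
#' set throughout: stimulus filters keep unit norm and zero tail (mean of
#' the last five taps), the feedback filter keeps the zero tail, monotone
#' weights stay nondecreasing above the 1e-16 floor, bump weights stay
#' unimodal in \[1e-16, 1\] with the center weight pinned at 1, and the
#' rectifier keeps `a, m > 0`.  If the optimizer fails or would increase
#' the objective, the block is left unchanged with a warning.
#'
#' @inheritParams make_block_context
#' @param max_steps maximum optimizer iterations for this block update.
#' @return the updated [encoding_model()], with attribute `"nll"` carrying
#'   the objective after the update.
#' @export
fit_block <- function(model, block_id, stim, counts, valid = NULL,
                      max_steps = 10L, cache = NULL) {
  obj <- block_objective(model, block_id, stim, counts, valid, cache)
  nll0 <- obj$state(obj$par)$value
  ctrl <- list(maxit = max_steps)

  res <- tryCatch({
    if (block_id == "rectifier") {
      fn <- function(p) obj$state(p)$value
      gr <- function(p) obj$state(p)$grad
      o <- stats::optim(obj$par, fn, gr, method = "L-BFGS-B",
                        lower = c(1e-8, -Inf, -Inf, 1e-8), control = ctrl)
      o$par
    } else if (grepl("_weights$", block_id)) {
      nl <- obj$ctx$nl
      nk <- length(nl$weights)
      if (nl$shape == "monotone") {
        fn <- function(p) obj$state(increments_to_monotone(p))$value
        gr <- function(p) {
          gw <- obj$state(increments_to_monotone(p))$grad
          rev(cumsum(rev(gw)))
        }
        o <- stats::optim(monotone_to_increments(nl$weights), fn, gr,
                          method = "L-BFGS-B",
                          lower = c(WEIGHT_FLOOR, rep(0, nk - 1L)),
                          control = ctrl)
        pmax(increments_to_monotone(o$par), WEIGHT_FLOOR)
      } else {
        ci <- center_knot_index(nl$knots)
        fn <- function(th) obj$state(theta_to_bump(th, ci, nk))$value
        gr <- function(th) {
          w <- theta_to_bump(th, ci, nk)
          bump_chain(th, w, obj$state(w)$grad, ci, nk)
        }
        o <- stats::optim(bump_to_theta(nl$weights, ci), fn, gr,
                          method = "BFGS", control = ctrl)
        w <- pmin(pmax(theta_to_bump(o$par, ci, nk), WEIGHT_FLOOR), 1)
        w[ci] <- 1
        w
      }
    } else {
      rp <- if (block_id == "fb_filter") reparam_tail(obj$par)
            else reparam_norm_tail(obj$par)
      fn <- function(th) {
        k <- rp$to_par(th)
        if (is.null(k)) return(nll0 + 1e6)
        obj$state(k)$value
      }
      gr <- function(th) {
        k <- rp$to_par(th)
        if (is.null(k)) return(numeric(length(th)))
        rp$chain(th, k, obj$state(k)$grad)
      }
      o <- stats::optim(rp$theta0, fn, gr, method = "BFGS", control = ctrl)
      rp$to_par(o$par)
    }
  }, error = function(e) {
    warning(sprintf("block '%s' update failed (%s); leaving it unchanged",
                    block_id, conditionMessage(e)), call. = FALSE)
    NULL
  })

  if (!is.null(res)) {
    nll1 <- obj$state(res)$value
    if (is.finite(nll1) && nll1 <= nll0 + 1e-9) {
      model <- set_block_par(model, block_id, res)
      attr(model, "nll") <- nll1
      return(model)
    }
  }
  attr(model, "nll") <- nll0
  model
}

set_block_par <- function(model, block_id, par) {
  switch(block_id,
    exc_filter = { model$exc$taps <- par },
    exc_weights = { model$exc$nl$weights <- par },
    sup_filter = { model$sup$taps <- par },
    sup_weights = { model$sup$nl$weights <- par },
    fb_filter = { model$fb_taps <- par },
    rectifier = {
      model$rectifier <- softplus_rectifier(par[1L], par[2L], par[3L],
                                            par[4L])
    })
  model
}

# ---- initialization ------------------------------------------------------

# Pre-defined deterministic weight shapes for initialization: W_mono is the
# softplus with (a, b, c, m) = (10, 0, 0, 0.1) sampled at the knots; W_bi
# is a Gaussian spanning about 2 SDs over the knot range, rescaled to
# [0, 1].
w_mono_init <- function(knots) 0.1 * softplus(10 * knots)

w_bi_init <- function(knots) {
  span <- knots[length(knots)] - knots[1L]
  g <- exp(-knots^2 / (2 * (span / 4)^2))
  (g - min(g)) / (max(g) - min(g))
}

project_monotone_weights <- function(w) {
  pmax(stats::isoreg(seq_along(w), w)$yf, WEIGHT_FLOOR)
}

project_bump_weights <- function(w, ci = center_knot_index(tent_knots())) {
  nk <- length(w)
  left <- stats::isoreg(seq_len(ci), w[seq_len(ci)])$yf
  right <- rev(stats::isoreg(seq_len(nk - ci + 1L),
                             rev(w[ci:nk]))$yf)
  scale <- max(left[ci], right[1L], WEIGHT_FLOOR)
  out <- c(left, right[-1L]) / scale
  out <- pmin(pmax(out, WEIGHT_FLOOR), 1)
  out[ci] <- 1
  out
}

#' Initialize one training run
#'
#' Produces the starting model for run `run_index` (1-5) of the restart
#' schedule.  Filters are drawn from the spike-triggered features (STA, the
#' first or last principal component of the spike-triggered covariance) or
#' standard-normal noise in run 5; feedback filters start at zero (noise in
#' run 5).  Weight vectors start from the deterministic monotone
#' (softplus-shaped) or bell-shaped templates, with N(0, 0.1) jitter added
#' at every knot, and are then projected onto their constraint set; for
#' kinds whose excitatory nonlinearity starts from the bell template (runs
#' 2 and 4 of the divisive and LN models), the projection makes it
#' monotone.  The rectifier always starts at `(a, b, c, m) = (0.1, 0, 0,
#' 10)`.
#'
#' @param run_index restart index, 1-5.
#' @param kind model kind.
#' @param features an `sta_features` object (not needed for run 5).
#' @param n_taps filter length in frames.
#' @param seed integer seed for the jitter and noise draws of this run.
#' @param frame_rate_hz stimulus update rate.
#' @return a constraint-satisfying [encoding_model()].
#' @export
initialize_run <- function(run_index, kind, features = NULL, n_taps = 15L,
                           seed = 1, frame_rate_hz = 60) {
  if (!run_index %in% 1:5) stop_invalid("run_index must be in 1..5")
  if (run_index < 5L && is.null(features)) {
    stop_invalid("runs 1-4 require spike-triggered features")
  }
  knots <- tent_knots()
  with_seed(seed, {
    noise_filter <- function() project_filter(stats::rnorm(n_taps))
    exc_taps <- switch(run_index,
      project_filter(features$sta),
      project_filter(features$sta),
      project_filter(features$stc_first),
      project_filter(features$stc_last),
      noise_filter())
    # exc nonlinearity template: bell-shaped in runs 2 and 4 for the
    # divisive and LN kinds, monotone softplus otherwise
    exc_bi <- run_index %in% c(2L, 4L) && kind %in% c("divisive", "ln")
    exc_w0 <- if (exc_bi) w_bi_init(knots) else w_mono_init(knots)
    exc_w <- project_monotone_weights(exc_w0 + stats::rnorm(length(knots),
                                                            sd = 0.1))
    exc_nl <- tent_nonlinearity(exc_w, "monotone", knots)

    sup_taps <- NULL; sup_nl <- NULL; fb_taps <- NULL
    if (kind %in% c("subtractive", "divisive")) {
      sup_taps <- switch(run_index,
        project_filter(features$stc_first),
        project_filter(features$stc_last),
        project_filter(features$stc_last),
        project_filter(features$stc_first),
        noise_filter())
      if (kind == "subtractive") {
        w <- project_monotone_weights(w_mono_init(knots) +
                                        stats::rnorm(length(knots), sd = 0.1))
        sup_nl <- tent_nonlinearity(w, "monotone", knots)
      } else {
        w <- project_bump_weights(w_bi_init(knots) +
                                    stats::rnorm(length(knots), sd = 0.1),
                                  center_knot_index(knots))
        sup_nl <- tent_nonlinearity(w, "bump", knots)
      }
    } else if (kind == "feedback") {
      fb_taps <- if (run_index == 5L) {
        project_tail(stats::rnorm(n_taps))
      } else {
        numeric(n_taps)
      }
    }
    encoding_model(kind, exc_taps, exc_nl, sup_taps, sup_nl, fb_taps,
                   softplus_rectifier(0.1, 0, 0, 10), frame_rate_hz)
  })
}

#' Fit an encoding model by constrained block-coordinate descent
#'
#' Maximum-likelihood training of any model kind within the unified
#' structure: the blocks (excitatory filter, excitatory weights,
#' suppressive filter and weights, feedback filter, rectifier) are updated
#' cyclically, each by at most `max_steps` constrained quasi-Newton steps,
#' until the relative change of the objective between outer iterations
#' falls below `tol` (default 0.01%) or `max_iter` iterations are reached.
#' Training is restarted `n_runs` times from the initializations of
#' [initialize_run()] and the run with the lowest training negative
#' log-likelihood is returned.  The feedback filter is trained with the
#' observed spike counts as its input (teacher forcing).
#'
#' @param kind model kind (`"ln"`, `"subtractive"`, `"divisive"`,
#'   `"feedback"`).
#' @param stim training stimulus ([stimulus_trace()] or numeric vector).
#' @param counts observed spike counts per bin.
#' @param schedule optional [train_test_schedule()]; when given, only
#'   training-interval bins enter the likelihood.
#' @param n_taps filter length in frames.
#' @param n_runs number of restarts (default 5).
#' @param seed master seed; per-run seeds are derived deterministically.
#' @param max_iter outer iteration cap (default 100).
#' @param tol relative objective-change stopping threshold (default 1e-4,
#'   i.e. 0.01%).
#' @param max_steps optimizer steps per block update (default 10).
#' @param verbose print per-run progress.
#' @return object of class `fit_result`: list with `model` (best run),
#'   `objective_trace`, `run_index`, `converged_by` (`"relative_change"`
#'   or `"iteration_cap"`), `train_nll`, and per-run summary `runs`.
#' @export
fit_model <- function(kind = c("ln", "subtractive", "divisive", "feedback"),
                      stim, counts, schedule = NULL, n_taps = 15L,
                      n_runs = 5L, seed = 1, max_iter = 100L, tol = 1e-4,
                      max_steps = 10L, verbose = FALSE) {
  kind <- match.arg(kind)
  x <- stim_values(stim)
  n <- length(x)
  frame_rate_hz <- if (inherits(stim, "stimulus_trace"))
    stim$frame_rate_hz else 60
  valid <- default_valid(n, n_taps)
  if (!is.null(schedule)) {
    valid <- valid & intervals_to_mask(schedule$train_intervals, n)
  }
  if (!any(valid)) stop_invalid("no valid training bins")
  features <- tryCatch(
    compute_stc_features(x, counts, n_taps, valid = valid),
    error = function(e) NULL)
  cache <- fit_cache(x, counts, n_taps, kind == "feedback")
  blocks <- model_blocks(kind)

  run_one <- function(run) {
    model <- initialize_run(run, kind,
                            features = features, n_taps = n_taps,
                            seed = derive_seed(seed, run),
                            frame_rate_hz = frame_rate_hz)
    trace <- numeric(0)
    converged <- "iteration_cap"
    nll_prev <- Inf
    for (it in seq_len(max_iter)) {
      for (b in blocks) {
        model <- fit_block(model, b, x, counts, valid = valid,
                           max_steps = max_steps, cache = cache)
      }
      nll_it <- attr(model, "nll")
      trace <- c(trace, nll_it)
      if (is.finite(nll_prev) &&
          (nll_prev - nll_it) / abs(nll_prev) < tol) {
        converged <- "relative_change"
        break
      }
      nll_prev <- nll_it
    }
    if (verbose) {
      message(sprintf("  run %d: nll %.2f after %d iterations (%s)",
                      run, utils::tail(trace, 1L), length(trace), converged))
    }
    list(model = model, trace = trace, converged = converged,
         nll = utils::tail(trace, 1L))
  }

  runs <- lapply(seq_len(n_runs), function(r) {
    tryCatch(run_one(r), error = function(e) {
      warning(sprintf("run %d failed: %s", r, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop_invalid("all training runs failed")
  nlls <- vapply(runs, function(r) if (is.null(r)) Inf else r$nll, numeric(1))
  best <- which.min(nlls)
  res <- runs[[best]]
  structure(
    list(model = res$model,
         objective_trace = res$trace,
         run_index = best,
         converged_by = res$converged,
         train_nll = res$nll,
         runs = data.frame(
           run = seq_len(n_runs),
           train_nll = nlls,
           converged_by = vapply(runs, function(r)
             if (is.null(r)) "failed" else r$converged, character(1)),
           n_iter = vapply(runs, function(r)
             if (is.null(r)) NA_integer_ else length(r$trace), integer(1)))),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model, best run %d (%s), train -LL = %.3f\n",
              x$model$kind, x$run_index, x$converged_by, x$train_nll))
  invisible(x)
}
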