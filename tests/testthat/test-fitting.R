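test_that("negative log-likelihood has its closed-form values", {
  # all-zero counts: -LL reduces to the summed rate
  r <- c(0.3, 1.2, 2)
  expect_equal(negative_log_likelihood(r, c(0, 0, 0)), sum(r))
  # direct Poisson arithmetic
  expect_equal(negative_log_likelihood(c(1, 2), c(1, 2)), 3 - log(2))
  # minimized over a constant rate at the sample mean
  counts <- c(0, 3, 1, 2, 5, 0, 1)
  nll_const <- function(r) negative_log_likelihood(rep(r, 7), counts)
  opt <- optimize(nll_const, c(0.01, 10))
  expect_equal(opt$minimum, mean(counts), tolerance = 1e-4)
  expect_error(negative_log_likelihood(c(1, 2), c(1, 2, 3)), "length")
})

test_that("analytic block gradients match central finite differences", {
  set.seed(31)
  n <- 400
  for (kind in all_kinds) {
    model <- random_model(kind)
    x <- rnorm(n)
    drive <- master_drive(model, x, rep(0L, n))
    counts <- if (kind == "feedback") {
      simulate_spikes(model, x, seed = 1)$counts
    } else {
      sample_spikes(eval_rectifier(model$rectifier, drive), seed = 1)
    }
    valid <- suppfilt:::default_valid(n, model$n_taps)
    for (block in blocks_of(kind)) {
      g <- nll_gradient(model, block, x, counts)
      par0 <- block_par_of(model, block)
      eps <- 1e-6
      gfd <- vapply(seq_along(par0), function(i) {
        pp <- par0; pp[i] <- pp[i] + eps
        pm <- par0; pm[i] <- pm[i] - eps
        (nll_of_block(model, block, pp, x, counts, valid) -
           nll_of_block(model, block, pm, x, counts, valid)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(g - gfd)) / max(abs(gfd)), 1e-5,
                label = sprintf("%s/%s gradient error", kind, block))
    }
  }
})

test_that("the rectifier offset gradient equals sum(1 - n/r)", {
  set.seed(32)
  model <- random_model("ln")
  x <- rnorm(300)
  rate <- forward(model, x)
  counts <- sample_spikes(rate, seed = 2)
  valid <- suppfilt:::default_valid(300, model$n_taps)
  g <- nll_gradient(model, "rectifier", x, counts)
  expect_equal(g[3], sum(1 - counts[valid] / rate[valid]), tolerance = 1e-8)
})

test_that("block contexts reproduce the master-structure variable assignment", {
  set.seed(33)
  x <- rnorm(200)
  for (kind in all_kinds) {
    model <- random_model(kind)
    counts <- rpois(200, 0.3)
    exc_out <- eval_nonlinearity(model$exc$nl,
                                 apply_filter(model$exc$taps, x))
    ctx <- make_block_context(model, "exc_filter", x, counts)
    if (kind == "ln") {
      expect_identical(ctx$X, x)
      expect_true(all(ctx$P == 0) && all(ctx$M == 1) && all(ctx$A == 0))
    } else if (kind == "subtractive") {
      sup_out <- eval_nonlinearity(model$sup$nl,
                                   apply_filter(model$sup$taps, x))
      expect_equal(ctx$P, sup_out)
      expect_identical(ctx$sign_P, -1)
      ctx_sup <- make_block_context(model, "sup_filter", x, counts)
      expect_identical(ctx_sup$X, x)
      expect_equal(ctx_sup$P, exc_out)
      expect_identical(ctx_sup$sign, -1)  # fixed negative branch sign
    } else if (kind == "divisive") {
      sup_out <- eval_nonlinearity(model$sup$nl,
                                   apply_filter(model$sup$taps, x))
      expect_equal(ctx$M, sup_out)
      ctx_sup <- make_block_context(model, "sup_filter", x, counts)
      expect_equal(ctx_sup$M, exc_out)
    } else {
      fb_out <- apply_filter(model$fb_taps,
                             c(0, counts[-200]))
      expect_equal(ctx$A, fb_out)
      expect_true(all(ctx$M == 1))
      ctx_fb <- make_block_context(model, "fb_filter", x, counts)
      expect_identical(ctx_fb$X, c(0, counts[-200]))
      expect_equal(ctx_fb$A, exc_out)
    }
  }
  m <- random_model("ln")
  expect_error(make_block_context(m, "sup_filter", x, rpois(200, 1)),
               "does not exist")
})

test_that("fit_block honors constraints and never increases the objective", {
  set.seed(34)
  truth <- random_model("divisive")
  x <- rnorm(3000)
  counts <- sample_spikes(forward(truth, x), seed = 3)
  model <- random_model("divisive")
  for (block in blocks_of("divisive")) {
    obj0 <- negative_log_likelihood(
      eval_rectifier(model$rectifier, master_drive(model, x, counts)),
      counts, suppfilt:::default_valid(3000, model$n_taps))
    model <- fit_block(model, block, x, counts)
    expect_lte(attr(model, "nll"), obj0 + 1e-6)
  }
  expect_constraints_hold(model)
  expect_lt(abs(suppfilt:::filter_norm(model$exc$taps) - 1), 1e-6)
  expect_lt(abs(suppfilt:::filter_tail_mean(model$exc$taps)), 1e-6)
})

test_that("initialization follows the five-run table and projects onto
           the constraint sets", {
  set.seed(35)
  n <- 2e4
  k <- suppfilt:::biphasic_filter(15, polarity = "off")
  x <- rnorm(n)
  counts <- rpois(n, pmax(0.05 + 0.5 * apply_filter(k, x), 0))
  feats <- compute_stc_features(x, counts, 15)
  # run 1, subtractive: exc = STA, sup = STC_1 (up to the tail projection)
  m1 <- initialize_run(1, "subtractive", feats, 15, seed = 1)
  expect_gt(abs(sum(m1$exc$taps * feats$sta)), 0.98)
  expect_gt(abs(sum(m1$sup$taps * feats$stc_first)), 0.98)
  expect_identical(m1$rectifier[c("a", "b", "c", "m")],
                   list(a = 0.1, b = 0, c = 0, m = 10))
  # run 5: noise filters, re-normalized
  m5a <- initialize_run(5, "divisive", feats, 15, seed = 7)
  m5b <- initialize_run(5, "divisive", feats, 15, seed = 8)
  expect_false(isTRUE(all.equal(m5a$exc$taps, m5b$exc$taps)))
  expect_lt(abs(sum(m5a$exc$taps * feats$sta)), 0.9)
  # every run of every kind satisfies the constraint set after projection
  for (kind in all_kinds) {
    for (run in 1:5) {
      m <- initialize_run(run, kind, feats, 15, seed = run)
      expect_silent(validate_model(m))
      expect_constraints_hold(m)
    }
  }
  expect_error(initialize_run(6, "ln", feats), "run_index")
  expect_error(initialize_run(1, "ln", NULL), "features")
})

test_that("fit_model converges, selects the best run, and tracks a
           non-increasing objective", {
  set.seed(36)
  cell <- make_cell("ln_off", seed = 2)
  built <- build_schedule(800, 200, 5, frame_rate_hz = 60, seed = 4)
  counts <- simulate_spikes(cell, built$stim, seed = 5)$counts
  fit <- fit_model("ln", built$stim, counts, built$schedule,
                   n_runs = 2, seed = 1, max_iter = 40)
  expect_s3_class(fit, "fit_result")
  expect_true(all(diff(fit$objective_trace) <= 1e-6))
  expect_equal(fit$train_nll, min(fit$runs$train_nll))
  expect_identical(fit$run_index, which.min(fit$runs$train_nll))
  expect_true(fit$converged_by %in% c("relative_change", "iteration_cap"))
  if (fit$converged_by == "relative_change") {
    expect_lt(length(fit$objective_trace), 40)
  }
  expect_constraints_hold(fit$model)
  # recovered excitatory filter resembles the generating one
  expect_gt(abs(sum(fit$model$exc$taps * cell$exc$taps)), 0.9)
})

test_that("the unified LN fit is competitive with the histogram-LN baseline", {
  set.seed(37)
  cell <- make_cell("ln_off", seed = 3)
  built <- build_schedule(1000, 200, 6, frame_rate_hz = 60, seed = 6)
  counts <- simulate_spikes(cell, built$stim, seed = 7)$counts
  n <- length(counts)
  masks <- suppfilt:::schedule_masks(built$schedule, n, 15)
  fit <- fit_model("ln", built$stim, counts, built$schedule,
                   n_runs = 2, seed = 2, max_iter = 40)
  info_fit <- info_per_spike(counts, forward(fit$model, built$stim),
                             masks$test)
  sta <- compute_sta(built$stim, counts, 15, valid = masks$train)
  hl <- histogram_ln(built$stim, counts, sta, valid = masks$train)
  info_hist <- info_per_spike(counts, predict(hl, built$stim), masks$test)
  expect_gte(info_fit, info_hist - 0.05)
})
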