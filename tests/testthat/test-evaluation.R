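test_that("information per spike has its closed-form values", {
  counts <- c(2, 0, 1, 3, 0)
  # mean-rate predictor carries zero information
  expect_equal(info_per_spike(counts, rep(mean(counts), 5)), 0)
  # direct arithmetic: LL difference over (total spikes * ln 2)
  cnt <- c(2, 0)
  pred <- c(2, 1e-12)
  ll <- function(r) sum(cnt * log(r) - r - lgamma(cnt + 1))
  want <- (ll(pred) - ll(rep(1, 2))) / (2 * log(2))
  expect_equal(info_per_spike(cnt, pred), want)
  # negative values are possible and must not be clipped
  expect_lt(info_per_spike(c(5, 0), c(0.1, 5)), 0)
  expect_error(info_per_spike(c(0, 0), c(1, 1)), "without spikes")
})

test_that("feedback information averages stochastic evaluations", {
  set.seed(41)
  model <- random_model("feedback")
  model$fb_taps <- numeric(model$n_taps)
  x <- rnorm(1000)
  counts <- sample_spikes(forward(model, x, spike_history = rep(0L, 1000)),
                          seed = 1)
  # zero feedback: every evaluation equals the LN value exactly
  v <- info_per_spike_feedback(model, x, counts, n_eval = 5, seed = 2)
  ln_info <- info_per_spike(counts, forward(model, x,
                                            spike_history = rep(0L, 1000)))
  expect_equal(as.numeric(v), ln_info)
  expect_true(all(attr(v, "per_eval") == ln_info))
  # reproducibility
  v2 <- info_per_spike_feedback(model, x, counts, n_eval = 5, seed = 2)
  expect_identical(as.numeric(v), as.numeric(v2))
  expect_error(info_per_spike_feedback(random_model("ln"), x, counts),
               "feedback")
})

test_that("Monte-Carlo averaging shrinks the feedback evaluation spread", {
  set.seed(42)
  model <- random_model("feedback", seed = 5)
  model$fb_taps <- suppfilt:::project_tail(-2 * exp(-(0:7) / 1.5))
  x <- rnorm(2000)
  counts <- simulate_spikes(model, x, seed = 1)$counts
  per_eval <- attr(info_per_spike_feedback(model, x, counts, n_eval = 100,
                                           seed = 3), "per_eval")
  se1 <- sd(per_eval)                      # spread of single evaluations
  means10 <- colMeans(matrix(per_eval, nrow = 10))
  se10 <- sd(means10)                      # spread of 10-evaluation means
  expect_lt(se10, se1)                     # ~ sqrt(10) reduction
  expect_gt(se1, 0)
})

test_that("Poisson explained variance and R^2 have their closed forms", {
  psth <- c(0.5, 1.5, 0.2, 2, 1)
  expect_equal(poisson_explained_variance(psth, psth), 1)
  expect_equal(poisson_explained_variance(psth, rep(mean(psth), 5)), 0)
  # hand-evaluated deviance for r = (1, 3), rhat = (2, 2)
  r <- c(1, 3); rhat <- c(2, 2)
  dev1 <- 2 * sum(r * log(r / rhat) - (r - rhat))
  dev0 <- 2 * sum(r * log(r / mean(r)) - (r - mean(r)))
  expect_equal(poisson_explained_variance(r, rhat), 1 - dev1 / dev0)
  # 0 * ln 0 convention
  expect_equal(poisson_explained_variance(c(0, 2), c(0.5, 1.5)),
               1 - (2 * (0.5 + 2 * log(2 / 1.5) - 0.5)) /
                 (2 * (2 * log(2 / 1) - 1 + 1)))
  expect_warning(poisson_explained_variance(c(1, 1.2), c(0, 1)), "floored")

  expect_equal(r_squared(psth, psth), 1)
  expect_equal(r_squared(psth, rep(mean(psth), 5)), 0)
  expect_equal(r_squared(c(0, 2), c(1, 1)), 0)
  expect_lt(r_squared(c(0, 1, 2), c(2, 1, 0)), 0)
  expect_true(is.na(r_squared(c(1, 1), c(1, 2))))
})

test_that("sliding windows count, label, and score as specified", {
  set.seed(43)
  psth <- runif(480)
  axis <- chirp_sweep_axis(480, "contrast")
  prof <- sliding_window_r2(psth, psth, axis, frame_rate_hz = 60)
  expect_identical(nrow(prof), 472L)           # 480 - 9 + 1
  expect_true(all(prof$r2 == 1, na.rm = TRUE))
  expect_equal(prof$axis[1], 0)                # first window starts at 0%
  noisy <- psth + rnorm(480, sd = 2)
  prof2 <- sliding_window_r2(psth, noisy, axis, frame_rate_hz = 60)
  expect_identical(nrow(prof2), 472L)
  expect_true(any(prof2$r2 < 0, na.rm = TRUE))
})

test_that("performance range spans the qualifying windows", {
  prof <- data.frame(axis = seq(0, 100, length.out = 101),
                     r2 = rep(-1, 101))
  expect_equal(performance_range(prof)$width, 0)
  prof$r2 <- 1
  pr <- performance_range(prof)
  expect_equal(c(pr$axis_min, pr$axis_max, pr$width), c(0, 100, 100))
  prof$r2 <- ifelse(prof$axis >= 20 & prof$axis <= 80, 0.5, -0.2)
  pr <- performance_range(prof)
  expect_equal(c(pr$axis_min, pr$axis_max, pr$width), c(20, 80, 60))
  # an isolated positive window at the far end must not inflate the range
  prof$r2[101] <- 0.5
  pr2 <- performance_range(prof)
  expect_equal(c(pr2$axis_min, pr2$axis_max), c(20, 80))
})

test_that("low-frequency performance averages the first ten windows", {
  prof <- data.frame(axis = 1:20, r2 = c(rep(1, 10), rep(0, 10)))
  expect_equal(low_frequency_performance(prof), 1)
  prof$r2 <- c(seq(1, 0.1, by = -0.1), rep(0, 10))
  expect_equal(low_frequency_performance(prof), 0.55)
  short <- data.frame(axis = 1:4, r2 = rep(0.5, 4))
  expect_warning(v <- low_frequency_performance(short), "windows")
  expect_equal(v, 0.5)
})

test_that("filter shift finds the cross-correlogram peak", {
  set.seed(44)
  k <- rnorm(12)
  expect_identical(filter_shift(k, k), 0L)
  delayed <- c(0, 0, k[1:10])
  expect_identical(filter_shift(k, delayed), 2L)
  # brute-force oracle over all lags
  a <- rnorm(12); b <- rnorm(12)
  cc <- sapply(-11:11, function(L) {
    s <- 0
    for (i in 1:12) {
      j <- i + L
      if (j >= 1 && j <= 12) s <- s + a[i] * b[j]
    }
    s
  })
  expect_identical(filter_shift(a, b), (-11:11)[which.max(cc)])
})

test_that("asymmetry index measures left/right imbalance", {
  knots <- tent_knots()
  sym <- tent_nonlinearity(pmax(exp(-knots^2 / 2), 1e-16), "bump")
  expect_equal(asymmetry_index(sym), 0)
  left <- ifelse(knots < 0, 1, 1e-16)
  left[8] <- 1
  one_sided <- tent_nonlinearity(suppfilt:::project_bump_weights(left, 8),
                                 "bump")
  expect_equal(asymmetry_index(one_sided), 1, tolerance = 1e-10)
  w <- pmax(c(rep(0.2, 7), 1, rep(0.6, 7)), 1e-16)
  nl <- tent_nonlinearity(suppfilt:::project_bump_weights(w, 8), "bump")
  expect_equal(asymmetry_index(nl),
               abs(sum(nl$weights[1:7]) - sum(nl$weights[9:15])) /
                 sum(nl$weights[-8]))
})

test_that("transiency classification uses the preferred step", {
  segs <- generate_chirp(60)$segments
  psth <- rep(0, 1380)
  on_idx <- 121:180
  psth[on_idx[1:6]] <- 10           # early peak
  psth[on_idx[-(1:6)]] <- 1         # sustained tail
  out <- classify_transiency(psth, segs, 60)
  expect_identical(c(out), "transient")
  psth[on_idx[-(1:6)]] <- 3         # ratio 0.3
  expect_identical(c(classify_transiency(psth, segs, 60)), "sustained")
  psth[on_idx[-(1:6)]] <- 2         # ratio exactly 0.2 -> sustained
  expect_identical(c(classify_transiency(psth, segs, 60)), "sustained")
  # OFF-dominated cell uses the OFF step
  psth <- rep(0, 1380)
  off_idx <- 181:240
  psth[off_idx[1:6]] <- 8
  expect_identical(c(classify_transiency(psth, segs, 60)), "transient")
})

test_that("ON-OFF detection follows the slope-ratio rule", {
  knots <- tent_knots()
  mk <- function(f) list(knots = knots, weights = f(knots))
  # U shape: sL = -1, sR = 1 -> index -0.5 -> ON-OFF
  u <- detect_on_off(mk(function(k) abs(k)))
  expect_true(c(u))
  expect_equal(attr(u, "index"), -0.5)
  # monotone rising: sL = sR = 1 -> +0.5 -> not ON-OFF
  r <- detect_on_off(mk(function(k) k))
  expect_false(c(r))
  expect_equal(attr(r, "index"), 0.5)
  # mild left slope: sL = -0.1, sR = 0.9 -> -0.1 -> not ON-OFF
  m <- detect_on_off(mk(function(k) ifelse(k < 0, -0.1 * k, 0.9 * k)))
  expect_false(c(m))
  expect_equal(attr(m, "index"), -0.1)
})

test_that("unit selection applies the five criteria to fixtures", {
  set.seed(45)
  n <- 6000
  fr <- 60
  lambda <- 0.05 + 1.5 * (sin(2 * pi * (1:500) / 50) > 0)
  trials <- t(vapply(1:20, function(i) rpois(500, lambda), numeric(500)))
  good <- list(counts = rpois(n, 0.15), frame_rate_hz = fr,
               species = "mouse", trials = trials,
               nl = list(knots = tent_knots(), weights = tent_knots()),
               info_train = c(ln = 0.2, subtractive = 0.3),
               info_test = c(ln = 0.18, subtractive = 0.28))
  drift <- good
  drift$counts <- rpois(n, seq(0.1, 0.3, length.out = n))  # 2x rate ramp
  quiet <- good
  quiet$counts <- rpois(n, 0.05)                           # 3 sp/s < 5 Hz
  onoff <- good
  onoff$nl <- list(knots = tent_knots(), weights = abs(tent_knots()))
  overfit <- good
  overfit$info_test <- c(ln = 0.05, subtractive = 0.28)
  crit <- select_units(list(good, drift, quiet, onoff, overfit), seed = 1)
  expect_true(all(crit[1, ]))
  expect_false(crit[2, "stationary"])
  expect_false(crit[3, "rate"])
  expect_false(crit[4, "not_on_off"])
  expect_false(crit[5, "generalization"])
  # every other criterion of the drift cell still passes
  expect_true(all(crit[2, c("rate", "reliability", "not_on_off",
                            "generalization")]))
})

test_that("duplicate units collapse to one representative per clique", {
  set.seed(46)
  n <- 1e4
  base <- rnorm(n)
  dup <- function() base + rnorm(n, sd = 0.5)   # pairwise r ~ 0.8
  rates <- rbind(dup(), dup(), dup(), rnorm(n), rnorm(n))
  kept <- dedup_units(rates)
  expect_identical(kept, c(1L, 4L, 5L))
  # independent traces all survive
  indep <- matrix(rnorm(5 * n), 5)
  expect_identical(dedup_units(indep), 1:5)
  # two identical traces -> one kept
  two <- rbind(base, base)
  expect_identical(dedup_units(two), 1L)
})

test_that("split-half reliability separates reliable from flat responses", {
  set.seed(47)
  lambda <- 0.05 + 2 * (sin(2 * pi * (1:400) / 40) > 0)
  reliable <- t(vapply(1:20, function(i) rpois(400, lambda), numeric(400)))
  flat <- t(vapply(1:20, function(i) rpois(400, 0.5), numeric(400)))
  expect_gt(split_half_reliability(reliable, seed = 1), 0.5)
  expect_lt(split_half_reliability(flat, seed = 1), 0.5)
})
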