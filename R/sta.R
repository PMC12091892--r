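#' Spike-triggered average
#'
#' Count-weighted mean of the `n_taps`-frame stimulus window preceding and
#' including each spike bin, returned in tau-order (tap 1 = spike bin) and
#' normalized to unit Euclidean norm.  The un-normalized vector is attached
#' as attribute `"raw"`.
#'
#' @param stim a [stimulus_trace()] or numeric vector.
#' @param counts spike counts per bin, aligned to the stimulus frames.
#' @param n_taps window length in frames.
#' @param valid optional logical mask of bins to use (e.g. training bins);
#'   bins before `n_taps` are always excluded.
#' @return unit-norm numeric vector of length `n_taps`.
#' @export
compute_sta <- function(stim, counts, n_taps, valid = NULL) {
  x <- stim_values(stim)
  counts <- as.numeric(counts)
  if (length(counts) != length(x)) {
    stop_invalid("counts length differs from stimulus length")
  }
  w <- counts
  w[seq_len(min(n_taps - 1L, length(w)))] <- 0
  if (!is.null(valid)) w[!valid] <- 0
  total <- sum(w)
  if (total < 1) stop_invalid("no spikes available for the STA")
  X <- lagged_matrix(x, n_taps)
  raw <- as.numeric(crossprod(X, w)) / total
  nn <- filter_norm(raw)
  if (nn < 1e-15) stop_invalid("degenerate (zero) spike-triggered average")
  out <- raw / nn
  attr(out, "raw") <- raw
  out
}

#' Spike-triggered covariance features
#'
#' Eigen-decomposition of the count-weighted covariance of spike-preceding
#' stimulus windows after projecting the STA direction out of every window.
#' The decomposition is performed in the orthogonal complement of the STA,
#' so both returned eigenvectors are orthogonal to the STA.  Returns the
#' first (largest-eigenvalue) and last (smallest-eigenvalue) components,
#' each unit-norm, which serve as initializers for suppressive filters.
#'
#' @inheritParams compute_sta
#' @return object of class `sta_features`: list with `sta`, `stc_first`,
#'   `stc_last`, `eigenvalues`, `n_spikes_used`.
#' @export
compute_stc_features <- function(stim, counts, n_taps, valid = NULL) {
  x <- stim_values(stim)
  counts <- as.numeric(counts)
  w <- counts
  w[seq_len(min(n_taps - 1L, length(w)))] <- 0
  if (!is.null(valid)) w[!valid] <- 0
  total <- sum(w)
  if (total < 1) stop_invalid("no spikes available for the STC analysis")
  if (total < n_taps) {
    warning("fewer spikes than filter taps; covariance is rank-deficient",
            call. = FALSE)
  }
  sta <- compute_sta(x, counts, n_taps, valid = valid)
  X <- lagged_matrix(x, n_taps)
  # project the STA direction out of every window
  Xp <- X - (X %*% sta) %*% t(sta)
  mu <- as.numeric(crossprod(Xp, w)) / total
  Xc <- sweep(Xp, 2L, mu)
  C <- crossprod(Xc * sqrt(w)) / total
  # orthonormal basis of the complement of the STA; eigenvectors with
  # meaningful variance live there, and the trivial zero-variance STA
  # direction is excluded from the ranking
  Q <- qr.Q(qr(cbind(sta, diag(n_taps))))[, 2L:n_taps, drop = FALSE]
  eig <- eigen(crossprod(Q, C %*% Q), symmetric = TRUE)
  first <- as.numeric(Q %*% eig$vectors[, 1L])
  last <- as.numeric(Q %*% eig$vectors[, n_taps - 1L])
  structure(list(sta = as.numeric(sta),
                 stc_first = first / filter_norm(first),
                 stc_last = last / filter_norm(last),
                 eigenvalues = eig$values,
                 n_spikes_used = total),
            class = "sta_features")
}

#' @export
print.sta_features <- function(x, ...) {
  cat(sprintf("<sta_features> %d taps, %g spikes; eigenvalues [%.3g, %.3g]\n",
              length(x$sta), x$n_spikes_used,
              min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Histogram-nonlinearity LN baseline
#'
#' The classical LN construction: a fixed filter (typically the STA or the
#' first STC component) and a nonlinearity computed as the histogram of
#' filter outputs versus mean spike counts.  Prediction looks the filtered
#' stimulus up in the histogram with linear interpolation between bin
#' centers; empty bins inherit the nearest non-empty bin's value.
#'
#' @param stim a [stimulus_trace()] or numeric vector (training stimulus).
#' @param counts spike counts per bin (training response).
#' @param filter filter taps in tau-order.
#' @param n_bins number of histogram bins (>= 2).
#' @param valid optional logical mask of training bins.
#' @return object of class `histogram_ln` with a [predict()] method.
#' @export
histogram_ln <- function(stim, counts, filter, n_bins = 40L, valid = NULL) {
  if (n_bins < 2L) stop_invalid("n_bins must be >= 2")
  x <- stim_values(stim)
  counts <- as.numeric(counts)
  n_taps <- length(filter)
  use <- seq_along(x) >= n_taps
  if (!is.null(valid)) use <- use & valid
  y <- apply_filter(filter, x)
  yv <- y[use]
  cv <- counts[use]
  breaks <- seq(min(yv), max(yv), length.out = n_bins + 1L)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  bin <- pmin(pmax(findInterval(yv, breaks, all.inside = TRUE), 1L), n_bins)
  values <- vapply(seq_len(n_bins), function(b) {
    if (any(bin == b)) mean(cv[bin == b]) else NA_real_
  }, numeric(1))
  if (anyNA(values)) {
    filled <- which(!is.na(values))
    for (b in which(is.na(values))) {
      values[b] <- values[filled[which.min(abs(filled - b))]]
    }
  }
  structure(list(filter = as.numeric(filter), centers = centers,
                 values = values, n_taps = n_taps),
            class = "histogram_ln")
}

#' Predict rates from a histogram-LN baseline
#'
#' @param object a [histogram_ln()] model.
#' @param stim a [stimulus_trace()] or numeric vector.
#' @param ... unused.
#' @return numeric rate vector (expected counts per bin) with attribute
#'   `valid_from`.
#' @export
predict.histogram_ln <- function(object, stim, ...) {
  y <- apply_filter(object$filter, stim_values(stim))
  rate <- stats::approx(object$centers, object$values, xout = y, rule = 2)$y
  rate <- pmax(rate, 0)
  attr(rate, "valid_from") <- object$n_taps
  rate
}

#' Classify temporal filters by PCA scores
#'
#' Principal component analysis (centered, unscaled) over a set of temporal
#' filters; each cell's scores on the first two components are compared to
#' symmetric thresholds to assign kinetic/polarity classes: slow ON
#' (`s1 > thr` and `s2 > thr`), fast ON (`s1 > thr`, `s2 < -thr`), slow OFF
#' (`s1 < -thr`, `s2 < -thr`), fast OFF (`s1 < -thr`, `s2 > thr`); anything
#' else is unclassified.  Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the labels deterministic;
#' the polarity/kinetics meaning of the score axes should be checked
#' against the mean filters of each class.
#'
#' @param filters matrix with one filter per row (or a list of equal-length
#'   vectors).
#' @param threshold score threshold (the classification uses `+/-
#'   threshold`).
#' @return factor with levels `slow_ON`, `fast_ON`, `slow_OFF`, `fast_OFF`,
#'   `unclassified` and attribute `"scores"` (n x 2 matrix).
#' @export
pca_classify_filters <- function(filters, threshold = 0.02) {
  if (is.list(filters)) filters <- do.call(rbind, filters)
  filters <- as.matrix(filters)
  if (nrow(filters) < 2L) stop_invalid("need at least 2 filters for PCA")
  p <- stats::prcomp(filters, center = TRUE, scale. = FALSE)
  scores <- p$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    load <- p$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  s1 <- scores[, 1L]
  s2 <- scores[, 2L]
  cls <- rep("unclassified", nrow(filters))
  cls[s1 > threshold & s2 > threshold] <- "slow_ON"
  cls[s1 > threshold & s2 < -threshold] <- "fast_ON"
  cls[s1 < -threshold & s2 < -threshold] <- "slow_OFF"
  cls[s1 < -threshold & s2 > threshold] <- "fast_OFF"
  out <- factor(cls, levels = c("slow_ON", "fast_ON", "slow_OFF", "fast_OFF",
                                "unclassified"))
  attr(out, "scores") <- scores
  out
}
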