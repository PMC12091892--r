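# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so seeded helpers never perturb the
# global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 101 + as.numeric(k) * 7919) %%
               .Machine$integer.max)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) < 1e-8)
}

# Half-open [start, end) frame intervals (0-based) as a data.frame.
make_intervals <- function(start, end) {
  data.frame(start = as.integer(start), end = as.integer(end))
}

# Logical mask over n frames (1-based positions) from 0-based intervals.
intervals_to_mask <- function(intervals, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals$start[i]
    b <- intervals$end[i]
    if (a < 0 || b > n || a >= b) {
      stop_invalid("interval [%d, %d) out of range for %d frames", a, b, n)
    }
    mask[(a + 1L):b] <- TRUE
  }
  mask
}
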