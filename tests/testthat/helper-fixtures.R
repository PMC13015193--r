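# Shared fixtures: default plant pieces, hand-built peak sets, and the
# brute-force peak-scan oracle used to validate the rle-based detector.

biceps <- default_plant()$flexor
triceps <- default_plant()$extensor

# Construct a peak_set directly from peak times/values (for classifier
# tests that do not need a full series).
make_peak_set <- function(times, values, baseline = -60) {
  structure(
    list(peaks = tibble::tibble(time = times, value = values),
         minima = tibble::tibble(time = numeric(0), value = numeric(0)),
         baseline = baseline),
    class = "peak_set"
  )
}

# Exhaustive per-sample scan: a sample (or exact-equality plateau) is a
# peak when strictly above both flanking values and above baseline;
# plateaus report their center sample (floor of the mean index).
brute_force_peaks <- function(values, times = seq_along(values),
                              baseline = -60) {
  n <- length(values)
  peak_idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    j <- i
    while (j < n && values[j + 1] == values[i]) j <- j + 1
    if (j <= n - 1 && values[i] > baseline &&
        values[i - 1] < values[i] && values[j + 1] < values[i]) {
      peak_idx <- c(peak_idx, (i + j) %/% 2)
    }
    i <- j + 1
  }
  tibble::tibble(time = times[peak_idx], value = values[peak_idx])
}

# Random piecewise-linear EMG-like signal starting/ending at baseline.
random_pl_signal <- function(n_knots = 8, n = 200, baseline = -60) {
  kx <- sort(c(1, n, sample(2:(n - 1), n_knots)))
  ky <- c(baseline, baseline + runif(length(kx) - 2, 0, 40), baseline)
  approx(kx, ky, xout = seq_len(n))$y
}

# Deterministic movement-producing command vector on the full topology:
# scans a seeded stream for a vector whose trial moves the arm.
find_moving_vector <- function(topology, min_excursion = 10, seed = 421) {
  set.seed(seed)
  for (i in 1:100) {
    v <- runif(topology$n_params)
    tr <- run_trial(v, topology)
    if (!isTRUE(attr(tr, "failed")) &&
        max(tr$angle) - tr$angle[1] >= min_excursion) {
      return(v)
    }
  }
  stop("no moving vector found in 100 draws")
}
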