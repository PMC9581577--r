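# Independent brute-force oracles used to cross-check the pipeline.

# Burst detection by explicit spike-by-spike scan: walk the train, grow a run
# while consecutive ISIs stay at or below the threshold, then apply the size
# floor (>= max(3, ceil(N/3000)) spikes) and, for valley thresholds above
# 0.1 s, the enclosure rule against the runs the 0.1 s detector accepts.
oracle_bursts <- function(st, threshold, flag = "bimodal", fallback = 0.1) {
  n <- length(st)
  min_spikes <- max(3, ceiling(n / 3000))
  runs_at <- function(thr) {
    res <- list()
    i <- 1L
    while (i < n) {
      if (st[i + 1L] - st[i] <= thr) {
        j <- i + 1L
        while (j < n && st[j + 1L] - st[j] <= thr) j <- j + 1L
        res[[length(res) + 1L]] <- c(i, j)
        i <- j + 1L
      } else i <- i + 1L
    }
    res
  }
  cand <- if (n >= 2) runs_at(threshold) else list()
  cand <- Filter(function(r) r[2] - r[1] + 1L >= min_spikes, cand)
  if (identical(flag, "enclosure-required") && length(cand)) {
    ref <- Filter(function(r) r[2] - r[1] + 1L >= min_spikes, runs_at(fallback))
    cand <- Filter(function(r)
      any(vapply(ref, function(q) q[1] >= r[1] && q[2] <= r[2], logical(1))),
      cand)
  }
  if (!length(cand))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  data.frame(start = vapply(cand, function(r) st[r[1]], numeric(1)),
             end = vapply(cand, function(r) st[r[2]], numeric(1)),
             n_spikes = vapply(cand, function(r) r[2] - r[1] + 1L, integer(1)))
}

# random spike train for the burst property sweep: mixes short (in-burst) and
# long (between-burst) ISI scales so runs of every size occur
random_train <- function(max_spikes = 50) {
  n <- sample.int(max_spikes, 1)
  if (n == 1) return(stats::runif(1, 0, 10))
  isi <- ifelse(stats::runif(n - 1) < 0.6,
                stats::rexp(n - 1, 1 / 0.02),
                stats::rexp(n - 1, 1 / 0.8))
  cumsum(c(stats::runif(1, 0, 1), isi))
}

# mean-of-top-decile / 3 by explicit sorting and hand-rolled linear
# interpolation between order statistics
oracle_nb_threshold <- function(v) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * 0.9
  lo <- floor(h)
  q90 <- s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  mean(v[v >= q90]) / 3
}

# entropy by direct elementwise summation
oracle_entropy <- function(p) {
  tot <- 0
  for (pi in p) if (pi > 0) tot <- tot - pi * log(pi)
  tot
}

# wrap a probability vector as a log-ISI histogram object
make_hist <- function(p, bins_per_decade = 10) {
  N <- length(p)
  edges <- seq(-3, -3 + N / bins_per_decade, by = 1 / bins_per_decade)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-(N + 1)]) / 2,
                 p = p, counts = NULL, N = N),
            class = "log_isi_histogram")
}

# fabricate a spike_events object from raw pieces (for sorting tests)
make_events <- function(waveforms, times = NULL, electrode = "11",
                        sample_rate = 32000) {
  n <- nrow(waveforms)
  if (is.null(times)) times <- seq_len(n) * 0.01
  amp <- waveforms[cbind(seq_len(n), max.col(abs(waveforms)))]
  structure(list(electrode_id = electrode,
                 peak_index = as.integer(round(times * sample_rate)) + 1L,
                 peak_time = times,
                 amplitude = amp,
                 waveforms = waveforms,
                 sigma = 1, k = 5, sample_rate = sample_rate),
            class = "spike_events")
}
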