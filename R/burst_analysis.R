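#' Log-ISI histogram of a spike train
#'
#' Probability mass function of base-10 log interspike intervals over
#' uniform log10 bins (default 10 bins per decade from 1 ms to 100 s; ISIs
#' outside the range are clipped into the end bins). Requires at least three
#' spikes (two ISIs); units with fewer are treated as non-bursting.
#'
#' @param spike_times ascending spike times (s).
#' @param bins_per_decade bins per decade of ISI.
#' @param range ISI range (s), length 2.
#' @return An object of class `log_isi_histogram`: list with `bin_edges`
#'   (log10 s), `bin_centers` (log10 s), `p` (sums to 1), `N` (bin count)
#'   and `counts`; or `NULL` when fewer than 3 spikes.
#' @export
log_isi_histogram <- function(spike_times, bins_per_decade = 10,
                              range = c(1e-3, 1e2)) {
  if (length(spike_times) < 3) return(NULL)
  isi <- diff(spike_times)
  if (any(isi <= 0)) stop("spike_times must be strictly increasing")
  lo <- log10(range[1]); hi <- log10(range[2])
  edges <- seq(lo, hi, by = 1 / bins_per_decade)
  # snap to 1e-9 so ISIs landing numerically on a bin edge bin consistently
  l <- round(pmin(pmax(log10(isi), lo), hi), 9)
  # right-closed bins; values at the left edge fall in the first bin
  bin <- pmin(pmax(findInterval(l, edges, rightmost.closed = TRUE), 1L),
              length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 p = counts / sum(counts),
                 counts = counts,
                 N = length(edges) - 1L),
            class = "log_isi_histogram")
}

# local maxima of a vector (strictly above both flat-resolved neighbours)
.local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      # walk over any plateau
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j <= n - 1L && y[j + 1L] < y[j]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

#' Adaptive burst threshold from a log-ISI histogram
#'
#' Implements the valley-seeking rule of the adaptive log-ISI method: the
#' lightly smoothed histogram is scanned for peaks; a peak pair qualifies
#' when the first peak sits below `intra_max` (100 ms, the intra-burst
#' regime) and the void parameter of the valley between them,
#' `1 - h_valley / sqrt(h1 * h2)`, is at least `void_min`. The threshold is
#' the ISI at the deepest bin between the best-separated qualifying pair.
#' Without a qualifying pair the threshold falls back to 0.1 s; a threshold
#' above 0.1 s additionally triggers the enclosure rule in
#' [detect_bursts()].
#'
#' @param hist a [log_isi_histogram()].
#' @param void_min minimum void parameter certifying bimodality.
#' @param intra_max largest ISI (s) allowed for the intra-burst peak.
#' @param fallback fallback threshold (s).
#' @return List with `threshold` (s) and `flag`: one of `"bimodal"`,
#'   `"fallback"`, `"enclosure-required"`.
#' @export
find_burst_threshold <- function(hist, void_min = 0.7, intra_max = 0.1,
                                 fallback = 0.1) {
  if (is.null(hist)) return(list(threshold = fallback, flag = "fallback"))
  stopifnot(inherits(hist, "log_isi_histogram"))
  p <- hist$p
  # light 3-bin moving-average smoothing
  ps <- stats::filter(c(p[1], p, p[length(p)]), rep(1 / 3, 3))[2:(length(p) + 1)]
  ps <- as.numeric(ps)
  centers <- 10^hist$bin_centers
  peaks <- .local_peaks(ps)
  best <- NULL
  if (length(peaks) >= 2) {
    for (a in seq_len(length(peaks) - 1)) {
      if (centers[peaks[a]] >= intra_max) next
      for (b in (a + 1):length(peaks)) {
        between <- (peaks[a] + 1):(peaks[b] - 1)
        if (!length(between)) next
        vmin <- min(ps[between])
        void <- 1 - vmin / sqrt(ps[peaks[a]] * ps[peaks[b]])
        if (void >= void_min && (is.null(best) || void > best$void)) {
          vi <- between[which.min(ps[between])]
          best <- list(void = void, valley = vi)
        }
      }
    }
  }
  if (is.null(best)) return(list(threshold = fallback, flag = "fallback"))
  thr <- centers[best$valley]
  list(threshold = thr,
       flag = if (thr > fallback) "enclosure-required" else "bimodal")
}

# maximal runs of consecutive spikes with ISI <= threshold, as index ranges
.isi_runs <- function(spike_times, threshold) {
  n <- length(spike_times)
  if (n < 2) return(list(first = integer(0), last = integer(0)))
  short <- diff(spike_times) <= threshold
  if (!any(short)) return(list(first = integer(0), last = integer(0)))
  idx <- which(short)
  first <- idx[c(TRUE, diff(idx) > 1L)]
  last <- idx[c(diff(idx) > 1L, TRUE)] + 1L
  list(first = first, last = last)
}

#' Detect bursts in a spike train
#'
#' Candidate bursts are maximal runs of consecutive spikes whose ISIs do not
#' exceed the threshold. Candidates with fewer than `max(3, ceil(N/3000))`
#' spikes (N = total spikes of the unit) are excluded. When the threshold
#' came from a valley above 0.1 s (`flag = "enclosure-required"`), only
#' candidates that fully enclose at least one burst that the 0.1 s detector
#' itself accepts are kept.
#'
#' @param spike_times ascending spike times (s) of one unit (or an
#'   [mea_unit()]).
#' @param threshold ISI threshold (s), > 0.
#' @param flag threshold flag from [find_burst_threshold()].
#' @param enclosure_threshold reference threshold (s) for the enclosure rule.
#' @return Data frame of class `burst_set` with columns `start`, `end`,
#'   `n_spikes`, `i_first`, `i_last` (spike indices), ordered and
#'   non-overlapping.
#' @export
detect_bursts <- function(spike_times, threshold, flag = "bimodal",
                          enclosure_threshold = 0.1) {
  if (inherits(spike_times, "mea_unit")) spike_times <- spike_times$spike_times
  if (threshold <= 0) stop("threshold must be > 0")
  n_total <- length(spike_times)
  min_spikes <- max(3, ceiling(n_total / 3000))
  runs <- .isi_runs(spike_times, threshold)
  keep <- (runs$last - runs$first + 1L) >= min_spikes
  first <- runs$first[keep]; last <- runs$last[keep]
  if (identical(flag, "enclosure-required") && length(first)) {
    ref <- .isi_runs(spike_times, enclosure_threshold)
    rkeep <- (ref$last - ref$first + 1L) >= min_spikes
    rf <- ref$first[rkeep]; rl <- ref$last[rkeep]
    encl <- vapply(seq_along(first), function(i)
      any(rf >= first[i] & rl <= last[i]), logical(1))
    first <- first[encl]; last <- last[encl]
  }
  structure(data.frame(start = spike_times[first],
                       end = spike_times[last],
                       n_spikes = last - first + 1L,
                       i_first = first, i_last = last),
            class = c("burst_set", "data.frame"))
}

#' Burstiness of a unit
#'
#' Fraction of a unit's spikes that fall inside its detected bursts:
#' (sum of burst spike counts) / (total spikes). 0 when no bursts, 1 when
#' every spike is within a burst.
#'
#' @param spike_times spike times of the unit (or an [mea_unit()]).
#' @param bursts a [detect_bursts()] result.
#' @return Fraction in \[0, 1\]; `NA` for a unit without spikes.
#' @export
burstiness <- function(spike_times, bursts) {
  if (inherits(spike_times, "mea_unit")) spike_times <- spike_times$spike_times
  n <- length(spike_times)
  if (n == 0) return(NA_real_)
  sum(bursts$n_spikes) / n
}

#' Burst analysis of one unit (threshold + detection + burstiness)
#'
#' Convenience wrapper running [log_isi_histogram()],
#' [find_burst_threshold()] and [detect_bursts()] for one unit.
#'
#' @param unit an [mea_unit()] or spike-time vector.
#' @param bins_per_decade,range passed to [log_isi_histogram()].
#' @param void_min,intra_max,fallback passed to [find_burst_threshold()].
#' @return List with `threshold`, `flag`, `bursts`, `burstiness`,
#'   `histogram`.
#' @export
unit_bursts <- function(unit, bins_per_decade = 10, range = c(1e-3, 1e2),
                        void_min = 0.7, intra_max = 0.1, fallback = 0.1) {
  st <- if (inherits(unit, "mea_unit")) unit$spike_times else unit
  hist <- log_isi_histogram(st, bins_per_decade, range)
  if (is.null(hist)) {
    bursts <- structure(data.frame(start = numeric(0), end = numeric(0),
                                   n_spikes = integer(0), i_first = integer(0),
                                   i_last = integer(0)),
                        class = c("burst_set", "data.frame"))
    return(list(threshold = NA_real_, flag = "too-few-spikes", bursts = bursts,
                burstiness = if (length(st)) 0 else NA_real_, histogram = NULL))
  }
  th <- find_burst_threshold(hist, void_min = void_min, intra_max = intra_max,
                             fallback = fallback)
  bursts <- detect_bursts(st, th$threshold, th$flag,
                          enclosure_threshold = fallback)
  list(threshold = th$threshold, flag = th$flag, bursts = bursts,
       burstiness = burstiness(st, bursts), histogram = hist)
}

#' Export bursts to CSV
#'
#' @param bursts_by_unit named list of `burst_set` data frames.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_bursts <- function(bursts_by_unit, path) {
  df <- do.call(rbind, lapply(names(bursts_by_unit), function(u) {
    b <- bursts_by_unit[[u]]
    if (!nrow(b)) return(NULL)
    data.frame(unit_id = u, start_s = b$start, end_s = b$end,
               n_spikes = b$n_spikes)
  }))
  if (is.null(df))
    df <- data.frame(unit_id = character(), start_s = numeric(),
                     end_s = numeric(), n_spikes = integer())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
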