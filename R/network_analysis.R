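#' Number of concurrently bursting units over time
#'
#' Builds a uniform time series over the recording (default resolution 1 ms)
#' whose value at sample time t is the number of units whose burst interval
#' covers t (closed intervals). Burst edges are spike times far coarser than
#' the resolution, so this series carries the same intervals as a
#' per-raw-sample construction at a fraction of the memory.
#'
#' @param bursts_by_unit list of `burst_set` data frames, one per unit.
#' @param duration recording duration (s).
#' @param dt series resolution (s).
#' @return Object of class `burst_count_series`: list with `counts`
#'   (integer vector), `dt`, `duration`. Sample i sits at time `(i-1) * dt`.
#' @export
burst_count_series <- function(bursts_by_unit, duration, dt = 1e-3) {
  n <- round(duration / dt) + 1L
  counts <- integer(n)
  for (b in bursts_by_unit) {
    if (is.null(b) || !nrow(b)) next
    if (any(b$start < 0 | b$end > duration))
      stop("burst intervals must lie within [0, duration]")
    i0 <- ceiling(b$start / dt - 1e-9) + 1L      # first sample time >= start
    i1 <- floor(b$end / dt + 1e-9) + 1L          # last sample time <= end
    ok <- i1 >= i0
    for (j in which(ok)) {
      counts[i0[j]] <- counts[i0[j]] + 1L
      if (i1[j] + 1L <= n) counts[i1[j] + 1L] <- counts[i1[j] + 1L] - 1L
    }
  }
  counts <- cumsum(counts)
  structure(list(counts = as.integer(counts), dt = dt, duration = duration),
            class = "burst_count_series")
}

#' Network-burst detection threshold
#'
#' One-third of the mean of the top decile of the burst-count series: the
#' 90th percentile of the counts is found (linear interpolation between
#' order statistics) and the mean of all samples at or above it is divided
#' by 3.
#'
#' @param series a [burst_count_series()] (or bare numeric vector).
#' @return Threshold (units concurrently bursting).
#' @export
nb_threshold <- function(series) {
  v <- if (inherits(series, "burst_count_series")) series$counts else series
  if (!length(v)) stop("series must be non-empty")
  q90 <- stats::quantile(v, 0.9, names = FALSE, type = 7)
  mean(v[v >= q90]) / 3
}

#' Detect network bursts
#'
#' Network bursts are maximal runs of the burst-count series with at least
#' `max(threshold, 1)` units bursting concurrently. Each candidate's spike
#' count totals the spikes of *all* units inside its interval; candidates
#' with fewer than `max(10, ceil(total bursting spikes on the array / 300))`
#' spikes are excluded.
#'
#' @param series a [burst_count_series()].
#' @param threshold from [nb_threshold()].
#' @param units list of [mea_unit()] (all sorted units of the array).
#' @param bursts_by_unit the per-unit `burst_set`s used to build `series`
#'   (provides the total-bursting-spikes exclusion quantity and
#'   participation).
#' @return Data frame of class `network_burst_set` with columns `start`,
#'   `end`, `n_spikes`, `n_units`, plus attribute `participating` (list of
#'   unit-id vectors).
#' @export
detect_network_bursts <- function(series, threshold, units, bursts_by_unit) {
  stopifnot(inherits(series, "burst_count_series"))
  if (threshold < 0) stop("threshold must be >= 0")
  counts <- series$counts
  dt <- series$dt
  need <- max(threshold, 1)
  over <- counts >= need
  empty <- structure(data.frame(start = numeric(0), end = numeric(0),
                                n_spikes = integer(0), n_units = integer(0)),
                     participating = list(),
                     class = c("network_burst_set", "data.frame"))
  if (!any(over)) return(empty)
  idx <- which(over)
  run_first <- idx[c(TRUE, diff(idx) > 1L)]
  run_last <- idx[c(diff(idx) > 1L, TRUE)]
  start <- (run_first - 1L) * dt
  end <- (run_last - 1L) * dt
  total_bursting <- sum(vapply(bursts_by_unit, function(b)
    if (is.null(b)) 0L else sum(b$n_spikes), numeric(1)))
  min_spikes <- max(10, ceiling(total_bursting / 300))
  all_times <- lapply(units, function(u) u$spike_times)
  n_spikes <- vapply(seq_along(start), function(i)
    sum(vapply(all_times, function(st)
      sum(st >= start[i] & st <= end[i]), numeric(1))), numeric(1))
  participating <- lapply(seq_along(start), function(i) {
    ids <- vapply(units, function(u) u$unit_id, character(1))
    has <- vapply(seq_along(units), function(j) {
      b <- bursts_by_unit[[ids[j]]]
      if (is.null(b) || !nrow(b)) return(FALSE)
      any(b$start <= end[i] & b$end >= start[i])
    }, logical(1))
    ids[has]
  })
  keep <- n_spikes >= min_spikes & end > start
  structure(data.frame(start = start[keep], end = end[keep],
                       n_spikes = as.integer(n_spikes[keep]),
                       n_units = lengths(participating)[keep]),
            participating = participating[keep],
            class = c("network_burst_set", "data.frame"))
}

#' Network burstiness of a unit
#'
#' Fraction of a unit's spikes that fall inside any network-burst interval.
#'
#' @param spike_times spike times of the unit (or an [mea_unit()]).
#' @param nbs a `network_burst_set` from [detect_network_bursts()].
#' @return Fraction in \[0, 1\]; `NA` for a unit without spikes.
#' @export
network_burstiness <- function(spike_times, nbs) {
  if (inherits(spike_times, "mea_unit")) spike_times <- spike_times$spike_times
  n <- length(spike_times)
  if (n == 0) return(NA_real_)
  if (!nrow(nbs)) return(0)
  inside <- vapply(spike_times, function(t)
    any(t >= nbs$start & t <= nbs$end), logical(1))
  sum(inside) / n
}

#' Summary statistics of a network-burst set
#'
#' @param nbs a `network_burst_set`.
#' @param duration recording duration (s).
#' @return List with `count_per_10min` (count scaled to a 600 s basis) and
#'   `mean_duration_s` (`NA` when no network bursts).
#' @export
nb_summary <- function(nbs, duration) {
  if (duration <= 0) stop("duration must be > 0")
  list(count_per_10min = nrow(nbs) * 600 / duration,
       mean_duration_s = if (nrow(nbs)) mean(nbs$end - nbs$start) else NA_real_)
}

#' Per-electrode activity map
#'
#' Mean amplitude envelope (mean absolute value) of the filtered signal over
#' a time window, per electrode, arranged on the layout grid. This is the
#' quantity behind array "heat-map" snapshots of a network burst.
#'
#' @param rec a filtered [raw_recording()].
#' @param window numeric length-2, `c(t0, t1)` in seconds.
#' @param layout an [mea_layout()]; defaults to the recording's.
#' @return Data frame with `electrode_id`, `x`, `y`, `value` (uV; `NA` for
#'   layout electrodes without a trace).
#' @export
activity_map <- function(rec, window, layout = rec$layout) {
  stopifnot(inherits(rec, "raw_recording"), length(window) == 2)
  if (window[1] < 0 || window[2] > rec$duration || window[2] <= window[1])
    stop("window must be a non-empty interval within the recording")
  i0 <- floor(window[1] * rec$sample_rate) + 1L
  i1 <- min(ceiling(window[2] * rec$sample_rate) + 1L,
            round(rec$duration * rec$sample_rate))
  val <- vapply(layout$electrode_id, function(id) {
    tr <- rec$traces[[id]]
    if (is.null(tr)) NA_real_ else mean(abs(tr[i0:i1]))
  }, numeric(1))
  data.frame(electrode_id = layout$electrode_id, x = layout$x, y = layout$y,
             value = unname(val))
}

#' Export network bursts to CSV
#'
#' @param nbs a `network_burst_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_network_bursts <- function(nbs, path) {
  utils::write.csv(data.frame(start_s = nbs$start, end_s = nbs$end,
                              n_spikes = nbs$n_spikes, n_units = nbs$n_units),
                   path, row.names = FALSE)
  invisible(path)
}
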