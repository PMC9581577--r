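#' Is a unit active?
#'
#' A unit is active when it fires strictly more than 10 spikes per minute
#' over the recording.
#'
#' @param unit an [mea_unit()] or a spike count.
#' @param duration recording duration (s), > 0.
#' @param rate_min threshold (spikes/min).
#' @return Logical.
#' @export
is_active <- function(unit, duration, rate_min = 10) {
  if (duration <= 0) stop("duration must be > 0")
  n <- if (inherits(unit, "mea_unit")) unit$n_spikes else as.numeric(unit)
  n / (duration / 60) > rate_min
}

#' Mean firing rate over active units
#'
#' Mean of spikes-per-second across the active units of an array (units
#' firing > 10 spikes/min); inactive units do not enter the mean.
#'
#' @param units list of [mea_unit()].
#' @param duration recording duration (s).
#' @param rate_min active-unit threshold (spikes/min).
#' @return Spikes/s, or `NA` when no unit is active.
#' @export
mean_firing_rate <- function(units, duration, rate_min = 10) {
  act <- vapply(units, is_active, logical(1), duration = duration,
                rate_min = rate_min)
  if (!any(act)) return(NA_real_)
  mean(vapply(units[act], function(u) u$n_spikes / duration, numeric(1)))
}

#' Shannon entropy of a log-ISI histogram
#'
#' `-sum(p_i * ln p_i)` over occupied bins of the normalized log-ISI
#' histogram (0 * ln 0 taken as 0), in nats. Zero for a single occupied bin
#' (clock-like firing); at most `ln N` for `N` bins (attained by the
#' uniform histogram).
#'
#' @param hist a [log_isi_histogram()].
#' @return An object of class `entropy_value`: list with `entropy` (nats)
#'   and `N`.
#' @export
isi_entropy <- function(hist) {
  stopifnot(inherits(hist, "log_isi_histogram"))
  p <- hist$p
  if (abs(sum(p) - 1) > 1e-9) stop("histogram is not normalized")
  pp <- p[p > 0]
  structure(list(entropy = -sum(pp * log(pp)), N = hist$N),
            class = "entropy_value")
}

#' Instantaneous-rate vector of a unit (log10 inverse ISI at 320 Hz)
#'
#' For each consecutive spike pair the inverse ISI (Hz) fills the whole span
#' between the two spikes; before the first and after the last spike the
#' adjacent interval's value is extended. The base-10 logarithm of that
#' piecewise-constant signal is evaluated directly on a uniform 320 Hz grid
#' covering the recording.
#'
#' @param unit an [mea_unit()] or spike-time vector (needs >= 2 spikes).
#' @param duration recording duration (s).
#' @param sample_rate grid rate (Hz).
#' @return Numeric vector of length `round(duration * sample_rate)`, or
#'   `NULL` when fewer than 2 spikes.
#' @export
rate_vector <- function(unit, duration, sample_rate = 320) {
  st <- if (inherits(unit, "mea_unit")) unit$spike_times else unit
  if (length(st) < 2) return(NULL)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  vals <- log10(1 / diff(st))
  k <- findInterval(t, st)            # 0 before first spike, m after last
  k <- pmin(pmax(k, 1L), length(vals))
  vals[k]
}

#' Pairwise correlation of unit rate vectors
#'
#' Zero-lag Pearson correlation between the log10 inverse-ISI rate vectors
#' of unit pairs. Pairs of units sorted from the same electrode are excluded
#' (spike-sorting artifacts induce spurious negative correlation), as are
#' zero-variance vectors.
#'
#' @param vectors named list of rate vectors (equal length), one per unit.
#' @param electrode_of named character vector mapping unit id to electrode.
#' @return List with `correlation` (symmetric matrix, `NA` where excluded),
#'   `excluded` (logical matrix, `TRUE` for same-electrode or degenerate
#'   pairs) and `mean_correlation` (mean over included off-diagonal pairs).
#' @export
pairwise_correlation <- function(vectors, electrode_of) {
  ids <- names(vectors)
  stopifnot(!is.null(ids), all(ids %in% names(electrode_of)))
  m <- length(ids)
  if (m < 2) stop("need >= 2 rate vectors")
  X <- do.call(cbind, vectors)
  sds <- apply(X, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(X))
  same_el <- outer(electrode_of[ids], electrode_of[ids], "==")
  degen <- outer(sds == 0, sds == 0, "|")
  excluded <- (same_el | degen)
  diag(excluded) <- FALSE
  cm <- cc
  cm[same_el & row(cm) != col(cm)] <- NA
  cm[degen] <- NA
  dimnames(cm) <- list(ids, ids)
  off <- upper.tri(cm) & !excluded & !is.na(cm)
  list(correlation = cm,
       excluded = excluded,
       mean_correlation = if (any(off)) mean(cm[off]) else NA_real_)
}

#' Per-unit metrics table
#'
#' One row per unit: spike count, firing rate, activity flag, burstiness,
#' network burstiness and log-ISI entropy.
#'
#' @param units list of [mea_unit()].
#' @param duration recording duration (s).
#' @param bursts_by_unit named list of `burst_set`s.
#' @param nbs a `network_burst_set` (may be empty).
#' @param bins_per_decade,range passed to [log_isi_histogram()].
#' @return Data frame.
#' @export
unit_metrics_table <- function(units, duration, bursts_by_unit, nbs,
                               bins_per_decade = 10, range = c(1e-3, 1e2)) {
  rows <- lapply(units, function(u) {
    b <- bursts_by_unit[[u$unit_id]]
    hist <- log_isi_histogram(u$spike_times, bins_per_decade, range)
    data.frame(unit_id = u$unit_id,
               electrode_id = u$electrode_id,
               n_spikes = u$n_spikes,
               firing_rate = u$n_spikes / duration,
               active = is_active(u, duration),
               burstiness = if (is.null(b)) 0 else burstiness(u, b),
               network_burstiness = network_burstiness(u, nbs),
               entropy = if (is.null(hist)) NA_real_ else isi_entropy(hist)$entropy)
  })
  do.call(rbind, rows)
}
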