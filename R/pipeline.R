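#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its default: the band-pass
#' filter (250-3000 Hz, order 2), the detection threshold (5 SD, 1 ms dead
#' time), the sorting scan (k_max 6, 10 restarts, 20% knee drop), the burst
#' detector (10 bins/decade over 1 ms - 100 s, void >= 0.7, intra-burst
#' peak < 0.1 s, 0.1 s fallback), the network-burst detector (1 ms series,
#' top-decile/3 threshold, floors 10 and N/300), the activity metrics
#' (active > 10 spikes/min, 320 Hz rate vectors), the bootstrap (B = 6000,
#' 5th-95th percentiles), and the imaging chain (1.4 SD segmentation,
#' 15/300 um band-pass, 31 um clusterness window). Serializes losslessly to
#' JSON via [save_config()] / [load_config()].
#'
#' @param ... overrides of the defaults listed above.
#' @param seed master RNG seed for the run.
#' @return Object of class `mea_run_config` (a named list).
#' @export
run_config <- function(..., seed = 1) {
  cfg <- list(
    filter_low = 250, filter_high = 3000, filter_order = 2,
    detect_k = 5, dead_time = 1e-3, waveform_pre = 1e-3, waveform_post = 2e-3,
    sort_k_max = 6, sort_restarts = 10, sort_min_drop = 0.2,
    sort_min_resid = 0.15,
    isi_bins_per_decade = 10, isi_range = c(1e-3, 1e2),
    burst_void_min = 0.7, burst_intra_max = 0.1, burst_fallback = 0.1,
    nb_dt = 1e-3,
    active_rate_min = 10, rate_vector_hz = 320,
    bootstrap_B = 6000,
    image_k = 1.4, image_sigma_low = 15, image_sigma_high = 300,
    clusterness_window_um = 31, hue_invert = FALSE,
    seed = seed)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "mea_run_config")
}

#' @rdname run_config
#' @param config an `mea_run_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(x) if (is.integer(x)) as.numeric(x) else x)
  do.call(run_config, cfg)
}

#' Analyze one recording end to end
#'
#' Runs the full electrophysiology chain on a raw recording: band-pass
#' filtering, per-electrode noise estimation and spike detection, spike
#' sorting into units, per-unit burst detection, network-burst detection,
#' and the per-unit activity metrics (firing rate, burstiness, network
#' burstiness, entropy) plus the pairwise rate-vector correlation of active
#' units across electrodes.
#'
#' @param rec a [raw_recording()].
#' @param config an [run_config()].
#' @return Object of class `mea_analysis`: list with `units`, `sortings`,
#'   `bursts_by_unit`, `thresholds`, `network_bursts`, `nb_threshold`,
#'   `metrics` (per-unit data frame), `correlation`, `summary` (named list
#'   of array-level numbers), `config`, `metadata`.
#' @export
analyze_recording <- function(rec, config = run_config()) {
  stopifnot(inherits(rec, "raw_recording"), inherits(config, "mea_run_config"))
  filtered <- bandpass_filter(rec, config$filter_low, config$filter_high,
                              config$filter_order)
  units <- list()
  sortings <- list()
  for (el in names(filtered$traces)) {
    tr <- filtered$traces[[el]]
    noise <- estimate_noise(tr, electrode_id = el)
    if (noise$sigma <= 0) next
    ev <- detect_spikes(tr, noise, filtered$sample_rate, k = config$detect_k,
                        dead_time = config$dead_time,
                        pre = config$waveform_pre, post = config$waveform_post,
                        electrode_id = el)
    srt <- sort_electrode(ev, k_max = config$sort_k_max,
                          n_restarts = config$sort_restarts,
                          min_drop = config$sort_min_drop,
                          min_resid = config$sort_min_resid,
                          seed = config$seed)
    sortings[[el]] <- srt$sorting
    units <- c(units, srt$units)
  }
  names(units) <- vapply(units, `[[`, character(1), "unit_id")
  bursts_by_unit <- list()
  thresholds <- list()
  for (u in units) {
    ub <- unit_bursts(u, bins_per_decade = config$isi_bins_per_decade,
                      range = config$isi_range,
                      void_min = config$burst_void_min,
                      intra_max = config$burst_intra_max,
                      fallback = config$burst_fallback)
    bursts_by_unit[[u$unit_id]] <- ub$bursts
    thresholds[[u$unit_id]] <- list(threshold = ub$threshold, flag = ub$flag)
  }
  series <- burst_count_series(bursts_by_unit, rec$duration, config$nb_dt)
  thr <- nb_threshold(series)
  nbs <- detect_network_bursts(series, thr, units, bursts_by_unit)
  metrics <- if (length(units))
    unit_metrics_table(units, rec$duration, bursts_by_unit, nbs,
                       config$isi_bins_per_decade, config$isi_range)
  else NULL
  correlation <- NULL
  active <- Filter(function(u)
    is_active(u, rec$duration, config$active_rate_min) && u$n_spikes >= 2,
    units)
  if (length(active) >= 2) {
    vecs <- lapply(active, rate_vector, duration = rec$duration,
                   sample_rate = config$rate_vector_hz)
    el_of <- vapply(active, `[[`, character(1), "electrode_id")
    if (length(unique(el_of)) >= 2)
      correlation <- pairwise_correlation(vecs, el_of)
  }
  smry <- list(
    n_units = length(units),
    n_active_units = sum(vapply(units, is_active, logical(1),
                                duration = rec$duration,
                                rate_min = config$active_rate_min)),
    mfr = mean_firing_rate(units, rec$duration, config$active_rate_min),
    mean_burstiness = if (!is.null(metrics)) mean(metrics$burstiness, na.rm = TRUE) else NA_real_,
    mean_network_burstiness = if (!is.null(metrics)) mean(metrics$network_burstiness, na.rm = TRUE) else NA_real_,
    mean_entropy = if (!is.null(metrics)) mean(metrics$entropy, na.rm = TRUE) else NA_real_,
    nb_count_per_10min = nb_summary(nbs, rec$duration)$count_per_10min,
    nb_mean_duration = nb_summary(nbs, rec$duration)$mean_duration_s,
    mean_correlation = if (!is.null(correlation)) correlation$mean_correlation else NA_real_)
  structure(list(units = units, sortings = sortings,
                 bursts_by_unit = bursts_by_unit, thresholds = thresholds,
                 network_bursts = nbs, nb_threshold = thr,
                 metrics = metrics, correlation = correlation,
                 summary = smry, config = config, metadata = rec$metadata,
                 duration = rec$duration),
            class = "mea_analysis")
}

#' @export
print.mea_analysis <- function(x, ...) {
  s <- x$summary
  cat("<mea_analysis>\n")
  cat(sprintf("  units: %d (%d active)   MFR: %s sp/s\n", s$n_units,
              s$n_active_units,
              if (is.na(s$mfr)) "NA" else sprintf("%.3g", s$mfr)))
  cat(sprintf("  burstiness: %.3g   network burstiness: %.3g   entropy: %.3g nats\n",
              s$mean_burstiness, s$mean_network_burstiness, s$mean_entropy))
  cat(sprintf("  network bursts: %g per 10 min, mean duration %s s\n",
              s$nb_count_per_10min,
              if (is.na(s$nb_mean_duration)) "NA"
              else sprintf("%.3g", s$nb_mean_duration)))
  if (!is.na(s$mean_correlation))
    cat(sprintf("  mean pairwise correlation: %.3g\n", s$mean_correlation))
  invisible(x)
}

#' @export
summary.mea_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics)) {
    cat("\nPer-unit metrics:\n")
    print(object$metrics, row.names = FALSE)
  }
  invisible(object$summary)
}

#' Raster plot of an analysis
#'
#' Spike raster per unit with in-burst spikes highlighted and network-burst
#' epochs shaded.
#'
#' @param x an `mea_analysis`.
#' @param xlim time window (s); default whole recording.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mea_analysis <- function(x, xlim = c(0, x$duration), ...) {
  units <- x$units
  if (!length(units)) {
    graphics::plot.new(); graphics::title("no units"); return(invisible(x))
  }
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, length(units) + 0.5),
                 xlab = "time (s)", ylab = "unit", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(units), labels = names(units), las = 2,
                 cex.axis = 0.6)
  nbs <- x$network_bursts
  if (nrow(nbs))
    graphics::rect(nbs$start, 0.5, nbs$end, length(units) + 0.5,
                   col = grDevices::adjustcolor("green", 0.2), border = NA)
  for (i in seq_along(units)) {
    st <- units[[i]]$spike_times
    b <- x$bursts_by_unit[[names(units)[i]]]
    inb <- rep(FALSE, length(st))
    if (!is.null(b) && nrow(b))
      for (j in seq_len(nrow(b)))
        inb[st >= b$start[j] & st <= b$end[j]] <- TRUE
    graphics::points(st[!inb], rep(i, sum(!inb)), pch = ".", col = "black")
    graphics::points(st[inb], rep(i, sum(inb)), pch = ".", col = "red")
  }
  invisible(x)
}

#' Run the full pipeline over recordings and images
#'
#' Reads each recording (HDF5 container), analyzes it with
#' [analyze_recording()], quantifies the matching image when one is given,
#' and writes tidy CSV/JSON reports to `out_dir`: per-unit metrics, bursts,
#' network bursts, pair correlations, per-image cluster quantification, and
#' a run manifest (config, seed, versions). Failures are isolated per
#' recording and reported in the manifest.
#'
#' @param recording_paths character vector of HDF5 recording paths.
#' @param image_paths optional named character vector of image paths (PNG),
#'   names matching the recordings' `mea_id`.
#' @param config an [run_config()].
#' @param out_dir output directory (created if needed).
#' @param scale_um_per_px pixel scale for the images.
#' @return Invisibly, a list of `mea_analysis` objects (and image results),
#'   one per input.
#' @export
run_pipeline <- function(recording_paths, image_paths = NULL,
                         config = run_config(), out_dir,
                         scale_um_per_px = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  failures <- character(0)
  all_metrics <- list()
  for (p in recording_paths) {
    res <- tryCatch({
      rec <- read_recording(p)
      an <- analyze_recording(rec, config)
      id <- rec$metadata$mea_id
      tag <- function(df) {
        df$mea_id <- id; df$div <- rec$metadata$div
        df$condition <- rec$metadata$cell_density_condition
        df
      }
      if (!is.null(an$metrics))
        all_metrics[[id]] <- tag(an$metrics)
      export_bursts(an$bursts_by_unit,
                    file.path(out_dir, paste0(id, "_bursts.csv")))
      export_network_bursts(an$network_bursts,
                            file.path(out_dir, paste0(id, "_network_bursts.csv")))
      if (!is.null(image_paths) && id %in% names(image_paths)) {
        img <- read_rgb_image(image_paths[[id]])
        iq <- quantify_image(img, rec$layout, scale_um_per_px,
                             k = config$image_k,
                             sigma_low = config$image_sigma_low,
                             sigma_high = config$image_sigma_high,
                             invert = config$hue_invert)
        jsonlite::write_json(
          list(mea_id = id, cluster_ratio = iq$cluster_ratio,
               clusterness = as.list(iq$clusterness)),
          file.path(out_dir, paste0(id, "_image.json")),
          auto_unbox = TRUE, digits = NA)
        an$image <- iq
      }
      an
    }, error = function(e) {
      failures <<- c(failures, paste0(p, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (length(all_metrics))
    utils::write.csv(do.call(rbind, all_metrics),
                     file.path(out_dir, "unit_metrics.csv"), row.names = FALSE)
  manifest <- list(
    n_recordings = length(recording_paths),
    n_analyzed = length(results),
    failures = failures,
    seed = config$seed,
    config = unclass(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("spheromea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(failures))
    warning(length(failures), " recording(s) failed; see manifest.json")
  invisible(results)
}
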