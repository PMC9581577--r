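#' Biphasic extracellular spike template
#'
#' Difference-of-Gaussians biphasic waveform spanning 1.5 ms, normalized so
#' the dominant phase has unit absolute amplitude and carries the requested
#' polarity. Typical extracellular action potentials have a dominant
#' negative phase; `polarity = +1` flips the template, giving a second unit
#' on the same electrode a well-separated PCA footprint.
#'
#' @param sample_rate sampling rate (Hz).
#' @param polarity -1 (negative-dominant, default) or +1.
#' @param width_s template span (s).
#' @return Numeric template vector.
#' @export
spike_template <- function(sample_rate, polarity = -1, width_s = 1.5e-3) {
  n <- round(width_s * sample_rate)
  t <- seq(0, width_s, length.out = n)
  c1 <- width_s * 0.35; c2 <- width_s * 0.6
  s1 <- width_s * 0.08; s2 <- width_s * 0.16
  w <- exp(-(t - c1)^2 / (2 * s1^2)) - 0.55 * exp(-(t - c2)^2 / (2 * s2^2))
  sign(polarity) * w / max(abs(w))
}

#' Recording scenario: the ground-truthed plan for a synthetic recording
#'
#' Describes every simulated unit (electrode, baseline rate, burst epochs,
#' in-burst rate, template polarity and amplitude) plus a network-burst
#' schedule shared by participating units, the background-noise SD and the
#' recording geometry. Defaults reflect the recorded conditions the package
#' targets: 10 min at 32 kHz on the standard 59-electrode layout, with
#' units whose firing alternates between sparse tonic spiking and
#' high-frequency bursts that coincide across electrodes during scheduled
#' network-burst epochs.
#'
#' @param units list; each element a list with fields `electrode_id`,
#'   `baseline_rate` (Hz), `in_burst_rate` (Hz), `burst_epochs` (2-column
#'   matrix / data frame of start, end in s; may be `NULL`),
#'   `participates_nb` (logical: use the NB schedule as burst epochs),
#'   `polarity` (+1/-1), `amplitude` (uV; default `10 * noise_sd`).
#' @param nb_epochs 2-column matrix / data frame of scheduled network-burst
#'   epochs (s).
#' @param noise_sd Gaussian background-noise SD (uV).
#' @param duration recording duration (s).
#' @param sample_rate sampling rate (Hz).
#' @param refractory absolute refractory period (s).
#' @param amplitude_jitter relative SD of per-spike amplitude jitter.
#' @param layout an [mea_layout()].
#' @param metadata a [culture_metadata()].
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return Object of class `recording_scenario`.
#' @export
recording_scenario <- function(units, nb_epochs = NULL, noise_sd = 3,
                               duration = 600, sample_rate = 32000,
                               refractory = 2e-3, amplitude_jitter = 0.1,
                               layout = mea_layout(),
                               metadata = culture_metadata(), seed = 1) {
  stopifnot(is.list(units), length(units) >= 1)
  if (!is.null(nb_epochs)) {
    nb_epochs <- as.matrix(nb_epochs)
    stopifnot(ncol(nb_epochs) == 2)
    if (any(nb_epochs < 0 | nb_epochs > duration))
      stop("NB epochs must lie within [0, duration]")
  }
  units <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    u$unit_label <- i
    if (is.null(u$baseline_rate)) u$baseline_rate <- 1
    if (is.null(u$in_burst_rate)) u$in_burst_rate <- 100
    if (is.null(u$participates_nb)) u$participates_nb <- FALSE
    if (is.null(u$polarity)) u$polarity <- -1
    if (is.null(u$amplitude)) u$amplitude <- 10 * noise_sd
    if (u$participates_nb) u$burst_epochs <- nb_epochs
    if (!is.null(u$burst_epochs)) {
      u$burst_epochs <- as.matrix(u$burst_epochs)
      if (any(u$burst_epochs < 0 | u$burst_epochs > duration))
        stop("burst epochs must lie within [0, duration]")
    }
    if (u$baseline_rate < 0 || u$in_burst_rate < 0)
      stop("rates must be >= 0")
    u
  })
  structure(list(units = units, nb_epochs = nb_epochs, noise_sd = noise_sd,
                 duration = duration, sample_rate = sample_rate,
                 refractory = refractory, amplitude_jitter = amplitude_jitter,
                 layout = layout, metadata = metadata, seed = seed),
            class = "recording_scenario")
}

# piecewise-constant-rate Poisson spike train with absolute refractory
.draw_spikes <- function(baseline, in_rate, epochs, duration, refractory) {
  if (is.null(epochs)) epochs <- matrix(numeric(0), 0, 2)
  bounds <- sort(unique(c(0, duration, epochs[, 1], epochs[, 2])))
  spikes <- numeric(0)
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    mid <- (a + b) / 2
    inb <- nrow(epochs) && any(epochs[, 1] <= mid & mid < epochs[, 2])
    rate <- if (inb) in_rate else baseline
    if (rate <= 0) next
    k <- stats::rpois(1, rate * (b - a))
    if (k > 0) spikes <- c(spikes, stats::runif(k, a, b))
  }
  spikes <- sort(spikes)
  if (length(spikes) > 1) {
    keep <- c(TRUE, diff(spikes) >= refractory)
    # iterate: dropping a spike can bring the next one inside the window
    while (!all(keep)) {
      spikes <- spikes[keep]
      if (length(spikes) < 2) break
      keep <- c(TRUE, diff(spikes) >= refractory)
    }
  }
  spikes
}

#' Generate a synthetic recording with ground truth
#'
#' Draws each unit's spikes as an inhomogeneous Poisson process with
#' piecewise-constant rate (baseline outside its burst epochs, the in-burst
#' rate inside) and an absolute refractory period, then renders each spike's
#' template (with per-spike amplitude jitter) onto Gaussian background
#' noise on its electrode. Returns both the recording and the ground truth
#' needed to score every pipeline stage.
#'
#' @param scn a [recording_scenario()].
#' @return List with `recording` (a [raw_recording()] holding only the
#'   planned electrodes) and `truth`: per-unit spike times, per-unit burst
#'   epochs, realized in-burst spike fractions, the NB schedule, and
#'   `electrode_of` (unit label -> electrode).
#' @export
generate_recording <- function(scn) {
  stopifnot(inherits(scn, "recording_scenario"))
  tmpl_len <- round(1.5e-3 * scn$sample_rate)
  if (tmpl_len / scn$sample_rate > scn$refractory + 1e-3)
    stop("template longer than the refractory window plus margin")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(scn$seed)
  n <- round(scn$duration * scn$sample_rate)
  electrodes <- unique(vapply(scn$units, `[[`, character(1), "electrode_id"))
  traces <- stats::setNames(vector("list", length(electrodes)), electrodes)
  for (el in electrodes)
    traces[[el]] <- stats::rnorm(n, 0, scn$noise_sd)
  spike_times <- list()
  in_burst_fraction <- numeric(length(scn$units))
  for (i in seq_along(scn$units)) {
    u <- scn$units[[i]]
    st <- .draw_spikes(u$baseline_rate, u$in_burst_rate, u$burst_epochs,
                       scn$duration, scn$refractory)
    # keep spikes whose full template fits in the trace
    st <- st[round(st * scn$sample_rate) + tmpl_len <= n & st >= 0]
    spike_times[[i]] <- st
    ep <- u$burst_epochs
    in_burst_fraction[i] <- if (is.null(ep) || !nrow(ep) || !length(st)) 0
      else mean(vapply(st, function(t)
        any(ep[, 1] <= t & t <= ep[, 2]), logical(1)))
    tmpl <- spike_template(scn$sample_rate, u$polarity)
    amp <- u$amplitude *
      pmax(0.5, 1 + stats::rnorm(length(st), 0, scn$amplitude_jitter))
    idx0 <- round(st * scn$sample_rate)           # 0-based sample of spike onset
    for (j in seq_along(st)) {
      sel <- (idx0[j] + 1):(idx0[j] + tmpl_len)
      traces[[u$electrode_id]][sel] <- traces[[u$electrode_id]][sel] +
        amp[j] * tmpl
    }
  }
  rec <- raw_recording(traces, sample_rate = scn$sample_rate,
                       duration = scn$duration, layout = scn$layout,
                       metadata = scn$metadata)
  names(spike_times) <- paste0("unit", seq_along(scn$units))
  list(recording = rec,
       truth = list(
         spike_times = spike_times,
         burst_epochs = lapply(scn$units, `[[`, "burst_epochs"),
         in_burst_fraction = in_burst_fraction,
         nb_epochs = scn$nb_epochs,
         electrode_of = stats::setNames(
           vapply(scn$units, `[[`, character(1), "electrode_id"),
           names(spike_times))))
}

#' Image scenario: the plan for a synthetic phase-contrast montage
#'
#' Describes a stitched phase-contrast image of the electrode area: canvas
#' size and pixel scale, the electrode grid (drawn as black disks), a set
#' of cell clusters (red-shifted soft-edged disks), optional strands
#' connecting cluster centres, and per-channel background texture.
#'
#' @param clusters data frame with columns `x`, `y` (um), `radius` (um),
#'   `contrast` (red-shift amplitude in \[0, 1\] channel units).
#' @param layout an [mea_layout()].
#' @param scale_um_per_px pixel scale (um/px).
#' @param margin_um margin around the electrode grid (um).
#' @param background base grayscale level of the substrate.
#' @param texture_sd per-channel Gaussian texture SD.
#' @param strands logical: draw faint strands between cluster centres.
#' @param seed RNG seed.
#' @return Object of class `image_scenario`.
#' @export
image_scenario <- function(clusters = NULL, layout = mea_layout(),
                           scale_um_per_px = 4, margin_um = 200,
                           background = 0.72, texture_sd = 0.015,
                           strands = TRUE, seed = 1) {
  if (is.null(clusters))
    clusters <- data.frame(x = numeric(0), y = numeric(0),
                           radius = numeric(0), contrast = numeric(0))
  stopifnot(all(c("x", "y", "radius", "contrast") %in% names(clusters)))
  if (nrow(clusters) && any(clusters$contrast <= 0))
    stop("cluster contrast must be > 0")
  w_um <- diff(range(layout$x)) + 2 * margin_um
  h_um <- diff(range(layout$y)) + 2 * margin_um
  origin_um <- c(min(layout$x) - margin_um, min(layout$y) - margin_um)
  if (nrow(clusters)) {
    if (any(clusters$x - clusters$radius < origin_um[1] |
            clusters$x + clusters$radius > origin_um[1] + w_um |
            clusters$y - clusters$radius < origin_um[2] |
            clusters$y + clusters$radius > origin_um[2] + h_um))
      stop("clusters must lie within the canvas")
  }
  structure(list(clusters = clusters, layout = layout,
                 scale_um_per_px = scale_um_per_px,
                 width_px = round(w_um / scale_um_per_px),
                 height_px = round(h_um / scale_um_per_px),
                 origin_um = origin_um, background = background,
                 texture_sd = texture_sd, strands = strands, seed = seed),
            class = "image_scenario")
}

#' Generate a synthetic phase-contrast image with ground truth
#'
#' Renders the scenario: pale textured background, red-shifted cluster
#' disks with soft (Gaussian-tapered) edges, faint strand lines between
#' cluster centres, and black electrode disks at the layout positions.
#' The red shift raises the red channel and lowers the blue channel by the
#' cluster contrast, emulating the brownish tint of dense cell aggregates.
#'
#' @param scn an [image_scenario()].
#' @return List with `image` (H x W x 3 array in \[0, 1\]), `true_mask`
#'   (logical matrix: pixels inside a designed cluster), `origin_um`,
#'   `scale_um_per_px`.
#' @export
generate_image <- function(scn) {
  stopifnot(inherits(scn, "image_scenario"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(scn$seed)
  H <- scn$height_px; W <- scn$width_px; sc <- scn$scale_um_per_px
  px_x <- scn$origin_um[1] + (seq_len(W) - 1) * sc   # columns
  px_y <- scn$origin_um[2] + (seq_len(H) - 1) * sc   # rows
  shift_field <- matrix(0, H, W)
  true_mask <- matrix(FALSE, H, W)
  edge_um <- 8     # soft-edge width
  for (i in seq_len(nrow(scn$clusters))) {
    cl <- scn$clusters[i, ]
    d <- sqrt(outer((px_y - cl$y)^2, (px_x - cl$x)^2, "+"))
    soft <- 1 / (1 + exp((d - cl$radius) / (edge_um / 4)))
    shift_field <- shift_field + cl$contrast * soft
    true_mask <- true_mask | d <= cl$radius
  }
  if (scn$strands && nrow(scn$clusters) >= 2) {
    cs <- scn$clusters
    for (i in seq_len(nrow(cs) - 1)) {
      a <- c(cs$x[i], cs$y[i]); b <- c(cs$x[i + 1], cs$y[i + 1])
      ts <- seq(0, 1, length.out = 200)
      for (tt in ts) {
        p <- a + tt * (b - a)
        d <- sqrt(outer((px_y - p[2])^2, (px_x - p[1])^2, "+"))
        shift_field <- shift_field + 0.02 * cs$contrast[i] * (d < 6)
      }
    }
  }
  base <- scn$background
  img <- array(0, c(H, W, 3))
  img[, , 1] <- base + shift_field +
    matrix(stats::rnorm(H * W, 0, scn$texture_sd), H, W)
  img[, , 2] <- base + 0.3 * shift_field +
    matrix(stats::rnorm(H * W, 0, scn$texture_sd), H, W)
  img[, , 3] <- base - shift_field +
    matrix(stats::rnorm(H * W, 0, scn$texture_sd), H, W)
  # electrode disks: black (grayscale 0)
  lay <- scn$layout
  rad <- attr(lay, "radius")
  for (i in seq_len(nrow(lay))) {
    d <- sqrt(outer((px_y - lay$y[i])^2, (px_x - lay$x[i])^2, "+"))
    el <- d <= rad
    for (ch in 1:3) {
      m <- img[, , ch]; m[el] <- 0; img[, , ch] <- m
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, true_mask = true_mask,
       origin_um = scn$origin_um, scale_um_per_px = sc)
}
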