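# Shared scenario builders for end-to-end tests. The standard synchronous
# scenario: units with sparse tonic baseline firing plus high-rate bursts
# during a shared network-burst schedule — two of them on one electrode with
# opposite template polarity so sorting and the same-electrode exclusion are
# exercised.

sync_scenario <- function(duration = 60, n_epochs = 6, seed = 3,
                          baseline = 2, in_rate = 150) {
  gap <- duration / n_epochs
  starts <- gap * (seq_len(n_epochs) - 1) + gap / 2
  nb <- cbind(starts, starts + 0.5)
  units <- list(
    list(electrode_id = "22", baseline_rate = baseline, in_burst_rate = in_rate,
         participates_nb = TRUE),
    list(electrode_id = "33", baseline_rate = baseline, in_burst_rate = in_rate,
         participates_nb = TRUE),
    list(electrode_id = "44", baseline_rate = baseline, in_burst_rate = in_rate,
         participates_nb = TRUE),
    list(electrode_id = "55", baseline_rate = baseline, in_burst_rate = in_rate,
         participates_nb = TRUE),
    list(electrode_id = "55", baseline_rate = baseline * 0.75,
         in_burst_rate = in_rate, participates_nb = TRUE, polarity = +1))
  recording_scenario(units, nb_epochs = nb, duration = duration, seed = seed)
}

# a small image scenario: clusters centred on chosen electrodes
cluster_image_scenario <- function(on_electrodes = c("33", "66"),
                                   radius = 80, contrast = 0.18, seed = 11,
                                   layout = mea_layout(), ...) {
  idx <- match(on_electrodes, layout$electrode_id)
  clusters <- data.frame(x = layout$x[idx], y = layout$y[idx],
                         radius = radius, contrast = contrast)
  image_scenario(clusters, layout = layout, seed = seed, ...)
}
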