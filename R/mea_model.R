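#' Electrode layout of a microelectrode array
#'
#' Describes the geometry of a planar MEA: electrode identifiers, positions in
#' micrometres, electrode radius and inter-electrode pitch. The default layout
#' is the standard 60-channel grid: an 8 x 8 array minus the four corners,
#' with one internal reference electrode, leaving 59 recording electrodes with
#' 30 um radius and 200 um pitch.
#'
#' @param electrode_id character vector of unique electrode identifiers.
#' @param x,y numeric electrode centre positions (um).
#' @param radius electrode radius (um), > 0.
#' @param pitch centre-to-centre electrode spacing (um), > 0.
#' @param reference_id optional id of the reference electrode (excluded from
#'   the recording electrodes).
#' @return An object of class `mea_layout`: a data frame with columns
#'   `electrode_id`, `x`, `y` (recording electrodes only) and attributes
#'   `radius`, `pitch`, `reference_id`.
#' @examples
#' lay <- mea_layout()
#' nrow(lay)  # 59 recording electrodes
#' @export
mea_layout <- function(electrode_id = NULL, x = NULL, y = NULL,
                       radius = 30, pitch = 200, reference_id = NULL) {
  if (is.null(electrode_id)) {
    # 8x8 grid minus corners; MCS-style column-row ids, "15" is the reference
    grid <- expand.grid(col = 1:8, row = 1:8)
    grid <- grid[!(grid$col %in% c(1, 8) & grid$row %in% c(1, 8)), ]
    electrode_id <- sprintf("%d%d", grid$col, grid$row)
    x <- (grid$col - 1) * pitch
    y <- (grid$row - 1) * pitch
    if (is.null(reference_id)) reference_id <- "15"
  }
  electrode_id <- as.character(electrode_id)
  stopifnot(length(x) == length(electrode_id), length(y) == length(electrode_id))
  if (anyDuplicated(electrode_id))
    stop("electrode ids must be unique")
  if (anyDuplicated(cbind(x, y)))
    stop("electrode positions must be pairwise distinct")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(pitch) || pitch <= 0) stop("pitch must be > 0")
  df <- data.frame(electrode_id = electrode_id, x = as.numeric(x),
                   y = as.numeric(y), stringsAsFactors = FALSE)
  if (!is.null(reference_id)) {
    if (!reference_id %in% df$electrode_id)
      stop("reference_id not among electrode ids")
    df <- df[df$electrode_id != reference_id, ]
    rownames(df) <- NULL
  }
  structure(df, radius = radius, pitch = pitch,
            reference_id = reference_id, class = c("mea_layout", "data.frame"))
}

#' Culture metadata for one MEA
#'
#' Seeding and history metadata for a culture: days in vitro, the density
#' condition, astrocyte fraction, whether the MEA was fresh or previously
#' used, and the seeded live-cell counts over the seeded area.
#'
#' @param div days in vitro (integer >= 0), counted from seeding.
#' @param cell_density_condition `"high"` or `"low"`.
#' @param astrocyte_ratio astrocyte fraction of seeded cells, in \[0, 1\].
#' @param mea_history `"new"` or `"used"`.
#' @param n_neurons_seeded,n_astrocytes_seeded live-cell counts (>= 0).
#' @param seeded_area area covered by the seeded droplet (mm^2), > 0.
#' @param mea_id optional MEA identifier used to match recordings to images.
#' @return An object of class `culture_metadata` (a named list).
#' @export
culture_metadata <- function(div = 0L,
                             cell_density_condition = c("high", "low"),
                             astrocyte_ratio = 0.5,
                             mea_history = c("new", "used"),
                             n_neurons_seeded = 75000,
                             n_astrocytes_seeded = 75000,
                             seeded_area = 25.5,
                             mea_id = "MEA1") {
  cell_density_condition <- match.arg(cell_density_condition)
  mea_history <- match.arg(mea_history)
  div <- as.integer(div)
  if (is.na(div) || div < 0) stop("div must be a non-negative integer")
  if (astrocyte_ratio < 0 || astrocyte_ratio > 1)
    stop("astrocyte_ratio must lie in [0, 1]")
  if (seeded_area <= 0) stop("seeded_area must be > 0")
  if (n_neurons_seeded < 0 || n_astrocytes_seeded < 0)
    stop("cell counts must be >= 0")
  structure(list(div = div,
                 cell_density_condition = cell_density_condition,
                 astrocyte_ratio = astrocyte_ratio,
                 mea_history = mea_history,
                 n_neurons_seeded = n_neurons_seeded,
                 n_astrocytes_seeded = n_astrocytes_seeded,
                 seeded_area = seeded_area,
                 mea_id = mea_id),
            class = "culture_metadata")
}

#' Seeding density of a culture
#'
#' Total live cells (neurons + astrocytes) per square millimetre of seeded
#' area, rounded to the nearest integer for reporting. With the standard
#' droplet area of 25.5 mm^2, 75,000 + 75,000 cells give 5882 cells/mm^2 and
#' 37,500 + 37,500 give 2941 cells/mm^2.
#'
#' @param meta a [culture_metadata()] object.
#' @return Integer cells per mm^2.
#' @export
seeding_density <- function(meta) {
  stopifnot(inherits(meta, "culture_metadata"))
  if (meta$seeded_area <= 0) stop("seeded_area must be > 0")
  round((meta$n_neurons_seeded + meta$n_astrocytes_seeded) / meta$seeded_area)
}

#' Raw multichannel recording
#'
#' Container for a multichannel extracellular voltage recording: one trace per
#' electrode (uV), a common sample rate, the electrode layout and culture
#' metadata. Time is seconds from recording start throughout the package.
#'
#' @param traces named list of numeric vectors (uV), names are electrode ids.
#' @param sample_rate sampling frequency (Hz).
#' @param duration recording length (s); every trace must have
#'   `round(duration * sample_rate)` samples.
#' @param layout an [mea_layout()].
#' @param metadata a [culture_metadata()].
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(traces, sample_rate = 32000, duration = 600,
                          layout = mea_layout(), metadata = culture_metadata()) {
  stopifnot(is.list(traces), inherits(layout, "mea_layout"),
            inherits(metadata, "culture_metadata"))
  if (is.null(names(traces)) || any(names(traces) == ""))
    stop("traces must be a named list (electrode ids)")
  n_expected <- round(duration * sample_rate)
  if (n_expected <= 0) stop("recording must contain at least one sample")
  lens <- vapply(traces, length, integer(1))
  if (any(lens != n_expected))
    stop(sprintf("every trace must have %d samples (duration x sample_rate)",
                 n_expected))
  missing <- setdiff(names(traces), layout$electrode_id)
  if (length(missing))
    stop("trace electrode ids absent from layout: ",
         paste(missing, collapse = ", "))
  structure(list(traces = traces, sample_rate = sample_rate,
                 duration = duration, layout = layout, metadata = metadata),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d electrodes, %.4g s at %g Hz (%s density, DIV %d)\n",
              length(x$traces), x$duration, x$sample_rate,
              x$metadata$cell_density_condition, x$metadata$div))
  invisible(x)
}

#' A sorted unit (putative single neuron)
#'
#' @param unit_id unit identifier.
#' @param electrode_id electrode of origin.
#' @param spike_times strictly increasing spike times (s).
#' @param mean_waveform mean spike waveform (uV), may be `NULL`.
#' @return An object of class `mea_unit` with `n_spikes` field.
#' @export
mea_unit <- function(unit_id, electrode_id, spike_times, mean_waveform = NULL) {
  spike_times <- as.numeric(spike_times)
  if (length(spike_times) && any(diff(spike_times) <= 0))
    stop("spike_times must be strictly increasing")
  if (length(spike_times) && any(spike_times < 0))
    stop("spike_times must be >= 0")
  structure(list(unit_id = as.character(unit_id),
                 electrode_id = as.character(electrode_id),
                 spike_times = spike_times,
                 mean_waveform = mean_waveform,
                 n_spikes = length(spike_times)),
            class = "mea_unit")
}

#' @export
print.mea_unit <- function(x, ...) {
  cat(sprintf("<mea_unit> %s on electrode %s: %d spikes\n",
              x$unit_id, x$electrode_id, x$n_spikes))
  invisible(x)
}

# serialize layout + metadata to a JSON-compatible list
.meta_to_list <- function(layout, metadata) {
  list(layout = list(electrode_id = layout$electrode_id,
                     x = layout$x, y = layout$y,
                     radius = attr(layout, "radius"),
                     pitch = attr(layout, "pitch"),
                     reference_id = attr(layout, "reference_id")),
       metadata = unclass(metadata))
}

.meta_from_list <- function(ml) {
  lay <- ml$layout
  # the serialized table holds recording electrodes only (reference already
  # stripped), so rebuild without re-stripping and restore the attribute
  layout <- mea_layout(as.character(lay$electrode_id),
                       as.numeric(lay$x), as.numeric(lay$y),
                       radius = lay$radius, pitch = lay$pitch,
                       reference_id = NULL)
  if (!is.null(lay$reference_id) && length(lay$reference_id))
    attr(layout, "reference_id") <- as.character(lay$reference_id)
  md <- ml$metadata
  list(layout = layout,
       metadata = culture_metadata(div = md$div,
                                   cell_density_condition = md$cell_density_condition,
                                   astrocyte_ratio = md$astrocyte_ratio,
                                   mea_history = md$mea_history,
                                   n_neurons_seeded = md$n_neurons_seeded,
                                   n_astrocytes_seeded = md$n_astrocytes_seeded,
                                   seeded_area = md$seeded_area,
                                   mea_id = md$mea_id))
}

#' Write a recording to an HDF5 container
#'
#' Stores one analog-stream group with one dataset per channel (uV, doubles),
#' each carrying `sample_rate` and `conversion` attributes, plus a JSON
#' document holding the electrode layout and culture metadata. The file is
#' read back by [read_recording()].
#'
#' @param rec a [raw_recording()].
#' @param path output file path (.h5).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "analog")
  for (id in names(rec$traces)) {
    ds <- paste0("analog/", id)
    rhdf5::h5write(as.numeric(rec$traces[[id]]), path, ds)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, ds)
    rhdf5::h5writeAttribute(rec$sample_rate, did, "sample_rate")
    rhdf5::h5writeAttribute(1.0, did, "conversion_uV")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  meta_json <- jsonlite::toJSON(.meta_to_list(rec$layout, rec$metadata),
                                auto_unbox = TRUE, digits = NA)
  rhdf5::h5write(as.character(meta_json), path, "meta_json")
  rhdf5::h5write(rec$duration, path, "duration_s")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a recording from an HDF5 container
#'
#' Counterpart of [write_recording()]. Rejects files without an analog stream
#' and files whose channels disagree on sample rate. If the file carries no
#' embedded layout/metadata JSON, a sidecar file `<path>.json` is consulted;
#' absent both, the default layout and metadata are used.
#'
#' @param path file path.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)
  if (!"analog" %in% contents$name[contents$otype == "H5I_GROUP"])
    stop("not a recording container: missing group 'analog'")
  ch <- contents$name[contents$group == "/analog"]
  if (!length(ch)) stop("group 'analog' contains no channels")
  traces <- list()
  rates <- numeric(length(ch))
  for (i in seq_along(ch)) {
    ds <- paste0("analog/", ch[i])
    at <- rhdf5::h5readAttributes(path, ds)
    conv <- if (!is.null(at$conversion_uV)) as.numeric(at$conversion_uV) else 1
    rates[i] <- as.numeric(at$sample_rate)
    traces[[ch[i]]] <- as.vector(rhdf5::h5read(path, ds)) * conv
  }
  if (length(unique(rates)) != 1L)
    stop("sample-rate mismatch across channels: ",
         paste(unique(rates), collapse = ", "))
  duration <- as.numeric(rhdf5::h5read(path, "duration_s"))
  names_all <- contents$name
  if ("meta_json" %in% names_all) {
    ml <- jsonlite::fromJSON(as.character(rhdf5::h5read(path, "meta_json")),
                             simplifyVector = TRUE)
  } else if (file.exists(paste0(path, ".json"))) {
    ml <- jsonlite::fromJSON(paste0(path, ".json"), simplifyVector = TRUE)
  } else {
    ml <- NULL
  }
  rhdf5::h5closeAll()
  if (is.null(ml)) {
    layout <- mea_layout(); metadata <- culture_metadata()
  } else {
    lm <- .meta_from_list(ml)
    layout <- lm$layout; metadata <- lm$metadata
  }
  raw_recording(traces, sample_rate = rates[1], duration = duration,
                layout = layout, metadata = metadata)
}

#' Export unit spike times to CSV
#'
#' One row per spike, columns `unit_id`, `electrode_id`, `spike_time_s`.
#'
#' @param units list of [mea_unit()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_spike_times <- function(units, path) {
  rows <- lapply(units, function(u)
    if (u$n_spikes) data.frame(unit_id = u$unit_id,
                               electrode_id = u$electrode_id,
                               spike_time_s = u$spike_times) else NULL)
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(unit_id = character(), electrode_id = character(),
                     spike_time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
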