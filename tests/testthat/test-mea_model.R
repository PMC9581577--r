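test_that("default layout is the 59-electrode grid with valid geometry", {
  lay <- mea_layout()
  expect_equal(nrow(lay), 59)
  expect_false(anyDuplicated(lay$electrode_id) > 0)
  expect_false(anyDuplicated(cbind(lay$x, lay$y)) > 0)
  expect_equal(attr(lay, "radius"), 30)
  expect_equal(attr(lay, "pitch"), 200)
  expect_error(mea_layout(c("a", "a"), c(0, 1), c(0, 0)), "unique")
  expect_error(mea_layout(c("a", "b"), c(0, 0), c(0, 0)), "distinct")
  expect_error(mea_layout(radius = 0), "radius")
})

test_that("seeding density reproduces the per-condition values and scales linearly", {
  high <- culture_metadata(n_neurons_seeded = 75000, n_astrocytes_seeded = 75000,
                           seeded_area = 25.5)
  low <- culture_metadata(cell_density_condition = "low",
                          n_neurons_seeded = 37500, n_astrocytes_seeded = 37500,
                          seeded_area = 25.5)
  expect_equal(seeding_density(high), 5882)
  expect_equal(seeding_density(low), 2941)
  expect_equal(seeding_density(culture_metadata(n_neurons_seeded = 0,
                                                n_astrocytes_seeded = 0)), 0)
  # linear in counts, inverse-linear in area
  double_cells <- culture_metadata(n_neurons_seeded = 150000,
                                   n_astrocytes_seeded = 150000,
                                   seeded_area = 25.5)
  half_area <- culture_metadata(seeded_area = 25.5 / 2)
  expect_equal(seeding_density(double_cells), round(2 * 150000 / 25.5))
  expect_equal(seeding_density(half_area), round(150000 / 12.75))
})

test_that("raw_recording enforces trace lengths and layout membership", {
  n <- 32000
  tr <- list("22" = numeric(n), "33" = numeric(n))
  rec <- raw_recording(tr, sample_rate = 32000, duration = 1)
  expect_equal(length(rec$traces[["22"]]), 32000)
  expect_error(raw_recording(list("22" = numeric(10)), 32000, 1), "samples")
  expect_error(raw_recording(stats::setNames(list(numeric(n)), "zz"), 32000, 1),
               "absent from layout")
  expect_error(raw_recording(list("22" = numeric(0)), 32000, 0), "sample")
})

test_that("recordings round-trip through the HDF5 container", {
  set.seed(1)
  n <- 3200
  tr <- list("22" = rnorm(n), "87" = rnorm(n))
  meta <- culture_metadata(div = 25, cell_density_condition = "low",
                           astrocyte_ratio = 0.15, mea_history = "used",
                           mea_id = "M7")
  rec <- raw_recording(tr, sample_rate = 32000, duration = 0.1,
                       metadata = meta)
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$traces, rec$traces)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$duration, rec$duration)
  expect_equal(back$layout$electrode_id, rec$layout$electrode_id)
  expect_equal(back$metadata$div, 25)
  expect_equal(back$metadata$mea_id, "M7")
  expect_equal(back$metadata$astrocyte_ratio, 0.15)
})

test_that("a full-array recording writes one channel per electrode", {
  lay <- mea_layout()
  n <- 320          # 0.01 s at 32 kHz keeps the file small
  tr <- stats::setNames(lapply(lay$electrode_id, function(i) numeric(n)),
                        lay$electrode_id)
  rec <- raw_recording(tr, 32000, 0.01)
  path <- withr::local_tempfile(fileext = ".h5")
  write_recording(rec, path)
  ls <- rhdf5::h5ls(path)
  expect_equal(sum(ls$group == "/analog"), 59)
})

test_that("malformed containers are rejected with a named cause", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5write(1:10, path, "unrelated")
  rhdf5::h5closeAll()
  expect_error(read_recording(path), "analog")

  # channels disagreeing on sample rate
  path2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path2)
  rhdf5::h5createGroup(path2, "analog")
  for (spec in list(c("a", 32000), c("b", 25000))) {
    ds <- paste0("analog/", spec[1])
    rhdf5::h5write(rnorm(100), path2, ds)
    fid <- rhdf5::H5Fopen(path2)
    did <- rhdf5::H5Dopen(fid, ds)
    rhdf5::h5writeAttribute(as.numeric(spec[2]), did, "sample_rate")
    rhdf5::H5Dclose(did); rhdf5::H5Fclose(fid)
  }
  rhdf5::h5write(1, path2, "duration_s")
  rhdf5::h5closeAll()
  expect_error(read_recording(path2), "mismatch")
})

test_that("unit construction validates spike times and exports to CSV", {
  expect_error(mea_unit("u1", "22", c(1, 1, 2)), "strictly increasing")
  expect_error(mea_unit("u1", "22", c(-1, 2)), ">= 0")
  u1 <- mea_unit("22_u1", "22", c(0.5, 1.2))
  u2 <- mea_unit("33_u1", "33", 2.5)
  expect_equal(u1$n_spikes, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_spike_times(list(u1, u2), path)
  df <- read.csv(path, colClasses = c("character", "character", "numeric"))
  expect_equal(names(df), c("unit_id", "electrode_id", "spike_time_s"))
  expect_equal(nrow(df), 3)
  expect_equal(df$spike_time_s, c(0.5, 1.2, 2.5))
})
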