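mk_bursts <- function(start, end, n = rep(10L, length(start))) {
  structure(data.frame(start = start, end = end, n_spikes = n,
                       i_first = NA_integer_, i_last = NA_integer_),
            class = c("burst_set", "data.frame"))
}

test_that("burst-count series counts covering intervals exactly", {
  s0 <- burst_count_series(list(), 10)
  expect_true(all(s0$counts == 0))
  expect_equal(length(s0$counts), 10001)

  s1 <- burst_count_series(list(u1 = mk_bursts(1, 2)), 10)
  t <- (seq_along(s1$counts) - 1) * s1$dt
  expect_true(all(s1$counts[t >= 1 & t <= 2] == 1))
  expect_true(all(s1$counts[t < 1 | t > 2] == 0))

  s2 <- burst_count_series(list(u1 = mk_bursts(1, 2), u2 = mk_bursts(1.5, 2.5)), 10)
  expect_true(all(s2$counts[t >= 1.5 & t <= 2] == 2))
  expect_true(all(s2$counts[(t >= 1 & t < 1.5) | (t > 2 & t <= 2.5)] == 1))
  expect_true(all(s2$counts[t < 1 | t > 2.5] == 0))
  expect_error(burst_count_series(list(u1 = mk_bursts(-1, 2)), 10), "within")
})

test_that("NB threshold equals mean of top decile over three", {
  expect_equal(nb_threshold(rep(4, 50)), 4 / 3)
  expect_equal(nb_threshold(1:100), 95.5 / 3)
  expect_equal(nb_threshold(numeric(100)), 0)
  set.seed(3)
  for (i in 1:50) {
    v <- rpois(sample(20:200, 1), 3)
    expect_equal(nb_threshold(v), oracle_nb_threshold(v))
  }
})

test_that("network bursts are supra-threshold runs with both size exclusions", {
  units <- lapply(1:5, function(i)
    mea_unit(paste0("u", i), paste0("e", i), seq(1.05, 1.95, length.out = 12) + i * 1e-4))
  bursts <- stats::setNames(lapply(1:5, function(i) mk_bursts(1, 2, 12L)), paste0("u", 1:5))
  series <- burst_count_series(bursts, 10)
  nbs <- detect_network_bursts(series, 1.5, units, bursts)
  expect_equal(nrow(nbs), 1)
  expect_equal(nbs$start, 1)
  expect_equal(nbs$end, 2)
  expect_equal(nbs$n_spikes, 60L)
  expect_equal(nbs$n_units, 5L)

  # candidate with fewer than 10 spikes rejected
  units8 <- lapply(1:5, function(i)
    mea_unit(paste0("u", i), paste0("e", i),
             if (i <= 4) seq(1.2, 1.8, length.out = 2) + i * 1e-3 else 1.5))
  bursts8 <- stats::setNames(lapply(1:5, function(i) mk_bursts(1, 2, 3L)), paste0("u", 1:5))
  series8 <- burst_count_series(bursts8, 10)
  nbs8 <- detect_network_bursts(series8, 1.5, units8, bursts8)
  expect_equal(nrow(nbs8), 0)

  # 6000 bursting spikes on the array raise the floor to 20
  big <- stats::setNames(lapply(1:2, function(i)
    mk_bursts(c(1, 5), c(2, 6), c(2985L, 15L))), c("u1", "u2"))
  u_big <- list(mea_unit("u1", "e1", seq(5.01, 5.99, length.out = 8)),
                mea_unit("u2", "e2", seq(5.02, 5.98, length.out = 7)))
  series_big <- burst_count_series(big, 10)
  nbs_big <- detect_network_bursts(series_big, 1.5, u_big, big)
  # the [5,6] candidate holds 15 spikes < 20 and is dropped; [1,2] holds none
  expect_equal(nrow(nbs_big), 0)
})

test_that("raising the threshold never increases the NB count", {
  set.seed(7)
  bursts <- stats::setNames(lapply(1:6, function(i) {
    s <- sort(runif(8, 0, 50))
    mk_bursts(s, s + runif(8, 0.2, 1.5), rep(12L, 8))
  }), paste0("u", 1:6))
  units <- lapply(1:6, function(i)
    mea_unit(paste0("u", i), paste0("e", i), sort(runif(200, 0, 60))))
  series <- burst_count_series(bursts, 60)
  counts <- vapply(c(0.5, 1, 1.5, 2, 3, 4), function(th)
    nrow(detect_network_bursts(series, th, units, bursts)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("network burstiness is the in-NB spike fraction", {
  nbs <- structure(data.frame(start = c(1, 5), end = c(2, 6),
                              n_spikes = c(30L, 30L), n_units = c(3L, 3L)),
                   class = c("network_burst_set", "data.frame"))
  expect_equal(network_burstiness(c(1.1, 1.5, 5.5, 3, 8), nbs), 0.6)
  expect_equal(network_burstiness(c(1.1, 1.9), nbs), 1)
  empty <- structure(data.frame(start = numeric(0), end = numeric(0),
                                n_spikes = integer(0), n_units = integer(0)),
                     class = c("network_burst_set", "data.frame"))
  expect_equal(network_burstiness(c(1, 2), empty), 0)
  expect_true(is.na(network_burstiness(numeric(0), nbs)))
})

test_that("NB summary scales counts to 10 minutes", {
  nbs <- structure(data.frame(start = c(0, 10), end = c(1, 13),
                              n_spikes = c(20L, 20L), n_units = c(2L, 2L)),
                   class = c("network_burst_set", "data.frame"))
  expect_equal(nb_summary(nbs, 600)$count_per_10min, 2)
  expect_equal(nb_summary(nbs, 300)$count_per_10min, 4)
  expect_equal(nb_summary(nbs, 600)$mean_duration_s, 2)
  empty <- nbs[0, ]
  expect_equal(nb_summary(empty, 600)$count_per_10min, 0)
  expect_true(is.na(nb_summary(empty, 600)$mean_duration_s))
})

test_that("activity map averages the rectified signal per electrode", {
  fs <- 8000
  t <- (0:(fs - 1)) / fs
  rec <- raw_recording(list("22" = 5 * sin(2 * pi * 500 * t),
                            "33" = numeric(fs)),
                       sample_rate = fs, duration = 1)
  m <- activity_map(rec, c(0, 1))
  v22 <- m$value[m$electrode_id == "22"]
  expect_equal(v22, 5 * 2 / pi, tolerance = 0.02)     # mean |sin|, discrete grid
  expect_equal(m$value[m$electrode_id == "33"], 0)
  expect_true(is.na(m$value[m$electrode_id == "44"]))
  flipped <- rec; flipped$traces[["22"]] <- -flipped$traces[["22"]]
  expect_equal(activity_map(flipped, c(0, 1))$value, m$value)
  expect_error(activity_map(rec, c(0.5, 0.2)), "interval")
})
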