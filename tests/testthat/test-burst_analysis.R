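test_that("log-ISI histogram mass lands in the right bins and normalizes", {
  periodic <- cumsum(c(0, rep(0.5, 10)))
  h <- log_isi_histogram(periodic)
  expect_s3_class(h, "log_isi_histogram")
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(sum(h$p > 0), 1)                      # all mass in one bin
  expect_equal(h$N, 50)                              # 10/decade over 5 decades

  mixed <- cumsum(c(0, rep(c(0.01, 1), 10)))         # half 10 ms, half 1 s
  h2 <- log_isi_histogram(mixed)
  expect_equal(sort(h2$p[h2$p > 0]), c(0.5, 0.5))

  ratio <- cumsum(c(0, rep(c(0.01, 0.01, 0.01, 1), 12)))  # 3:1 mixture
  h3 <- log_isi_histogram(ratio)
  expect_equal(sort(h3$p[h3$p > 0]), c(0.25, 0.75))

  expect_null(log_isi_histogram(c(0, 1)))            # < 3 spikes
  # out-of-range ISIs are clipped into the end bins, never dropped
  h4 <- log_isi_histogram(cumsum(c(0, 1e-4, 1e-4, 500)))
  expect_equal(sum(h4$p), 1, tolerance = 1e-12)
})

test_that("burst threshold: fallback for unimodal, valley for bimodal", {
  set.seed(1)
  # unimodal: tight lognormal ISIs around 0.3 s
  uni <- cumsum(c(0, exp(rnorm(500, log(0.3), 0.15))))
  th_uni <- find_burst_threshold(log_isi_histogram(uni))
  expect_equal(th_uni$threshold, 0.1)
  expect_equal(th_uni$flag, "fallback")

  # bimodal: bursts of 10 ms ISIs separated by ~1 s pauses
  bi <- cumsum(c(0, rep(c(rep(0.01, 8), 1), 60)))
  th_bi <- find_burst_threshold(log_isi_histogram(bi))
  expect_gt(th_bi$threshold, 0.01)
  expect_lt(th_bi$threshold, 1)
  expect_equal(th_bi$flag, "bimodal")

  # valley above 0.1 s: slow bursts (90 ms ISIs) against ~5 s pauses
  slow <- cumsum(c(0, rep(c(rep(0.09, 10), 5), 50)))
  th_slow <- find_burst_threshold(log_isi_histogram(slow))
  expect_gt(th_slow$threshold, 0.1)
  expect_equal(th_slow$flag, "enclosure-required")

  expect_equal(find_burst_threshold(NULL)$flag, "fallback")
})

test_that("burst detection applies the size floors and finds exact spans", {
  # two-spike runs never qualify (minimum 3 spikes)
  expect_equal(nrow(detect_bursts(c(0, 0.01, 5, 5.01), 0.1)), 0)

  st <- c(0, .01, .02, .03, 5, 5.01, 5.02, 5.03)
  b <- detect_bursts(st, 0.1)
  expect_equal(b$start, c(0, 5))
  expect_equal(b$end, c(0.03, 5.03))
  expect_equal(b$n_spikes, c(4L, 4L))

  # 30,000-spike unit: floor rises to ceil(30000/3000) = 10
  long <- cumsum(c(0, rep(1, 29994), rep(0.01, 5)))   # a 6-spike fast run
  expect_equal(length(long), 30000)
  expect_equal(nrow(detect_bursts(long, 0.1)), 0)
  long2 <- cumsum(c(0, rep(1, 29988), rep(0.01, 11))) # a 12-spike fast run
  expect_equal(nrow(detect_bursts(long2, 0.1)), 1)
  expect_equal(detect_bursts(long2, 0.1)$n_spikes, 12L)
})

test_that("enclosure rule keeps only candidates containing a 0.1 s burst", {
  # loose run (0.4 s ISIs) with a dense 0.01 s core: accepted at 0.5 s
  with_core <- cumsum(c(0, 0.4, 0.4, 0.01, 0.01, 0.01, 0.4, 0.4))
  b1 <- detect_bursts(with_core, 0.5, flag = "enclosure-required")
  expect_equal(nrow(b1), 1)
  # same loose run without a dense core: rejected
  no_core <- cumsum(c(0, rep(0.4, 7)))
  b2 <- detect_bursts(no_core, 0.5, flag = "enclosure-required")
  expect_equal(nrow(b2), 0)
  # without the flag the loose run stands
  expect_equal(nrow(detect_bursts(no_core, 0.5, flag = "bimodal")), 1)
})

test_that("burstiness is the in-burst spike fraction", {
  st <- cumsum(c(0, rep(c(rep(0.01, 5), 2), 4)))
  b <- detect_bursts(st, 0.1)
  expect_equal(burstiness(st, b), sum(b$n_spikes) / length(st))
  none <- structure(data.frame(start = numeric(0), end = numeric(0),
                               n_spikes = integer(0)),
                    class = c("burst_set", "data.frame"))
  expect_equal(burstiness(st, none), 0)
  all_in <- detect_bursts(cumsum(c(0, rep(0.01, 9))), 0.1)
  expect_equal(burstiness(cumsum(c(0, rep(0.01, 9))), all_in), 1)
  expect_true(is.na(burstiness(numeric(0), none)))
})

test_that("in-burst ISIs obey the threshold and borders exceed it", {
  set.seed(13)
  for (i in 1:50) {
    st <- random_train()
    thr <- runif(1, 0.02, 0.3)
    b <- detect_bursts(st, thr)
    for (j in seq_len(nrow(b))) {
      inb <- st[st >= b$start[j] & st <= b$end[j]]
      expect_true(all(diff(inb) <= thr))
      before <- st[st < b$start[j]]
      after <- st[st > b$end[j]]
      if (length(before)) expect_gt(b$start[j] - max(before), thr)
      if (length(after)) expect_gt(min(after) - b$end[j], thr)
    }
  }
})

test_that("vectorized detector matches the spike-by-spike oracle", {
  set.seed(14)
  for (i in 1:400) {
    st <- random_train()
    thr <- sample(c(0.05, 0.1, 0.3), 1)
    flag <- if (thr > 0.1) "enclosure-required" else "bimodal"
    got <- detect_bursts(st, thr, flag)
    want <- oracle_bursts(st, thr, flag)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_spikes, as.integer(want$n_spikes))
  }
})

test_that("unit_bursts recovers a designed in-burst fraction", {
  set.seed(15)
  scn <- recording_scenario(
    list(list(electrode_id = "22", baseline_rate = 1, in_burst_rate = 120,
              burst_epochs = cbind(seq(2, 56, by = 6), seq(2.5, 56.5, by = 6)))),
    duration = 60, seed = 22)
  g <- generate_recording(scn)
  st <- g$truth$spike_times[[1]]
  ub <- unit_bursts(st)
  expect_lt(abs(ub$burstiness - g$truth$in_burst_fraction[1]), 0.05)
})
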