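test_that("logISI threshold separates bimodal trains and rejects unimodal ones", {
  tr <- make_bimodal_train()
  th <- logisi_threshold(tr)
  expect_false(is.null(th))
  expect_gt(th, 0.005)
  expect_lt(th, 1)

  # homogeneous Poisson: unimodal log-ISI, no burst threshold
  set.seed(2)
  p <- cumsum(rexp(600, 1))
  expect_null(logisi_threshold(p))

  # too few spikes
  expect_null(logisi_threshold(c(0.1, 0.2, 0.3)))
})

test_that("burst detector matches the construction and the min-spike rule", {
  tr <- make_bimodal_train(n_bursts = 20, spikes_per_burst = 6,
                           intra_isi = 0.005, gap_s = 1)
  b <- detect_bursts(tr, isi_threshold = 0.05)
  expect_equal(nrow(b), 20)
  expect_true(all(b$n_spikes == 6))
  expect_equal(b$t_end_s - b$t_start_s, rep(0.025, 20))

  # a 4-spike cluster never forms a burst
  b4 <- detect_bursts(c(0, 0.005, 0.01, 0.015), isi_threshold = 0.05)
  expect_equal(nrow(b4), 0)
  # ... but 5 spikes do
  b5 <- detect_bursts(c(0, 0.005, 0.01, 0.015, 0.02), isi_threshold = 0.05)
  expect_equal(nrow(b5), 1)
})

test_that("burst detector equals the exhaustive run-scan oracle", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    train <- sort(round(cumsum(rexp(n, rate = sample(c(5, 20, 60), 1))), 6))
    train <- unique(train)
    isith <- sample(c(0.02, 0.05, 0.1, 0.15, 0.3), 1)
    got <- detect_bursts(train, isith)
    want <- burst_oracle(train, isith)
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("core-and-extension branch activates above the 100 ms core ISI", {
  # core run at 50 ms ISIs, flanked by 120 ms ISIs; ISITh 150 ms extends
  train <- c(0, 0.12, 0.17, 0.22, 0.27, 0.32, 0.44)
  b <- detect_bursts(train, isi_threshold = 0.15)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 7)
  expect_equal(b$t_start_s, 0)
  expect_equal(b$t_end_s, 0.44)
  # same train with ISITh 150 ms but no sub-100 ms core: no burst
  train2 <- seq(0, by = 0.12, length.out = 7)
  expect_equal(nrow(detect_bursts(train2, 0.15)), 0)
})

test_that("merge rule unions close bursts only when ISITh < 100 ms", {
  bs <- tibble::tibble(t_start_s = c(0, 0.28), t_end_s = c(0.2, 0.5),
                       n_spikes = c(6L, 6L))
  m <- merge_bursts(bs, isi_threshold = 0.05)
  expect_equal(nrow(m), 1)
  expect_equal(m$t_start_s, 0)
  expect_equal(m$t_end_s, 0.5)
  expect_equal(m$n_spikes, 12L)

  # inactive when the threshold itself exceeds the merge gap
  expect_equal(merge_bursts(bs, isi_threshold = 0.15), bs)

  # idempotence and spike-count conservation
  set.seed(5)
  starts <- cumsum(runif(20, 0.05, 0.4))
  bs2 <- tibble::tibble(t_start_s = starts,
                        t_end_s = starts + 0.03,
                        n_spikes = sample(5:12, 20, replace = TRUE))
  m1 <- merge_bursts(bs2, 0.05)
  expect_equal(merge_bursts(m1, 0.05), m1)
  expect_equal(sum(m1$n_spikes), sum(bs2$n_spikes))
  gaps <- m1$t_start_s[-1] - m1$t_end_s[-nrow(m1)]
  expect_true(all(gaps >= 0.1))
})

test_that("electrode burst features follow the stated arithmetic", {
  tr <- make_bimodal_train(n_bursts = 20, spikes_per_burst = 6,
                           intra_isi = 0.005, gap_s = 29)
  extra <- seq(15, by = 19, length.out = 30)
  train <- sort(c(tr, extra))
  sp <- spike_table(data.frame(well_id = "W1", electrode_id = "E01",
                               time_s = train), duration_s = 600)
  b <- tibble::tibble(well_id = "W1", electrode_id = "E01",
                      detect_bursts(tr, 0.05))
  f <- burst_features(b, sp)
  expect_equal(f$burst_rate_per_min, 2)        # 20 bursts in 10 min
  expect_equal(f$burst_duration_s, 0.025)
  expect_equal(f$spikes_in_burst, 6)
  expect_equal(f$spike_freq_in_burst_hz, 200)  # (6-1)/0.025
  expect_equal(f$pct_spikes_in_bursts, 100 * 120 / 150)
})

test_that("percentage of spikes in bursts is invariant under time rescaling", {
  tr <- make_bimodal_train(n_bursts = 10, gap_s = 2)
  for (scale in c(0.5, 1, 3)) {
    train <- tr * scale
    sp <- spike_table(data.frame(well_id = "W1", electrode_id = "E01",
                                 time_s = train),
                      duration_s = max(train) + 1)
    b <- tibble::tibble(well_id = "W1", electrode_id = "E01",
                        detect_bursts(train, 0.05 * scale,
                                      max_core_isi = 0.1 * scale))
    f <- burst_features(b, sp)
    expect_equal(f$pct_spikes_in_bursts, 100)
  }
})

test_that("well aggregation takes the median over bursting electrodes", {
  f <- tibble::tibble(
    well_id = "W1", electrode_id = c("E01", "E02", "E03"),
    burst_rate_per_min = c(10, 11, 30),
    burst_duration_s = c(0.5, 0.5, 0.5),
    spikes_in_burst = c(6, 6, 6),
    spike_freq_in_burst_hz = c(10, 10, 10),
    pct_spikes_in_bursts = c(80, 90, 100))
  w <- well_burst_features(f)
  expect_equal(w$burst_rate_per_min, 11)
  expect_equal(w$n_bursting_electrodes, 3L)
  # identical electrodes: medians reproduce the values
  w2 <- well_burst_features(f[c(1, 1, 1), ])
  expect_equal(w2$burst_rate_per_min, 10)
})

test_that("non-bursting electrodes are excluded from features", {
  # electrode with tonic-only spiking alongside a bursting one
  tr <- make_bimodal_train(n_bursts = 10, gap_s = 2)
  tonic <- seq(0.4, 29.6, by = 0.75)  # regular tonic firing, no bursts
  sp <- spike_table(
    rbind(data.frame(well_id = "W1", electrode_id = "E01", time_s = tr),
          data.frame(well_id = "W1", electrode_id = "E02",
                     time_s = tonic)),
    duration_s = 30)
  fb <- find_bursts(sp)
  expect_true(all(fb$bursts$electrode_id == "E01"))
  expect_true(is.na(
    fb$thresholds$isi_threshold_s[fb$thresholds$electrode_id == "E02"]))
  f <- burst_features(fb, sp)
  expect_equal(f$electrode_id, "E01")
})
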