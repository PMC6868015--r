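fs <- 12500

test_that("bandpass filter passes the band and rejects out-of-band tones", {
  t <- (0:(10 * fs - 1)) / fs
  mid <- (4 * fs):(6 * fs)
  y_pass <- bandpass_filter(sin(2 * pi * 1000 * t), fs)
  expect_gt(max(abs(y_pass[mid])), 0.95)
  expect_lt(max(abs(y_pass[mid])), 1.05)
  y_stop <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(y_stop[mid])), 0.05)
  expect_equal(bandpass_filter(numeric(fs), fs), numeric(fs))
  expect_error(bandpass_filter(numeric(fs), fs, f_hi = 7000), "fs/2")
})

test_that("noise SD estimator is consistent and robust to spikes", {
  set.seed(11)
  x <- rnorm(125000)
  expect_gt(estimate_noise_sd(x), 0.97)
  expect_lt(estimate_noise_sd(x), 1.03)
  xc <- x
  xc[sample(length(x), 1250)] <- 20
  expect_gt(estimate_noise_sd(xc), 0.97)
  expect_lt(estimate_noise_sd(xc), 1.05)
  expect_gt(sd(xc), 2)  # the plain SD collapses under the same contamination
  expect_warning(estimate_noise_sd(numeric(2000)), "sigma_hat = 0")
})

test_that("threshold detector finds extrema with dead-time thinning", {
  tr <- numeric(5000)
  tr[1001] <- -10  # 0-based sample index 1000
  expect_equal(threshold_detect(tr, fs, sigma_hat = 1), 1000 / fs)

  # two peaks 0.5 ms apart, 1 ms dead time: larger extremum wins
  tr2 <- numeric(5000)
  tr2[1000] <- -8
  tr2[1006] <- -12
  got <- threshold_detect(tr2, fs, sigma_hat = 1, dead_time_s = 0.001)
  expect_equal(got, 1005 / fs)

  # polarity "neg" ignores positive deflections
  tr3 <- numeric(5000)
  tr3[1000] <- 10
  expect_length(threshold_detect(tr3, fs, 1, polarity = "neg"), 0)
  expect_length(threshold_detect(tr3, fs, 1, polarity = "both"), 1)
})

test_that("detection is translation-equivariant", {
  set.seed(4)
  tr <- rnorm(20000)
  tr[c(5000, 9000, 15000)] <- -30
  t1 <- threshold_detect(tr, fs, 1)
  shift <- 100
  t2 <- threshold_detect(c(numeric(shift), tr), fs, 1)
  expect_equal(t2, t1 + shift / fs)
})

test_that("SWTTEO energy localises spikes and ignores slow oscillations", {
  expect_equal(swtteo_energy(numeric(4096), fs), numeric(4096))

  tmpl <- waveform_model()$template
  tr <- numeric(25000)
  centre <- 12501
  off <- which.min(tmpl) - 1
  tr[(centre - off):(centre - off + length(tmpl) - 1)] <- 40 * tmpl
  en <- swtteo_energy(tr, fs)
  expect_lte(abs(which.max(en) - centre), 1)

  # 50 Hz mains alone vs mains + spike: the spike dominates the energy
  t <- (0:24999) / fs
  mains <- 20 * sin(2 * pi * 50 * t)
  en_mains <- swtteo_energy(mains, fs)
  en_both <- swtteo_energy(mains + tr, fs)
  at_spike <- en_both[centre]
  expect_gt(at_spike / max(en_mains), 5)
})

test_that("swtteo_select returns the requested number of energy peaks", {
  en <- numeric(10000)
  en[c(2000, 5000, 8000)] <- c(3, 2, 1)
  expect_length(swtteo_select(en, fs, 0), 0)
  expect_equal(swtteo_select(en, fs, 3),
               (c(2000, 5000, 8000) - 1) / fs)
  expect_equal(swtteo_select(en, fs, 2), (c(2000, 5000) - 1) / fs)
  # fewer maxima than requested: returns what exists
  expect_length(swtteo_select(en, fs, 10), 3)
})

test_that("consensus keeps only coincident detections, one-to-one", {
  expect_equal(consensus_spikes(c(0.1, 0.2), c(0.1001, 0.5), 0.001), 0.1)
  a <- sort(runif(20))
  expect_equal(consensus_spikes(a, a, 0.001), a)
  expect_length(consensus_spikes(numeric(0), a, 0.001), 0)

  # greedy in-order matching achieves the maximum one-to-one matching
  set.seed(21)
  for (i in 1:20) {
    a <- sort(runif(50, 0, 10))
    b <- sort(a + rnorm(50, 0, 0.002))
    got <- length(consensus_spikes(a, b, 0.001))
    expect_equal(got, max_matching_oracle(a, b, 0.001))
  }
})

test_that("consensus count is monotone in the tolerance", {
  set.seed(31)
  a <- sort(runif(100, 0, 10))
  b <- sort(runif(100, 0, 10))
  tols <- c(0.0005, 0.001, 0.005, 0.02, 0.1)
  counts <- vapply(tols, function(tol)
    length(consensus_spikes(a, b, tol)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("threshold detection with injected sigma recovers zero-noise truth", {
  sr <- small_truth_recording(seed = 13, duration_s = 20,
                              n_electrodes = 1,
                              wf = waveform_model(amplitude_uv = 40,
                                                  noise_sd_uv = 0))
  tr <- sr$rec$traces[1, ]
  tt <- sr$truth$spikes$time_s
  half_ms <- 0.001
  interior <- tt[tt > half_ms & tt < 20 - half_ms]
  # dead time one sample below the generator's 1 ms refractory so spikes
  # at the refractory bound are not thinned away
  got <- threshold_detect(tr, fs, sigma_hat = 1, k = 4.5,
                          dead_time_s = 0.0008)
  # every non-edge true spike recovered within one sample
  expect_true(all(vapply(interior, function(x)
    any(abs(got - x) <= 1 / fs + 1e-9), logical(1))))
})

test_that("full consensus detection recovers inserted spikes in zero noise", {
  set.seed(51)
  tt <- sort(sample(seq(0.05, 9.95, by = 0.05), 10))
  sp <- spike_table(data.frame(well_id = "W1", electrode_id = "E01",
                               time_s = tt), duration_s = 10)
  truth <- structure(list(spikes = sp, bursts = NULL,
                          params = network_params(n_electrodes = 1,
                                                  duration_s = 10),
                          seed = 1L), class = "mea_ground_truth")
  # tiny noise floor so sigma_hat is positive but spikes tower above it
  rec <- synthesize_raw(truth, waveform_model(amplitude_uv = 40,
                                              amplitude_cv = 0,
                                              noise_sd_uv = 0.5), seed = 3)
  det <- detect_spikes(rec)
  expect_equal(nrow(det$spikes), 10)
  expect_true(all(vapply(tt, function(x)
    any(abs(det$spikes$time_s - x) <= 0.001), logical(1))))
  pe <- det$per_electrode
  expect_true(all(pe$n_consensus <=
                    pmin(pe$n_threshold_candidates,
                         pe$n_swtteo_candidates)))
})

test_that("active-electrode rule is strict at 10 spikes per minute", {
  mk <- function(n_spikes, id) {
    data.frame(well_id = "W1", electrode_id = id,
               time_s = seq(0.5, 599.5, length.out = n_spikes))
  }
  df <- rbind(
    do.call(rbind, lapply(1:16, function(i) mk(120, sprintf("A%02d", i)))),
    do.call(rbind, lapply(1:48, function(i) mk(50, sprintf("B%02d", i)))))
  sp <- spike_table(df, duration_s = 600)
  act <- active_electrodes(sp)
  expect_equal(sum(act$active), 16)
  expect_equal(unique(act$pct_active), 25.0)

  # exactly 10 spikes/min is inactive (strict >)
  sp2 <- spike_table(mk(100, "E01"), duration_s = 600)
  expect_false(active_electrodes(sp2)$active)
  expect_true(active_electrodes(sp2, min_spikes_per_min = 9.9)$active)

  # empty table: no active electrodes
  sp3 <- spike_table(data.frame(well_id = character(),
                                electrode_id = character(),
                                time_s = numeric()), duration_s = 600)
  expect_equal(nrow(active_electrodes(sp3)), 0)
})
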