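test_that("STTC reproduces hand-computed and degenerate cases", {
  # T_A = T_B = 0.1, P_A = P_B = 0 -> -0.1
  expect_equal(sttc(5, 8, dt = 0.5, duration = 10), -0.1)
  tr <- c(1, 2.5, 7)
  expect_equal(sttc(tr, tr, dt = 0.05, duration = 10), 1)
  expect_true(is.na(sttc(numeric(0), tr, dt = 0.05, duration = 10)))
})

test_that("STTC equals the brute-force tiling oracle", {
  set.seed(41)
  for (i in 1:500) {
    na <- sample(1:30, 1)
    nb <- sample(1:30, 1)
    dur <- 10
    a <- sort(runif(na, 0, dur))
    b <- sort(runif(nb, 0, dur))
    dt <- sample(c(0.01, 0.05, 0.2, 1), 1)
    got <- sttc(a, b, dt, dur)
    want <- sttc_oracle(a, b, dt, dur)
    expect_equal(got, want, tolerance = 1e-12, info = paste("case", i))
    if (!is.na(got)) {
      expect_gte(got, -1)
      expect_lte(got, 1)
    }
    expect_equal(got, sttc(b, a, dt, dur))
  }
})

test_that("STTC is invariant under joint time translation", {
  set.seed(43)
  # trains kept away from the window edges so tiles never clip
  a <- sort(runif(20, 0.5, 7.5))
  b <- sort(runif(25, 0.5, 7.5))
  v1 <- sttc(a, b, 0.05, 10)
  for (shift in c(0.3, 1, 2)) {
    expect_equal(sttc(a + shift, b + shift, 0.05, 10), v1,
                 tolerance = 1e-12)
  }
})

test_that("independent Poisson trains have near-zero mean STTC", {
  set.seed(44)
  vals <- replicate(200, {
    a <- sort(runif(rpois(1, 120), 0, 60))
    b <- sort(runif(rpois(1, 120), 0, 60))
    sttc(a, b, 0.05, 60)
  })
  expect_gt(mean(vals, na.rm = TRUE), -0.02)
  expect_lt(mean(vals, na.rm = TRUE), 0.02)
})

test_that("sttc_matrix summarises wells and respects identical trains", {
  tr <- seq(0.5, 9.5, by = 0.5)
  df <- do.call(rbind, lapply(sprintf("E%02d", 1:4), function(e)
    data.frame(well_id = "W1", electrode_id = e, time_s = tr)))
  sp <- spike_table(df, duration_s = 10)
  res <- sttc_matrix(sp)
  expect_true(all(res$pairs$sttc == 1))
  expect_equal(res$well_summary$sttc, 1)
  expect_equal(nrow(res$pairs), 6)
  expect_true(all(res$pairs$electrode_a < res$pairs$electrode_b))
})

test_that("well median STTC decreases with burst-onset jitter", {
  summaries <- vapply(c(0.000, 0.010, 0.050, 0.200), function(j) {
    par <- preset("rat_peak")
    par$jitter_s <- j
    par$duration_s <- 300
    par$n_electrodes <- 8L
    truth <- simulate_trains(par, seed = 55)
    sttc_matrix(truth$spikes)$well_summary$sttc
  }, numeric(1))
  expect_true(all(diff(summaries) < 0))
})

test_that("spectral entropy separates tones from broadband noise", {
  fs <- 12500
  t <- (0:(15 * fs - 1)) / fs
  se_tone <- spectral_entropy_series(sin(2 * pi * 1000 * t), fs)
  expect_lt(mean(se_tone), 0.3)
  set.seed(61)
  se_noise <- spectral_entropy_series(rnorm(15 * fs), fs)
  expect_gt(mean(se_noise), 0.9)
  se_zero <- spectral_entropy_series(numeric(15 * fs), fs)
  expect_true(all(se_zero == 1))
  expect_error(spectral_entropy_series(rnorm(100), 48, window_s = 1),
               "64 samples")
})

test_that("CorSE is reflexive, scale-invariant and symmetric", {
  fs <- 12500
  sr <- small_truth_recording(seed = 71, duration_s = 30,
                              n_electrodes = 1)
  x <- sr$rec$traces[1, ]
  expect_equal(corse(x, x, fs), 1.0)
  set.seed(72)
  y <- x + rnorm(length(x), 0, 3)
  v1 <- corse(x, y, fs)
  v2 <- corse(5 * x, 0.2 * y, fs)
  expect_equal(v1, v2, tolerance = 1e-9)
  expect_equal(corse(y, x, fs), v1)
  # constant trace: entropy series is constant, correlation undefined
  expect_true(is.na(corse(x, numeric(length(x)), fs)))
})

test_that("independent noise channels show weak CorSE", {
  fs <- 12500
  set.seed(73)
  vals <- replicate(10, corse(rnorm(30 * fs, 0, 5), rnorm(30 * fs, 0, 5),
                              fs))
  expect_lt(mean(vals), 0.3)
})

test_that("channels sharing burst envelopes are strongly connected", {
  par <- preset("rat_peak")
  par$n_electrodes <- 1L
  par$duration_s <- 60
  t1 <- simulate_trains(par, seed = 74)
  two <- rbind(as.data.frame(t1$spikes),
               transform(as.data.frame(t1$spikes), electrode_id = "E02"))
  par2 <- par
  par2$n_electrodes <- 2L
  truth <- structure(list(spikes = spike_table(two, 60),
                          bursts = t1$bursts, params = par2, seed = 74L),
                     class = "mea_ground_truth")
  rec <- synthesize_raw(truth, waveform_model(amplitude_uv = 40,
                                              noise_sd_uv = 5), seed = 74)
  cm <- corse_matrix(rec)
  expect_gt(cm$corse, 0.7)
})

test_that("connectivity maps threshold edges deterministically", {
  pairs <- tibble::tibble(
    well_id = "W1",
    electrode_a = c("E01", "E01", "E02"),
    electrode_b = c("E02", "E03", "E03"),
    corse = c(0.9, 0.3, 0.75),
    sttc = c(0.5, 0.1, 0.4))
  edges <- connectivity_map(pairs, 0.7)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$electrode_a, c("E01", "E02"))
  expect_equal(nrow(connectivity_map(pairs, 0.95)), 0)
  expect_equal(nrow(connectivity_map(pairs, 0)), 3)
})

test_that("average CorSE is the mean over defined pairs", {
  pairs <- tibble::tibble(well_id = "W1", electrode_a = c("a", "a", "b"),
                          electrode_b = c("b", "c", "c"),
                          corse = c(0.2, 0.4, 0.6), sttc = NA_real_)
  expect_equal(average_corse(pairs)$avg_corse, 0.4)
  pairs$corse <- c(0.5, 0.5, NA)
  expect_equal(average_corse(pairs)$avg_corse, 0.5)
  pairs$corse <- NA_real_
  expect_true(is.na(average_corse(pairs)$avg_corse))
})
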