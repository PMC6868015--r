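test_that("mean firing rate averages active electrodes", {
  df <- rbind(
    data.frame(well_id = "W1", electrode_id = "E01",
               time_s = seq(0.1, 599.9, length.out = 600)),
    data.frame(well_id = "W1", electrode_id = "E02",
               time_s = seq(0.05, 599.95, length.out = 1200)))
  sp <- spike_table(df, duration_s = 600)
  expect_equal(mean_firing_rate(sp)$mfr_hz, 1.5)

  # an electrode marked active by the caller but silent counts as 0 Hz
  act <- tibble::tibble(well_id = "W1",
                        electrode_id = c("E01", "E02", "E03"),
                        active = TRUE)
  expect_equal(mean_firing_rate(sp, active = act)$mfr_hz, 1800 / 600 / 3)
})

test_that("simulated well MFR matches the generative expectation", {
  par <- preset("hPSC_peak")
  par$n_electrodes <- 4L
  truth <- simulate_trains(par, seed = 19)
  act <- active_electrodes(truth$spikes)
  mfr <- mean_firing_rate(truth$spikes, active = act)$mfr_hz
  # participation x burst rate x spikes/burst + tonic background
  expected <- 0.95 * (11 / 60) * 34 + 0.6
  expect_lt(abs(mfr - expected) / expected, 0.1)
})

test_that("feature matrix assembly drops incomplete samples", {
  f <- tibble::tibble(
    well_id = rep(sprintf("W%02d", 1:12), 3),
    timepoint = rep(c("t1", "t2", "t3"), each = 12),
    mfr_hz = runif(36, 1, 5), burst_rate_per_min = runif(36, 5, 20),
    burst_duration_s = runif(36, 0.2, 1),
    spike_freq_in_burst_hz = runif(36, 20, 100),
    spikes_in_burst = runif(36, 10, 40),
    pct_spikes_in_bursts = runif(36, 50, 100), sttc = runif(36))
  fm <- build_feature_matrix(f)
  expect_equal(dim(fm$matrix), c(36, 7))
  expect_equal(colnames(fm$matrix)[1], "mfr_hz")

  f2 <- f
  f2$burst_rate_per_min[5] <- NA
  expect_message(fm2 <- build_feature_matrix(f2), "dropping 1")
  expect_equal(nrow(fm2$matrix), 35)

  # column order is stable
  fm3 <- build_feature_matrix(f[sample(36), ])
  expect_identical(colnames(fm3$matrix), colnames(fm$matrix))
})

test_that("standard score uses the population SD and is idempotent", {
  z <- zscore(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(cbind(a = c(1, 2, 3), b = c(4, 4, 4))), "b")
  # sample-SD variant divides by n - 1
  zs <- zscore(matrix(c(1, 2, 3), ncol = 1), sd_type = "sample")
  expect_equal(as.vector(zs), c(-1, 0, 1))
})

test_that("PCA matches the SVD oracle and fixes component signs", {
  set.seed(81)
  for (i in 1:20) {
    m <- zscore(matrix(rnorm(36 * 7), 36, 7,
                       dimnames = list(NULL, paste0("f", 1:7))))
    got <- pca_project(m, n_components = 3)
    want <- pca_svd_oracle(m)
    expect_equal(got$explained_pct, want$explained_pct, tolerance = 1e-8)
    expect_equal(sum(got$explained_pct), 100, tolerance = 1e-6)
    for (j in 1:7) {
      # equal up to sign
      d1 <- max(abs(got$loadings[, j] - want$loadings[, j]))
      d2 <- max(abs(got$loadings[, j] + want$loadings[, j]))
      expect_lt(min(d1, d2), 1e-8)
      # sign convention: largest-magnitude loading positive
      expect_gt(got$loadings[which.max(abs(got$loadings[, j])), j], 0)
    }
    # scores: zero means, diagonal covariance
    s <- as.matrix(got$scores[paste0("PC", 1:7)])
    expect_equal(colMeans(s), rep(0, 7), ignore_attr = TRUE,
                 tolerance = 1e-10)
    cv <- cov(s)
    expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  }
})

test_that("degenerate PCA inputs behave as documented", {
  # collinear points: one component carries all variance
  m <- cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  res <- suppressWarnings(pca_project(m, n_components = 2))
  expect_equal(res$explained_pct[1], 100)
  expect_warning(pca_project(m, n_components = 2), "rank")

  # isotropic 2-D Gaussian: each component near 50%
  set.seed(82)
  g <- matrix(rnorm(2e4), ncol = 2)
  res2 <- pca_project(zscore(g), n_components = 2)
  expect_equal(res2$explained_pct[1], 50, tolerance = 2)
})

test_that("group separation scores distinct and shuffled labels correctly", {
  scores <- rbind(matrix(0, 5, 3), matrix(5, 5, 3))
  labels <- rep(c("a", "b"), each = 5)
  expect_equal(group_separation(scores, labels, k = 3), 1.0)

  set.seed(83)
  x <- matrix(rnorm(60), 20, 3)
  nulls <- replicate(100, group_separation(x, sample(labels[c(1:5, 6:10,
                                                              1:5, 6:10)]),
                                           k = 3))
  expect_lt(abs(mean(nulls)), 0.15)
  expect_error(group_separation(x, rep("a", 20)), "two distinct")
})

test_that("percent change handles silencing and zero baselines", {
  expect_equal(percent_change(2, 3), 50)
  expect_equal(percent_change(2, 0), -100)
  expect_equal(percent_change(2, 2), 0)
  expect_warning(out <- percent_change(c(0, 1), c(1, 2)), "undefined")
  expect_true(is.na(out[1]))
  expect_equal(out[2], 100)
})

test_that("tidiers expose loadings and variance summaries", {
  set.seed(84)
  m <- zscore(matrix(rnorm(36 * 7), 36, 7,
                     dimnames = list(NULL, paste0("f", 1:7))))
  p <- pca_project(m, labels = tibble::tibble(group = rep(c("a", "b"),
                                                          18)))
  td <- tidy(p)
  expect_equal(nrow(td), 49)
  expect_named(td, c("feature", "component", "loading"))
  gl <- glance(p)
  expect_equal(gl$n_samples, 36)
  expect_equal(gl$pc1_pct + gl$pc2_pct + gl$pc3_pct, gl$total_first3_pct)
  plt <- autoplot(p)
  expect_s3_class(plt, "ggplot")
})
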