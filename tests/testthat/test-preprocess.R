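test_that("R-peak detection recovers every simulated beat precisely", {
  ana <- fixture_analyzed()
  truth <- ana$rec$truth$r_times
  det <- ana$r_times
  # sensitivity and precision at a 10 ms matching radius
  d_true <- vapply(truth, function(x) min(abs(det - x)), numeric(1))
  d_det <- vapply(det, function(x) min(abs(truth - x)), numeric(1))
  expect_equal(mean(d_true <= 0.010), 1)
  expect_equal(mean(d_det <= 0.010), 1)
})

test_that("R-peak detection is robust across heart rates", {
  for (hr in c(50, 90, 120)) {
    rec <- fixture_recording(hr = hr, dur = 60, noise = 0, seed = 21)
    ecg_f <- wavelet_band_limit(rec$ecg, rec$fs, 0.122, 31.25)
    det <- detect_r_peaks(ecg_f, rec$fs)
    truth <- rec$truth$r_times
    d <- vapply(truth, function(x) min(abs(det - x)), numeric(1))
    expect_gte(mean(d <= 0.010), 0.99)
  }
})

test_that("unmodulated 60 bpm over 300 s yields 300 +/- 1 peaks", {
  cfg <- sim_config(duration_s = 300, hr_mean = 60,
                    lf_mod = list(freq = 0.1, depth = 0),
                    resp = list(freq = 0.25, depth = 0), noise_sd = 0)
  rec <- generate_recording(cfg, 4)
  det <- detect_r_peaks(wavelet_band_limit(rec$ecg, rec$fs, 0.122, 31.25),
                        rec$fs)
  expect_lte(abs(length(det) - 300), 1)
})

test_that("degenerate ECG inputs are rejected", {
  expect_error(detect_r_peaks(rep(0, 10000), 1000), "flat")
  expect_error(detect_r_peaks(rnorm(100), 1000), "shorter")
})

test_that("finite differences match closed forms", {
  fs <- 1000
  t <- seq(0, 2, 1 / fs)
  ramp <- 3 * t
  expect_equal(differentiate(ramp, fs, 1)[10:1990], rep(3, 1981),
               tolerance = 1e-9)
  f <- 2
  s <- sin(2 * pi * f * t)
  d2 <- differentiate(s, fs, 2)
  expect_equal(max(abs(d2[100:1900] + (2 * pi * f)^2 * s[100:1900])) /
                 (2 * pi * f)^2, 0, tolerance = 0.01)
  # first derivative applied twice approximates the second derivative
  d11 <- differentiate(differentiate(s, fs, 1), fs, 1)
  expect_equal(d11[100:1900], d2[100:1900],
               tolerance = 0.01 * max(abs(d2)))
})

test_that("rate series are normalised, gridded and artifact-robust", {
  ev <- cumsum(rep(1, 60))
  rs <- build_rate_series(ev)
  expect_true(all(abs(rs$values - 1) < 1e-9))
  expect_equal(unique(round(diff(rs$times), 9)), 0.25)

  ev2 <- cumsum(rep(c(0.9, 1.1), 30))
  rs2 <- build_rate_series(ev2)
  expect_lt(abs(mean(rs2$values) - 1), 1e-9)

  rec <- fixture_recording(hr = 60, dur = 120, noise = 0, seed = 9,
                           resp = list(freq = 0.25, depth = 0.05),
                           lf_mod = list(freq = 0.1, depth = 0))
  rs3 <- build_rate_series(rec$truth$r_times)
  tf <- morlet_power(rs3, freq_range = c(0.05, 0.4))
  pm <- rowMeans(tf$power[, .tf_ok(tf)])
  expect_lt(abs(tf$freqs[which.max(pm)] - 0.25), 0.03)

  expect_error(build_rate_series(c(1, 2, 1.5, 3:12)), "increasing")
  expect_error(build_rate_series(1:5), "10 events")

  # one grossly long interval (missed beat) is interpolated over
  ev4 <- cumsum(c(rep(1, 30), 2, rep(1, 30)))
  rs4 <- build_rate_series(ev4)
  expect_equal(rs4$n_outliers, 1L)
  expect_true(all(abs(rs4$values - 1) < 0.05))
})
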