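test_that("unmodulated beats are exactly periodic and deterministic", {
  cfg <- sim_config(duration_s = 30, hr_mean = 60,
                    lf_mod = list(freq = 0.1, depth = 0),
                    resp = list(freq = 0.25, depth = 0), noise_sd = 0)
  rec <- generate_recording(cfg, 7)
  ibis <- diff(rec$truth$r_times)
  expect_true(all(abs(ibis - 1) < 2e-3))
  expect_equal(length(rec$truth$r_times),
               cfg$hr_mean * cfg$duration_s / 60, tolerance = 2 / 30)

  rec2 <- generate_recording(cfg, 7)
  expect_identical(rec$ppg, rec2$ppg)
  expect_identical(rec$ecg, rec2$ecg)
  expect_identical(rec$resp, rec2$resp)
})

test_that("respiratory rate modulation lands at the configured frequency", {
  rec <- fixture_recording(hr = 60, dur = 120, noise = 0, seed = 9,
                           resp = list(freq = 0.25, depth = 0.05),
                           lf_mod = list(freq = 0.1, depth = 0))
  f_hat <- rate_peak_freq(rec$truth$r_times)  # independent periodogram
  expect_lt(abs(f_hat - 0.25), 0.02)
})

test_that("template landmark ordering holds in stored ground truth", {
  rec <- fixture_recording()
  tf <- rec$truth$fiducials
  expect_true(all(tf$O_t < tf$S_t))
  expect_true(all(tf$S_t < tf$N_t))
  expect_true(all(tf$N_t <= tf$D_t))
  expect_true(all(tf$O_t < tf$w_t & tf$w_t < tf$S_t))
  expect_true(all(tf$a_t < tf$b_t & tf$b_t < tf$e_t))
  # diastolic peak precedes the next onset
  expect_true(all(utils::head(tf$D_t, -1) < utils::tail(tf$O_t, -1)))
})

test_that("respiration and rate modulation are phase-locked", {
  rec <- fixture_recording(hr = 60, dur = 300, noise = 0, seed = 3)
  # instantaneous rate from true beat times vs respiration, both at 4 Hz
  iv <- diff(rec$truth$r_times)
  at <- rec$truth$r_times[-1]
  grid <- seq(at[1], at[length(at)], by = 0.25)
  rate <- stats::approx(at, 60 / iv, xout = grid)$y
  resp <- rec$resp[round(grid * rec$fs) + 1]
  coh <- coherence_at(rate, resp, fs = 4, f0 = rec$config$resp$freq)
  expect_gt(coh, 0.95)
})

test_that("cohorts are paired, preset-ordered and seed-sensitive", {
  coh <- generate_cohort(28, c("BSL", "SDB", "CPT", "MAT"), seed = 1)
  expect_equal(nrow(coh$manifest), 112)
  for (s in unique(coh$manifest$subject_id)) {
    rows <- which(coh$manifest$subject_id == s)
    cfgs <- coh$configs[rows]
    names(cfgs) <- coh$manifest$state[rows]
    expect_lt(cfgs$SDB$resp$freq, cfgs$BSL$resp$freq)
    expect_gt(cfgs$SDB$resp$depth, cfgs$BSL$resp$depth)
    expect_lt(cfgs$CPT$gain, cfgs$BSL$gain)
    expect_gt(cfgs$MAT$lf_mod$depth, cfgs$BSL$lf_mod$depth)
  }
  r1 <- cohort_recording(generate_cohort(3, "BSL", seed = 1), 1)
  r2 <- cohort_recording(generate_cohort(3, "BSL", seed = 2), 1)
  expect_false(isTRUE(all.equal(utils::head(diff(r1$truth$r_times), 10),
                                utils::head(diff(r2$truth$r_times), 10))))
  expect_error(generate_cohort(4, c("BSL", "XXX"), seed = 1), "unknown state")
  expect_error(generate_cohort(1, "BSL", seed = 1))
})

test_that("configuration validation rejects unresolvable settings", {
  expect_error(sim_config(fs = 20), "fs")
  expect_error(sim_config(hr_mean = 200))
  expect_error(sim_config(resp = list(freq = 0.25, depth = 1.2)))
  expect_error(sim_config(duration_s = -5))
})

test_that("recordings round-trip through the CSV + sidecar writer", {
  rec <- fixture_recording(dur = 20, seed = 13, noise = 0.005)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$ppg, rec$ppg, tolerance = 1e-12)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$truth$r_times, rec$truth$r_times, tolerance = 1e-9)
  expect_equal(back$config$hr_mean, rec$config$hr_mean)
})
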