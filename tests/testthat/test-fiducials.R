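test_that("all ten landmarks are recovered against ground truth", {
  ana <- fixture_analyzed()
  expect_gte(fiducial_recovery_rate(ana$rec, ana$fid, tol_s = 0.015), 0.95)
  # systolic-group points are the tightest
  tf <- ana$rec$truth$fiducials
  for (p in c("S", "w", "b")) {
    err <- vapply(seq_len(nrow(ana$fid)), function(i) {
      j <- which.min(abs(tf$r_time - ana$fid$r_time[i]))
      abs(ana$fid[[paste0(p, "_t")]][i] - tf[[paste0(p, "_t")]][j])
    }, numeric(1))
    expect_lt(stats::quantile(err, 0.95), 0.010)
  }
  # the onset-referenced systolic height matches the rendered template
  s_err <- vapply(seq_len(nrow(ana$fid)), function(i) {
    j <- which.min(abs(tf$r_time - ana$fid$r_time[i]))
    h_det <- ana$fid$S_amp[i] - ana$fid$O_amp[i]
    h_true <- tf$S_amp[j] - tf$O_amp[j]
    abs(h_det - h_true) / h_true
  }, numeric(1))
  expect_lt(max(s_err), 0.02)
})

test_that("ordering invariants hold on every emitted beat", {
  for (hr in c(50, 120)) {
    rec <- fixture_recording(hr = hr, dur = 60, noise = 0, seed = 21)
    ppg_f <- wavelet_band_limit(rec$ppg, rec$fs, 0.122, 15.625)
    ecg_f <- wavelet_band_limit(rec$ecg, rec$fs, 0.122, 31.25)
    fid <- detect_fiducials(ppg_f, rec$fs, detect_r_peaks(ecg_f, rec$fs))
    expect_true(all(fid$O_idx < fid$w_idx & fid$w_idx < fid$S_idx))
    expect_true(all(fid$a_idx < fid$b_idx & fid$b_idx < fid$e_idx))
    expect_true(all(fid$S_idx < fid$N_idx & fid$N_idx <= fid$D_idx))
    expect_true(all(fid$e_idx > fid$b_idx))
  }
})

test_that("detection is translation-invariant", {
  ana <- fixture_analyzed()
  k <- 1000L
  shift <- function(x) c(rep(x[1], k), x[seq_len(length(x) - k)])
  vpg <- differentiate(ana$ppg_f, 1000, 1, stride = 8)
  apg <- differentiate(ana$ppg_f, 1000, 2, stride = 8)
  vpg <- wavelet_band_limit(vpg, 1000, 0.122, 15.625)
  apg <- wavelet_band_limit(apg, 1000, 0.122, 15.625)
  f0 <- detect_fiducials(ana$ppg_f, 1000, ana$r_times, vpg = vpg, apg = apg)
  f1 <- detect_fiducials(shift(ana$ppg_f), 1000, ana$r_times + k / 1000,
                         vpg = shift(vpg), apg = shift(apg))
  m <- min(nrow(f0), nrow(f1)) - 1L   # trailing beat may differ
  for (p in c("O", "S", "M", "N", "D", "w", "z", "a", "b", "e")) {
    expect_equal(f1[[paste0(p, "_idx")]][seq_len(m)],
                 f0[[paste0(p, "_idx")]][seq_len(m)] + k, tolerance = 1e-9)
  }
})

test_that("notch and diastolic peak follow the two-branch slope rule", {
  fs <- 1000
  t <- seq(0, 1.299, 1 / fs)
  # branch 1: pronounced dicrotic wave -> positive slope at z, crossings
  vpg <- -sin(2 * pi * 2 * t)              # sign changes every 0.25 s
  z <- 800L                                # vpg > 0 there
  nd <- detect_notch_and_diastolic_peak(NULL, vpg, z, e_index = 780L, fs)
  expect_true(nd$ok)
  expect_true(nd$N < z && nd$D > z)
  expect_true(vpg[nd$N] > 0 && vpg[nd$N - 1L] <= 0)   # upward crossing
  expect_true(vpg[nd$D] <= 0 && vpg[nd$D - 1L] > 0)   # downward crossing
  expect_lt(abs(t[nd$N] - 0.75), 0.005)
  expect_lt(abs(t[nd$D] - 1.00), 0.005)
  # branch 2: weak dicrotic wave -> D at z, N midway between e and z
  vpg2 <- rep(-1, 1000)
  nd2 <- detect_notch_and_diastolic_peak(NULL, vpg2, 600L, e_index = 500L, fs)
  expect_true(nd2$ok)
  expect_equal(nd2$D, 600L)
  expect_equal(nd2$N, 550L)
  expect_lte(nd2$N, nd2$D)
})

test_that("degenerate beats are skipped, not emitted", {
  fs <- 1000
  ramp <- seq(0, 10, length.out = 5000)   # monotone: no interior maximum
  sys <- detect_systolic_group(ramp, rep(1, 5000), rep(0.1, 5000), 0.5, fs)
  expect_false(sys$ok)
  # window truncated by signal end
  sys2 <- detect_systolic_group(sin(1:100), sin(1:100), sin(1:100), 0.02, fs)
  expect_false(sys2$ok)
  dia <- detect_diastolic_group(rep(1, 300), rep(1, 300), 250L, fs)
  expect_false(dia$ok)
})

test_that("onset detection finds the foot of a clean linear edge", {
  fs <- 1000
  # flat baseline then a linear rise to a rounded peak
  y <- c(rep(0, 200), seq(0, 1, length.out = 100),
         1 - 0.5 * (seq(0, 1, length.out = 100))^2)
  on <- detect_onset(y, seg_lo = 1L, s_index = 300L, w_index = 250L, fs)
  expect_true(on$ok)
  expect_lt(abs(on$O - 200), 3)           # foot of the edge
  target <- on$O_amp + (y[300] - on$O_amp) / 2
  expect_lt(abs(y[on$M] - target), 0.02)  # half-height midpoint
})
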