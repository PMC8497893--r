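test_that("band powers localise tones to the correct band", {
  t4 <- seq(0, 400, 0.25)
  rs_hf <- make_rate_series(1 + 0.03 * sin(2 * pi * 0.25 * t4))
  bp <- band_powers(morlet_power(rs_hf, freq_range = c(0.03, 0.4)))
  expect_gt(bp$HF / bp$TP, 0.95)

  rs_mix <- make_rate_series(1 + 0.03 * sin(2 * pi * 0.1 * t4) +
                               0.03 * sin(2 * pi * 0.25 * t4))
  bp2 <- band_powers(morlet_power(rs_mix, freq_range = c(0.03, 0.4)))
  expect_lt(abs(bp2$nLF - 0.5), 0.05)
  expect_equal(bp2$TP, bp2$LF + bp2$HF)
  expect_equal(bp2$nLF + bp2$HF / (bp2$LF + bp2$HF), 1)

  # zero variability: every band power zero, ratios undefined
  bp0 <- band_powers(morlet_power(make_rate_series(rep(2, 1601)),
                                  freq_range = c(0.03, 0.4)))
  expect_equal(bp0$TP, 0)
  expect_true(is.na(bp0$LF_HF))
})

test_that("respiration-referenced decomposition routes power by coupling", {
  t4 <- seq(0, 400, 0.25)
  resp <- sin(2 * pi * 0.25 * t4)
  hr_coupled <- make_rate_series(1 + 0.05 * sin(2 * pi * 0.25 * t4))
  ih <- improved_hrv(hr_coupled, resp, 4)
  expect_gt(ih$HFr / (ih$HFr + ih$LFru), 0.9)
  expect_lt(max(abs(ih$HR - ih$HRr - ih$HRru)), 1e-12)

  hr_free <- make_rate_series(1 + 0.05 * sin(2 * pi * 0.08 * t4))
  ih2 <- improved_hrv(hr_free, resp, 4)
  expect_gt(ih2$LFru / (ih2$HFr + ih2$LFru), 0.9)

  expect_error(improved_hrv(hr_free, rep(1, length(t4)), 4), "flat")
})

test_that("slow breathing moves respiratory power from LF into HFr", {
  # at a 0.1 Hz breathing rate the respiratory peak sits inside the
  # traditional LF band, inflating nLF; the ridge-referenced split
  # assigns the same power to the respiratory component instead
  t4 <- seq(0, 400, 0.25)
  hr <- make_rate_series(1 + 0.05 * sin(2 * pi * 0.1 * t4))
  resp <- sin(2 * pi * 0.1 * t4)
  trad <- band_powers(morlet_power(hr, freq_range = c(0.03, 0.4)))
  imp <- suppressWarnings(improved_hrv(hr, resp, 4))
  expect_gt(trad$nLF, 0.9)                        # misattributed to LF
  expect_gt(imp$HFr / (imp$HFr + imp$LFru), 0.9)  # reassigned to HFr
})

test_that("sample entropy equals the brute-force pair counter exactly", {
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(40:90, 1)
    x <- switch(1 + rep %% 3,
                rnorm(n),
                sin(seq_len(n) / sample(2:6, 1)) + rnorm(n, 0, 0.2),
                cumsum(rnorm(n)))
    expect_identical(sample_entropy(x), sampen_brute(x))
  }
})

test_that("sample entropy behaves across signal classes", {
  expect_equal(sample_entropy(rep(2, 100)), 0)
  # length-2 templates match across the zero runs, but no length-3
  # template ever repeats, so the conditional probability is undefined
  spiky <- c(0, 0, 1e6, 0, 0, 2e6, 0, 0, 3e6, 0, 0, 4e6)
  expect_warning(expect_true(is.na(sample_entropy(spiky))), "undefined")
  wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(1000)
    periodic <- sin(seq_len(1000) / 5)
    if (sample_entropy(noise) > sample_entropy(periodic)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("PRV and HRV spectra agree on a shared beat-time ground truth", {
  ana <- fixture_analyzed(hr = 60, dur = 300, noise = 0, seed = 3)
  hrv <- band_powers(morlet_power(build_rate_series(ana$r_times),
                                  freq_range = c(0.03, 0.4)))
  prv <- band_powers(morlet_power(build_rate_series(ana$fid$w_t,
                                                    source = "ww"),
                                  freq_range = c(0.03, 0.4)))
  expect_lt(abs(prv$LF - hrv$LF) / hrv$LF, 0.05)
  expect_lt(abs(prv$HF - hrv$HF) / hrv$HF, 0.05)
  expect_lt(abs(prv$TP - hrv$TP) / hrv$TP, 0.05)
})
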