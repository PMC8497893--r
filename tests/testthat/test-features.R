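test_that("aggregates match their definitional formulas", {
  expect_equal(aggregate_stats(c(1, 2, 3)),
               c(mean = 2, std = 1, rmssd = 1))
  expect_equal(aggregate_stats(rep(5, 10))[c("std", "rmssd")],
               c(std = 0, rmssd = 0))
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    expect_equal(unname(aggregate_stats(x)["rmssd"]), rmssd_brute(x))
    expect_equal(unname(aggregate_stats(x)["std"]), sd(x))
  }
  expect_true(all(is.na(aggregate_stats(c(1, 2)))))
})

test_that("beat morphometrics satisfy their partition identities", {
  ana <- fixture_analyzed()
  mo <- beat_morphometrics(ana$fid, ana$ppg_f, 1000)
  fs <- 1000
  expect_true(all(abs(mo$T2 + mo$T3 - mo$T) <= 1 / fs + 1e-12))
  expect_equal(mo$A, mo$A1 + mo$A2)
  expect_equal(mo$T1_T, mo$T1 / mo$T)
  expect_equal(mo$PPT_T, mo$PPT / mo$T)
  expect_true(all(mo$T1 > 0 & mo$T1 < mo$T))
  expect_true(all(is.finite(as.matrix(mo))))
  # T matches the true inter-onset interval up to the onset-detection
  # jitter of the intersecting-tangent method
  tf <- ana$rec$truth$fiducials
  true_T <- diff(tf$onset_time)
  matched <- vapply(mo$beat, function(b) true_T[b], numeric(1))
  expect_lt(stats::median(abs(mo$T - matched)), 0.003)
  expect_lt(max(abs(mo$T - matched)), 0.010)
})

test_that("slope features agree with height/time quotients", {
  ana <- fixture_analyzed()
  mo <- beat_morphometrics(ana$fid, ana$ppg_f, 1000)
  expect_equal(mo$RS, mo$H1 / mo$T1)
  expect_equal(mo$FS, mo$H1 / (mo$T - mo$T1))
  expect_equal(mo$RI, mo$H3 / mo$H1)
})

test_that("tidal-wave descriptors obey the power identity and scaling", {
  ana <- fixture_analyzed()
  tw <- tidal_wave_features(ana$rec$ppg, ana$fid, 1000)
  expect_equal(tw$TWsi * tw$TWv * tw$TWt, tw$TWp, tolerance = 1e-12)
  expect_true(all(tw$TWp >= 0))
  expect_true(all(tw$TWt > 0))
  tw2 <- tidal_wave_features(2 * ana$rec$ppg, ana$fid, 1000)
  expect_equal(tw2$TWp, 4 * tw$TWp, tolerance = 1e-9)
  expect_equal(tw2$TWv, 2 * tw$TWv, tolerance = 1e-9)
  # a signal with no content at 15-35 Hz carries no tidal-wave power
  t <- seq(0, 60, 1e-3)
  smooth <- sin(2 * pi * 1 * t)
  tw0 <- tidal_wave_features(smooth, ana$fid[1:20, ], 1000)
  expect_lt(max(tw0$TWp), 1e-6 * max(tw$TWp))
})

test_that("cardiorespiratory power separates the two bands", {
  fs <- 1000
  t <- seq(0, 300, 1 / fs)
  beats <- abs(sin(pi * 1.2 * t))^3       # pulse train at 1.2 Hz
  tp <- cardiorespiratory_power(beats, fs)
  expect_gt(tp[["TPcar"]] / tp[["TPres"]], 10)
  # respiration-rate amplitude modulation raises the respiratory band
  mod <- beats * (1 + 0.3 * sin(2 * pi * 0.25 * t))
  tp2 <- cardiorespiratory_power(mod, fs)
  expect_gt(tp2[["TPres"]], tp[["TPres"]])
  expect_equal(unname(cardiorespiratory_power(rep(0, 300001), fs)), c(0, 0))
})

test_that("the feature vector has the canonical 110-entry schema", {
  rec <- fixture_recording(dur = 150, noise = 0, seed = 6)
  fv <- extract_features(rec)
  nm <- ppg_feature_names()
  expect_length(fv, 110)
  expect_identical(names(fv), nm)
  expect_true(all(is.finite(unclass(fv))))
  # partition: 80 pulse-wave, 24 derivative, 6 pulse-rate features
  expect_identical(length(nm), 110L)
  der_idx <- 81:104
  prv_idx <- 105:110
  expect_true(all(grepl("H[wzabe]|Hb_Ha|He_Ha|HbHe_Ha", nm[der_idx])))
  expect_true(all(grepl("^PRV_", nm[prv_idx])))
  expect_false(any(grepl("^PRV_|H[wzabe]$|_H[wzabe]|Ha$", nm[1:80])))
})

test_that("feature extraction is deterministic and gain-covariant", {
  rec <- fixture_recording(dur = 150, noise = 0, seed = 6)
  fv1 <- extract_features(rec)
  fv2 <- extract_features(rec)
  expect_identical(unclass(fv1)[1:110], unclass(fv2)[1:110])

  rec2 <- rec
  rec2$ppg <- 2 * rec$ppg
  fv3 <- extract_features(rec2)
  # amplitude features double, time features and ratios are unchanged
  expect_equal(fv3[["mean_H1"]], 2 * fv1[["mean_H1"]], tolerance = 1e-6)
  expect_equal(fv3[["mean_Ha"]], 2 * fv1[["mean_Ha"]], tolerance = 1e-6)
  expect_equal(fv3[["mean_T"]], fv1[["mean_T"]], tolerance = 1e-9)
  expect_equal(fv3[["mean_RI"]], fv1[["mean_RI"]], tolerance = 1e-6)
  expect_equal(fv3[["mean_Hb_Ha"]], fv1[["mean_Hb_Ha"]], tolerance = 1e-6)
  expect_equal(fv3[["PRV_LF"]], fv1[["PRV_LF"]], tolerance = 1e-6)
})

test_that("feature tables round-trip through CSV", {
  rec <- fixture_recording(dur = 150, noise = 0, seed = 6)
  fv <- extract_features(rec)
  tab <- cbind(data.frame(subject_id = 1L, state = "BSL"),
               as.data.frame(as.list(unclass(fv)[1:110])))
  path <- file.path(withr::local_tempdir(), "features.csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(names(back), names(tab))
  expect_equal(as.numeric(back[1, ppg_feature_names()]),
               as.numeric(tab[1, ppg_feature_names()]), tolerance = 1e-12)
})
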