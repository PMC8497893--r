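# Memoised simulated fixtures, shared across test files (generation is
# deterministic, so caching only saves time).

.fixtures <- new.env(parent = emptyenv())

fixture_recording <- function(hr = 60, dur = 60, noise = 0, seed = 42,
                              state = "BSL", ...) {
  extra <- list(...)
  key <- paste("rec", hr, dur, noise, seed, state,
               paste(names(extra),
                     vapply(extra, function(e) paste(unlist(e),
                                                     collapse = "."), ""),
                     collapse = "_"), sep = "_")
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(duration_s = dur, hr_mean = hr, noise_sd = noise, ...)
    if (state != "BSL") cfg <- apply_state_preset(cfg, state)
    .fixtures[[key]] <- generate_recording(cfg, seed)
  }
  .fixtures[[key]]
}

# band-limited PPG + detected R peaks + fiducials for a fixture recording
fixture_analyzed <- function(hr = 60, dur = 60, noise = 0, seed = 42) {
  key <- paste("ana", hr, dur, noise, seed, sep = "_")
  if (is.null(.fixtures[[key]])) {
    rec <- fixture_recording(hr, dur, noise, seed)
    ppg_f <- wavelet_band_limit(rec$ppg, rec$fs, 0.122, 15.625)
    ecg_f <- wavelet_band_limit(rec$ecg, rec$fs, 0.122, 31.25)
    r_times <- detect_r_peaks(ecg_f, rec$fs)
    fid <- detect_fiducials(ppg_f, rec$fs, r_times)
    .fixtures[[key]] <- list(rec = rec, ppg_f = ppg_f, r_times = r_times,
                             fid = fid)
  }
  .fixtures[[key]]
}

# fraction of true beats whose ten landmarks are all recovered within tol_s
fiducial_recovery_rate <- function(rec, fid, tol_s = 0.015) {
  tf <- rec$truth$fiducials
  pts <- c("O", "S", "M", "N", "D", "w", "z", "a", "b", "e")
  ok <- vapply(seq_len(nrow(fid)), function(i) {
    j <- which.min(abs(tf$r_time - fid$r_time[i]))
    all(vapply(pts, function(p)
      abs(fid[[paste0(p, "_t")]][i] - tf[[paste0(p, "_t")]][j]) <= tol_s,
      logical(1)))
  }, logical(1))
  sum(ok) / length(rec$truth$r_times)
}

.tf_ok <- function(tf) ppgans:::.tf_retained_times(tf)

# a mean-1 rate series object built directly (for spectral unit tests)
make_rate_series <- function(values, fs = 4) {
  structure(list(times = (seq_along(values) - 1) / fs,
                 values = values / mean(values), fs = fs,
                 mean_rate_bpm = 60 * mean(values), source = "RR",
                 n_outliers = 0L),
            class = "rate_series")
}

# planted-signal classification table: n rows, p features, the first two
# informative (shifted by class), optionally an exact duplicate of the
# first informative feature appended in third position
planted_table <- function(n = 112, p = 110, seed = 1, effect = 1.5,
                          duplicate = FALSE) {
  set.seed(seed)
  x <- as.data.frame(matrix(stats::rnorm(n * p), n))
  names(x) <- sprintf("V%03d", seq_len(p))
  y <- factor(rep(c("A", "B"), length.out = n))
  x$V001 <- x$V001 + ifelse(y == "A", effect, 0)
  x$V002 <- x$V002 + ifelse(y == "A", -effect * 0.8, 0)
  if (duplicate) x$V003 <- x$V001
  list(x = x, y = y)
}
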