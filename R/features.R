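# The 110-item PPG feature vector: 22 per-beat morphometrics (mean, Std,
# Rmssd -> features 1-66), tidal-wave descriptors (67-78), cardiac and
# respiratory wavelet power of the raw pulse wave (79-80), derivative
# amplitudes (81-104) and pulse-rate-variability indices (105-110).

#' Canonical feature names
#'
#' @return Character vector of length 110: names of the features in their
#'   canonical order (index 1-110).
#' @export
ppg_feature_names <- function() {
  base22 <- c("T", "T1", "T2", "T3", "PW", "PPT", "T1_T", "T2_T", "PW_T",
              "PPT_T", "A1", "A2", "A", "IPA", "A1_A", "H1", "H2", "H3",
              "H2_H1", "RI", "RS", "FS")
  tw4 <- c("TWa", "TWp", "TWvt", "TWsi")
  der8 <- c("Hw", "Hz", "Ha", "Hb", "He", "Hb_Ha", "He_Ha", "HbHe_Ha")
  c(paste0("mean_", base22),          # 1-22
    paste0("std_", base22),           # 23-44
    paste0("rmssd_", base22),         # 45-66
    paste0("mean_", tw4),             # 67-70
    paste0("std_", tw4),              # 71-74
    paste0("rmssd_", tw4),            # 75-78
    "TPcar", "TPres",                 # 79-80
    paste0("mean_", der8),            # 81-88
    paste0("std_", der8),             # 89-96
    paste0("rmssd_", der8),           # 97-104
    "PRV_LF", "PRV_HF", "PRV_TP", "PRV_nLF", "PRV_LF_HF", "PRV_SampEn")
}

#' Aggregate a per-beat series
#'
#' @param x Numeric per-beat values (>= 3 finite values required).
#' @return Named numeric: `mean`, `std` (n-1 denominator) and `rmssd`
#'   (root mean square of successive differences).
#' @export
aggregate_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3) {
    return(c(mean = NA_real_, std = NA_real_, rmssd = NA_real_))
  }
  c(mean = mean(x), std = stats::sd(x),
    rmssd = sqrt(mean(diff(x)^2)))
}

# Time a signal spends at or above a level, counting whole sample steps
# where both endpoints are above and linearly interpolated fractions at
# the crossings.
.time_above <- function(y, level, fs) {
  above <- y >= level
  if (!any(above)) return(0)
  whole <- sum(above[-length(above)] & above[-1]) / fs
  extra <- 0
  for (i in which(diff(above) != 0)) {
    frac <- (level - y[i]) / (y[i + 1] - y[i])  # crossing position in (0,1)
    extra <- extra + (if (above[i + 1]) 1 - frac else frac) / fs
  }
  whole + extra
}

#' Per-beat pulse morphometrics
#'
#' Computes the 22 interval, area, height and slope descriptors for every
#' beat with a complete fiducial set and a successor onset: T (onset to
#' next onset), T1 (onset to systolic peak), T2 (onset to notch), T3
#' (notch to next onset), PW (time the pulse spends at or above the
#' rising-edge midpoint amplitude), PPT (systolic to diastolic peak);
#' areas A1 (onset to notch), A2 (notch to next onset) and A = A1 + A2 by
#' trapezoidal integration of the onset-referenced pulse; heights H1, H2,
#' H3 of S, N, D above the onset amplitude; slopes RS = H1/T1 and
#' FS = H1/(T - T1); and the derived ratios.
#'
#' @param fiducials A `beat_fiducials` data frame.
#' @param ppg The PPG waveform the fiducials refer to.
#' @param fs Sampling rate in Hz.
#' @return Data frame, one row per beat (last beat is excluded for lack of
#'   a successor onset), 22 feature columns plus `beat`.
#' @export
beat_morphometrics <- function(fiducials, ppg, fs) {
  fid <- as.data.frame(fiducials)
  if (nrow(fid) < 2) stop("need at least two consecutive beats")
  cols <- c("T", "T1", "T2", "T3", "PW", "PPT", "T1_T", "T2_T", "PW_T",
            "PPT_T", "A1", "A2", "A", "IPA", "A1_A", "H1", "H2", "H3",
            "H2_H1", "RI", "RS", "FS")
  nb <- nrow(fid) - 1L
  m <- matrix(NA_real_, nb, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(nb)) {
    if (fid$beat[i + 1L] != fid$beat[i] + 1L) next  # successor was dropped
    o_i <- fid$O_idx[i]; o_next <- fid$O_idx[i + 1L]
    T_ <- (o_next - o_i) / fs
    T1 <- (fid$S_idx[i] - o_i) / fs
    T2 <- (fid$N_idx[i] - o_i) / fs
    T3 <- (o_next - fid$N_idx[i]) / fs
    PPT <- (fid$D_idx[i] - fid$S_idx[i]) / fs
    i0 <- max(1L, round(o_i)); i1 <- min(length(ppg), round(o_next))
    seg <- ppg[i0:i1] - fid$O_amp[i]
    PW <- .time_above(seg, fid$M_amp[i] - fid$O_amp[i], fs)
    iN <- round(fid$N_idx[i]) - i0 + 1L
    A1 <- sum((seg[1:(iN - 1)] + seg[2:iN]) / 2) / fs
    nn <- length(seg)
    A2 <- sum((seg[iN:(nn - 1)] + seg[(iN + 1):nn]) / 2) / fs
    H1 <- fid$S_amp[i] - fid$O_amp[i]
    H2 <- fid$N_amp[i] - fid$O_amp[i]
    H3 <- fid$D_amp[i] - fid$O_amp[i]
    m[i, ] <- c(T_, T1, T2, T3, PW, PPT, T1 / T_, T2 / T_, PW / T_,
                PPT / T_, A1, A2, A1 + A2, A2 / A1, A1 / (A1 + A2),
                H1, H2, H3, H2 / H1, H3 / H1, H1 / T1, H1 / (T_ - T1))
  }
  ok <- is.finite(m[, "T"])
  if (!any(ok)) stop("no beat pairs with consecutive fiducials")
  cbind(data.frame(beat = fid$beat[seq_len(nb)][ok]),
        as.data.frame(m[ok, , drop = FALSE]))
}

#' Tidal-wave descriptors per beat
#'
#' The tidal wave is the secondary systolic shoulder between the systolic
#' peak S and the dicrotic notch N, characterised through the 15-35 Hz
#' Morlet band of the baseline-corrected (but not low-pass-limited) pulse
#' wave: TWp sums the time-frequency power over t in \[S, N\] and f in
#' \[15, 35\] Hz; TWv is the range of the band-reconstructed signal over
#' the same span; TWt = N - S; TWa the area between the pulse and the
#' S-to-N chord; TWvt = TWv * TWt and the stress index
#' TWsi = TWp / (TWv * TWt).
#'
#' @param ppg Raw (unfiltered) PPG waveform.
#' @param fiducials A `beat_fiducials` data frame.
#' @param fs Sampling rate in Hz.
#' @param tw_band Analysis band in Hz (default c(15, 35)).
#' @param n_voices Voices across the band (default 12).
#' @return Data frame with columns `beat`, `TWa`, `TWp`, `TWv`, `TWt`,
#'   `TWvt`, `TWsi`.
#' @export
tidal_wave_features <- function(ppg, fiducials, fs, tw_band = c(15, 35),
                                n_voices = 12) {
  fid <- as.data.frame(fiducials)
  if (nrow(fid) == 0) stop("no fiducials")
  # mean removal suffices as baseline correction here: content below the
  # pulse band cannot reach a 15-35 Hz analysis band
  x <- ppg - mean(ppg)
  # decimate: the analysis band tops out far below the raw Nyquist
  k_dec <- max(1L, floor(fs / (4 * tw_band[2])))
  while (fs / k_dec != round(fs / k_dec) && k_dec > 1L) k_dec <- k_dec - 1L
  fs_an <- fs / k_dec
  x_an <- if (k_dec > 1L) .decimate(x, fs, fs_an) else x
  freqs <- exp(seq(log(tw_band[1]), log(tw_band[2]), length.out = n_voices))
  W <- morlet_cwt(x_an, fs_an, freqs)
  pw <- Mod(W)^2
  recon <- 2 * colSums(Re(W)) / n_voices
  nb <- nrow(fid)
  m <- matrix(NA_real_, nb, 6,
              dimnames = list(NULL, c("TWa", "TWp", "TWv", "TWt", "TWvt",
                                      "TWsi")))
  for (i in seq_len(nb)) {
    s_i <- fid$S_idx[i]; n_i <- fid$N_idx[i]
    if (n_i <= s_i + 1L) next
    rng_d <- max(1L, ceiling(s_i / k_dec)):min(ncol(pw), floor(n_i / k_dec))
    if (length(rng_d) < 2L) next
    TWp <- sum(pw[, rng_d]) / fs_an
    TWt <- (n_i - s_i) / fs
    TWv <- diff(range(recon[rng_d]))
    rng <- s_i:n_i
    dev <- ppg[rng] - seq(ppg[s_i], ppg[n_i], length.out = length(rng))
    TWa <- sum((dev[-1] + dev[-length(dev)]) / 2) / fs
    m[i, ] <- c(TWa, TWp, TWv, TWt, TWv * TWt,
                if (TWv * TWt > 0) TWp / (TWv * TWt) else NA_real_)
  }
  ok <- is.finite(m[, "TWt"])
  if (!any(ok)) stop("no beats with usable S-N spans")
  cbind(data.frame(beat = fid$beat[ok]), as.data.frame(m[ok, , drop = FALSE]))
}

#' Cardiac and respiratory wavelet power of the pulse wave
#'
#' Total Morlet time-frequency power of the baseline-corrected PPG over
#' the cardiac band (0.75-2.5 Hz, i.e. 45-150 beats/min) and the
#' respiratory band (0.1-0.6 Hz, 6-36 breaths/min). The signal is
#' decimated internally (the bands lie far below the raw sampling rate).
#'
#' @param ppg Raw PPG waveform.
#' @param fs Sampling rate in Hz.
#' @param car_band,res_band Band edges in Hz.
#' @param n_voices Voices across the combined range.
#' @return Named numeric: `TPcar`, `TPres`.
#' @export
cardiorespiratory_power <- function(ppg, fs, car_band = c(0.75, 2.5),
                                    res_band = c(0.1, 0.6), n_voices = 32) {
  if (length(ppg) / fs < 4 / res_band[1]) {
    warning("recording shorter than four periods of ", res_band[1],
            " Hz; powers computed over the available span")
  }
  if (stats::sd(ppg) == 0) return(c(TPcar = 0, TPres = 0))
  fs_dec <- 8
  dec <- .decimate(ppg - mean(ppg), fs, fs_dec)
  tf <- morlet_power(dec, fs = fs_dec,
                     freq_range = c(res_band[1], car_band[2]),
                     n_voices = n_voices)
  ok <- try(.tf_retained_times(tf), silent = TRUE)
  if (inherits(ok, "try-error")) ok <- rep(TRUE, length(tf$times))
  c(TPcar = .tf_band_sum(tf, car_band[1], car_band[2], closed_right = TRUE,
                         times_ok = ok),
    TPres = .tf_band_sum(tf, res_band[1], res_band[2], closed_right = TRUE,
                         times_ok = ok))
}

# FFT low-pass to the new Nyquist, then subsample. The signal is extended
# by reflection to a highly composite length so the FFT stays O(n log n)
# whatever the input length.
.decimate <- function(x, fs, fs_new) {
  stopifnot(fs_new < fs)
  k <- fs / fs_new
  if (abs(k - round(k)) > 1e-9) stop("fs must be a multiple of fs_new")
  k <- round(k)
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  ext <- if (m > n) c(x, x[n:(2L * n - m + 1L)]) else x
  xf <- stats::fft(ext)
  cutoff <- floor(m / k / 2)
  mask <- rep(0, m)
  mask[c(seq_len(cutoff + 1L), seq(m - cutoff + 1L, m))] <- 1
  xl <- Re(stats::fft(xf * mask, inverse = TRUE))[seq_len(n)] / m
  xl[seq(1, n, by = k)]
}

#' Extract the full 110-item feature vector from a recording
#'
#' Runs the complete single-recording pipeline: band limitation of ECG and
#' PPG, R-peak detection, fiducial detection, per-beat morphometrics and
#' tidal-wave descriptors, cardiorespiratory power, and pulse rate
#' variability from the w-w intervals (band powers of the w-rate series
#' plus its sample entropy). Aggregates use only beats with complete
#' fiducial sets.
#'
#' @param recording A `ppg_recording` (or any list with `ecg`, `ppg`,
#'   `resp`, `fs`).
#' @param ppg_band PPG analysis band in Hz.
#' @param ecg_band ECG analysis band in Hz.
#' @param keep_intermediates Return the intermediate products as
#'   attributes (`fiducials`, `r_times`, `prv`, `hrv`)?
#' @return Object of class `feature_vector`: named numeric of length 110
#'   in canonical order, with attributes `n_beats` (beats contributing),
#'   `state` (if ground truth carries one) and, optionally, the
#'   intermediates.
#' @export
extract_features <- function(recording, ppg_band = c(0.122, 15.625),
                             ecg_band = c(0.122, 31.25),
                             keep_intermediates = FALSE) {
  fs <- recording$fs
  ecg_f <- wavelet_band_limit(recording$ecg, fs, ecg_band[1], ecg_band[2])
  r_times <- detect_r_peaks(ecg_f, fs)
  ppg_f <- wavelet_band_limit(recording$ppg, fs, ppg_band[1], ppg_band[2])
  fid <- detect_fiducials(ppg_f, fs, r_times)
  if (nrow(fid) < 12) stop("too few beats with complete fiducials")

  morpho <- beat_morphometrics(fid, ppg_f, fs)
  tw <- tidal_wave_features(recording$ppg, fid, fs)
  tp <- cardiorespiratory_power(recording$ppg, fs)

  der <- data.frame(Hw = fid$w_amp, Hz = fid$z_amp, Ha = fid$a_amp,
                    Hb = fid$b_amp, He = fid$e_amp)
  der$Hb_Ha <- der$Hb / der$Ha
  der$He_Ha <- der$He / der$Ha
  der$HbHe_Ha <- (der$Hb - der$He) / der$Ha

  # pulse rate from w-w intervals
  prv_rs <- build_rate_series(fid$w_t, source = "ww")
  prv_tf <- morlet_power(prv_rs, freq_range = c(0.03, 0.4))
  prv <- band_powers(prv_tf)
  samp <- sample_entropy(prv_rs$values)

  base22 <- c("T", "T1", "T2", "T3", "PW", "PPT", "T1_T", "T2_T", "PW_T",
              "PPT_T", "A1", "A2", "A", "IPA", "A1_A", "H1", "H2", "H3",
              "H2_H1", "RI", "RS", "FS")
  agg_m <- vapply(base22, function(cn) aggregate_stats(morpho[[cn]]),
                  numeric(3))
  tw4 <- c("TWa", "TWp", "TWvt", "TWsi")
  agg_t <- vapply(tw4, function(cn) aggregate_stats(tw[[cn]]), numeric(3))
  der8 <- c("Hw", "Hz", "Ha", "Hb", "He", "Hb_Ha", "He_Ha", "HbHe_Ha")
  agg_d <- vapply(der8, function(cn) aggregate_stats(der[[cn]]), numeric(3))

  vec <- c(agg_m["mean", ], agg_m["std", ], agg_m["rmssd", ],
           agg_t["mean", ], agg_t["std", ], agg_t["rmssd", ],
           tp[["TPcar"]], tp[["TPres"]],
           agg_d["mean", ], agg_d["std", ], agg_d["rmssd", ],
           prv$LF, prv$HF, prv$TP, prv$nLF, prv$LF_HF, samp)
  names(vec) <- ppg_feature_names()
  attr(vec, "n_beats") <- nrow(fid)
  attr(vec, "state") <- if (!is.null(recording$truth)) recording$truth$state
  if (keep_intermediates) {
    attr(vec, "fiducials") <- fid
    attr(vec, "r_times") <- r_times
    attr(vec, "prv") <- prv
  }
  class(vec) <- "feature_vector"
  vec
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> 110 features from", attr(x, "n_beats"), "beats")
  if (!is.null(attr(x, "state"))) cat(" (state ", attr(x, "state"), ")", sep = "")
  cat("\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(utils::head(round(v, 4), 10))
  cat("...\n")
  invisible(x)
}
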