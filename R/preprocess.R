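# ECG/PPG conditioning: R-peak detection on a wavelet detail, finite
# differences for the PPG velocity/acceleration, and construction of the
# normalised 4 Hz rate series used for all spectral analysis.

#' Detect R peaks on a (band-limited) ECG
#'
#' Works on the modulus of a mid-scale dyadic wavelet detail of the ECG
#' (default pass band fs/2^7 to fs/2^4, i.e. 7.8-62.5 Hz at 1000 Hz, where
#' QRS energy concentrates). Local modulus maxima above an adaptive
#' threshold (a fraction of the rolling peak amplitude over `seg_s`-second
#' segments) are kept, and candidates are gated physiologically: peaks
#' closer than `refractory_s` keep only the larger, and inter-beat
#' intervals outside \[0.33, 2\] s drop the offending peak. Replaces
#' manual artifact editing with an automatic policy.
#'
#' @param ecg Numeric ECG waveform (band limitation is applied internally).
#' @param fs Sampling rate in Hz.
#' @param threshold_frac Fraction of the segment peak amplitude a modulus
#'   maximum must exceed (default 0.3).
#' @param seg_s Segment length in seconds for the adaptive threshold.
#' @param refractory_s Minimum peak separation in seconds.
#' @param wavelet Wavelet family for the detail extraction.
#' @return Strictly increasing numeric vector of beat times in seconds.
#' @export
detect_r_peaks <- function(ecg, fs, threshold_frac = 0.3, seg_s = 10,
                           refractory_s = 0.33, wavelet = "db4") {
  stopifnot(is.numeric(ecg), fs > 0)
  if (length(ecg) < fs) stop("ECG shorter than one second")
  if (stats::sd(ecg) == 0) stop("flat ECG: no peaks found")
  detail <- wavelet_band_limit(ecg, fs, fs / 2^7, fs / 2^4, wavelet = wavelet)
  y <- abs(detail)
  n <- length(y)

  # adaptive threshold: fraction of each segment's peak, interpolated
  seg_n <- max(1L, round(seg_s * fs))
  starts <- seq(1L, n, by = seg_n)
  seg_peak <- vapply(starts, function(s) max(y[s:min(n, s + seg_n - 1L)]),
                     numeric(1))
  centers <- pmin(starts + seg_n / 2, n)
  thr <- if (length(starts) == 1L) rep(threshold_frac * seg_peak, n) else
    threshold_frac * stats::approx(centers, seg_peak, xout = seq_len(n),
                                   rule = 2)$y

  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE) & y > thr
  cand <- which(is_max)
  if (length(cand) == 0) stop("no peaks found above threshold")

  # refractory merge: keep the larger of peaks closer than refractory_s
  keep <- logical(length(cand))
  last <- 1L
  keep[1] <- TRUE
  for (i in seq_along(cand)[-1]) {
    if ((cand[i] - cand[last]) / fs < refractory_s) {
      if (y[cand[i]] > y[cand[last]]) {
        keep[last] <- FALSE
        keep[i] <- TRUE
        last <- i
      }
    } else {
      keep[i] <- TRUE
      last <- i
    }
  }
  peaks <- cand[keep]

  # physiological gating on inter-beat intervals
  repeat {
    ib <- diff(peaks) / fs
    bad <- which(ib < 0.33)
    if (length(bad) == 0) break
    b <- bad[1]
    drop <- if (y[peaks[b]] < y[peaks[b + 1]]) b else b + 1L
    peaks <- peaks[-drop]
    if (length(peaks) < 2) break
  }
  if (length(peaks) < 2) stop("no plausible beat sequence found")

  # refine each peak to the local modulus maximum of the ECG itself:
  # the detail-band envelope locates beats, the waveform extremum times
  # them (robust to the detail band's sample-scale ripple)
  refine <- round(0.025 * fs)
  e_abs <- abs(ecg - stats::median(ecg))
  peaks <- vapply(peaks, function(p) {
    win <- max(1L, p - refine):min(n, p + refine)
    win[which.max(e_abs[win])]
  }, integer(1))
  peaks <- sort(unique(peaks))
  (peaks - 1) / fs
}

#' Differentiate a waveform
#'
#' Central finite differences scaled by the sampling rate, with edge
#' replication so the output keeps the input length. `order = 1` gives the
#' velocity (VPG when applied to PPG), `order = 2` the acceleration (APG).
#'
#' At high sampling rates a one-sample step amplifies any residual
#' high-frequency ripple by `fs^2` in the second derivative, so the
#' landmark detectors use a wider step (`stride` samples, default 1):
#' differences are taken over `stride` samples and scaled accordingly,
#' which leaves the sub-15 Hz pulse derivatives essentially unchanged
#' while strongly attenuating ripple far above the pulse band.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param order 1 or 2.
#' @param stride Difference step in samples (default 1).
#' @return Numeric derivative waveform, same length as `x`.
#' @export
differentiate <- function(x, fs, order = 1, stride = 1L) {
  stride <- as.integer(stride)
  stopifnot(order %in% c(1, 2), stride >= 1L, length(x) >= 2L * stride + 1L)
  n <- length(x)
  k <- stride
  core <- (k + 1L):(n - k)
  d <- numeric(n)
  if (order == 1) {
    d[core] <- (x[core + k] - x[core - k]) * fs / (2 * k)
  } else {
    d[core] <- (x[core + k] - 2 * x[core] + x[core - k]) * (fs / k)^2
  }
  d[seq_len(k)] <- d[k + 1L]
  d[(n - k + 1L):n] <- d[n - k]
  d
}

#' Build a normalised uniform rate series from event times
#'
#' Converts inter-event intervals to instantaneous rate (60/interval,
#' assigned at the interval end time), interpolates with a cubic spline to
#' a uniform grid (default 4 Hz) and divides by the series mean so the
#' result is dimensionless with mean exactly 1 — removing the mathematical
#' impact of the mean rate on spectral power. Intervals deviating more than
#' `outlier_frac` from an 11-point running median are treated as artifacts
#' and replaced by linear interpolation over their neighbours.
#'
#' @param event_times Strictly increasing event times in seconds (>= 10).
#' @param grid_fs Grid rate in Hz (default 4).
#' @param outlier_frac Relative deviation from the running median beyond
#'   which an interval is interpolated over (default 0.3).
#' @param source Label for the event source (e.g. `"RR"` or `"ww"`).
#' @return Object of class `rate_series`: list with `times`, `values`
#'   (mean 1), `fs`, `mean_rate_bpm`, `source`, `n_outliers`.
#' @export
build_rate_series <- function(event_times, grid_fs = 4, outlier_frac = 0.3,
                              source = "RR") {
  stopifnot(is.numeric(event_times))
  if (length(event_times) < 10) stop("need at least 10 events")
  if (any(diff(event_times) <= 0)) stop("event times must be strictly increasing")
  iv <- diff(event_times)
  med <- stats::runmed(iv, k = min(11L, 2L * (length(iv) %/% 2L) - 1L))
  bad <- abs(iv - med) > outlier_frac * med
  if (any(bad)) {
    ok <- which(!bad)
    if (length(ok) < 2) stop("too many artifact intervals")
    iv[bad] <- stats::approx(ok, iv[ok], xout = which(bad), rule = 2)$y
  }
  rate <- 60 / iv
  at <- event_times[-1]
  grid <- seq(at[1], at[length(at)], by = 1 / grid_fs)
  vals <- stats::spline(at, rate, xout = grid)$y
  mean_rate <- mean(vals)
  structure(list(times = grid, values = vals / mean_rate, fs = grid_fs,
                 mean_rate_bpm = mean_rate, source = source,
                 n_outliers = sum(bad)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat("<rate_series> ", length(x$values), " points at ", x$fs, " Hz from ",
      x$source, " events, mean rate ", round(x$mean_rate_bpm, 1), " bpm",
      if (x$n_outliers > 0) paste0(", ", x$n_outliers, " artifact interval(s)"),
      "\n", sep = "")
  invisible(x)
}
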