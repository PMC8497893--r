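# Rate-variability spectra: traditional band powers from the Morlet
# time-frequency spectrum, the respiration-referenced decomposition of
# heart rate into respiratory (HRr) and non-respiratory (HRru) components,
# and sample entropy.

#' Band powers of a rate-variability spectrum
#'
#' Integrates the time-frequency power within the standard bands:
#' LF = 0.03-0.15 Hz, HF = 0.15-0.4 Hz, TP = LF + HF (total power over
#' 0.03-0.4 Hz), plus the normalised ratios nLF = LF/(LF+HF) and LF/HF.
#' Power is summed over the voices inside each band and averaged over the
#' times outside the cone of influence.
#'
#' @param tf A `tf_power` object from [morlet_power()] whose frequency grid
#'   covers 0.03-0.4 Hz.
#' @param lf_band,hf_band Band edges in Hz. LF is integrated over
#'   `[lf_band[1], lf_band[2])`, HF over `[hf_band[1], hf_band[2]]`.
#' @return Object of class `band_powers`: list `LF`, `HF`, `TP`, `nLF`,
#'   `LF_HF` (`NA` with HF = 0).
#' @export
band_powers <- function(tf, lf_band = c(0.03, 0.15), hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(tf, "tf_power"))
  if (min(tf$freqs) > lf_band[1] || max(tf$freqs) < hf_band[2]) {
    stop("frequency grid must cover [", lf_band[1], ", ", hf_band[2], "] Hz")
  }
  ok <- .tf_retained_times(tf)
  LF <- .tf_band_sum(tf, lf_band[1], lf_band[2], times_ok = ok)
  HF <- .tf_band_sum(tf, hf_band[1], hf_band[2], closed_right = TRUE,
                     times_ok = ok)
  structure(list(LF = LF, HF = HF, TP = LF + HF,
                 nLF = if (LF + HF > 0) LF / (LF + HF) else NA_real_,
                 LF_HF = if (HF > 0) LF / HF else NA_real_),
            class = "band_powers")
}

#' @export
print.band_powers <- function(x, ...) {
  cat(sprintf("<band_powers> LF=%.4g HF=%.4g TP=%.4g nLF=%.3f LF/HF=%.3f\n",
              x$LF, x$HF, x$TP, x$nLF, x$LF_HF))
  invisible(x)
}

#' Respiration-referenced decomposition of heart rate
#'
#' Splits the normalised heart-rate series into a respiratory-related
#' component (HRr) and a respiratory-unrelated component (HRru), taking
#' the respiration signal as reference: the instantaneous respiratory
#' frequency is the per-time ridge (argmax) of the Morlet power of
#' respiration over 0.1-0.6 Hz, HRr is reconstructed from the heart-rate
#' wavelet coefficients within ridge +/- `delta` Hz, and HRru = HR - HRr
#' (the decomposition is additive by construction). The respiratory band
#' power HFr sums the heart-rate power inside the time-varying ridge band;
#' LFru sums the power of HRru over the LF band (0.03-0.15 Hz). Under slow
#' breathing the respiratory peak moves below 0.15 Hz, where traditional
#' analysis misattributes it to LF; here it follows the ridge into HFr.
#'
#' @param hr A [rate_series] from the R-R intervals (mean-1 normalised).
#' @param resp Respiration waveform.
#' @param fs_resp Sampling rate of `resp` in Hz.
#' @param delta Half-width of the ridge reconstruction band in Hz
#'   (default 0.05).
#' @param resp_range Frequency range searched for the respiratory ridge.
#' @param n_voices Voices for the underlying spectra.
#' @return Object of class `improved_hrv`: list with `times`, `HR`, `HRr`,
#'   `HRru`, `f_ridge`, and the spectral summaries `HFr`, `LFru`, `nLFru`,
#'   `LFru_HFr`.
#' @export
improved_hrv <- function(hr, resp, fs_resp, delta = 0.05,
                         resp_range = c(0.1, 0.6), n_voices = 64) {
  stopifnot(inherits(hr, "rate_series"))
  if (stats::sd(resp) < 1e-12) stop("respiration signal is flat")
  # resample respiration onto the heart-rate grid
  t_resp <- (seq_along(resp) - 1) / fs_resp
  if (hr$times[1] < t_resp[1] || hr$times[length(hr$times)] > t_resp[length(t_resp)]) {
    stop("heart rate and respiration must cover the same time span")
  }
  resp_g <- stats::approx(t_resp, resp, xout = hr$times)$y

  tf_resp <- morlet_power(resp_g - mean(resp_g), fs = hr$fs,
                          freq_range = resp_range, n_voices = n_voices)
  ridge_i <- apply(tf_resp$power, 2, which.max)
  f_ridge <- tf_resp$freqs[ridge_i]
  at_edge <- ridge_i == 1L | ridge_i == length(tf_resp$freqs)
  ok_t <- .tf_retained_times(tf_resp)
  if (mean(at_edge[ok_t]) > 0.2) {
    warning("respiratory ridge at the search-range boundary for ",
            round(100 * mean(at_edge[ok_t])), "% of the record")
  }

  # heart-rate spectrum over a grid wide enough for both LF and the ridge
  x <- hr$values - mean(hr$values)
  grid_lo <- 0.03
  tf_hr <- morlet_power(x, fs = hr$fs, freq_range = c(grid_lo, resp_range[2]),
                        n_voices = n_voices)
  nt <- length(tf_hr$times)
  mask <- abs(outer(tf_hr$freqs, f_ridge, function(f, fr) f - fr)) <= delta

  # HRr: real part of the masked analytic coefficients, normalised by the
  # summed wavelet response at the ridge frequency so that an in-band
  # sinusoid is reconstructed at its own amplitude
  resp_gain <- exp(-pi^2 * 3 *
                     (outer(tf_hr$freqs, f_ridge, "/") - 1)^2)
  G <- colSums(resp_gain * mask)
  num <- colSums(Re(tf_hr$coefs) * mask)
  HRr <- ifelse(G > 1e-6, 2 * num / G, 0)
  HRru <- x - HRr

  ok <- .tf_retained_times(tf_hr)
  HFr <- mean(colSums((tf_hr$power * mask)[, ok, drop = FALSE]))
  tf_ru <- morlet_power(HRru, fs = hr$fs, freq_range = c(grid_lo, resp_range[2]),
                        n_voices = n_voices)
  LFru <- .tf_band_sum(tf_ru, 0.03, 0.15, times_ok = ok)

  structure(list(times = hr$times, HR = x, HRr = HRr, HRru = HRru,
                 f_ridge = f_ridge,
                 HFr = HFr, LFru = LFru,
                 nLFru = if (LFru + HFr > 0) LFru / (LFru + HFr) else NA_real_,
                 LFru_HFr = if (HFr > 0) LFru / HFr else NA_real_),
            class = "improved_hrv")
}

#' @export
print.improved_hrv <- function(x, ...) {
  cat(sprintf(
    "<improved_hrv> HFr=%.4g LFru=%.4g nLFru=%.3f LFru/HFr=%.3f (ridge %.2f-%.2f Hz)\n",
    x$HFr, x$LFru, x$nLFru, x$LFru_HFr, min(x$f_ridge), max(x$f_ridge)))
  invisible(x)
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(B^(m+1)/B^m), where B^k counts pairs of length-k
#' templates within Chebyshev distance r of each other (self-matches
#' excluded). The tolerance is `r_frac` times the series standard
#' deviation; matches use distance <= r so a constant series (all
#' templates identical) has entropy 0.
#'
#' @param x Numeric series.
#' @param m Pattern length (default 2).
#' @param r_frac Tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Sample entropy (dimensionless); `NA` with a warning when no
#'   template pairs match at length m or m+1.
#' @export
sample_entropy <- function(x, m = 2, r_frac = 0.2) {
  n <- length(x)
  stopifnot(m >= 1, n > m + 1)
  r <- r_frac * stats::sd(x)
  n_tpl <- n - m                      # length-(m+1) templates: n - m
  # running Chebyshev distances over the first m coordinates, then extend
  Bm <- 0; Bm1 <- 0
  for (i in seq_len(n_tpl - 1L)) {
    js <- (i + 1L):n_tpl
    d <- abs(x[i] - x[js])
    for (k in seq_len(m - 1L)) {
      d <- pmax(d, abs(x[i + k] - x[js + k]))
    }
    match_m <- d <= r
    Bm <- Bm + sum(match_m)
    d1 <- pmax(d, abs(x[i + m] - x[js + m]))
    Bm1 <- Bm1 + sum(match_m & d1 <= r)
  }
  if (Bm == 0 || Bm1 == 0) {
    warning("sample entropy undefined: no matching templates")
    return(NA_real_)
  }
  -log(Bm1 / Bm)
}
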