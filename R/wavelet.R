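# Dyadic wavelet band limitation and complex-Morlet time-frequency analysis.
#
# Both transforms are implemented here rather than delegated: the band
# limitation must zero whole dyadic detail levels so that its cut-offs land
# exactly on the dyadic fractions of the sampling rate (e.g. 1000/2^13 =
# 0.122 Hz, 1000/2^6 = 15.625 Hz), and the time-frequency spectrum must use
# the analytic Morlet wavelet with bandwidth 3 and centre frequency 1.

# Orthonormal Daubechies scaling filters (L2 normalised, sum = sqrt(2)).
# Indexed by number of vanishing moments, as in the usual dbN naming.
.db_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153,
          0.63088076792959036, -0.02798376941698385,
          -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728),
  db8 = c(0.05441584224308161, 0.31287159091446592,
          0.67563073629801285, 0.58535468365486909,
          -0.01582910525602155, -0.28401554296242809,
          0.00047248457399797, 0.12874742662018601,
          -0.01736930100202211, -0.04408825393106472,
          0.01398102791739828, 0.00874609404701566,
          -0.00487035299301066, -0.00039174037299597,
          0.00067544940599855, -0.00011747678400228)
)

.wavelet_filters <- function(wavelet) {
  h <- .db_filters[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_filters), collapse = ", "))
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  list(h = h, g = g, length = L)
}

# One periodised analysis step: x (length N, N even) -> approx/detail (N/2).
.dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n / 2L
  base <- 2L * (seq_len(half) - 1L)
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    xk <- x[idx]
    a <- a + h[k] * xk
    d <- d + g[k] * xk
  }
  list(a = a, d = d)
}

# Adjoint of .dwt_step (the analysis operator is orthonormal, so the adjoint
# is the exact inverse).
.idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% n + 1L
    contrib <- h[k] * a + g[k] * d
    # idx values are distinct within one k, so plain assignment accumulates
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Periodised discrete wavelet transform
#'
#' Multilevel orthonormal DWT with periodic boundary handling. Mostly an
#' internal building block for [wavelet_band_limit()]; exported because the
#' level structure is occasionally useful for diagnostics.
#'
#' @param x Numeric vector whose length is divisible by `2^levels`.
#' @param levels Decomposition depth.
#' @param wavelet Filter name (`"db2"`, `"db4"`, `"db8"`).
#' @return List with `details` (list of detail coefficient vectors, level 1 =
#'   finest) and `approx` (coarsest approximation).
#' @export
dwt_periodic <- function(x, levels, wavelet = "db4") {
  flt <- .wavelet_filters(wavelet)
  if (length(x) %% 2^levels != 0) {
    stop("length(x) must be divisible by 2^levels")
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- .dwt_step(a, flt$h, flt$g)
    details[[j]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a, wavelet = wavelet, levels = levels)
}

#' Inverse of [dwt_periodic()]
#'
#' @param decomp A decomposition as returned by [dwt_periodic()].
#' @return Reconstructed numeric vector.
#' @export
idwt_periodic <- function(decomp) {
  flt <- .wavelet_filters(decomp$wavelet)
  a <- decomp$approx
  for (j in rev(seq_len(decomp$levels))) {
    a <- .idwt_step(a, decomp$details[[j]], flt$h, flt$g)
  }
  a
}

# Map a band edge onto a dyadic level index, insisting that fs/edge is a
# power of two (within a small tolerance for decimal printing of the edge).
.dyadic_level <- function(fs, edge, what) {
  lev <- log2(fs / edge)
  if (abs(lev - round(lev)) > 0.05) {
    stop(what, " = ", edge, " Hz is not a dyadic fraction of fs = ", fs,
         " Hz; band limitation zeroes whole dyadic levels and needs ",
         "fs/2^k edges (e.g. ", signif(fs / 2^round(lev), 4), ")")
  }
  as.integer(round(lev))
}

#' Wavelet band limitation
#'
#' Removes baseline drift and high-frequency noise by zeroing whole dyadic
#' levels of a discrete wavelet transform. Detail level j spans
#' \eqn{[fs/2^{j+1}, fs/2^j]} Hz; levels whose span falls outside
#' `[low, high]`, together with the final approximation, are zeroed before
#' reconstruction. Both band edges must therefore be dyadic fractions of
#' `fs` (at fs = 1000 Hz: 0.122 Hz = 1000/2^13, 15.625 = 1000/2^6,
#' 31.25 = 1000/2^5).
#'
#' The signal is extended by symmetric reflection to a multiple of the
#' deepest level's block size before the periodised transform, then cropped,
#' which suppresses wrap-around artifacts at the ends.
#'
#' @param signal Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param low,high Pass band edges in Hz, `low < high < fs/2`.
#' @param wavelet Daubechies filter to use (default `"db4"`).
#' @return Band-limited waveform of the same length.
#' @export
wavelet_band_limit <- function(signal, fs, low, high, wavelet = "db4") {
  stopifnot(is.numeric(signal), fs > 0)
  if (!(low < high && high < fs / 2)) {
    stop("need low < high < fs/2")
  }
  j_deep <- .dyadic_level(fs, low, "low")    # levels 1..j_deep-1 exist above low
  j_min <- .dyadic_level(fs, high, "high")   # first kept detail level
  n <- length(signal)
  block <- 2^j_deep
  if (n < block) {
    stop("signal too short for decomposition to ", low, " Hz: need at least ",
         block, " samples (", signif(block / fs, 3), " s) at fs = ", fs)
  }
  n_pad <- ceiling(n / block) * block
  pad <- n_pad - n
  pad_l <- pad %/% 2L
  pad_r <- pad - pad_l
  ext <- c(if (pad_l > 0) signal[pad_l:1], signal,
           if (pad_r > 0) signal[n:(n - pad_r + 1L)])
  dec <- dwt_periodic(ext, levels = j_deep, wavelet = wavelet)
  keep <- seq.int(j_min, j_deep - 1L)
  for (j in seq_len(j_deep)) {
    if (!(j %in% keep)) dec$details[[j]][] <- 0
  }
  dec$approx[] <- 0
  out <- idwt_periodic(dec)
  out[(pad_l + 1L):(pad_l + n)]
}

#' Complex Morlet continuous wavelet transform
#'
#' Analytic CWT computed in the frequency domain. The mother wavelet is the
#' complex Morlet with bandwidth parameter B = 3 and centre frequency C = 1
#' (the "cmor3-1" convention), whose frequency response at analysis
#' frequency `f` is \eqn{\exp(-\pi^2 B (\nu/f - 1)^2)} for \eqn{\nu > 0}.
#' The response has unit peak, so the coefficient magnitude at a matching
#' ridge equals half the sinusoid amplitude.
#'
#' @param x Numeric series (uniformly sampled).
#' @param fs Sampling rate of `x` in Hz.
#' @param freqs Analysis frequencies in Hz.
#' @param bandwidth Morlet bandwidth parameter (default 3).
#' @param center Morlet centre frequency parameter (default 1).
#' @return Complex matrix with `length(freqs)` rows and `length(x)` columns.
#' @export
morlet_cwt <- function(x, fs, freqs, bandwidth = 3, center = 1) {
  n <- length(x)
  stopifnot(n > 1, all(freqs > 0), all(freqs < fs / 2))
  n_fft <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, numeric(n_fft - n)))
  nu <- (seq_len(n_fft) - 1) / n_fft * fs
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs  # negative frequencies
  W <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  pos <- nu > 0
  for (i in seq_along(freqs)) {
    psi <- numeric(n_fft)
    psi[pos] <- exp(-pi^2 * bandwidth * center^2 * (nu[pos] / freqs[i] - 1)^2)
    W[i, ] <- stats::fft(xf * psi, inverse = TRUE)[seq_len(n)] / n_fft
  }
  W
}

#' Time-frequency power spectrum
#'
#' Squared magnitude of the complex Morlet wavelet transform on a
#' log-spaced frequency grid, the time-frequency power used for all band
#' powers in this package.
#'
#' @param series Numeric series, or a [rate_series] object (its 4 Hz values
#'   are analysed and `fs` is taken from it).
#' @param fs Sampling rate in Hz (ignored when `series` is a rate series).
#' @param freq_range Two-element numeric, analysis range in Hz.
#' @param n_voices Number of log-spaced analysis frequencies (default 64).
#' @param bandwidth,center Morlet parameters, see [morlet_cwt()].
#' @return Object of class `tf_power`: list with `times` (s), `freqs` (Hz),
#'   `power` (matrix, freqs x times), `coefs` (complex matrix), `fs`, and
#'   `edge_s`, the cone-of-influence margin (one period of the lowest
#'   analysis frequency) excluded from band integration.
#' @export
morlet_power <- function(series, fs = NULL, freq_range = c(0.01, 0.6),
                         n_voices = 64, bandwidth = 3, center = 1) {
  if (inherits(series, "rate_series")) {
    fs <- series$fs
    x <- series$values - mean(series$values)
    t0 <- series$times[1]
  } else {
    if (is.null(fs)) stop("fs must be given for a plain numeric series")
    x <- as.numeric(series)
    t0 <- 0
  }
  stopifnot(length(freq_range) == 2, freq_range[1] > 0,
            freq_range[2] > freq_range[1])
  n <- length(x)
  if (n / fs < 4 / freq_range[1]) {
    stop("series covers ", signif(n / fs, 4), " s; need at least four ",
         "periods (", signif(4 / freq_range[1], 4), " s) of the lowest ",
         "analysis frequency ", freq_range[1], " Hz")
  }
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]),
                   length.out = n_voices))
  W <- morlet_cwt(x, fs, freqs, bandwidth = bandwidth, center = center)
  structure(list(
    times = t0 + (seq_len(n) - 1) / fs,
    freqs = freqs,
    power = Mod(W)^2,
    coefs = W,
    fs = fs,
    edge_s = 1 / freq_range[1]
  ), class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  cat("<tf_power> ", length(x$freqs), " voices over [",
      signif(min(x$freqs), 3), ", ", signif(max(x$freqs), 3), "] Hz, ",
      length(x$times), " time points at ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

# Logical index of times retained for band integration (cone of influence
# trimmed at both ends).
.tf_retained_times <- function(tf) {
  t <- tf$times
  ok <- t >= t[1] + tf$edge_s & t <= t[length(t)] - tf$edge_s
  if (!any(ok)) {
    stop("series too short: nothing remains after excluding ", tf$edge_s,
         " s edges; use a longer series or a higher minimum frequency")
  }
  ok
}

# Sum of power over the voices inside [f1, f2), averaged over retained
# times. The frequency grid is log-spaced and the Morlet response has
# constant relative bandwidth, so a plain sum over voices weights every
# frequency equally: equal-amplitude sinusoids yield equal band powers
# regardless of where in the band they sit.
.tf_band_sum <- function(tf, f1, f2, closed_right = FALSE, times_ok = NULL) {
  if (is.null(times_ok)) times_ok <- .tf_retained_times(tf)
  sel <- if (closed_right) tf$freqs >= f1 & tf$freqs <= f2
         else tf$freqs >= f1 & tf$freqs < f2
  if (!any(sel)) return(0)
  mean(colSums(tf$power[sel, times_ok, drop = FALSE]))
}
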