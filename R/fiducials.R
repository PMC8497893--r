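# Landmark detection on PPG, VPG and APG.
#
# Ten points per beat: O (onset), S (systolic peak), M (rising-edge
# midpoint), N (dicrotic notch), D (diastolic peak) on the PPG; w, z
# (maximum systolic/diastolic slope) on the VPG; a, b, e (acceleration
# extrema) on the APG. Search strategy: S/w/a/b within 400 ms of the ECG R
# peak; e/z within 200 ms of b; N and D from VPG zero crossings around z
# (with a midpoint fallback when the dicrotic wave is weak); O by the
# intersecting-tangent technique on the rising edge. Beats failing any
# sub-detector are dropped entirely and counted.

# Windows are half-open on the left, closed on the right; indices are 1-based
# sample positions. O may fall between samples and is stored with sub-sample
# position; amplitude reads snap to the nearest sample.

#' Detect the systolic landmark group (S, w, a, b)
#'
#' Extremum search within 400 ms after the R peak: S is the PPG maximum,
#' w the VPG maximum, a the APG maximum and b the APG minimum constrained
#' to follow a.
#'
#' @param ppg,vpg,apg Waveform vectors.
#' @param r_time R-peak time in seconds.
#' @param fs Sampling rate in Hz.
#' @param window_s Search window length (default 0.4 s).
#' @return List with indices `S`, `w`, `a`, `b` and `ok = TRUE`, or
#'   `ok = FALSE` with a `reason`.
#' @export
detect_systolic_group <- function(ppg, vpg, apg, r_time, fs, window_s = 0.4) {
  r_idx <- round(r_time * fs) + 1L
  win <- (r_idx + 1L):(r_idx + round(window_s * fs))
  if (win[length(win)] > length(ppg)) {
    return(list(ok = FALSE, reason = "window truncated by signal end"))
  }
  S <- win[which.max(ppg[win])]
  if (S == win[1] || S == win[length(win)]) {
    return(list(ok = FALSE, reason = "no interior PPG maximum in window"))
  }
  w <- win[which.max(vpg[win])]
  a <- win[which.max(apg[win])]
  b_win <- win[win > a]
  if (length(b_win) < 2) {
    return(list(ok = FALSE, reason = "no room for b after a"))
  }
  b <- b_win[which.min(apg[b_win])]
  list(ok = TRUE, S = S, w = w, a = a, b = b)
}

#' Detect the diastolic derivative landmarks (e, z)
#'
#' e is the APG maximum and z the VPG maximum, both within 200 ms after b.
#'
#' @param vpg,apg Waveform vectors.
#' @param b_index Sample index of point b.
#' @param fs Sampling rate in Hz.
#' @param window_s Search window length (default 0.2 s).
#' @return List with indices `e`, `z` and `ok`, or `ok = FALSE` + `reason`.
#' @export
detect_diastolic_group <- function(vpg, apg, b_index, fs, window_s = 0.2) {
  win <- (b_index + 1L):(b_index + round(window_s * fs))
  if (win[length(win)] > length(vpg)) {
    return(list(ok = FALSE, reason = "window truncated by signal end"))
  }
  list(ok = TRUE, e = win[which.max(apg[win])], z = win[which.max(vpg[win])])
}

#' Locate the dicrotic notch N and diastolic peak D
#'
#' Two-branch rule on the VPG: if VPG at z is positive (pronounced dicrotic
#' wave), N is the upward VPG zero crossing before z and D the downward
#' crossing after z; otherwise (weak dicrotic wave) D coincides with z and
#' N is the index midpoint of e and z.
#'
#' @param ppg,vpg Waveform vectors (`ppg` is accepted for interface
#'   symmetry; the rule operates on the VPG).
#' @param z_index,e_index Landmark indices from [detect_diastolic_group()].
#' @param fs Sampling rate in Hz.
#' @param search_start First index to search for the crossing before z
#'   (default: 400 ms before z).
#' @param search_end Last index to search for the crossing after z
#'   (default: 400 ms past z).
#' @return List with indices `N`, `D` and `ok`, or `ok = FALSE` + `reason`.
#' @export
detect_notch_and_diastolic_peak <- function(ppg, vpg, z_index, e_index, fs,
                                            search_start = NULL,
                                            search_end = NULL) {
  if (is.null(search_start)) {
    search_start <- max(1L, z_index - round(0.4 * fs))
  }
  if (is.null(search_end)) {
    search_end <- min(length(vpg), z_index + round(0.4 * fs))
  }
  if (vpg[z_index] > 0) {
    pre <- which(vpg[search_start:(z_index - 1)] <= 0 &
                   vpg[(search_start + 1L):z_index] > 0)
    if (!length(pre)) {
      return(list(ok = FALSE, reason = "no upward VPG crossing before z"))
    }
    N <- search_start + max(pre)
    rng <- z_index:(search_end - 1L)
    post <- which(vpg[rng] > 0 & vpg[rng + 1L] <= 0)
    if (!length(post)) {
      return(list(ok = FALSE, reason = "no downward VPG crossing after z"))
    }
    D <- z_index + min(post)
  } else {
    D <- z_index
    N <- as.integer(round((e_index + z_index) / 2))
  }
  if (N > D) return(list(ok = FALSE, reason = "notch after diastolic peak"))
  list(ok = TRUE, N = N, D = D)
}

#' Detect the pulse onset O and rising-edge midpoint M
#'
#' Intersecting-tangent technique: starting from the maximal-VPG point on
#' the rising edge, a tangent segment grows point by point (symmetrically,
#' then one-sided at the bounds) while the linear-fit correlation stays at
#' or above `r_min`. O is the intersection of the fitted line with the
#' horizontal line through the minimum of the PPG segment between
#' `seg_lo` and S, stored with sub-sample position. M is the rising-edge
#' sample closest to the half-height `PPG(O) + H1/2`.
#'
#' @param ppg Waveform vector.
#' @param seg_lo First index of the PPG segment used for the minimum
#'   reference (previous notch, or the search-window start).
#' @param s_index,w_index Indices of S and w for this beat.
#' @param fs Sampling rate in Hz.
#' @param r_min Correlation threshold for tangent growth (default 0.999).
#' @return List with `O` (fractional index), `M` (index), `O_amp`
#'   (amplitude at the nearest sample) and `ok`, or `ok = FALSE` + `reason`.
#' @export
detect_onset <- function(ppg, seg_lo, s_index, w_index, fs, r_min = 0.999) {
  seg <- seg_lo:s_index
  foot <- seg[which.min(ppg[seg])]
  if (w_index - foot < 1L || s_index - w_index < 1L) {
    return(list(ok = FALSE, reason = "degenerate rising edge"))
  }
  gr <- .grow_tangent(ppg, w_index, lo = foot, hi = s_index, r_min = r_min)
  if (length(gr$idx) < 3L) {
    return(list(ok = FALSE, reason = "tangent fit has fewer than 3 points"))
  }
  fit <- stats::lm.fit(cbind(1, gr$idx), ppg[gr$idx])
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope <= 0) {
    return(list(ok = FALSE, reason = "degenerate tangent slope"))
  }
  y_min <- min(ppg[seg])
  o_frac <- unname((y_min - fit$coefficients[1]) / slope)
  if (o_frac < seg_lo - 0.5 || o_frac > w_index) {
    return(list(ok = FALSE, reason = "onset intersection outside segment"))
  }
  o_amp <- ppg[max(1L, round(o_frac))]
  target <- o_amp + (ppg[s_index] - o_amp) / 2
  rng <- max(1L, ceiling(o_frac)):s_index
  M <- rng[which.min(abs(ppg[rng] - target))]
  list(ok = TRUE, O = o_frac, M = M, O_amp = o_amp)
}

#' Detect all ten fiducial points per beat
#'
#' Runs the four sub-detectors beat by beat, anchored at the supplied R
#' times. A beat is emitted only when every sub-detector succeeds and the
#' ordering invariants (O < w < S, a < b < e, S < N <= D) hold; otherwise
#' the beat is dropped and the reason recorded.
#'
#' @param ppg PPG waveform (band-limited).
#' @param fs Sampling rate in Hz.
#' @param r_times R-peak times in seconds from [detect_r_peaks()].
#' @param vpg,apg Optional precomputed derivatives; computed with
#'   [differentiate()] when `NULL`.
#' @param deriv_band Pass band in Hz applied to the internally computed
#'   derivatives (default the PPG analysis band 0.122-15.625 Hz). Finite
#'   differences amplify any residual ripple far above the pulse band by
#'   the square of its frequency, so the VPG/APG are band-limited again
#'   before extremum search; the genuine pulse derivatives live inside
#'   this band and are unaffected. Set to `NULL` to skip.
#' @return Object of class `beat_fiducials`: data frame with one row per
#'   emitted beat (`beat`, `r_time`, and `<p>_idx`, `<p>_t`, `<p>_amp`
#'   for each point O, S, M, N, D, w, z, a, b, e). Attributes: `dropped`
#'   (data frame of beat/reason), `fs`.
#' @export
detect_fiducials <- function(ppg, fs, r_times, vpg = NULL, apg = NULL,
                             deriv_band = c(0.122, 15.625)) {
  stopifnot(is.numeric(ppg), fs > 0, length(r_times) >= 1)
  clean <- function(d) {
    if (is.null(deriv_band)) d else
      wavelet_band_limit(d, fs, deriv_band[1], deriv_band[2])
  }
  stride <- max(1L, round(0.008 * fs))
  if (is.null(vpg)) vpg <- clean(differentiate(ppg, fs, 1, stride = stride))
  if (is.null(apg)) apg <- clean(differentiate(ppg, fs, 2, stride = stride))
  pts <- c("O", "S", "M", "N", "D", "w", "z", "a", "b", "e")
  n_r <- length(r_times)
  idx_m <- matrix(NA_real_, n_r, 10, dimnames = list(NULL, pts))
  amp_m <- matrix(NA_real_, n_r, 10, dimnames = list(NULL, pts))
  dropped <- list()
  prev_N <- NA_integer_
  for (k in seq_along(r_times)) {
    r_idx <- round(r_times[k] * fs) + 1L
    fail <- function(reason) {
      dropped[[length(dropped) + 1L]] <<- data.frame(beat = k, reason = reason)
      NULL
    }
    sys <- detect_systolic_group(ppg, vpg, apg, r_times[k], fs)
    if (!sys$ok) { fail(sys$reason); prev_N <- NA; next }
    dia <- detect_diastolic_group(vpg, apg, sys$b, fs)
    if (!dia$ok) { fail(dia$reason); prev_N <- NA; next }
    nd <- detect_notch_and_diastolic_peak(ppg, vpg, dia$z, dia$e, fs)
    if (!nd$ok) { fail(nd$reason); prev_N <- NA; next }
    seg_lo <- if (!is.na(prev_N) && prev_N < sys$S - 2L) prev_N else r_idx
    on <- detect_onset(ppg, seg_lo, sys$S, sys$w, fs)
    if (!on$ok) { fail(on$reason); prev_N <- nd$N; next }
    idx <- c(O = on$O, S = sys$S, M = on$M, N = nd$N, D = nd$D,
             w = sys$w, z = dia$z, a = sys$a, b = sys$b, e = dia$e)
    if (!(idx[["O"]] < idx[["w"]] && idx[["w"]] < idx[["S"]] &&
          idx[["a"]] < idx[["b"]] && idx[["b"]] < idx[["e"]] &&
          idx[["S"]] < idx[["N"]] && idx[["N"]] <= idx[["D"]])) {
      fail("ordering invariant violated"); prev_N <- nd$N; next
    }
    amp <- c(O = on$O_amp, S = ppg[sys$S], M = ppg[on$M], N = ppg[nd$N],
             D = ppg[nd$D], w = vpg[sys$w], z = vpg[dia$z], a = apg[sys$a],
             b = apg[sys$b], e = apg[dia$e])
    if (!all(is.finite(amp))) { fail("non-finite amplitude"); prev_N <- nd$N; next }
    idx_m[k, ] <- idx
    amp_m[k, ] <- amp
    prev_N <- nd$N
  }
  keep <- which(is.finite(idx_m[, "O"]))
  out <- data.frame(beat = keep, r_time = r_times[keep])
  for (p in pts) {
    out[[paste0(p, "_idx")]] <- idx_m[keep, p]
    out[[paste0(p, "_t")]] <- (idx_m[keep, p] - 1) / fs
    out[[paste0(p, "_amp")]] <- amp_m[keep, p]
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(beat = integer(), reason = character())
  structure(out, dropped = dropped, fs = fs,
            class = c("beat_fiducials", "data.frame"))
}

#' @export
print.beat_fiducials <- function(x, ...) {
  cat("<beat_fiducials> ", nrow(x), " beats with all 10 points, ",
      nrow(attr(x, "dropped")), " dropped\n", sep = "")
  if (nrow(x)) utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}
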