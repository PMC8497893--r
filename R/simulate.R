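# Synthetic cardiorespiratory recordings with known ground truth.
#
# Beat times come from an integral pulse frequency modulation (IPFM) model
# whose instantaneous rate carries a low-frequency (sympathetic-like,
# ~0.1 Hz) and a respiratory-frequency modulation. Each beat renders a PPG
# pulse as the sum of three positive Gaussian waves (systolic, tidal,
# dicrotic) whose superposition shows the canonical systolic peak, tidal
# shoulder, dicrotic notch and diastolic peak; the ECG is a narrow spike
# train at the beat times and respiration a sinusoid.

#' Simulation configuration
#'
#' Assembles and validates the parameter set for [generate_recording()].
#' Defaults describe a resting adult: 5-minute recording at 1000 Hz, mean
#' heart rate 70 bpm, a 0.1 Hz low-frequency rate modulation of 4% depth,
#' respiration at 0.25 Hz modulating the rate by 5% (respiratory sinus
#' arrhythmia) and the pulse amplitude by 10%, plus a slow (0.04 Hz)
#' amplitude wander. The pulse transit delay between the ECG R spike and
#' the PPG pulse onset is fixed at 200 ms.
#'
#' The beat template widths/offsets are in seconds and are kept fixed in
#' absolute time while the beat period varies: systole is nearly constant
#' physiologically, and beats lengthen mostly through the diastolic runoff.
#'
#' @param state State label, one of `"BSL"`, `"SDB"`, `"CPT"`, `"MAT"`.
#'   The label is recorded; use [apply_state_preset()] to also apply the
#'   state's parameter offsets.
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_mean Mean heart rate in beats/min, in (30, 180).
#' @param lf_mod List `freq` (Hz), `depth` (fraction in \[0,1)): slow
#'   sympathetic-like rate modulation.
#' @param resp List `freq` (Hz), `depth` (fraction): respiratory rate
#'   modulation (the high-frequency band of rate variability).
#' @param beat_shape List `amp`, `mu`, `sigma`, each length 3 (systolic,
#'   tidal, dicrotic Gaussian amplitude in a.u., centre and width in s).
#' @param amp_mod List `resp_depth`, `slow_depth`, `slow_freq`:
#'   respiration-coupled and slow amplitude modulation of the pulse.
#' @param gain Overall PPG amplitude gain (a.u.).
#' @param noise_sd Additive white noise s.d. (a.u.) on every channel.
#' @param transit_s Pulse transit time from R spike to pulse onset (s).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(state = "BSL",
                       duration_s = 300,
                       fs = 1000,
                       hr_mean = 70,
                       lf_mod = list(freq = 0.1, depth = 0.04),
                       resp = list(freq = 0.25, depth = 0.05),
                       beat_shape = list(amp = c(1, 0.30, 0.65),
                                         mu = c(0.11, 0.20, 0.33),
                                         sigma = c(0.042, 0.045, 0.045)),
                       amp_mod = list(resp_depth = 0.10, slow_depth = 0.05,
                                      slow_freq = 0.04),
                       gain = 1,
                       noise_sd = 0.005,
                       transit_s = 0.2) {
  state <- match.arg(state, c("BSL", "SDB", "CPT", "MAT"))
  stopifnot(duration_s > 0, fs > 0,
            hr_mean > 30, hr_mean < 180,
            lf_mod$depth >= 0, lf_mod$depth < 1,
            resp$depth >= 0, resp$depth < 1,
            lf_mod$freq > 0, resp$freq > 0,
            length(beat_shape$amp) == 3, length(beat_shape$mu) == 3,
            length(beat_shape$sigma) == 3,
            all(beat_shape$amp > 0), all(beat_shape$sigma > 0),
            amp_mod$resp_depth >= 0, amp_mod$resp_depth < 1,
            amp_mod$slow_depth >= 0, amp_mod$slow_depth < 1,
            gain > 0, noise_sd >= 0, transit_s >= 0)
  # the narrowest rendered structure must be resolvable
  if (fs < 2 / min(beat_shape$sigma)) {
    stop("fs = ", fs, " Hz too low for beat template widths (min sigma = ",
         min(beat_shape$sigma), " s); need fs >= ",
         ceiling(2 / min(beat_shape$sigma)), " Hz")
  }
  if (fs <= 2 * max(lf_mod$freq, resp$freq, amp_mod$slow_freq)) {
    stop("fs must exceed twice the highest modulation frequency")
  }
  structure(list(state = state, duration_s = duration_s, fs = fs,
                 hr_mean = hr_mean, lf_mod = lf_mod, resp = resp,
                 beat_shape = beat_shape, amp_mod = amp_mod, gain = gain,
                 noise_sd = noise_sd, transit_s = transit_s),
            class = "sim_config")
}

#' Apply a state preset to a configuration
#'
#' Shifts the parameter means of a baseline configuration in the direction
#' characteristic of each condition: slow deep breathing (`SDB`) lowers the
#' respiratory frequency to ~0.1 Hz and triples the respiratory rate
#' modulation (parasympathetic activation); the cold pressor test (`CPT`)
#' doubles the amplitude-variation depths and lowers the mean pulse
#' amplitude to 80% (peripheral vasoconstriction); the mental arithmetic
#' test (`MAT`) doubles the low-frequency rate modulation and lowers the
#' amplitude to 90% (cardiac sympathetic activation). Magnitudes are free
#' parameters of the generator, not measured effect sizes.
#'
#' @param config A `sim_config` (treated as the subject's baseline).
#' @param state Target state label.
#' @return A new `sim_config` with the preset applied and `state` set.
#' @export
apply_state_preset <- function(config, state) {
  stopifnot(inherits(config, "sim_config"))
  state <- match.arg(state, c("BSL", "SDB", "CPT", "MAT"))
  cfg <- unclass(config)
  cfg$state <- state
  if (state == "SDB") {
    cfg$resp$freq <- cfg$resp$freq * 0.4
    cfg$resp$depth <- min(cfg$resp$depth * 3, 0.95)
  } else if (state == "CPT") {
    cfg$amp_mod$resp_depth <- min(cfg$amp_mod$resp_depth * 2, 0.95)
    cfg$amp_mod$slow_depth <- min(cfg$amp_mod$slow_depth * 2, 0.95)
    cfg$gain <- cfg$gain * 0.8
  } else if (state == "MAT") {
    cfg$lf_mod$depth <- min(cfg$lf_mod$depth * 2, 0.95)
    cfg$gain <- cfg$gain * 0.9
  }
  do.call(sim_config, cfg)
}

# The three-Gaussian pulse template (systolic, tidal, dicrotic waves).
.beat_template <- function(t, shape) {
  a <- shape$amp; mu <- shape$mu; sg <- shape$sigma
  a[1] * exp(-((t - mu[1]) / sg[1])^2 / 2) +
    a[2] * exp(-((t - mu[2]) / sg[2])^2 / 2) +
    a[3] * exp(-((t - mu[3]) / sg[3])^2 / 2)
}

# Shared helper: grow a tangent segment around index `center` while the
# linear-fit correlation stays >= r_min. Growth is symmetric, one point per
# side per step, continuing one-sided when a bound is reached.
.grow_tangent <- function(y, center, lo, hi, r_min = 0.999) {
  i0 <- max(lo, center - 1L)
  i1 <- min(hi, center + 1L)
  if (i1 - i0 < 2L) return(list(idx = i0:i1, r = NA_real_))
  repeat {
    grew <- FALSE
    for (side in c(-1L, 1L)) {
      cand0 <- if (side < 0) i0 - 1L else i0
      cand1 <- if (side < 0) i1 else i1 + 1L
      if (cand0 < lo || cand1 > hi) next
      idx <- cand0:cand1
      r <- suppressWarnings(stats::cor(idx, y[idx]))
      if (!is.na(r) && r >= r_min) {
        i0 <- cand0; i1 <- cand1; grew <- TRUE
      }
    }
    if (!grew) break
  }
  list(idx = i0:i1, r = suppressWarnings(stats::cor(i0:i1, y[i0:i1])))
}

#' Generate one synthetic cardiorespiratory recording
#'
#' Draws beat times from the IPFM model with instantaneous rate
#' \eqn{r(t) = (hr/60)(1 + d_{LF}\sin(2\pi f_{LF} t) + d_{HF}\sin(2\pi f_R t))}
#' beats per second, renders each pulse from the Gaussian beat template
#' with a respiration-coupled amplitude gain, and populates ground truth
#' (beat times, per-beat fiducial times and amplitudes, state label).
#' Identical `(config, seed)` give bit-identical output.
#'
#' Ground-truth fiducials are the definitional landmark rules evaluated on
#' the clean (pre-noise) rendered pulse wave in the standard analysis
#' bandwidth, anchored at the true beat times — exact for the rendered
#' signal, including beat-to-beat context effects of the band limitation.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for all randomness (noise and phase draws).
#' @param truth Populate the per-beat fiducial ground truth (default
#'   TRUE)? Skipping it saves about a third of the generation time when
#'   only the channels are needed; beat and onset times are always stored.
#' @return Object of class `ppg_recording`: list with `ecg`, `ppg`, `resp`
#'   (numeric channels of equal length), `fs`, `duration_s`, `config`,
#'   `seed` and `truth` (list: `r_times`, `onset_times`, `fiducials`
#'   data frame or `NULL`, `state`).
#' @export
generate_recording <- function(config, seed, truth = TRUE) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  fs <- config$fs
  n <- round(config$duration_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  phi_r <- stats::runif(1, 0, 2 * pi)    # respiration phase
  phi_lf <- stats::runif(1, 0, 2 * pi)   # LF modulation phase
  u0 <- stats::runif(1)                  # IPFM integrator start

  # IPFM: integrate the instantaneous rate and take integer crossings
  rate <- (config$hr_mean / 60) *
    (1 + config$lf_mod$depth * sin(2 * pi * config$lf_mod$freq * t + phi_lf) +
       config$resp$depth * sin(2 * pi * config$resp$freq * t + phi_r))
  integ <- cumsum(rate) / fs - rate[1] / fs + u0
  n_beats <- floor(integ[n])
  if (n_beats < 3) stop("configuration yields fewer than 3 beats")
  r_times <- stats::approx(integ, t, xout = seq_len(n_beats))$y
  r_times <- r_times[!is.na(r_times)]

  # ECG: narrow Gaussian spikes at the beat times
  ecg <- numeric(n)
  spike_sd <- 0.004
  half_w <- round(4 * spike_sd * fs)
  for (rt in r_times) {
    c_i <- round(rt * fs) + 1L
    idx <- max(1L, c_i - half_w):min(n, c_i + half_w)
    ecg[idx] <- ecg[idx] + exp(-((t[idx] - rt) / spike_sd)^2 / 2)
  }

  # PPG: template rendered at onset = R + transit, amplitude-modulated
  onset_times <- r_times + config$transit_s
  gains <- config$gain *
    (1 + config$amp_mod$resp_depth *
       sin(2 * pi * config$resp$freq * onset_times + phi_r) +
       config$amp_mod$slow_depth *
       sin(2 * pi * config$amp_mod$slow_freq * onset_times))
  ppg <- numeric(n)
  span <- max(config$beat_shape$mu) + 6 * max(config$beat_shape$sigma)
  span_n <- round(span * fs)
  for (k in seq_along(onset_times)) {
    o_i <- round(onset_times[k] * fs) + 1L
    idx <- o_i:min(n, o_i + span_n)
    if (idx[1] > n) break
    ppg[idx] <- ppg[idx] +
      gains[k] * .beat_template(t[idx] - onset_times[k], config$beat_shape)
  }

  resp <- sin(2 * pi * config$resp$freq * t + phi_r)

  fid <- NULL
  if (truth) {
    ppg_clean_f <- wavelet_band_limit(ppg, fs,
                                      fs / 2^round(log2(fs / 0.122)), 15.625)
    fid <- as.data.frame(detect_fiducials(ppg_clean_f, fs, r_times))
    fid$onset_time <- onset_times[fid$beat]
  }

  if (config$noise_sd > 0) {
    ecg <- ecg + stats::rnorm(n, 0, config$noise_sd)
    ppg <- ppg + stats::rnorm(n, 0, config$noise_sd)
    resp <- resp + stats::rnorm(n, 0, config$noise_sd)
  }

  structure(list(
    ecg = ecg, ppg = ppg, resp = resp, fs = fs,
    duration_s = config$duration_s, config = config, seed = seed,
    truth = list(r_times = r_times, onset_times = onset_times,
                 fiducials = fid, state = config$state)
  ), class = "ppg_recording")
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat("<ppg_recording> ", x$duration_s, " s at ", x$fs, " Hz, ",
      length(x$truth$r_times), " beats, state ", x$truth$state,
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Generate a labelled multi-state cohort
#'
#' Draws per-subject baseline physiology (mean heart rate, respiratory
#' frequency, modulation depths, amplitude gain) once per subject and
#' applies the state presets on top, so subject identity is preserved
#' across states (a paired design). Recordings are described lazily by a
#' manifest of configurations; realise individual recordings with
#' [cohort_recording()] to keep memory bounded.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param states Character vector of state labels.
#' @param seed Integer master seed; subject draws and per-recording seeds
#'   derive from it.
#' @param base_config Template `sim_config` for the cohort baseline.
#' @return Object of class `ppg_cohort`: list with `manifest` (data frame:
#'   `subject_id`, `state`, `seed`, `row`) and `configs` (list of
#'   `sim_config`, one per manifest row).
#' @export
generate_cohort <- function(n_subjects, states = c("BSL", "SDB", "CPT", "MAT"),
                            seed = 1, base_config = sim_config()) {
  stopifnot(n_subjects >= 2, inherits(base_config, "sim_config"))
  bad <- setdiff(states, c("BSL", "SDB", "CPT", "MAT"))
  if (length(bad)) stop("unknown state label(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  subj_hr <- pmin(pmax(stats::rnorm(n_subjects, base_config$hr_mean, 7), 45), 110)
  subj_fr <- pmin(pmax(stats::rnorm(n_subjects, base_config$resp$freq, 0.03),
                       0.15), 0.35)
  subj_lf <- base_config$lf_mod$depth * exp(stats::rnorm(n_subjects, 0, 0.15))
  subj_hf <- base_config$resp$depth * exp(stats::rnorm(n_subjects, 0, 0.15))
  subj_gain <- base_config$gain * exp(stats::rnorm(n_subjects, 0, 0.10))

  rows <- expand.grid(state = states, subject_id = seq_len(n_subjects),
                      stringsAsFactors = FALSE)[, c("subject_id", "state")]
  configs <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    s <- rows$subject_id[i]
    cfg <- unclass(base_config)
    cfg$hr_mean <- subj_hr[s]
    cfg$resp$freq <- subj_fr[s]
    cfg$lf_mod$depth <- min(subj_lf[s], 0.9)
    cfg$resp$depth <- min(subj_hf[s], 0.9)
    cfg$gain <- subj_gain[s]
    cfg <- do.call(sim_config, cfg)
    configs[[i]] <- apply_state_preset(cfg, rows$state[i])
  }
  manifest <- data.frame(subject_id = rows$subject_id, state = rows$state,
                         seed = as.integer(seed) + 1000L + seq_len(nrow(rows)),
                         row = seq_len(nrow(rows)))
  structure(list(manifest = manifest, configs = configs,
                 seed = as.integer(seed)),
            class = "ppg_cohort")
}

#' Realise one cohort recording
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Manifest row index.
#' @param truth Populate fiducial ground truth (see
#'   [generate_recording()]).
#' @return The `ppg_recording` for that row.
#' @export
cohort_recording <- function(cohort, i, truth = TRUE) {
  stopifnot(inherits(cohort, "ppg_cohort"),
            i >= 1, i <= nrow(cohort$manifest))
  generate_recording(cohort$configs[[i]], cohort$manifest$seed[i],
                     truth = truth)
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat("<ppg_cohort> ", length(unique(x$manifest$subject_id)), " subjects x ",
      length(unique(x$manifest$state)), " states = ", nrow(x$manifest),
      " recordings (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
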