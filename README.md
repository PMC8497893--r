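# ppgans

Autonomic nervous system (ANS) assessment from the finger
photoplethysmogram (PPG), in R.

## What problem this solves

Heart rate variability (HRV) from the ECG is the standard noninvasive
window on autonomic activity: low-frequency power (LF, 0.03–0.15 Hz),
high-frequency power (HF, 0.15–0.4 Hz), total power TP, nLF = LF/(LF+HF)
and LF/HF. It has two well-known failure modes. When breathing slows to
~0.1 Hz, respiratory (parasympathetic) power moves into the LF band and
is misread as sympathetic activation; and pulse-timing surrogates (pulse
rate variability, PRV) discard the amplitude and shape information in
the pulse wave that actually responds to vasomotor sympathetic tone.

`ppgans` implements a full pipeline for studying both problems:

* a **seeded synthetic generator** of ECG/PPG/respiration recordings
  with known ground truth (beat times from an integral pulse frequency
  modulation model; pulses as a three-Gaussian template with systolic
  peak, tidal shoulder, dicrotic notch and diastolic peak; respiration-
  coupled rate and amplitude modulation; presets for baseline, slow deep
  breathing, cold pressor and mental arithmetic states);
* **dyadic wavelet band limitation** with cut-offs at exact dyadic
  fractions of the sampling rate, and R-peak detection on a mid-scale
  wavelet detail;
* detection of the **ten pulse landmarks** O, S, M, N, D (PPG), w, z
  (first derivative) and a, b, e (second derivative) with the
  window-and-fallback search strategy of the fiducial literature;
* a **110-item feature vector**: 22 per-beat morphometrics × mean/Std/
  Rmssd, tidal-wave descriptors from the 15–35 Hz Morlet band, cardiac
  and respiratory wavelet power, 8 derivative amplitudes × three
  aggregates, and PRV indices including sample entropy;
* complex-**Morlet time-frequency spectra** (cmor, bandwidth 3, centre
  frequency 1) with traditional band powers, and a
  **respiration-referenced decomposition** of heart rate into a
  respiratory component (HFr) and the remainder (LFru) by ridge-masked
  reconstruction — the "improved HRV" that keeps slow breathing out of
  the sympathetic band;
* the four-step **interpretable random-forest selection** (rank by
  averaged importance → CART-thresholded elimination → minimal-OOB
  interpretation set → error-gain-pruned classification set) with
  grid-searched repeated 10-fold cross-validation;
* **stepwise regression** (partial F-tests, entry 0.05 / removal 0.10)
  of the improved-HRV indices on the selected PPG features, and paired
  t-statistics between states.

## A worked example

```r
library(ppgans)

# a 5-minute resting recording, then a slow-deep-breathing variant
cfg  <- sim_config(duration_s = 300, noise_sd = 0)
rec  <- generate_recording(apply_state_preset(cfg, "SDB"), seed = 17)

# heart rate from the ECG, then the two spectral readings
ecg_f <- wavelet_band_limit(rec$ecg, rec$fs, 0.122, 31.25)
hr    <- build_rate_series(detect_r_peaks(ecg_f, rec$fs))
band_powers(morlet_power(hr, freq_range = c(0.03, 0.4)))
#> <band_powers> LF=0.03953 HF=7.968e-05 TP=0.03961 nLF=0.998 LF/HF=496.127
improved_hrv(hr, rec$resp, rec$fs, resp_range = c(0.05, 0.6))
#> <improved_hrv> HFr=0.03418 LFru=3.279e-06 nLFru=0.000 LFru/HFr=0.000
#>                (ridge 0.10-0.10 Hz)
```

The subject is breathing at 0.1 Hz, so nearly all rate variability is
respiratory (parasympathetic). The traditional bands put 99.8% of it in
LF (nLF = 0.998 — read as strong sympathetic activation); the
respiration-referenced split assigns the same power to the respiratory
component (nLFru < 0.001), which is the physiologically correct reading.

The 110 features and their selection:

```r
fv <- extract_features(rec)
fv[c("mean_T", "mean_H1", "PRV_LF", "PRV_SampEn")]
#>     mean_T    mean_H1     PRV_LF PRV_SampEn
#> 0.85751570 0.93327077 0.03950398 0.26211947

# a small labelled cohort and the four-step feature selection
coh  <- generate_cohort(12, c("BSL", "SDB"), seed = 1,
                        base_config = sim_config(duration_s = 300))
# ... extract features per recording into `tab`, then:
# sel <- rf_select(tab[, ppg_feature_names()], tab$state)
# sel$interpretation; sel$classification
```

`run_study()` chains all stages (cohort → features → selection →
regression → paired statistics) into one reproducible, seeded run and
writes CSV/JSON reports.

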