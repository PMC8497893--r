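---
title: "Assessing autonomic activity from the pulse wave: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing autonomic activity from the pulse wave: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Autonomic nervous system (ANS) activity is conventionally assessed from
heart rate variability (HRV): the spectrum of the R-R interval series,
with low-frequency power (LF, 0.03-0.15 Hz) read as mixed
sympathetic/parasympathetic drive, high-frequency power (HF, 0.15-0.4 Hz)
as respiratory parasympathetic drive, and nLF = LF/(LF+HF) or LF/HF as
balance indices. Two well-known weaknesses motivate this package. First,
HF is tied to the respiratory *band* rather than to respiration itself:
when a subject breathes slowly (around 0.1 Hz, as in relaxation
exercises), respiratory parasympathetic power moves into the LF band and
is misread as sympathetic activation. Second, the finger
photoplethysmogram (PPG) contains far more autonomically relevant
information than pulse timing alone — pulse amplitude, its first (VPG)
and second (APG) derivatives, and the tidal-wave region all respond to
vasomotor (sympathetic) tone — but most PPG work reduces the signal to
pulse rate variability (PRV).

The package implements a complete pipeline around these two ideas: a
110-item PPG feature vector; a respiration-referenced decomposition of
heart rate that replaces the fixed HF band with the instantaneous
respiratory frequency; an interpretable random-forest procedure that
reduces the 110 features to a small mechanism-oriented set; and a
stepwise regression that predicts the respiration-referenced spectral
indices from the selected PPG features. Because the human recordings that
motivated the design are not public, a synthetic generator with known
ground truth defines the test bed.

## The synthetic generator

`generate_recording()` draws beat times from an integral pulse frequency
modulation (IPFM) model: beats occur at the integer crossings of the
integral of the instantaneous rate

r(t) = (HR/60) · (1 + d_LF sin(2π f_LF t + φ_LF) + d_HF sin(2π f_R t + φ_R)),

in beats per second. Defaults (HR = 70 bpm, f_LF = 0.1 Hz with 4% depth,
f_R = 0.25 Hz with 5% depth, 300 s at 1000 Hz) describe a resting young
adult; phases are drawn from the seed. Each pulse is rendered as a sum of
three positive Gaussian waves — systolic (amplitude 1, centre 0.11 s,
width 0.042 s), tidal (0.30, 0.20 s, 0.045 s) and dicrotic (0.65,
0.33 s, 0.045 s) — whose superposition shows the canonical systolic peak,
tidal shoulder, dicrotic notch and diastolic peak, and whose derivatives
carry the w/z and a/b/e landmarks the detectors expect. The template is
fixed in absolute time while the beat period varies, because systole is
nearly constant physiologically and beats lengthen mainly through
diastolic runoff. The wave amplitudes were chosen once so that every
landmark falls inside its search window *after* band limitation (the
heavy 15.625 Hz low-pass rounds the waveform substantially); they are not
fitted to any data. A per-beat gain couples pulse amplitude to
respiration (10%) and to a slow 0.04 Hz wander (5%); the ECG is a narrow
spike train at the beat times (only R times are consumed downstream); and
respiration is the sinusoid sin(2π f_R t + φ_R). White noise
(default sd 0.005 a.u.) is added to every channel.

State presets shift parameter means in the physiologically expected
directions: slow deep breathing (SDB) multiplies f_R by 0.4 (≈0.1 Hz) and
the respiratory rate-modulation depth by 3; the cold pressor test (CPT)
doubles the amplitude-variation depths and scales mean amplitude by 0.8;
mental arithmetic (MAT) doubles the LF depth and scales amplitude by 0.9.
The magnitudes are free parameters — the source experiments report only
normalized effect directions — and are documented here once; nothing in
the package tunes them.

Cohorts (`generate_cohort()`) draw per-subject baselines (heart rate
N(70, 7) clipped to 45-110 bpm, respiratory rate N(0.25, 0.03) clipped to
0.15-0.35 Hz, log-normal jitter of 15% on modulation depths and 10% on
gain) and apply the presets per state, so subject identity is preserved
across states (a paired design).

**Ground truth.** Per-beat landmark truth is obtained by applying the
definitional landmark rules to the *clean* (pre-noise) rendered pulse
wave, band-limited through the standard analysis path and anchored at the
true beat times. A context-free template truth was rejected during
development: the decimated dyadic band limitation makes the position of
flat extrema (notably APG point e) depend on neighbouring beats by
~10 ms, so truth must be computed in context to be meaningful at the
±15 ms recovery tolerance. Consequently the fiducial-recovery tests
measure the robustness of R-peak anchoring and noise handling; the
landmark rules themselves are validated separately on constructed
waveforms with known crossings and extrema.

What the generator does *not* emulate: motion artifacts, ectopic beats,
sensor optics, baseline drift of measurement origin, non-sinusoidal
respiration, and genuine hemodynamics. Passing tests therefore
demonstrate correctness of the *methods* under clean, well-specified
conditions, not field performance on clinical recordings.

## Band limitation and spectra

The ECG is limited to 0.122-31.25 Hz and the PPG to 0.122-15.625 Hz.
These edges are dyadic fractions of the 1000 Hz sampling rate
(1000/2^13 ≈ 0.122, 1000/2^5 = 31.25, 1000/2^6 = 15.625), so
`wavelet_band_limit()` implements them exactly by zeroing whole detail
levels of an orthonormal periodised discrete wavelet transform (db4 by
default; db2/db8 available). Detail level j spans [fs/2^(j+1), fs/2^j].
The signal is reflected to a multiple of the deepest block size; on
lengths already divisible the operator is an exact orthogonal projection
(hence exactly idempotent), otherwise idempotence holds to
boundary-effect accuracy.

One numerical consequence matters downstream: the reconstruction from a
decimated transform leaves a small high-frequency imaging residue
(~0.1% of signal range). Harmless in the waveform, it is amplified by
fs² in one-sample second differences and would dominate the pulse
acceleration. The fiducial detector therefore computes VPG/APG with an
8 ms difference step and band-limits the derivatives again to the PPG
band before extremum search; both choices leave the sub-15 Hz pulse
derivatives essentially unchanged.

Time-frequency power uses the analytic complex Morlet wavelet with
bandwidth 3 and centre frequency 1, unit peak response, on a log-spaced
frequency grid (64 voices by default). Band powers sum the per-voice
power inside the band and average over time. Because the Morlet response
has constant relative bandwidth and the grid is log-spaced, a plain sum
over voices weights every frequency equally — equal-amplitude modulations
yield equal band powers wherever they sit in the band. One period of the
lowest analysis frequency is trimmed from each end (cone of influence)
before averaging; spectra over [0.03, 0.4] Hz therefore need recordings
comfortably longer than 2/0.03 ≈ 67 s, and the package requires at least
four periods of the lowest frequency (133 s for 0.03 Hz).

Rate series are built from event times as 60/interval at the interval
end, cubic-spline interpolated to a uniform 4 Hz grid and divided by
their mean (removing the arithmetic effect of mean rate on spectral
power). Intervals deviating more than 30% from an 11-point running median
are treated as detection artifacts and interpolated over — an automated
stand-in for manual beat editing.

## The respiration-referenced decomposition

`improved_hrv()` takes the respiration signal as reference: the
instantaneous respiratory frequency f_r(t) is the per-time argmax (ridge)
of the Morlet power of respiration; the respiratory heart-rate component
HRr is reconstructed from the heart-rate wavelet coefficients within
f_r(t) ± 0.05 Hz (the reconstruction is normalised by the summed wavelet
response at the ridge frequency, so an in-band sinusoid is recovered at
its own amplitude); and HRru = HR − HRr, making the decomposition
additive by construction. HFr sums heart-rate power inside the
time-varying ridge band; LFru sums the power of HRru over the fixed LF
band. The published description of this decomposition is conceptual; the
ridge-masking reconstruction used here is this package's concrete
realisation, with the half-width Δ configurable. HFr integrates the
original heart rate's coefficients inside the ridge band (not the
reconstructed HRr's), which is equivalent up to mask leakage.

The default ridge search range follows the respiratory band,
[0.1, 0.6] Hz, and a warning is raised when the ridge sits on the range
boundary for more than 20% of the record. Because slow deep breathing
lives at ≈0.1 Hz — exactly the band edge — the study pipeline
(`run_study()`, `analyze_recording()`) widens the range to
[0.05, 0.6] Hz.

## Fiducial points and the 110 features

Ten landmarks per beat: onset O, systolic peak S, rising-edge midpoint M,
dicrotic notch N and diastolic peak D on the PPG; maximum systolic and
diastolic slopes w and z on the VPG; acceleration extrema a, b, e on the
APG (points c and d are deliberately excluded as unreliable). The search
strategy is window-based: S/w/a/b as extrema within 400 ms after the R
peak (b constrained to follow a), e/z within 200 ms after b, N and D from
VPG zero crossings around z when the dicrotic wave is pronounced
(VPG(z) > 0) or from the weak-wave fallback (D = z, N midway between e
and z) otherwise, and O by the intersecting-tangent technique: a tangent
segment grows symmetrically around the maximal-slope point while the
linear-fit correlation stays ≥ 0.999, and O is the intersection of that
line with the horizontal through the segment minimum (the segment runs
from the previous notch, or the window start, to S). M is interpreted as
the half-height point of the rising edge, consistent with the pulse-width
definition. Windows are half-open on the left and closed on the right;
O is stored with sub-sample position and its amplitude read at the
nearest sample. Beats failing any sub-detector are dropped whole, with
reasons counted — an all-or-nothing policy replacing manual review.

The feature vector (canonical order in `ppg_feature_names()`):

* 1-22: per-beat morphometric means — intervals T, T1, T2, T3, PW
  (time at or above M's amplitude, crossings linearly interpolated),
  PPT; ratios T1/T, T2/T, PW/T, PPT/T; areas A1 (onset→notch), A2
  (notch→next onset), A = A1+A2, IPA = A2/A1, A1/A; heights H1, H2, H3
  of S, N, D above the onset amplitude; H2/H1, RI = H3/H1; slopes
  RS = H1/T1, FS = H1/(T−T1). Heights are onset-referenced, which makes
  them gain- and drift-robust.
* 23-44 and 45-66: the standard deviation and the root mean square of
  successive differences (Rmssd) of the same 22 quantities over the
  recording.
* 67-78: tidal-wave descriptors (mean/Std/Rmssd of TWa, TWp, TWvt,
  TWsi). The tidal wave is characterised through the 15-35 Hz Morlet
  band of the *non-low-passed* pulse wave — computing it on the
  15.625 Hz-limited signal would null it by construction — with
  TWp the summed time-frequency power over [S, N] × [15, 35] Hz,
  TWv the range of the band-reconstructed signal, TWt = N − S,
  TWa the area above the S→N chord, and TWsi = TWp/(TWv·TWt).
* 79-80: total Morlet power of the pulse wave over the cardiac band
  (0.75-2.5 Hz) and the respiratory band (0.1-0.6 Hz).
* 81-104: derivative amplitudes Hw, Hz (VPG), Ha, Hb, He (APG), plus
  Hb/Ha, He/Ha, (Hb−He)/Ha, each as mean/Std/Rmssd.
* 105-110: PRV indices from the w-w intervals (w is the standard
  surrogate for the R peak in pulse timing): LF, HF, TP, nLF, LF/HF and
  the sample entropy of the pulse-rate series (m = 2, r = 0.2·sd,
  Chebyshev distance, self-matches excluded, matches at distance ≤ r so
  a constant series has entropy 0).

Aggregates use only beats with complete fiducial sets; the contributing
beat count is kept as an attribute.

## Interpretable feature selection

The four-step procedure: (1) rank features by forest importance averaged
over 50 forests of 2000 trees with `max_features = 0.3` (seeds 0-49);
(2) fit a depth-3 regression tree to the importance standard deviation
versus rank and remove features whose mean importance falls below the
minimum predicted value; (3) grow nested forests over prefixes of the
surviving ranking (500 trees, `max_features = "sqrt"`) and keep the
prefix with minimal out-of-bag (OOB) error — the interpretation set;
(4) re-introduce interpretation features sequentially, keeping one only
if it lowers the OOB error by more than the threshold
mean |Δ OOB| computed over the trace between the interpretation and the
surviving-set sizes — the classification set. Ties are broken everywhere
by ascending feature index, and determinism is guaranteed by fixed seeds.

One deliberate departure: importances are *permutation* importances, not
impurity importances. The step-two threshold compares mean importance
against a statistic of the importance noise floor; impurity importance is
inflated away from zero for uninformative features, so that threshold
would never bind and elimination would be vacuous. Permutation importance
is zero-centred for uninformative features, which is exactly what the
thresholding construction presumes.

Model evaluation is grid-searched repeated 10-fold cross-validation
(trees 40-540 by 50; `max_features` 0.3, sqrt, 0.7; random states 0-29),
reporting mean/max/min of the per-state best accuracies. Folds are
grouped by subject in multi-state problems so a subject's paired
recordings never straddle train and test (ungrouped stratified folds are
available). The unit and acceptance suites run the same machinery at
reduced sizes (5-8 ranking runs of 250-300 trees; evaluation grids of a
few points and 2-5 random states): the reduced sizes change only the
variance of importance estimates, not the logic under test, and keep the
suites desk-scale.

## Stepwise regression and paired statistics

`stepwise_fit()` performs forward entry by partial F-test (entry α =
0.05) with backward removal (removal α = 0.10), iterated to a fixed
point; exactly collinear candidates are blocked at entry. The reported
model statistics are the overall F and its p-value. The α levels are the
conventional stepwise defaults; the source procedure states the criterion
(significance of the partial regression sum of squares) but not the
levels. Between-state contrasts use two-sided paired t-tests with tiers
at 0.05 and 0.01, pooling all states' recordings for the regressions.

## Numerical choices and degenerate inputs

* DWT filters: standard Daubechies coefficient sets (db2/db4/db8),
  periodised transform with symmetric pre-padding.
* Morlet transforms zero-pad to the next power of two; decimation (used
  before low-frequency transforms of raw waveforms) low-passes by FFT
  after reflective extension to a highly composite length.
* Sample entropy with no matching templates, LF/HF with zero HF, and the
  step-four threshold with an empty eliminated tail are reported as
  undefined (`NA`) with a warning, never as infinities.
* Flat ECG or respiration, non-monotone event times, too-short signals
  for the requested decomposition depth, and sub-4-period spectra are
  rejected with informative errors.
* Recordings shorter than ~140 s cannot support the 0.03 Hz band
  analysis (four periods plus cone of influence), so study configurations
  use 150 s as the practical minimum and 300 s by default.

## Problem sizes used by the test suites

Unit tests use 20-150 s single recordings and small planted tables. The
acceptance suite uses: one 150 s recording (schema); 100 random series
(entropy oracle); four 60 s recordings at 50/60/90/120 bpm (fiducial
recovery); 30 seeded 112 × 110 planted tables for each of signal recovery
and redundancy pruning (ranking 5 × 250 trees, nested models 500 trees);
and one 28-subject × 4-state × 300 s noise-free cohort for the
end-to-end checks (PRV-vs-HRV agreement at baseline, constructed-response
recovery, respiration-referenced directionality). The planted-table
effect sizes (1.5 sd for recovery, 2.5 sd for duplicate pruning) are
chosen so the planted structure is unambiguous relative to OOB-error
noise at these forest sizes. The end-to-end cohort is noise-free because
the properties it checks (e.g. PRV-HRV spectral agreement from a shared
IPFM ground truth) are stated for noise-free conditions; per-recording
noise robustness is covered by the fiducial tests.

## Known limitations

* The Gaussian-bump pulse is a standard synthetic construction, not a
  hemodynamic model; absolute feature values (areas, tidal-wave power)
  are in arbitrary units and only their variation structure is
  meaningful.
* The respiration-referenced decomposition assumes a dominant, trackable
  respiratory ridge; irregular breathing would degrade HFr/LFru.
* The dyadic band limitation is shift-variant at the sample scale;
  derivative-domain landmarks inherit a few milliseconds of jitter,
  which bounds achievable fiducial agreement (~±10 ms) independent of
  noise.
* Selection behaviour on real cohorts (n = 112 recordings) depends on
  effect sizes the synthetic cohort can only mimic directionally.
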