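Package: ppgans
Title: Autonomic Nervous System Assessment from Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing autonomic nervous system (ANS) activity from
    the photoplethysmogram (PPG) and its derivatives. Provides a seeded
    generator of synthetic cardiorespiratory recordings (ECG, finger PPG,
    respiration) with known ground truth; dyadic wavelet band limitation and
    R-peak detection; detection of ten fiducial landmarks per pulse on the
    PPG, velocity (VPG) and acceleration (APG) waveforms; a 110-item
    feature vector covering pulse morphology, tidal-wave energy,
    cardiorespiratory wavelet power, derivative amplitudes and pulse rate
    variability; complex-Morlet time-frequency spectra with traditional
    heart rate variability band powers and a respiration-referenced
    decomposition of heart rate into respiratory and non-respiratory
    components; an interpretable random-forest feature-selection procedure
    with out-of-bag model sizing; and stepwise regression of the
    respiration-referenced spectral indices on the selected PPG features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
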