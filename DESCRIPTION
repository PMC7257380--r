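Package: eegstates
Title: Epileptic State Classification from Multichannel EEG via Band-Energy Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies four epileptic brain states (interictal, preictal I,
    preictal II, seizure) from multichannel scalp EEG. Recordings are denoised
    by db6 wavelet thresholding, cut into 4-second frames, and transformed into
    power spectrum density energy diagrams (PSDEDs): per-channel periodogram
    power integrated over 32 frequency bands, log-scaled and normalized into an
    image. An ensemble of convolutional network feature extractors
    (Inception-v3, ResNet152, Inception-ResNet-v2, or a compact test backbone)
    feeds a fully connected softmax head trained with cross-entropy or an
    online hard example mining (OHEM) top-k loss. Includes a seeded synthetic
    EEG generator with state-specific spectral profiles, EDF input/output,
    stratified splitting, confusion-matrix metrics, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    withr,
    jsonlite,
    png,
    EBImage,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
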