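Package: eegdecept
Title: Deception Decoding Benchmark for Low-Channel Wearable EEG
Version: 0.1.0
Authors@R: person("eegdecept", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A reproducible benchmark pipeline for lie-versus-truth decoding
    from five-channel wearable EEG (AF3, T7, Pz, T8, AF4 at 128 Hz).
    Implements the full chain: a synthetic-session generator with known
    ground truth, per-session CSV input/output, zero-phase notch and
    Butterworth band-pass filtering, wavelet-packet soft-threshold artifact
    reduction (db4), sliding-window segmentation with per-window channel
    z-scoring, three hand-crafted feature families (Welch band powers with
    Hjorth parameters and ratios; 4-level db4 DWT statistics; an extended
    spectral-statistical vector with differential entropies and frontal
    asymmetries), two compact 1-D convolutional networks (a residual SE
    network and a residual temporal convolutional network with SE and
    attention pooling, trained with focal or cross-entropy loss, MixUp and
    noise augmentation), and the two evaluation protocols: a session-disjoint
    subject-dependent overlapping sliding-window split and subject-grouped
    cross-validation with session-level score aggregation and Youden-J
    threshold calibration, plus Wilson intervals and exact binomial tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
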