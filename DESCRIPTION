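Package: virduet
Title: Duet Song Analysis for Drosophila virilis Courtship Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying acoustic duetting in Drosophila virilis
    courtship. Provides a seeded simulator of two-singer pulse-song
    recordings with ground-truth events, behavior tracks and playback
    stimuli; a wavelet-template song segmenter (continuous wavelet
    transform with a frequency B-spline mother wavelet, per-class
    template likelihoods, posterior rule cascade, pulse extraction and
    event-level scoring); bout assembly and song-structure statistics
    (inter-pulse intervals, song rates, overlap fractions, pulse
    spectra); duet response-time distributions with interval-shuffled
    nulls, bootstrap confidence bands, Kolmogorov-Smirnov comparisons
    and Kullback-Leibler divergences; Poisson rate GLMs for sensory
    manipulations; and sparse logistic history-filter GLMs predicting
    framewise song presence from annotated behaviors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    mclust,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
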