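Package: megsss
Title: Signal Space Separation, LCMV Beamforming and
    Magnetometer-Gradiometer Equivalence for MEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating multichannel magnetoencephalography (MEG)
    recordings from a Vectorview-like helmet array of magnetometer plus
    planar-gradiometer triplets, denoising them with signal space separation
    (SSS, an internal/external spherical-harmonic multipole decomposition),
    reconstructing source activity with regularized LCMV beamformers, and
    quantifying the agreement between magnetometer-only and gradiometer-only
    analysis pipelines with squared Pearson correlations, relative band power,
    phase-locking values and intraclass correlation coefficients. Includes a
    synthetic-scene generator (dipolar brain sources inside a conducting
    sphere, distant environmental interference, sensor noise) and end-to-end
    experiment drivers for regularization sweeps, whole-grid correlation
    maps, inter-pipeline reliability and evoked-field comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
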