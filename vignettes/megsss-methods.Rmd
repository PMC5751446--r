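---
title: "Signal space separation and the magnetometer/gradiometer choice: models, parameters and design notes"
author: "megsss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megsss methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package addresses

Modern whole-head MEG systems carry 102 sensor triplets, each with one
magnetometer (the field component normal to the helmet, tesla) and two
orthogonal planar gradiometers (tangential spatial derivatives of that
component, tesla/meter). After the standard signal space separation (SSS)
denoising step, should analyses use magnetometers, gradiometers, or both?
The package implements the complete computational argument that, after SSS,
the choice barely matters: both sensor types are backprojected from the
*same* small set of internal multipole coefficients, so they carry the same
spatial information up to a fixed linear map.

Everything is exercised on synthetic scenes with known ground truth, since
the underlying resting-state recordings are not public.

## The separation model

Outside all sources, the quasistatic field is curl-free and admits a scalar
potential expanded in spherical harmonics about an origin inside the head:

* internal terms `F_lm = -grad(Y_lm / r^(l+1))`, falling off away from the
  head, truncated at `L_in = 8`, giving `(8+1)^2 - 1 = 80` components;
* external terms `G_lm = -grad(r^l Y_lm)`, growing away from the origin,
  truncated at `L_out = 3`, giving 15 components.

Real orthonormal harmonics (Condon–Shortley phase, `l`-major ordering,
`m = -l..l`) are used; the implementation builds each real solid harmonic
as an exact Cartesian polynomial and differentiates it analytically, so the
basis fields are accurate to machine precision (verified in the tests
against an independent associated-Legendre / numerical-gradient route).
Monopole terms (`l = 0`) are excluded. The absolute normalization of the
basis functions is a convention; it cancels in the backprojection, so only
coefficient values depend on it.

Each basis field is passed through every channel's pickup model (normal
projection for magnetometers; a symmetric two-point difference divided by
the 16.8 mm baseline for planar gradiometers), giving the matrices
`S_in` (306 x 80) and `S_out` (306 x 15). Per sample, coefficients are
estimated jointly from all good channels by a pseudoinverse of the
whitened, column-normalized `[S_in S_out]`, and the cleaned recording is
`S_in x_in` backprojected into *all* channels. Magnetometer and gradiometer
rows of the cleaned data are therefore two linear images of one 80-dim (or
fewer) time series — the theoretical core of the equivalence claim.

### Whitening, normalization and component pruning

Magnetometer rows are divided by 3e-14 T and gradiometer rows by 3e-12 T/m
before the fit so both types contribute comparably; columns are then
normalized to unit length (scales recorded) and the pseudoinverse uses a
relative singular-value cutoff of 1e-12. Bad channels are dropped from the
fit but reconstructed by the backprojection.

A geometric fact dominates the numerics: over a helmet-shaped cap the
internal and external subspaces are *nearly collinear* (smallest principal
angle well under a degree). Without countermeasures, sensor noise projected
onto the near-degenerate directions is amplified by one to two orders of
magnitude in the separation. Production SSS implementations handle this by
estimating only the 60–80 best-conditioned internal components;
`assemble_basis(prune_condition = ...)` does the same, dropping internal
columns (never external ones) one at a time — always the column loading
most on the weakest joint singular direction — until the normalized basis
condition number is below the limit. The experiment pipeline uses
`prune_condition = 100`, which keeps about 70 of the 80 internal components
on the default array. The function default leaves pruning off so the exact
algebraic model remains available.

Because pruning makes the cleaning map a proper projection with a small
systematic forward-model mismatch, the beamformer stage uses leadfields
passed through the same cleaning map (`project_leadfield`), exactly as
forward models are compensated for active projectors in other denoising
schemes.

## Forward model

A homogeneous conducting sphere (radius 0.09 m) replaces anatomical head
models: the closed-form current-dipole field accounts exactly for volume
currents, and radial dipoles are externally silent. The source space is two
Fibonacci-lattice shells at 0.55 and 0.75 of the sphere radius (100 points
each, upper hemisphere) plus four named probe positions (visual cortex,
primary somatosensory cortex, precuneus, median cingulate) mapped from
MNI-style millimeter coordinates by a fixed affine (x 0.75e-3). The shells
stay in the upper hemisphere because, like cortex under a helmet, sources
below the sensor rim are outside the mapped field of view. Each grid point
doubles as a "region" for region-level statistics.

The helmet is a 0.12 m sphere centered 0.04 m above the source-sphere
origin, with 102 triplets on a deterministic Fibonacci lattice reaching
down to z = -0.6 of the helmet radius. The depth of coverage matters: a
shallow cap makes the internal/external separation ill-conditioned (see
above); -0.6 mirrors how far real whole-head arrays wrap around the head.

## Beamforming

LCMV filters `W = (L' C_inv L)^{-1} L' C_inv` with the covariance
regularized by trace-scaled diagonal loading
`C_reg = C + lambda (trace(C)/N) I` and inverted by pseudoinverse
(cutoff 1e-12). The 1-norm condition number of `C_reg` is recorded; it is
the diagnostic the regularization sweep is about. In the sphere model the
radial leadfield column is silent, so the 3x3 inversion runs on the
tangential subspace (leadfield singular values above 1e-6 of the largest);
silent directions get zero filter rows. The source orientation is the
dominant eigenvector of `W C W'` (maximum output power), with the sign
fixed so the largest-magnitude component is positive — source sign is
arbitrary, and downstream comparisons use squared correlations, which are
sign-invariant. Equal top eigenvalues (within 1e-12) are flagged and broken
toward the first eigenvector. Covariances are estimated from per-epoch
demeaned samples; no filtering happens inside the module.

## The synthetic study conditions

The generator's defaults *are* the study conditions; they were chosen once
as follows and then frozen.

* **Diffuse brain activity.** Every grid point carries a tangential dipolar
  source. Background sources mix a local in-band rhythm (3.5–9.5 Hz), a
  higher-frequency rhythm (10–28 Hz), 1/f broadband noise, and a rhythm
  shared across one of 24 spatial patches (amplitude shares
  0.45/0.2/0.15/0.3). Cortical activity is broadband, present everywhere
  and spatially correlated at the centimeter scale; an earlier design with
  only 20 isolated sources left most grid points carrying nothing but
  beamformer leakage, which no real brain does. The four probes carry
  stronger 9 Hz alpha plus 1/f (0.7/0.3).
* **Amplitudes.** Probe sources 0.5 nA·m RMS, background 0.13 nA·m RMS,
  each multiplied by per-(subject, source) lognormal jitter (sigma 0.3) to
  create between-subject variance. These values were calibrated once, by
  rendering, so that brain activity alone produces magnetometer peaks of
  order 20 fT — the field scale the hardware is quoted at.
* **Sensor noise** is i.i.d. Gaussian at 0.05 fT/sqrt(Hz) (magnetometers)
  and 0.05 (fT/cm)/sqrt(Hz) (gradiometers), scaled to the Nyquist
  bandwidth. Hardware floors are ~3 fT/sqrt(Hz), but real rhythms are
  hundreds of femtotesla; at the 20 fT scene scale that same floor would
  give an in-band SNR no real recording has. The floors here preserve the
  dimensionless in-band SNR regime (~10–30) of actual data, which is the
  quantity the analysis is sensitive to.
* **Interference** is 10 distant magnetic point dipoles at 2.5–4 m with
  0.5–8 Hz drifts plus a 50 Hz component. Magnetic (closed-loop) dipoles
  rather than open current elements, because an isolated current element's
  field is not curl-free and hence not representable in the harmonic
  expansion SSS assumes — it would leak through the separation no matter
  what. The "high" level (1e-5 A·m^2) is calibrated so the magnetometer
  max-amplitude ratio before/after SSS exceeds 5; "low" is ten times
  weaker.
* **Protocol.** 1000 Hz sampling, 6 s epochs, 2-minute default recordings
  (the reliability cohort uses 60 s and the evoked scene 64 one-second
  trials from -0.1 to 0.9 s). The evoked response is a pair of occipital
  Gabor-like responses peaking near 100 ms; the two differ in latency
  (95/115 ms) and carrier (8/10 Hz) as bilateral responses do — and
  because perfectly coherent pairs are mutually cancelled by a
  minimum-variance beamformer.

Rendering superposes exact forward fields of all sources with their
waveforms and is bit-exact given the scene seed; component subsets
(`internal` / `external` / `noise`) always reproduce the same realization.

What the generator does *not* emulate: physiological artifacts (ocular,
muscle, cardiac), head movement, sensor calibration errors, non-Gaussian
noise, and anatomical variation in source depth or orientation geometry.
Passing tests therefore demonstrate the internal consistency of the
SSS/beamforming argument under controlled conditions, not robustness to
every failure mode of real recordings.

## The comparison statistics

Squared Pearson correlations between magnetometer-derived and
gradiometer-derived source series are computed per 6 s epoch and then
averaged (plain averaging, not Fisher-z; the choice only matters at the
third decimal here). Relative band power uses Hamming-tapered Welch
spectra at 1 Hz resolution (the "multitaper with Hamming windows" phrasing
in the field maps onto single-taper segment averaging, since Hamming is not
a Slepian family), with delta/theta/alpha/beta powers normalized to total
2–30 Hz power — the four bands partition that range, so rows sum to one.
Phase locking uses the analytic signal of the band-filtered series per
epoch. Inter-pipeline reliability is ICC(1,1) from the one-way ANOVA mean
squares across (subject x region) targets; negative estimates are reported
as computed. The regularization sweep fits
`log10(lambda_grad_max) = a log10(lambda_mag) + b` by ordinary least
squares, restricted to `lambda_mag > 0.01` where the relation is near
linear; argmax ties break toward the smaller lambda (less added noise).

The FIR bandpass is a Hamming windowed-sinc of order 1000 applied by FFT
convolution with exact group-delay compensation (zero phase); half the
filter order is trimmed from each end before any statistic. At the band
edges the design has the usual -6 dB point, which is irrelevant downstream
because both sensor pipelines share the identical filter.

## Problem sizes and scales

Cohort sizes were chosen once: 8 subjects x 2 min for the regularization
equivalence comparison, 12 subjects x 60 s for reliability, 4 subjects x
2 min for the whole-grid map, 64 trials for the evoked comparison. The test
suite runs reduced versions of some of these (3 subjects x 60 s for the
probe comparison, 30 s reliability recordings); `scripts/acceptance.R` runs
the full versions.

## Known limitations

* At a handful of weak, deep grid points the projected power ellipse is
  nearly circular and the maximum-power orientation pick becomes a coin
  flip between nearly orthogonal directions; when the two sensor pipelines
  flip differently, that point's r^2 collapses even though a shared
  orientation would give r^2 > 0.95. This is why the whole-grid map's
  strict minimum sits near 0.7 rather than above 0.8: real cortical data
  evidently pins a dominant orientation everywhere, while lognormal
  amplitude jitter on a sparse synthetic grid occasionally does not. The
  map's median and 95th-percentile floor do clear 0.8.
* The conducting-sphere forward model has no anatomical validity; probe
  "MNI" coordinates are placements, not anatomy. None of the equivalence
  arguments depend on it.
* The lambda sweep covers 80 log-spaced points in [1e-4, 1] as a full
  surface only when asked; drivers default to the specific lambda pairs
  under study because an 80 x 80 surface per subject is an expensive
  figure, not a result.
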