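---
title: "Models and methods behind fretx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretx)
```

# Scope

`fretx` simulates and analyzes three single-molecule fluorescence assays
used to study ATP-independent displacement of the single-stranded-DNA
binding protein drSSB from ssDNA by the recombination mediator drRecO:

1. diffusion-based ALEX-FRET burst measurements of freely diffusing
   donor/acceptor-labeled ssDNA;
2. surface-tethered TIRF time traces of individual ssDNA molecules during
   protein exchange;
3. two-color colocalization of tethered ssDNA with labeled protein.

Because no raw data accompany the measurements the package models, every
generator is parameterized by the published values (peak positions,
dissociation constants, rates, percentages) and records its ground truth,
so the analysis pipelines can be validated by parameter recovery.

# ALEX burst model

## Photon splitting

A burst of $N$ photons from a molecule with FRET efficiency $E$ and
stoichiometry $S$ is split as nested binomials:
$N_{Dex} \sim \mathrm{Binom}(N, S)$ photons under donor excitation, of
which $I_{DA} \sim \mathrm{Binom}(N_{Dex}, E)$ arrive in the acceptor
channel and $I_{DD} = N_{Dex} - I_{DA}$ in the donor channel; the
remaining $I_{AA} = N - N_{Dex}$ photons are acceptor-excitation,
acceptor-emission counts. The estimators are then exactly the count
ratios the analysis computes:

$$E = \frac{I_{DA}}{I_{DD} + I_{DA}}, \qquad
  S = \frac{I_{DD} + I_{DA}}{I_{DD} + I_{DA} + I_{AA}}.$$

Species parameters $(E, S)$ per burst are drawn from truncated normals on
$[0, 1]$ (inverse-CDF sampling), species identity from a multinomial over
the configured fractions, and burst size from a shifted Poisson with a
floor of 20 photons (a log-normal option exists). No gamma factor,
spectral leakage or direct excitation is modeled: the package works in
*apparent* E and S throughout, which is also how the measured peak
positions (0.09 / 0.58 / 0.78 for free, SSB-bound and RecO-bound ssDNA)
are quoted.

## Why the default burst size is 300 photons

For a burst of mean size $N$ with $S = 0.5$, counting statistics alone
add a binomial width $\sqrt{E(1-E)/(N/2)}$ to the E histogram — about
0.07 at $N = 100$, i.e. as large as the configured species width. In
that regime a least-squares sum-of-Gaussians decomposition recovers
visibly biased means (the donor-only/free peak is pulled toward 0, the
others away from it). The species `eSd` parameter is defined as the
histogram width, so the default `burstSizeMean = 300` places the
generator in the bright-burst regime where shot noise
($\approx 0.03$–$0.04$) is subdominant and the configured widths describe
the histogram. Simulations targeting shot-noise-limited conditions can
lower it explicitly.

## Background

`backgroundRate` is expressed as photons per 0.6 ms bin and channel. In
count-level mode each burst receives Poisson background for a nominal
two-bin transit (a typical ~1 ms diffusion transit versus the 0.6 ms
binning). In stream mode (`returnStream = TRUE`), photons are placed in
alternation-consistent 100 µs half-cycles and background arrivals are
uniform over the acquisition.

## Histogram decomposition and gating

Burst search thresholds fixed 0.6 ms bins on total counts and merges
contiguous hot bins; donor-emission photons under acceptor excitation are
discarded as the ALEX optics discard them. The S-gate `0.25 < S < 0.75`
(strict) removes donor-only and acceptor-only molecules.
`fitFretHistogram()` bins gated E values (default bin width 0.02) and
fits a sum of Gaussians with `minpack.lm::nlsLM`, k-means-initialized;
component *area* is converted to burst counts so population fractions are
area shares. `method = "mixture"` provides an independent maximum-
likelihood cross-check via `mclust`. A degenerate input (all values
identical) returns the exact mean with the width pinned at half a bin.

## Equilibrium and kinetic fits

Titration curves follow the Hill isotherm
$\theta(C) = C^n / (K_d^n + C^n)$; binomial noise enters as
`rbinom(burstsPerPoint, theta)/burstsPerPoint`, which is exactly the
bound-fraction estimator's sampling law. `fitKd()` fits with
concentration-count weights, starts at the 0.5-crossing, reports the
half-saturation property $\theta(K_d) = 0.5$, and flags curves that never
cross half-saturation as `extrapolated_kd`.

Exchange kinetics follow the single-exponential relaxation
$f_{ssb}(t) = f_\infty + (f_0 - f_\infty) e^{-kt}$ expected for
pseudo-first-order exchange under excess competitor; the fitted
`halfLife` is $\ln 2 / k$. Two guards protect against over-reporting:
a flat series (range below 3 binomial standard errors) and, after the
fit, an insignificant relaxation amplitude ($|f_0 - f_\infty| \le 2\,
\mathrm{SE}$ from the fit covariance) both return rate 0 with the
`no_exchange` flag. The second guard exists because the sample range of
a dozen flat noisy bins typically *exceeds* 3 standard errors, so a
range screen alone lets spurious slow decays through.

# TIRF trace model

## Generator

State paths are sampled with the Gillespie algorithm from the configured
continuous-time Markov chain; before `injectionTime` the molecule is held
in its initial state (protein not yet added). Each trace draws its state
FRET values from $N(e_{mean}, e_{sd})$ once (molecule-to-molecule
heterogeneity), then renders donor/acceptor intensities at fixed total
intensity with Gaussian channel noise at 0.1 s frames. Donor and
acceptor photobleaching are exponential; acceptor bleaching returns the
full intensity to the donor channel, donor bleaching darkens both.
The continuous path, state E values and bleach times are stored in
`metadata` as ground truth.

`simulateDisplacementEnsemble()` builds the displacement experiment:
SSB-bound (MID, E = 0.6) molecules that, after injection, either never
convert (`pNoBinding`), convert directly to RecO-bound (HIGH, E = 0.8),
or pass through the LOW (E = 0.2) SSB–RecO–ssDNA intermediate with
probability `pIntermediate` (default 0.015, i.e. below the 2% bound
observed for dT70). Binding waits are exponential in `kBind`.

## Segmentation and classification

`segmentStates()` assigns each frame to the nearest level center within
`halfWidth` (default 0.12), marks frames with no nearby level
`UNASSIGNED` and dark frames `BLEACHED`, and iteratively merges runs
shorter than `minDwellFrames` (default 3) into their left flank. With the
default centers 0.2/0.6/0.8 the 0.12 half-windows of adjacent levels
overlap; nearest-center assignment resolves the overlap, so the validity
requirement is separation greater than `halfWidth`, not twice it.
Dwells touching the trace edge or a bleach are flagged censored;
`fitDwellRate()` excludes them by default (rate = reciprocal mean
lifetime, the exponential MLE) or uses the right-censored MLE
(events / total observed time).

Classification applies ordered rules to the post-injection dwell
sequence: no HIGH and no LOW is `NO_BINDING`; LOW without HIGH is
`INTERMEDIATE_RETURN`; a single terminal HIGH entry is
`DISPLACEMENT_DIRECT` (no LOW visit) or `DISPLACEMENT_VIA_INTERMEDIATE`;
anything that re-enters or leaves HIGH is `MULTI_TRANSITION`.
`classificationSummary()` counts categories; the displacement total is
direct + via-intermediate. One known limit: an intermediate dwell
shorter than the 3-frame segmentation resolution (probability
$1 - e^{-0.3 k_{exit}}$) is invisible, so a small fraction of
via-intermediate traces are reported as direct — an inherent
discretization effect, not noise.

Association kinetics use the reciprocal-mean estimator
$k_{obs} = 1/\overline{t}$ per concentration and a weighted linear fit of
$k_{obs} = k_a C$ through the origin.

# Colocalization model

Pairs lose the acceptor partner at the first of two competing
exponentials — photobleaching ($k_b$) and dissociation ($k_d$) — so the
both-present fraction at the 4.5 min (270 s) evaluation point factorizes
as $e^{-(k_b + k_d) t}$. Dividing by a no-treatment control
($e^{-k_b t}$) removes the bleaching term exactly, which is the
justification for `bleachingCorrectedFraction()` and is verified as a
property over a $(k_b, k_d)$ grid in the tests. Image mode renders
Gaussian PSF spots (channel B rigidly offset) with Poisson noise;
`detectSpots()` uses median/MAD thresholding, 3×3 local maxima and
centroid refinement, and `pairChannels()` performs greedy one-to-one
nearest-neighbor matching after removing the registration offset.

# File formats

Photon data use a columnar-text container (TSV with `timestamp`,
`excitation_phase`, `detection_channel` plus a JSON sidecar for the
alternation period and duration), keeping photon-HDF5 field naming in an
installation without an HDF5 stack. Trace tables are long-format CSV
with a JSON sidecar of per-trace metadata; ground-truth columns are
named as such (`state_truth`) and never read by analysis functions.
Images are 16-bit multi-page TIFF. Every CLI run writes a JSON report
with the package version, seed, configuration and filter-stage counts.

# Problem sizes

Default scales run on one CPU in seconds: 10⁴ bursts, 100–1000 traces of
3000 frames, thousands of colocalization pairs, 64×64 image frames.
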