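---
title: "Models and methods for live-cell transcription imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for live-cell transcription imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txspot)
```

txspot quantifies transcription dynamics at single gene loci imaged in
living cells with stem-loop reporter systems: a DNA label (a fluorescent
Tet repressor bound to a TetO repeat knocked in near the transcription
start site) marks the locus position, while coat-protein fusions (MCP,
PCP) bound to MS2/PP7 stem-loops on the nascent RNA report transcriptional
activity. This vignette explains the statistical models the package
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices behind the fits.

## The two-state promoter and the dual-reporter model

Transcription at most genes is bursty: the promoter switches between an
ON state, during which polymerases initiate, and a quiescent OFF state.
`simulate_telegraph()` implements the standard telegraph model — a
two-state continuous-time Markov chain with switching rates `k_on`,
`k_off` (per minute) and a Poisson initiation process at rate `k_init`
while ON. Dwell times are drawn exactly (Gillespie) and only then
discretized onto the sampling grid, so the discrete state trace carries no
time-step bias; the stationary ON fraction is `k_on / (k_on + k_off)`.

The study system this emulates does not come with published burst rates;
the package defaults (`k_on = 0.1`, `k_off = 0.5`, `k_init = 2` per
minute, used by the `xcorr` pipeline) were chosen once as plausible
embryonic-stem-cell scales — a burst every ~10 min lasting ~2 min with a
handful of initiations — and the elongation-delay analysis below is
insensitive to them.

`simulate_reporter_pair()` converts initiation times into the two
reporter intensity traces. Each initiated polymerase lights the
TSS-proximal (MCP) channel essentially at its initiation time and reaches
the 3'UTR (PCP) cassette `separation_kb / rate` minutes later. Each tag's
signal then persists for an exponential residence time (mean `dwell_min`,
default 3 min): the TSS-proximal repeat is carried on an intron that is
spliced out and degraded, while the 3'UTR repeat leaves with the released
transcript, so each tag has its own finite residence rather than lasting
until termination. The same residence draw is used for both tags of a
transcript. This choice is deliberate: a model in which the TSS-proximal
signal lasts until the polymerase reaches the 3' end makes that signal's
support a superset of the PCP signal's, the single-transcript
cross-covariance is then *flat* over lags `[0, delay]`, and the
cross-correlation argmax collapses toward half the delay. With per-tag
residence the PCP trace is an exact time-shift of the MCP trace and the
population cross-correlation peaks at the elongation delay — which is the
structure observed in dual-reporter experiments.

`ccf_average()` computes, per cell, the Pearson-normalized
cross-correlation (traces mean-subtracted and SD-normalized over their
full length; each lag's product sum divided by the number of overlapping
samples, which removes the edge bias of short overlaps), then averages
across cells with a 95% band `mean ± 1.96·SEM`. Positive lag means the
3'UTR trace lags the TSS-proximal trace. `delay_and_rate()` reads the
peak lag (optionally parabola-refined over the three points around the
discrete peak) and divides the genomic tag separation by it: an 11.2-kb
separation with a 4-min peak lag gives an elongation rate of 2.8 kb/min.

## Locus mobility: MSCD and anomalous-diffusion MSD

Two complementary statistics describe chromatin locus motion:

* **MSCD** (`mscd_curve()`), the mean square change in distance: with
  `d(t)` the Euclidean distance between the locus and the nuclear centre
  of mass, `MSCD(Δt) = <[d(t) − d(t+Δt)]²>` over all time pairs. Using
  the distance *to the nuclear centre of mass* cancels rigid whole-nucleus
  motion — the package tests this invariance explicitly. 2D or 3D
  coordinates are used according to input dimensionality (z-stacked
  imaging supports 3D; single-plane imaging is 2D).
* **MSD** (`msd_curve()`, `msd_fit()`): time-averaged MSD per track, then
  an unweighted ensemble average, fitted with the anomalous-diffusion
  model `MSD(t) = 4 D_α t^α` over lags up to 66 steps (2 s at 30-ms
  frames). The default fit is linear least squares on `log MSD` vs
  `log t`, which linearizes the two-parameter power law and weights
  relative errors equally; a natural-scale nonlinear option is available.
  No localization-noise offset is fitted — the model deliberately has two
  parameters — so appreciable localization error biases `α` downward at
  short lags; this is a documented limitation, and the generator lets you
  quantify it by setting `localization_sigma_nm`.

Sub-diffusive tracks (`α < 1`) are generated by `simulate_locus_track()`
from exact fractional Gaussian increments (Hurst exponent `α/2`) using the
Davies–Harte circulant embedding, so the ensemble MSD follows the target
power law at every lag without ad-hoc rescaling.

Tracks come from `link_tracks()`: greedy nearest-neighbour linking within
a search radius (default 2 px), tolerating gaps up to a memory (default 4
frames), with ties broken by smaller displacement and then a deterministic
spot order; tracks are kept only if detected in more than 50 consecutive
frames (all three values are the standard particle-tracking settings for
this assay and are parameters).

## Spot detection, measurement and state calling

`detect_and_refine()` finds local maxima above a threshold (exact-tie
plateaus resolve to the lowest (row, col) position), suppresses weaker
maxima within a minimum separation of a stronger one (camera noise can
split one diffraction-limited spot into adjacent maxima), and refines each
candidate by least-squares fitting a 2D isotropic Gaussian plus constant
offset in a square window. Two numerical guards matter in crowded fields:
candidates whose window would cross the image border are dropped rather
than padded (padded fits bias the centre), and the fitted centre is bound
to within roughly a spot radius of its candidate pixel so the optimizer
cannot latch onto a brighter neighbour inside the window. Fits that fail
fall back to the background-subtracted centroid with a flag.

Measurements follow the conventions of the assay: spot intensity is the
mean over a disk of radius 6 px around the sub-pixel centre
(`measure_spot()`), expressed relative to the nuclear mean; the
signal-to-noise ratio is the spot mean over the nuclear intensity SD
(`compute_snr()`); nuclear foci are counted by topographic prominence
(`count_foci()`), implemented as the h-maxima transform — grayscale
reconstruction of `image − prominence` under the image — followed by
regional maxima that retain a strictly lower neighbour (an all-flat
region is not a maximum).

Transcriptional state is called by three threshold rules
(`classify_snapshot_or_trace()`, `classify_rf_frame()`):

| rule | ON condition | default threshold |
|---|---|---|
| snapshot | relative intensity ≥ t | 3 |
| trace | any frame's relative intensity ≥ t | 5 |
| rf_proximity | an MCP spot within 390 nm of the anchor AND disk mean > 2× the 19×19-window mean | 390 nm, 2-fold |

Boundary conventions are literal: "3 or higher" is `≥`, "within 390 nm"
is `≤`, "greater than two-fold" is strict `>`. Every call records its
rule, thresholds and the deciding measurement, so calls can be re-audited
from raw numbers. The fold reference defaults to the anchored-window mean;
passing the nuclear mean instead is a one-argument change. The fixed
thresholds are defaults derived from intensity-histogram valleys;
`intensity_valley()` re-derives them from data when wanted.

## FRAP

Recovery curves are normalized to the pre-bleach mean
(`normalize_frap()`, time zeroed at the first post-bleach frame) and
fitted with `I(t) = baseline + f_mobile·(1 − exp(−t/τ))`
(`fit_frap()`), where `baseline` is the expected normalized intensity
immediately after the bleach, `f_mobile` the mobile fraction and `τ` the
recovery time constant (seconds). The fit multi-starts τ at
{5, 20, 50, 150, 400} s — spanning fast-dissociating (~26 s) and
slow-dissociating (~107 s) DNA-binding regimes — and keeps the converged
start with the smallest sum of squared offsets `S`. Constant curves are
flagged as τ-unidentifiable rather than fitted. When two conditions share
a bleached species whose post-bleach floor should be common,
`joint_baseline()` scans a baseline grid (default 0–0.8 by 0.01), fits
both per-condition *mean* curves with the baseline fixed at each grid
value, and returns the argmin of `S_a + S_b`; per-cell fitting is
available but averaging before fitting is the default, matching standard
practice for noisy single-locus FRAP.

## Cluster distances, smFISH and ChIP-qPCR

`nearest_distance()` converts sub-pixel coordinates to nm (130 nm/px
default) and reports the 2D distance from the DNA-label anchor to the
nearest factor cluster; only the nearest cluster is analyzed by default.
`stratified_comparison()` compares groups (short vs long distance around
350 nm, or ON vs OFF) with a two-sided Wilcoxon rank-sum test — exact by
full enumeration (midranks for ties) when the combined n ≤ 20, the
tie-corrected normal approximation otherwise. Records exactly on the
350-nm boundary go to the *short* group; the choice is recorded in the
result. `cluster_fwhm()` averages equally sized ROIs pixel-wise, fits a
circular Gaussian with offset and reports `FWHM = 2√(2 ln 2)·σ`.

`quantify_smfish()` calibrates the single-molecule unit intensity as the
median integrated intensity of non-transcription-site spots. Because
transcription sites (TS) are themselves defined through the unit (nuclear
spots of ≥ 3 rounded molecule equivalents), the unit is obtained by a
short fixed-point iteration starting from the median of all spots; in
realistic data single molecules dominate and the iteration converges
immediately. Cells are classed No/Mono/Bi by TS count, with > 2 flagged.
`chip_percent_input()` evaluates
`%input = 2^((Ct_input − 5.64) − Ct_sample) × 100`; the constant 5.64 is
the conventional correction for a 20% input fraction and its dilution and
is a parameter, not re-derived.

## The synthetic-microscopy generator

`ground_truth_scene()`/`render_scene()` render diffraction-limited spots
as 2D isotropic Gaussians evaluated at pixel centres, on a constant
background, with Poisson shot noise followed by additive Gaussian read
noise (both optional and seed-controlled). Pixel indices are 0-based and
a coordinate maps to nm as `130·(r, c)` from the centre of pixel (0, 0).
`simulate_cluster_scene()` builds two-channel anchor/cluster fields in
which the anchor-to-nearest-cluster distance is log-normal with an exact
configured median (default dispersion 0.5 on the log scale) and decoy
clusters are placed strictly farther, clear of borders and of each other.

What the generator deliberately does **not** emulate: 3D point-spread
functions (all rendering is single-plane), spectral bleed-through between
channels, reporter photobleaching (bleach correction is tested on
synthetic exponential decay applied post hoc), nuclear heterogeneity and
autofluorescence texture, and overlapping same-channel emitters closer
than the suppression radius. Tests passing on these scenes therefore
validate the estimators under their stated models — localization accuracy,
distance-median recovery, parameter recovery — not robustness to every
artefact of real microscopy.

## Problem sizes and reproducibility

The test suite scales the heavier simulation checks to run in about a
minute: diffusion-law checks use 2,000–4,000 tracks of 40–150 frames,
ensemble-bias checks 20 replicate ensembles of 50 tracks, the
distance-recovery checks 250 scenes per state, and the end-to-end
acceptance checks use 50 FRAP curves, 100 tracks × 400 frames, 20
reporter cells and 1,000 rendered scenes. All stochastic stages take
explicit integer seeds; the pipeline runner expands a single root seed
deterministically per stage, so identical configurations produce
byte-identical outputs.

## Known limitations

* The MSD fit has no localization-noise offset term (two-parameter model
  by design); with large localization error prefer reporting the fit
  window used and treat `α` near short lags with caution.
* The rolling-ball background is realized as a grayscale opening with a
  disk element — the standard deterministic equivalent of the named
  procedure, but not bit-identical to every legacy implementation.
* Simple-ratio bleach correction assumes the masked region's true mean is
  stationary; recovery inside the bleach spot violates this mildly.
* Auto-segmentation of nuclei (Otsu + hole filling + area filter) is a
  fallback for synthetic and high-contrast data; externally produced
  label masks are the intended input for real images.
* Linking is greedy nearest-neighbour, appropriate for the sparse
  (one-spot-per-cell) fields of this assay, not for dense fields where
  global assignment would be required.
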