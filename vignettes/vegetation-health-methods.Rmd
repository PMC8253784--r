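---
title: "Vegetation health indices, drought statistics and ENSO teleconnection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation health indices, drought statistics and ENSO teleconnection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhitools)
```

## The problem

Operational drought monitoring from polar-orbiting satellites rests on two
weekly observables: the Normalized Difference Vegetation Index (NDVI), a
proxy for green biomass, and the thermal-band brightness temperature (BT), a
proxy for canopy heat load. After noise removal these become the smoothed
series SMN and SMT, which are rescaled against their local multi-year
envelope into the Vegetation Condition Index (VCI, moisture), the
Temperature Condition Index (TCI, thermal stress; hot maps to low) and their
combination, the Vegetation Health Index (VHI):

$$\mathrm{VCI} = 100\,\frac{\mathrm{SMN}-\mathrm{SMN}_{\min}}{\mathrm{SMN}_{\max}-\mathrm{SMN}_{\min}},\qquad
\mathrm{TCI} = 100\,\frac{\mathrm{SMT}_{\max}-\mathrm{SMT}}{\mathrm{SMT}_{\max}-\mathrm{SMT}_{\min}},\qquad
\mathrm{VHI} = a\,\mathrm{VCI} + (1-a)\,\mathrm{TCI}.$$

The weight defaults to $a = 0.5$: the relative share of moisture and thermal
stress in total vegetation health is unknown for a given place and week, so
equal weighting is the conventional choice. VHI bands then classify
condition — drought intensities are nested upper-bound classes
(D4: VHI < 5, D3–D4: < 15, D2–D4: < 25, D1–D4: < 35; stress: < 40), and
normal/favorable conditions occupy 40–60 and > 60. From a VHI cube the
package derives percent-area-affected series, per-band mean value and
duration, regional drought events, trend estimates (OLS, Mann–Kendall,
Sen's slope), and linear plus wavelet-based teleconnections with an ENSO
index.

This vignette documents the modelling choices; nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The calendar and the climatology envelope

A year is exactly 52 weekly composites (the day-365/366 remainder of a real
calendar is dropped); all climatology is keyed to calendar weeks 1–52.

The operational product defines the envelope as the "multi-year absolute
maximum and minimum" of SMN/SMT. That wording supports two readings: an
envelope per calendar week, or one envelope per pixel over the whole record.
We default to the per-calendar-week envelope — the standard vegetation-health
practice, and the one that makes VCI an anomaly relative to the seasonal
climatology rather than to the raw seasonal cycle — and expose the
whole-record alternative behind `climatology_extrema(per_week = FALSE)`.

Two consequences of the per-week envelope are worth keeping in mind:

* **Degenerate pixels.** Where max = min (e.g. a noise-free constant series)
  the ratio is undefined; such cells are masked, never divided.
* **A climatological base rate.** At every non-degenerate pixel-week the
  multi-year VCI values span exactly [0, 100] (one year attains each
  endpoint), so even an episode-free record places a substantial share of
  pixel-weeks below any fixed VHI threshold. Drought statistics on these
  indices measure *relative* (rank-like) anomalies, not absolute deficits;
  tests of the episode-injection ground truth therefore check the *excess*
  area over the measured background rate rather than assuming a quiet
  background.

## Smoothing stand-in

The operational noise removal of NDVI/BT is empirical and unpublished in
detail. The package uses a documented stand-in: per-pixel median-of-3
despiking followed by a centered triangular-weight moving average (default
window 5 weeks), with the kernel renormalized over valid neighbours at
edges and gaps, and the validity mask propagated. The symmetric kernel
reproduces linear segments exactly away from edges and removes isolated
one-week spikes; it does not emulate orbital-drift artefacts or the
operational empirical-distribution corrections. At the first/last
half-window of the record the truncated kernel makes the edge year differ
slightly from interior years at the same calendar week, which is why
envelope-based tests exclude the outermost two calendar weeks of the record
edges.

## Drought bands, events, and the boundary convention

The printed band table leaves VHI exactly 40 and 60 unclassified ("40 < VHI
< 60"). We close the bands as stress = [0, 40), normal = [40, 60],
favorable = (60, 100] so the three top-level bands partition [0, 100];
the D-classes are implemented as the cumulative intervals exactly as
printed (D1–D4 means VHI < 35), with disjoint slices derivable by
subtraction. Percent-area denominators count valid (unmasked) pixels only.

Regional events are maximal runs of consecutive weeks with regional-mean
VHI strictly below 40, with inclusive duration — a series below 40 for
weeks 23–32 is one event of 10 weeks. Early warnings flag weeks where
regional TCI has declined strictly monotonically for at least 4 weeks while
VHI is still at or above 40, reflecting that thermal stress typically
builds before the composite index crosses into drought.

## Growing season

Fixed SMN thresholds define the season: onset at the first step reaching
0.20, senescence at the last step at or above 0.25. The thresholds are
stated without crossing semantics, so two conventions are ours: onset
requires the threshold to hold for ≥ 2 consecutive steps (a single-week
green-up blip must not start the season), and the end is searched at or
after the seasonal peak (a winter blip cannot terminate it). Raising either
threshold can only shrink the season — a property the tests exercise.

## Trend estimation

Three estimators are run side by side, with time in fractional years so all
slopes are per year: the OLS fit of $y_t = a + bt + e_t$; the Mann–Kendall
test on $S=\sum_{i<j}\operatorname{sign}(y_j-y_i)$ with tie-corrected
variance, a ±1 continuity correction and a two-sided normal p-value
(the test is named in the source analysis without a variant; this is the
standard textbook form, without prewhitening — documented rather than
configurable); and Sen's slope, the median of all pairwise slopes, which
equals the OLS slope exactly on noiseless lines and is insensitive to
outliers. Per-pixel trend maps apply no multiple-testing correction by
default, matching the per-grid 5% significance maps of the source analysis;
a Benjamini–Hochberg flag is available.

## Wavelet machinery

The continuous transform uses the Morlet mother wavelet with
$\omega_0 = 6$ over dyadic scales $s_0 2^{j\,\delta j}$ with
$s_0 = 2\,\mathrm{d}t$, $\delta j = 1/12$, and a maximum scale of one third
of the record, computed in Fourier space with zero-padding to the next
power of two. The cone of influence (COI) uses the $\sqrt2 s$ e-folding
convention; all headline statistics are reported for in-COI cells only.

The cross spectrum is $W^{XY}=W^X \overline{W^Y}$; its argument is the
relative phase (0 in phase, ±π anti-phase). Coherence is

$$R_n^2(s)=\frac{\bigl|S\langle s^{-1}W_n^{XY}(s)\rangle\bigr|^2}
{S\langle s^{-1}|W_n^X(s)|^2\rangle\, S\langle s^{-1}|W_n^Y(s)|^2\rangle},$$

where the smoothing operator $S$ is a Gaussian of standard deviation $s$
along time composed with a boxcar of 0.6 octaves along scale — the Morlet
decorrelation length, in the convention of the standard cross-wavelet
toolbox lineage. (Published restatements of these equations sometimes swap
the axis labels of the two smoothers; the axis assignment used here is the
one under which the 0.6 constant is defined, and it guarantees
$R^2\in[0,1]$ by the Cauchy–Schwarz inequality and $R^2(x,x)\equiv 1$.)
The scale boxcar uses whole scale bins (`round(0.6/dj)`), a simplification
of the fractional end-bins some implementations carry.

Significance is Monte-Carlo: AR(1) surrogate pairs matching each series'
lag-1 autocorrelation and variance (estimates ≥ 1 fall back to 0.99 with a
warning), with a per-(scale, time) 95th-percentile threshold from a seeded
surrogate ensemble (default 300 pairs). Because the null is simulated from
the same family as the test, the false-positive rate of the mask over the
in-COI region is calibrated near 5%, which the acceptance suite measures
with 500 surrogate pairs at n = 512. Phase summaries follow the convention
of drawing phase arrows only where coherence exceeds 0.5 — we read the
ambiguous "arrows when phase difference exceeds 0.5" of the source
analysis as a coherence threshold, the toolbox convention.

## The synthetic generator

No archive accompanies the analysis, so a seeded generator produces inputs
with the structure the method assumes. Per pixel,

$$\mathrm{NDVI}_t = \underbrace{0.255 + 0.145\cos\tfrac{2\pi(w_t-32)}{52}}_{\text{annual harmonic}}
 + \beta_{\mathrm{NDVI}}\,t + \mathrm{AR1}_t - \text{episodes},$$

clipped to [−1, 1] after episode injection (clips are counted in the run
log), and analogously for BT (mean 13 °C, amplitude 15.5 °C, peak week 28,
episode anomalies of opposite sign, plus an optional coupling
$\kappa\,\mathrm{ENSO}_t$ shared by all pixels). The NDVI harmonic is
calibrated to the regional climatology the analysis describes — winter
values near 0.11 and an early-August (week 32) peak near 0.40. The noise is
weekly AR(1) with coefficient 0.6 and marginal sd 0.02 NDVI / 0.8 °C; the
source analysis states no variances or autocorrelations, so these are the
package's own choices of a plausible weekly composite, fixed once and
exposed in `synthetic_config()`. The ENSO-like index is zero-mean AR(1)
(coefficient 0.9, marginal sd 0.5) plus a 4-year sinusoid of amplitude 0.8,
giving the interannual band power a real index has. Missing data are
exactly `round(missing_fraction × n_cells)` uniformly sampled cells.

Episode pixels are the first `round(extent × n_pix)` pixels in row-major
order — deterministic and outside the RNG stream, so a with/without-episode
pair under the same seed differs only by the injected anomaly, which the
difference-based oracles in the tests rely on.

What the generator does *not* emulate: spatially correlated noise fields,
radiative-transfer or orbital-drift artefacts, non-sinusoidal phenology,
double-cropping seasons, and spatially structured missingness. Passing
tests therefore demonstrate correctness of the computational chain and its
statistical calibration under the stated stochastic model, not fidelity to
any particular real archive.

## Problem sizes and numerical choices

The tests and the acceptance script run the chain at desk scale, chosen as
the smallest sizes at which each property is sharply testable: grids of
3×3 to 8×8 pixels over 3–10 years for the index/drought/teleconnection
chain; 10,000 white-noise series of length 35 (one value per year of a
35-year record) for the Mann–Kendall size experiment; and n = 512 with 500
surrogate pairs for the coherence calibration. Tolerances follow the
quantity: machine precision where arithmetic is exact (index endpoints, VHI
combination, event bookkeeping), 1e−9 for smoothed-coherence bounds, ±1
percentage point around the 5% Mann–Kendall size, ±2 points for the
coherence false-positive rate (a Monte-Carlo quantity with spatially
correlated cells), and ±0.15 rad for the analytic quarter-period phase.

I/O uses plain-text formats throughout: cubes as long-format CSV with
`#key=value` headers, index series as two-column CSV, run manifests as
JSON. Readers validate the weekly time axis and report missing weeks by
index.

## Known limitations

* The smoother is a stand-in; operational SMN/SMT will differ in detail.
* Rank-normalized indices cannot separate "drier than usual" from "dry":
  absolute drought severity requires external calibration.
* The wavelet significance test assumes AR(1) nulls; strongly non-AR(1)
  series (e.g. long-memory processes) will mis-calibrate.
* Event detection is regional-mean based; spatially compact droughts that
  never depress the regional mean below 40 are invisible to it (the
  percent-area series are the per-pixel complement).
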