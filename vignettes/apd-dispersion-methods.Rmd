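---
title: "Methods: APD dispersion mapping, pattern classification and phase analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APD dispersion mapping, pattern classification and phase analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apdmapr)
```

## The problem

Spatial heterogeneity of repolarization — neighbouring myocardium with
different action potential durations (APD) — creates the substrate for
unidirectional block and reentry, the mechanism behind atrial and
ventricular fibrillation. In voltage-dye optical mapping, a high-speed
camera records fluorescence proportional to membrane potential at thousands
of sites simultaneously (here the reference acquisition geometry is 1,000
frames/s, 100 × 100 pixels, 0.095 mm/pixel, 4–5 s recordings), so
repolarization heterogeneity can be quantified pixel by pixel.

`apdmapr` implements that quantification end to end:

1. per-pixel **APD maps** at a configurable repolarization level,
2. windowed **std(APD) dispersion maps** and max−min **gradient maps**,
3. **binarization** at a dispersion threshold (default 10 ms) with
   supra-threshold **area-fraction** quantification and island
   morphometry,
4. a **spatial-pattern classifier** that assigns the island arrangement to
   one of three archetypes — *uniform* (evenly spaced), *random*
   (unpredictable), *clustered* (patchy archipelagos) — using quadrat,
   nearest-neighbour and autocorrelation statistics,
5. **dominant-frequency, phase and phase-singularity** analysis for
   fibrillation recordings, and
6. a **synthetic movie generator** that provides exact ground truth for
   every stage.

## The dispersion statistic

Dispersion at pixel $(i,j)$ is the population standard deviation of APD
over a centred $w \times w$ window (default $w = 10$ px, i.e. ~1 mm of
tissue at 0.095 mm/px):

$$D_{ij} = \sqrt{\tfrac{1}{n}\sum_{(k,l) \in W_{ij}} (A_{kl} - \bar A_{ij})^2}$$

Conventions that make the maps bit-reproducible:

* stride-1 sliding window (per-pixel maps, matching the smooth published
  map style); a tiled variant is not offered because overlapping windows
  strictly dominate it for localization;
* **population** (divide-by-$n$) standard deviation: the window is a
  fixed descriptive neighbourhood, not a sample from a larger population;
* even window widths place the extra row/column on the bottom/right;
* a pixel is reported only when at least 50% of its window holds valid
  in-mask APDs — this stops tissue-edge curvature from fabricating border
  dispersion;
* binarization is strict (`> threshold`); a pixel exactly at 10 ms is
  below threshold.

The max−min *gradient map* (`gradient_map()`) implements the alternative
reading of "APD differences" as the largest long-vs-short APD contrast in
the window; both statistics share masking rules and the choice is a flag,
because the published wording is ambiguous between them. The area
fraction restricts its denominator to pixels where dispersion was
computable, so edge trimming does not deflate percentages.

The production implementation accumulates windowed sums by explicit shift
addition after centring on the global mean (numerically gentler than a
summed-area table); `brute_force_dispersion()` is a deliberately naive
per-pixel double loop kept as the independent oracle, and the test suite
requires agreement below $10^{-10}$ ms.

## APD measurement

Each pixel's trace is normalized per-pixel to $[0,1]$ after optional
linear detrending, temporal moving-average filtering and spatial mean
smoothing. Activations are upward crossings of 0.5 amplitude with a 30 ms
refractory lockout. For each beat, APD$_L$ runs from the interpolated
upstroke midpoint to the interpolated downward crossing of $(1 - L/100)$
of that beat's baseline-to-peak amplitude (default $L = 90$; APD90 is the
common optical-mapping convention, and results do depend on the level, so
it is explicit everywhere). Design choices worth knowing:

* the amplitude reference is **per beat** (local baseline to local peak),
  which tolerates residual drift;
* the baseline is the mean of a short diastolic window before the
  upstroke foot and the peak is the maximum of a 3-frame moving average —
  both chosen over raw min/max because extremes of noisy traces are
  biased estimators;
* the repolarization time is the midpoint of the first and the last
  downward level crossing: noise triggers spurious early and late
  crossings roughly symmetrically, so the midpoint debiases the estimate
  while coinciding with the unique crossing on clean data;
* beats are aggregated by the **median** (robust to one corrupted beat);
  a single-beat mode exists for pacing protocols;
* pixels whose repolarization is not reached before the next beat (or the
  end of the recording) are invalid, never extrapolated.

With the synthetic generator's noise at 10% of the AP amplitude, a ~5 ms
moving average is an appropriate default analysis choice; the measured
mean absolute APD error is then well under 3 ms, against under 1 ms
maximum error on noise-free input. Unfiltered analysis of noisy data is
*biased* (upward at baseline pixels, downward inside long-APD islands,
shrinking the very contrast under study), which is why the temporal
filter matters more than the per-beat median for map fidelity.

Conduction velocity uses a local plane fit of activation time over a
5 × 5 window; speed is the inverse gradient magnitude, with singular
fits, near-zero gradients (simultaneous activation) and high-residual
windows invalidated.

## The three dispersion archetypes as a statistical classifier

The archetypes are verbal categories; the package operationalizes them on
island centroids (the point-process view) with every threshold exposed:

* **quadrat variance-to-mean ratio** (VMR; index of dispersion) on
  quadrats of twice the dispersion window (default 20 px — quadrats must
  exceed the island scale for clumping to register; sensitivity to this
  choice is real and the parameter is explicit). The chi-square
  index-of-dispersion test provides the significance signal
  ($\chi^2 = \mathrm{VMR}\,(n_q - 1)$, sample variance); partial quadrats
  under 50% inside the region are dropped.
* **Clark–Evans R** (observed over CSR-expected mean nearest-neighbour
  distance): R < 1 indicates aggregation, R > 1 regularity, with a simple
  guard-region edge correction (focal points only away from the
  boundary). The full Donnelly correction is out of scope.
* **Moran's I** with rook/queen contiguity on the continuous dispersion
  map, recorded as a covariate rather than gating the label.

The rule: *clustered* when the upper-tail quadrat test rejects at
`alpha` and R < 1; *uniform* when the lower tail rejects and R > 1;
*random* when neither tail rejects; *indeterminate* on conflicting
signals or fewer than 5 islands. With one-sided tails at `alpha` each,
complete spatial randomness is labelled *random* with probability close
to $1 - 2\alpha$ (90% at the default $\alpha = 0.05$); the package's
Monte-Carlo checks hold that rate to within ±5 percentage points. On
the generator's default effect sizes, uniform and clustered arrangements
are recovered essentially always.

When the classifier runs on islands extracted from a binarized map
(rather than on generator centroids) nearby islands can merge into one
connected component, deflating the island count toward the
fewer-than-5-island guard; that conservatism is intentional.

## Phase and frequency analysis

Dominant frequency comes from a per-pixel detrended, Hann-windowed
periodogram restricted to a band (default 1–40 Hz), with the peak's share
of band power kept as a quality index. Phase uses the analytic signal
(FFT-based Hilbert transform) of the mean-subtracted trace — simpler than
state-space embedding and exact for the narrowband signals at issue; an
embedding-delay method would be the alternative for strongly non-sinusoidal
data. Phase singularities are plaquette windings: the wrapped phase
differences around every 2 × 2 pixel loop sum to ±2π exactly at a
singularity, giving sub-pixel localization (plaquette centres) and
topological charge. The singularity-point-density (SPD) map counts visits
per centred 10 × 10 px window per second — the window deliberately matches
the dispersion neighbourhood. The highest-SPD region is compared against
the nearest fully-valid non-overlapping window of the same size (ties
broken row-then-column; "neighbouring" is otherwise undefined in the
source material, so this convention is documented rather than guessed).

## The synthetic generator

The generator emulates a MiCAM-style paced acquisition: a ground-truth APD
field (baseline 50 ms) plus elevated-APD islands, swept by a plane wave
(default 0.3 mm/ms) of repeated analytic action potentials at 10 Hz
pacing, with additive white noise, sinusoidal baseline drift and a linear
photobleaching trend — the three dominant dye-imaging artifacts, each
separately removable by preprocessing. The waveform is a tanh upstroke
(2 ms foot-to-plateau), short plateau, and exponential repolarization
constructed to cross the configured level exactly APD milliseconds after
the upstroke midpoint, followed by a fast return to diastole. An ionic
model would add realism but no testability: the analytic template makes
the true APD exact by construction.

Island layouts implement the three archetypes as standard point
processes: jittered lattice (uniform), binomial/Poisson placement
(random) and a Matérn cluster process (clustered, optionally
edge-biased, mirroring the tendency of patchy dispersion to sit near
anatomic borders). Island shapes are ovoids (random-orientation
ellipses) or serpiginous forms (dilated self-avoiding walks), matching
the two qualitative shapes described for dispersion islands; the
morphometric cut-offs (elongation > 3 or solidity < 0.6 ⇒ serpiginous)
are package conventions, as no quantitative definition exists in the
source material.

Two generator defaults deserve justification:

* **island elevation 25 ms** (suggested realistic range 15–25 ms): the
  windowed std of a two-level field is bounded by elevation/2, so any
  elevation ≤ 20 ms makes supra-10 ms area *identically zero*; 25 ms is
  the smallest round value in the range that produces the reported ~10%
  supra-threshold regime;
* **island radius ~6 px, count ~10–30 per 100 × 100 grid**: places the
  oracle supra-threshold fraction in the ~5–20% range actually observed
  across mapped atria and ventricles.

The generator also computes its own oracle: the true supra-threshold
fraction of the noiseless field via the brute-force dispersion loop, and
analytic spiral movies ($\cos$ of an Archimedean-spiral phase) whose
singularity locations and charges are exact, including two-core
figure-of-eight layouts with zero net charge.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: motion artifact (experiments
assume excitation-contraction uncoupling), spatially correlated shot
noise, heterogeneous dye loading, tissue curvature at the 2D projection
edge (a recognized confound for border clusters), and any ionic-model
electrophysiology (restitution, alternans, wavebreak).

## Numerical and degenerate-input conventions

* Arrays are `[frame, row, col]`, row-major, origin top-left; masks are
  logical `[row, col]`. All modules share this convention.
* Flat (zero-variance) pixels are invalid, never errors; a fully flat
  movie raises a map-level warning.
* Zero-variance samples in `group_stats()` produce a degenerate t-test
  (t = 0, p = 1 when the mean equals the null) with a warning — the
  standard implementation errors instead, which is unhelpful for
  dispersion-free control groups.
* Coincident points are legal in `clark_evans()` (R = 0); fewer than 5
  points yield an indeterminate signal, not an exception.
* Determinism: every stochastic step draws from an explicit seed;
  identical configuration and seed reproduce outputs byte for byte.

## Problem sizes

The validation suite runs the full acquisition geometry where it matters
(100 × 100 px, 1,000 frames/s, 1.2 s movies for APD/dispersion recovery;
50 replicates per arrangement for the classifier; 200 CSR replicates;
30 × 30 × 100-seed oracle-equivalence sweeps) and smaller grids for
routine unit tests. Simulated cohorts in the acceptance script use
60 × 60 grids with 8 affected-like and 4 control subjects — a deliberate
scale-down of the reference design (n = 22 and n = 4 atrial subjects)
that preserves its structure: controls with homogeneous repolarization
show zero supra-threshold area, affected subjects cluster near the ~10%
regime, and the one-sample t-test against zero is decisive.

## Known limitations

* The classifier presumes enough distinguishable islands; archipelagos
  that merge into few components return *indeterminate* rather than
  guessing.
* SPD estimation is a visit-count density; trajectory linking of rotors
  across frames (and 3D filament analysis) is out of scope.
* The guard-region Clark–Evans correction is simple; for very small
  island counts the z approximation is rough.
* `max_minus_min` gradient maps are more noise-sensitive than std maps
  (the range of $n$ values grows with $n$ under noise); prefer std for
  noisy data.
* PNG export renders with fixed colour scales for figures; quantitative
  round-trips should use CSV or the binary format.
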