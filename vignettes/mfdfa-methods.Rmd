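---
title: "Methods: multifractal analysis of channel-gating currents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multifractal analysis of channel-gating currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfpatch)
```

## What is being estimated, and why

A single-channel patch-clamp trace is a noisy, non-stationary step process:
the current jumps between discrete levels as channels open and close. The
question `mfpatch` addresses is whether the *ordering* of those events
carries memory — whether quiet and busy stretches cluster across timescales
— and whether that memory is uniform (monofractal) or scale-dependent
(multifractal).

Multifractal detrended fluctuation analysis (MFDFA) answers this through
the scaling of detrended fluctuations. The q-th-order fluctuation function
`F_q(n)` is a generalised mean of segment-wise detrended standard
deviations at scale `n`; if `F_q(n) ~ n^H(q)`, the slope `H(q)` in log–log
coordinates is the generalised Hurst exponent. `H(q)` constant in `q` means
one exponent governs all fluctuation magnitudes; `H(q)` decreasing in `q`
means small fluctuations (weighted by negative `q`) scale differently from
large ones — multifractality. The Legendre transform

$$\alpha(q) = H(q) + q \frac{\partial H}{\partial q}, \qquad
  f(\alpha) = q\,[\alpha(q) - H(q)] + 1$$

re-expresses this as the singularity spectrum: the fractal dimension
`f(α)` of the set of time points with local Hölder regularity `α`. Its
width is the scalar multifractality measure used throughout the package.

Assumptions worth keeping in mind: the series must be long enough that the
smallest and largest scales both contain many segments; detrending removes
polynomial non-stationarity of order ℓ but nothing else (voltage-step
transients must be windowed out, not detrended away); and the power-law fit
is only meaningful where `ln F_q` vs `ln n` is actually linear — the per-q
`r_squared` diagnostic exists so users can restrict `fit_range` when it is
not.

## Tunable parameters

| parameter | default | rationale |
|---|---|---|
| `q` grid | −6 … 6 by 0.25 | covers the moment range where dispersion across conditions is typically discussed; beyond \|q\| ≈ 6 the moments are dominated by a handful of segments at these series lengths and the estimates stop being reliable |
| `order` (ℓ) | 1 | linear detrending is standard practice; configurable for stronger local trends |
| `n_min` | 16 samples | below ~10 samples the polynomial fit leaves too few residual degrees of freedom and `F²` is biased |
| `n_max` | ⌊N/4⌋ | keeps ≥ 4 forward segments at the largest scale, so the segment average is not a single-segment fluke |
| `n_scales` | 30, log-spaced | even coverage in `ln n`, the fitting abscissa |
| `fit_range` | whole grid | the linear region "is sought" by the user via `r_squared`; no automatic selection, because silent window pickers are a reproducibility hazard |
| window | start ≥ 0.501 s, 59,600 samples | see below |

The analysis window deserves a note. The voltage-step protocol (0.5 s
holding, 3.5 s test, 5×10⁻⁵ s sampling) produces 80,000-sample sweeps whose
step transients must be excluded. A window from 0.501 s to 3.49 s would
contain 59,780 samples, yet the analysis length used with such protocols is
conventionally quoted as 59,600 points; the two statements cannot both hold
at this sampling rate. The package resolves the ambiguity by *count*: the
default window starts at the first sample at or after 0.501 s and takes
exactly 59,600 samples (ending at 3.481 s). The count, not the end time, is
what fixes the statistical resolution of the analysis, so it is the honoured
quantity; both bounds are configurable.

## Numerical choices

* **q = 0.** The generalised mean is undefined at q = 0; the package uses
  the logarithmic average
  `F_0(n) = exp{ (1/4M_n) Σ ln F²(ν,n) }`, the continuous limit of the
  generalised mean and the standard choice in the DFA literature.
* **Zero-variance segments.** A segment the polynomial fits exactly has
  `F² = 0` and would make any non-positive moment infinite. Such segments
  are excluded from the average for q ≤ 0, kept for q > 0 (where they
  contribute 0 exactly as the formula says), counted per scale, and
  surfaced as a warning — never silently regularised. A scale where *every*
  segment is deterministic is an error ("series is locally deterministic"),
  which is also how a constant input fails.
* **Detrending abscissa.** Polynomials are fitted against the
  segment-local abscissa 1…n via a QR decomposition shared by all segments
  of a scale. This is a conditioning choice only: residuals, and hence
  everything downstream, are identical to fitting against absolute time.
* **Segmentation.** Forward segments tile from the first sample, backward
  segments tile from the last, so the tail left by `N mod n` is covered
  without a third "centered" pass. Reversal symmetry is exact at the
  profile level (reflecting the profile permutes the segment-variance
  multiset); at the raw-series level the profile's anchoring at the first
  sample shifts windows by one point, so there it holds only statistically.
* **Derivative for α(q).** Central finite differences on the q grid,
  one-sided at the two endpoints. Smoothing splines were considered and
  rejected: they introduce a hidden bandwidth parameter that changes the
  spectrum width, the package's headline output.
* **Width conventions.** Condition tables report both
  `max α − min α` (support of the spectrum) and `max H(q) − min H(q)`
  (spread of scaling exponents). Published tables in this area sometimes
  label the "spectrum width" with the H(q) convention, so both are emitted
  rather than guessing intent.
* **Left endpoint.** The "final point" coordinates reported per condition
  are `(α, f(α))` at the largest q — the small-α end of the curve, which is
  where treatment effects on the regularity of the *largest* fluctuations
  show up.
* **Replicate dispersion.** Sample standard deviation (denominator n − 1);
  with a single replicate the dispersion is reported as `NA`, never 0.

## The synthetic generators: what they emulate, what they do not

**Fractional Gaussian noise** (`simulate_fgn`) is generated by exact
circulant embedding (Davies–Harte): the theoretical autocovariance
`γ(k) = (σ²/2)(|k+1|^{2H} − 2|k|^{2H} + |k−1|^{2H})` is reproduced exactly,
not asymptotically, which is what makes the generator usable as a test
oracle for monofractal recovery (`H(q)` flat at the prescribed `H`). The
embedding for fGn is provably non-negative definite; the generator still
verifies this and refuses to silently fall back to an approximate spectral
method.

**The binomial multiplicative cascade** (`simulate_cascade`) splits unit
mass left/right with fractions `a` and `1 − a` over `k` levels. Its
generalised Hurst exponent is known in closed form,
`H(q) = [1 − log₂(aᑫ + (1−a)ᑫ)]/q`, giving the package its multifractal
oracle at every q simultaneously. The canonical cascade is deterministic;
`shuffle = TRUE` randomises branch orientation, which permutes the cell
masses without changing their multiset — useful for testing that `H(q)`
estimation is invariant to branch order.

A caution that the test suite makes explicit: multifractality detected by
MFDFA decomposes into a part due to temporal correlation and a part due to
the breadth of the value distribution. Randomly permuting a series destroys
only the first. For a mildly asymmetric cascade (a = 0.6) the correlation
part dominates and permutation collapses the `H(q)` width by well over
half; for a strongly asymmetric cascade (a = 0.75) the heavy-tailed cell-mass
distribution alone sustains an appreciable apparent width after shuffling.
The shuffle-destruction test therefore uses a = 0.6, the regime in which
"permutation destroys multifractality" is actually true; interpreting
shuffled-surrogate comparisons on real recordings needs the same care.

**The gating simulator** (`simulate_channel_current`) is a two-state
(closed/open) continuous-time Markov chain per channel, sampled at `dt`
with per-step switching probabilities `1 − exp(−rate·dt)`, summed over
independent channels, plus Gaussian recording noise. Defaults (unitary
current 1 pA, noise 0.2 pA, 1–3 channels) are order-of-magnitude plausible
for vacuolar K⁺ channel patches and produce the step-like traces such
recordings show. `assemble_protocol_recording` concatenates a holding-phase
and a test-phase simulation into the 80,000-sample voltage-step sweep.

What the simulator deliberately does **not** reproduce: a memoryless
two-state chain has exponential dwell times and *no* long-range
correlation, so its MFDFA width reflects only the distributional component
plus finite-size effects. It is a stand-in for unavailable raw recordings —
its amplitude and kinetic defaults are not calibrated to any real dataset —
and passing pipeline tests on it demonstrates that the estimator and
aggregation machinery are correct, not that real FV-channel currents are
multifractal. When a test needs a *known, tunable* multifractal signal
inside the protocol shape, the pipeline's `memory_a` option modulates the
Gaussian noise with branch-shuffled cascade weights (normalised to unit
RMS), giving a condition-level multifractality dial anchored to the cascade
closed form; the injected-effect test checks that the estimated width
ordering across conditions recovers the injected ordering of `a`.

## Problem sizes used in validation

The test-suite and acceptance computations run at the scales the protocol
defines where structure is being checked (80,000-sample sweeps,
59,600-sample windows, 6 potentials × 5 replicates; 20 independent fGn
draws of N = 2¹⁶ per Hurst value; cascades of 2¹⁶ cells), and at reduced
sizes (N ≈ 2¹²–2¹³, fewer scales) in unit tests that only exercise
plumbing. The brute-force equivalence check compares the optimised
implementation against an explicit-loop reference on 50 random series of
N ≤ 2,000, where the naive implementation is still fast.

## Known limitations

* `H(q)` at |q| near 6 rests on a few extreme segments even at
  N ≈ 6×10⁴; the per-q `r_squared` should be inspected before interpreting
  the spectrum tails, and the q grid should not be extended without longer
  series.
* No confidence intervals on `H(q)` beyond the per-fit `r_squared`;
  replicate dispersion is the intended uncertainty measure at the study
  level.
* The wavelet-based alternative (WTMM) and hybrid detrending schemes are
  out of scope, as are inferential statistics comparing conditions — the
  pipeline reports descriptive mean/sd only, matching how such studies are
  typically summarised.
* Only plain-text recording formats are supported; proprietary
  acquisition-software binaries must be exported to text first.
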