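---
title: "Estimating long-range temporal correlations on EEG manifolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating long-range temporal correlations on EEG manifolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodfa)
```

## The model

Multichannel EEG during sustained states (listening, rest) shows
*long-range temporal correlations* (LRTC): the alpha-band amplitude
envelope decorrelates as a power law rather than exponentially. `isodfa`
quantifies this with a single scaling exponent α estimated not per channel
but on a low-dimensional trajectory of the whole recording, on the premise
that the windowed alpha-power vectors lie near a curved manifold shaped by
a few underlying cortical sources.

The pipeline is: per-channel z-scoring → zero-phase 8–13 Hz band-pass →
non-overlapping windows of length `window_length_s` → per-window,
per-channel band power → manifold embedding (Isomap, with PCA as the
linear baseline) → detrended fluctuation analysis of the embedded
trajectory → moving-block bootstrap and paired statistics.

DFA works on the profile `Z(k) = Σ_{i≤k}(y_i − ȳ)`. At scale p the profile
is cut into ⌊n/p⌋ segments, a polynomial trend (degree 1 by default) is
removed from each, and F(p) is the RMS residual. Under scale-free dynamics
`F(p) ∝ p^α`; α is the OLS slope on log–log axes and R² its goodness of
fit. α = 0.5 is uncorrelated noise, 0.5 < α < 1 persistent LRTC, α > 1
outside the power-law regime. For an embedding, the *norm-based* variant
runs DFA once on the Euclidean norm of the coordinate rows; the
*mean-based* variant runs DFA per dimension and averages exponents (and
R²). The norm collapses all dimensions into a magnitude and can distort
temporal structure; tests in this package confirm the mean-based estimate
is at least as stable (standard deviation across white-noise embeddings).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `band` | 8–13 | Hz | the alpha band; all analyses are restricted to it |
| `window_length_s` | 2 | s | 0.5 Hz resolution, resolves the band; 3 min ⇒ n ≈ 90 windows |
| `k` | adaptive | – | smallest k ≥ ⌈√n⌉ with a connected k-NN graph |
| `dim` | elbow | – | automated elbow on the eigenvalue spectrum (below) |
| `detrend_order` | 1 | – | DFA-1, the canonical choice; exposed as a flag |
| scales | 4…⌊n/4⌋ | windows | all integers; at n ≈ 90 only 19 scales exist, so none are discarded |
| `n_resamples` | 1000 | – | moving-block bootstrap; block length max(2, round(√n)) |
| `correction_factor` | 4 | – | Bonferroni family: two stimuli × two conditions |

## Design choices where the design was open

**Filtering and spectra.** The band-pass is a zero-phase (forward–backward)
Butterworth of order 4 per pass: standard EEG practice that leaves
amplitude envelopes undistorted in phase. Band power is a Hamming-tapered
modified periodogram of the whole window — the single-segment form of
Welch's estimator, which is what a single short window admits — integrated
trapezoidally over the bins inside [8, 13] Hz inclusive. A unit 10 Hz
sinusoid integrates to A²/2 = 0.5 within the taper's leakage, which the
tests assert.

**Neighbourhood graph.** Edges follow the OR rule (i–j connected if either
is among the other's k nearest), ties broken by lowest index after a
stable sort so results are deterministic. The k search is upward-only from
⌈√n⌉ (the square root is a common heuristic initialization; ceiling makes
n = 90 start at 10) and stops at the first connected graph, so the
selected k is minimal at or above the start.

**Classical MDS.** `B = −½HG²H` is symmetrized as (B + Bᵀ)/2 before
eigendecomposition to guard against floating-point asymmetry. Geodesic
matrices are generally non-Euclidean, so negative eigenvalues occur: they
stay in the reported spectrum but are excluded from coordinates and from
explained-variance denominators (standard classical-MDS practice; keeps
`Y = V_dΛ_d^{1/2}` real). Eigenvector signs follow the
largest-magnitude-component-positive convention, and PCA uses the
covariance (not correlation) of column-centred, unstandardized band powers
— powers share units, so rescaling them would change the question.

**Elbow rule.** Visual elbow selection is automated as the discrete
curvature (central second difference) of the log of the max-normalized
positive spectrum, evaluated at indices 2…min(10, len − 1); the chosen
dimension is the index just before the curvature maximum — i.e. the last
dimension before the decay flattens. The log scale makes the rule respond
to *relative* flattening, which matches what the eye does on a scree plot:
(10, 5, 2, 0.50, 0.45, 0.40) elbows at 3, while (10, 0.1, 0.09, 0.08)
elbows at 1. A strictly geometric decay has zero curvature on the log
scale; if the maximum curvature is below 0.1 (log₁₀ units, a decay-rate
change of about 1.26×) the spectrum is flagged "no clear elbow" and a
configurable default (3) is returned. A fixed `dim` always overrides the
rule.

**DFA numerics.** Segmentation is forward from the start with the trailing
remainder excluded at each scale (the simplest reading of a
divisibility-assuming sum); the both-ends variant common in the DFA
literature is available behind a flag but is not the default. The scale
grid is every integer in [4, ⌊n/4⌋]: with n ≈ 90 there are only 19 scales,
so log-spacing would discard information. The fit uses base-10 logs (slope
and R² are base-invariant). Per-segment detrending uses cached orthonormal
polynomial bases, and residuals are computed explicitly rather than via
the norm-difference identity, which loses precision exactly when residuals
vanish (the linear-profile regression test would catch that). Degenerate
inputs error early: series shorter than 16 samples, a zero F(p) (log
undefined — the offending scale is named), constant channels in z-scoring.
Fewer than 4 available scales triggers a warning and a `short_series`
flag. The mean-based R² is the arithmetic mean of per-dimension R² values
(one of several defensible aggregations; it mirrors how α itself is
aggregated).

**Bootstrap.** What to resample is genuinely ambiguous for an embedded
trajectory; the default resamples *rows of the embedding*, preserving
cross-dimension structure so the norm- and mean-based estimators apply to
the same scheme, with plain 1-D series resampling available when the input
is a series. Intervals are percentile (no bias-correction is attempted),
and a failing resample is redrawn at most 10 times before erroring, so
silently dropped resamples cannot bias the interval. The square-root
block-length heuristic balances preserving short-range dependence against
block variety; it is not data-driven, and the intervals inherit that
caveat.

**Wilcoxon zeros.** Zero differences are discarded (classical signed-rank,
R's default); a Pratt-style policy (rank with zeros, then drop their
ranks) is selectable. Exact two-decimal α tables contain ties, so these
p-values are approximation-dependent — effect sizes and Bonferroni-corrected
t-test p-values are the stable quantities to compare.

## The synthetic generator

`simulate_recording()` emulates the statistical skeleton of alpha-band
EEG: `latent_dim` independent carriers at `carrier_hz` (default 10 Hz)
whose envelopes are `1 + 0.4·fGn(H)` clipped below at 0.05 — with unit
fGn variance the clip touches well under 1% of samples, so the envelope's
correlation structure survives — mixed through `tanh` of row-normalized
random linear combinations (a smooth saturating map that guarantees a
curved manifold, so Isomap's advantage is exercisable) plus white sensor
noise. The fGn itself uses exact circulant embedding of the fGn
autocovariance (eigenvalues by FFT; any round-off negatives are clipped,
equivalent to spectral synthesis), verified in tests against the
closed-form autocovariance and recovered by DFA to within ±0.05 in H.

What it does *not* emulate: 1/f broadband background, blinks and muscle
artifacts, volume conduction, nonstationary band shifts. Passing tests
therefore demonstrate that the estimator stack recovers known scaling
structure through a nonlinear mixture — not that real EEG meets the
model's assumptions.

Default study conditions follow the recording protocol the pipeline
targets: 3-minute conditions at a few hundred Hz across ~16–24 channels,
2-s windows giving n ≈ 90, three latent sources, envelope Hurst 0.8
(mid-LRTC range), noise SD 0.1 relative to unit-amplitude carriers.

## Problem sizes used in the test-suite simulations

Calibration and property tests use 20 series of length 10⁴ (white noise
and fGn), 100 white-noise embeddings of 90 × 3 for the stability
comparison, 100 bootstrap replications (100 resamples each) at n = 512 for
CI coverage, and one 180 s / 200 Hz / 16-channel recording for the
end-to-end recovery and k ± 2 sweep checks. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping the suite
quick.

## Known limitations

- At n ≈ 90 windows the scale range [4, 22] is short; α estimates carry a
  small-sample upward bias of a few hundredths (visible in the white-noise
  tests) and wide intervals. Longer recordings widen the scale range.
- The elbow rule automates a visual judgement; on noisy spectra adjacent
  dimensions can trade places, which is why a fixed `dim` override exists
  and the k ± 2 sweep reports sensitivity.
- Isomap has no out-of-sample extension here, and no landmark/sparse
  variant: n in the hundreds is the intended regime.
- The EDF reader covers continuous recordings with one common sampling
  rate (16-bit, the format's native quantization); EDF+ annotations and
  per-signal rates are out of scope.
- Bootstrap intervals preserve short-range dependence only; cross-scale
  correlations intrinsic to DFA are not modelled, so coverage can be
  optimistic for strongly persistent data.
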