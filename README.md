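# isodfa

Long-range temporal correlations (LRTC) in alpha-band EEG via nonlinear
manifold embedding and detrended fluctuation analysis.

## What it does

Resting or task EEG exhibits scale-free temporal structure: the amplitude
of alpha-band (8–13 Hz) oscillations is correlated over seconds to minutes.
The standard summary of that structure is the DFA scaling exponent α —
α = 0.5 for uncorrelated (white) dynamics, 0.5 < α < 1 for persistent
long-range temporal correlations, α > 1 outside the power-law regime.
Channel-wise DFA ignores the strong spatial correlation across electrodes;
`isodfa` instead estimates α on a low-dimensional trajectory of the whole
multichannel recording:

1. **Features.** Each channel is z-scored and band-passed 8–13 Hz
   (zero-phase Butterworth); the recording is cut into non-overlapping 2-s
   windows (`n = ⌊T/L⌋`, 0.5 Hz resolution) and per-window, per-channel
   alpha-band power is integrated from a Hamming-tapered periodogram,
   giving a feature matrix `X ∈ R^{n×N}`.
2. **Embedding.** Isomap: a k-nearest-neighbour graph on the pairwise
   Euclidean distances (k chosen adaptively as the smallest value at or
   above ⌈√n⌉ that connects the graph), geodesic distances by Dijkstra
   shortest paths, then classical MDS of the geodesic matrix
   (`B = −½HG²H`, `Y = V_d Λ_d^{1/2}`). A PCA embedding is available as
   the linear baseline. The dimension d comes from an automated elbow rule
   on the eigenvalue spectrum; trustworthiness and explained variance
   diagnose embedding quality.
3. **DFA.** On the embedding, either *norm-based* (DFA of the Euclidean
   norm of the coordinates) or *mean-based* (DFA per dimension, exponents
   averaged; the more stable variant). Fluctuations are computed at every
   integer scale p ∈ [4, ⌊n/4⌋] with order-1 detrending, and α is the OLS
   slope of log₁₀F(p) on log₁₀p with goodness of fit R².
4. **Inference.** Moving-block bootstrap (block length max(2, round(√n)))
   percentile confidence intervals for α; paired t-test, Wilcoxon
   signed-rank, Bonferroni correction and paired Cohen's d for comparing α
   vectors across methods or conditions; a k ± 2 sensitivity sweep.

A synthetic-EEG generator (fractional Gaussian noise envelopes with known
Hurst exponent, exact circulant-embedding synthesis, nonlinear tanh channel
mixing) provides ground truth for every stage, so the whole pipeline is
testable without external recordings.

## Worked example

```r
library(isodfa)

rec <- simulate_recording(synthetic_spec(
  n_channels = 16, duration_s = 180, fs = 200,
  latent_dim = 3, latent_hurst = 0.8, noise_sd = 0.1, seed = 2))

fit <- lrtc(rec, method = "isomap", approach = "mean",
            n_boot = 200, seed = 1)
summary(fit)
#> Band-power feature matrix: 90 windows x 16 channels (8-13 Hz, 2-s windows)
#> ISOMAP embedding: n = 90, d = 3, k = 10
#>   explained variance (top 3): 75.0%
#>   trustworthiness: k5 = 0.995, k7 = 0.995
#>
#> DFA-1 (mean approach): alpha = 0.777, R^2 = 0.947
#>   n = 90, scales 4..22 (19 points)
#>   per-dimension alpha: 0.779, 0.698, 0.855
#> Moving-block bootstrap (200 resamples, block length 9, mean approach)
#>   alpha = 0.777, bootstrap mean 0.675, 95% CI [0.532, 0.783]
```

The 3-minute, 200 Hz, 16-channel synthetic recording has three latent
alpha oscillations whose envelopes carry Hurst exponent 0.8; the pipeline
finds 90 windows, selects k = 10 and d = 3 (the true latent dimension) and
recovers α ≈ 0.78 — persistent LRTC, close to the ground-truth 0.8, with
the point estimate inside the bootstrap interval.

Comparing per-subject exponent tables (shipped with the package) between
the Isomap and PCA pipelines:

```r
tabs <- alpha_tables()
paired_comparison(tabs$isomap$mean_yaman_during, tabs$pca$mean_yaman_during)
#> Paired comparison, n = 13 pairs
#>   t = 2.581, p = 0.0241, Bonferroni (x4) p = 0.0962
#>   Wilcoxon signed-rank p = 0.0340
#>   paired Cohen's d = 0.716
```

A command-line front end with subcommands `simulate`, `features`, `embed`,
`dfa`, `bootstrap`, `compare`, `sweep-k` and `run` is installed at
`system.file("cli", "isodfa-cli", package = "isodfa")`.

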