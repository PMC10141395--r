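# mfpatch

Multifractal detrended fluctuation analysis (MFDFA) of single-channel
patch-clamp current recordings.

Ion-channel gating is not a memoryless coin flip: the open/closed state
sequence of many channels carries long-range correlation, and the strength of
that memory can depend on the timescale examined — the hallmark of
multifractality. `mfpatch` is for electrophysiologists and biophysicists who
want to quantify this from voltage-step recordings: it estimates the
generalised Hurst exponent H(q), converts it to the singularity spectrum
f(α), and aggregates replicate sweeps into per-condition summary tables
(e.g. across test potentials, or across hormone incubation times).

## The estimator

For an equidistant series *x₁ … x_N*, MFDFA proceeds in five steps:

1. Integrated profile: Y_j = Σ_{i≤j} (x_i − ⟨x⟩).
2. At each scale *n*, divide the profile into M_n = ⌊N/n⌋ disjoint
   length-*n* segments from the start, and another M_n from the end
   (2 M_n segments in total, so the incomplete tail is always covered).
3. Detrend each segment with a least-squares polynomial of order ℓ
   (default ℓ = 1, linear) and record the residual variance F²(ν, n).
4. Average over segments with a generalised mean of order q:
   F_q(n) = { (1/2M_n) Σ_ν [F²(ν,n)]^{q/2} }^{1/q}, with the logarithmic
   average at q = 0. Negative q magnifies the quietest segments, positive q
   the wildest.
5. Fit ln F_q(n) against ln n: the slope is H(q). A monofractal series has
   H(q) constant in q; a q-dependent H(q) is multifractal.

The Legendre transform α(q) = H(q) + q·∂H/∂q, f(α) = q[α − H(q)] + 1 then
gives the singularity spectrum; its width (reported both as
max α − min α and as max H(q) − min H(q)) is the headline multifractality
measure, and f(α(0)) = 1 by construction.

Because raw single-channel recordings are rarely published, the package
ships exact synthetic generators that double as analytic oracles:
fractional Gaussian noise by circulant embedding (monofractal, any Hurst
exponent), the binomial multiplicative cascade (multifractal with
closed-form H(q)), and a two-state Markov channel-gating simulator that
produces protocol-shaped voltage-step sweeps.

## Worked example

Simulate one voltage-step sweep (0.5 s holding at −40 mV, then 3.5 s at
−100 mV, sampled every 5×10⁻⁵ s → 80,000 samples), extract the analysis
window and run MFDFA:

```r
library(mfpatch)

p      <- protocol_spec(test_voltage = -100)
g_hold <- gating_spec(open_rate = 2,  close_rate = 400)
g_test <- gating_spec(open_rate = 75, close_rate = 220, unitary_current = -1e-12)
rec    <- assemble_protocol_recording(p, g_hold, g_test, replicate = 1, seed = 7)
rec
#> Patch-clamp recording: 80000 samples, dt = 5e-05 s (4 s)
#>   voltage: -100 mV | condition: control | replicate: 1 | incubation: NA min
#>   current range: [-1.82e-12, 8.38e-13] A

x   <- extract_analysis_window(rec)   # 59,600 samples from t >= 0.501 s
fit <- mfdfa(x)
summary(fit)
#> MFDFA fit over 49 moment orders, N = 59600
#>
#>   q      H intercept r_squared
#>  -6 1.0734    -33.27    0.9562
#>  -2 1.0889    -32.97    0.9772
#>   0 1.0499    -32.19    0.9834
#>   2 0.9222    -30.89    0.9723
#>   6 0.8284    -29.94    0.9790
#>
#> H(q) width (max - min): 0.2609
#> worst power-law fit R^2: 0.9562

spectrum_summary(singularity_spectrum(fit))
#> Singularity spectrum summary
#>   width (alpha support)     : 0.3254
#>   width (max H - min H)     : 0.2609
#>   left endpoint (alpha, f)  : (0.7793, 0.7058)
#>   over q in [-6, 6]
```

H(q) decreasing from ≈1.09 at negative q to ≈0.83 at q = 6 says the quiet
stretches of the trace are more persistent than the bursts — scale-dependent
memory, i.e. weak multifractality of the gating current. The spectrum width
(≈0.33 in α) quantifies it; a monofractal control (`simulate_fgn`) gives a
width an order of magnitude smaller.

The full study pipeline — several conditions × replicate sweeps, with
mean/sd aggregation and condition tables — is one call:

```r
study <- run_protocol_study(arm = "voltage", n_replicates = 5, master_seed = 1)
study$tables
```

`coef()`, `plot()` (fluctuation functions, H(q), f(α)) and `residuals()`
methods are available on the fitted objects, and recordings round-trip
through plain-text files via `write_recording()` / `read_recording()`.

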