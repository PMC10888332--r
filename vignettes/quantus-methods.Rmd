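---
title: "Methods: desk-scale quantitative ultrasound from phantom to diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale quantitative ultrasound from phantom to diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`quantus` models the full quantitative-ultrasound (QUS) measurement
chain for breast lesion characterization at desk scale: tissue phantom
→ plane-wave RF acquisition → parameter reconstruction (classical and
learned) → malignancy classification. This vignette records the models,
the assumptions behind them, the tunable parameters, and the design
decisions taken where the design was genuinely open. Nothing here claims
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The tissue world

A `tissue_phantom` holds five co-registered maps over a square region of
interest: attenuation coefficient AC (dB/cm/MHz), speed of sound SoS
(m/s), density (kg/m³), effective scatterer diameter ESD (µm) and
effective scatterer concentration ESC (scatterers per squared
wavelength, λ = 0.308 mm at 5 MHz in 1540 m/s tissue). The default grid
is 256 × 256 pixels at 0.2 mm pitch (51.2 mm square); 0.2 mm is finer
than any feature the spectral estimators resolve, and property maps need
not be sampled at the acoustic half-wavelength because no full-wave
field is computed on them.

Backgrounds are layered (2 mm skin, 8 mm fat, gland below by default);
lesions are ellipses or boundary-perturbed polygons. Each tissue class
draws its properties uniformly from a configurable range
(`tissue_property_ranges()`):

| class     | AC (dB/cm/MHz) | SoS (m/s)  | ESD (µm) | ESC (/λ²) |
|-----------|----------------|------------|----------|-----------|
| fat/gland/skin | 0.3–0.8   | 1420–1580  | 80–110   | 1.2–4.2   |
| cyst      | 0.05–0.2       | 1480–1540  | 80–110   | 1.2–4.2   |
| benign    | 0.35–0.65      | 1520–1560  | 85–105   | 1.2–4.2   |
| malignant | 0.6–1.1        | 1545–1600  | 70–92    | 1.2–4.2   |

These ranges bracket the published group medians and interquartile
ranges (benign AC median 0.506, malignant 0.666 dB/cm/MHz; benign SoS
1542, malignant 1565 m/s; benign ESD 91.5, malignant 83.8 µm) and the
cyst/malignant exemplar values (0.157 and 1.012 dB/cm/MHz). They are a
calibrated choice, not published values — the source study set its
simulation to "cover general soft-tissue characteristics" without
printing ranges. Density defaults to 1000 kg/m³ with a ±5% lesion
offset; density contrast participates in scattering in principle but no
quantitative values were available, so it does not drive any estimator.

## 2. The forward model

Full finite-difference wave propagation is out of desk scope. The
simulator is a point-scatterer model that preserves exactly the four
signal features the estimators (and the network) consume:

- **amplitude decay** with depth and frequency → AC,
- **arrival phase** across steering angles → SoS,
- **backscatter spectral shape** → ESD,
- **envelope statistics** → ESC.

Scatterers are drawn per pixel as Poisson with mean
`esc · pixel_area / λ²`, positioned uniformly within the pixel, with
zero-mean Gaussian reflectivity whose standard deviation scales as
`(esd / 85 µm)^{3/2}` — a Rayleigh-like d³ power weighting, so echo
power grows with scatterer size.

For each steering angle θ the transmit wavefront obeys the plane-wave
delay law `T(n) = n · pitch · sin θ / c_ref` (c_ref = 1540 m/s); in a
medium with column-averaged speed c the refracted propagation angle
satisfies `sin a = c sin θ / c_ref`, giving the transmit arrival time
`(x − x₀) sin θ / c_ref + z cos a / c`. Receive is the direct
element-to-scatterer path at the same column-averaged speed
(straight-ray approximation). Heterogeneous SoS maps act through the
per-column harmonic-mean slowness.

**Closed-form spectral filtering.** The pulse has a Gaussian amplitude
spectrum (5 MHz center, 60% fractional bandwidth). Both attenuation,
`exp(−a f)` with `a` from the cumulative AC column integral (two-way),
and the Gaussian form factor, amplitude `exp(−0.827 k² d² / 8)`, are
log-polynomial in frequency, so their product with the pulse spectrum is
again Gaussian with a shifted center frequency, a narrowed bandwidth and
a computable amplitude. Every echo is therefore synthesized exactly as a
Gaussian-enveloped carrier with per-scatterer (amplitude, f_c, σ_f) —
no per-echo filtering is needed, and the spectral content the estimators
fit is exact rather than approximated. A `center_only` attenuation mode
(pure amplitude factor at f₀) is retained for comparison.

Record geometry follows the hardware it mimics: 128 elements, 0.3 mm
pitch (not printed for the clinical probe; 0.3 mm ≈ λ is the standard
linear-array choice), 62.5 MHz sampling, 3018 samples. Note 3018
samples cover only ≈ 37 mm of two-way depth at 1540 m/s — less than the
50 mm region of interest; this mismatch exists in the source
description and is left as-is: scatterers beyond the record simply
truncate. Measurement noise is white Gaussian at 30 dB SNR by default.

Non-goals: multiple scattering, nonlinear propagation, elevation
focusing, speckle-exact equivalence to a full-wave solver.

## 3. Classical estimators

All spectral estimators normalize per-window power spectra by a
simulated uniform **reference phantom** (AC 0.5, SoS 1540, ESD 85 µm,
ESC 2/λ²), which cancels the system response, diffraction and
depth-gating. Four independent speckle realizations of the reference are
averaged, as scanning a physical reference block at several positions
would. Analysis windows are 4 × 4 mm with 50% overlap; spectra are
averaged over the in-window elements and all steering angles (gates
shifted per angle by the transmit geometry); the usable band is
f₀ ± 40%. A white-noise floor estimated from the bins just below
Nyquist is subtracted from all powers, and windows whose in-band signal
sits near that floor are down-weighted — without this the AC of highly
attenuating tissue is biased low at depth.

- **AC** (spectral log difference): per window, the slope over frequency
  of the normalized log spectrum; its depth derivative, taken by sliding
  weighted regression over ±2 window rows in the same column, equals
  −2·(AC − AC_ref) in dB/cm/MHz.
- **SoS** (coherence maximization): each angle is beamformed separately
  at candidate speeds; the speed maximizing the cross-angle coherence
  factor `Σ|Σ_a s_a|² / (A Σ Σ|s_a|²)` over a central patch wins, with
  parabolic refinement around the discrete peak. Ties break toward the
  lowest candidate; a boundary optimum is returned flagged and warned.
- **ESD** (Gaussian form-factor fit): the attenuation-compensated
  normalized log power spectrum is fitted by linear least squares to
  `c₀ + c₂ f²`; `c₂ = −0.827 (2π/c)² (d_s² − d_r²)/4` yields the
  diameter. The linear (attenuation) term is removed *before* the fit
  using the AC map accumulated over depth, because over a ±40% band a
  free linear term is nearly collinear with the constant and destroys
  the fit's conditioning.
- **ESC** (envelope statistics): for N scatterers with Gaussian
  strengths per resolution cell, the beamformed intensity moments obey
  `E[I²]/E[I]² = 2 + 1/N` — independent of the scatterer strength and
  hence of ESD. The ratio of `1/N` between the tissue window and the
  matched reference window cancels the (depth-dependent, unknown)
  resolution-cell geometry and rescales the known reference
  concentration. The tissue image is beamformed at the estimated SoS
  when available, since defocus inflates the apparent cell. This
  envelope-statistics route follows the field's definition of ESC as a
  property of the scatterer probability distribution; a
  spectral-intercept alternative (backscatter amplitude extrapolated to
  f = 0) was evaluated and rejected: over a ±40% band the intercept
  extrapolation amplifies speckle noise far beyond the 3.5× clinical
  ESC range. The absolute ESC scale carries a residual upward bias of
  order tens of percent (finite windows, correlated speckle samples);
  orderings and group contrasts, which the diagnostic use depends on,
  are preserved (rank correlation ≥ 0.9 in the recovery suite).

On ten random uniform phantoms (32 × 32 mm, 96 elements, five angles)
the suite requires median absolute errors ≤ 0.1 dB/cm/MHz (AC),
≤ 10 m/s (SoS), ≤ 15 µm (ESD) and ESC rank correlation ≥ 0.8; these are
computed in `test-acceptance.R`, not quoted from anywhere.

## 4. The conditional encoder–decoder

One network serves all four parameters. The condition is a one-hot
vector in the order (AC, SoS, ESD, ESC); it acts through **conditional
instance normalization**: per channel and instance,
`y = γ_cond (x − µ)/σ + β_cond` (ε = 10⁻⁵ inside the square root), with
one (γ, β) row per condition in every normalization layer.

- **Encoder**: three stages of 3 × 3 stride-2 convolution + conditional
  instance normalization + ReLU, compressing a 128 × 128 input to a
  16 × 16 spatial latent. Desk widths 16/32/64 channels (the published
  scale, 512 latent channels, sits behind `scale = "full"`); the
  architecture, not the capacity, is what the desk build exercises.
- **Decoder**: a parallel multi-resolution bank. For each resolution
  R ∈ {16, 32, 64, 128}: a 1 × 1 head + conditional normalization +
  ReLU, nearest-neighbour upsampling to R, and a residual block whose
  second convolution is zero-initialized (the block is an exact identity
  at initialization). Each branch emits an auxiliary 1-channel output at
  its resolution; branch feature maps are upsampled to 128, concatenated,
  conditionally normalized once more, and fused by a 1 × 1 bottleneck
  convolution into the final map. The fusion normalization sits directly
  before the bottleneck with no rectifier in between — deliberately, so
  that a condition can invert the contrast of a shared spatial feature
  through the sign of its γ row; with every conditional parameter
  upstream of a ReLU, sign flips are clipped and condition switching is
  slow to learn.
- **Loss**: `‖y − ŷ‖² + Σ_R ‖y_R − ŷ_R‖² + λ Σ w²` with sums (not
  means) over pixels, auxiliary targets by block-average pooling,
  equal weighting of the auxiliary term (its relative weight is not
  specified anywhere; equal is the neutral choice), and λ = 10⁻⁴ on
  convolution weights.
- **Training**: Adam (β₁ = 0.9, β₂ = 0.999), batch size 8, dropout with
  retention 0.5 on the latent, early stopping with patience 10 on
  validation loss, at most 120 epochs. The held-out fraction is 1/16.5
  of the dataset, reproducing the published 16,500 → 15,500/1,000
  design. **Learning rate**: the published 10⁻⁴ belongs to the
  full-scale regime (≈ 230k optimizer steps); Adam moves each parameter
  by roughly `lr` per step, so a desk run of a few hundred steps would
  move nothing. The desk default is 3 × 10⁻³; `scale = "full"` restores
  10⁻⁴. The γ/β tables carry small per-condition jitter at
  initialization so the condition input is active from the first step.

**Input representation.** The source system feeds raw 128 × 3018
channel data; how that reaches a 16 × 16 latent is not specified. At
desk scale the input is a 128 × 128 × n_angles stack: per angle, the
channel-envelope (analytic-signal magnitude) block-averaged in depth,
interpolated across elements, log-compressed over 50 dB and scaled to
[0, 1]. This preserves amplitude decay, angle-dependent arrival
structure and envelope texture; it discards the RF carrier phase, which
at desk scale the conditions do not resolve anyway.

**What the toy dataset establishes.** `make_toy_dataset()` builds
lesion phantoms with stylized contrasts (AC and ESC raised, SoS and ESD
lowered inside the lesion — the malignant direction for AC/ESD/ESC;
SoS is lowered rather than raised so that the AC and SoS targets are
anti-correlated and condition switching is falsifiable), simulates
their RF, and emits one (input, condition, target) triple per phantom
and parameter with targets normalized by fixed physical ranges
(AC 0–1.2, SoS 1400–1650, ESD 40–130, ESC 0–5). A green smoke test
establishes that the optimization machinery works and that conditions
select parameter-specific outputs; it does not establish metrological
accuracy of the learned maps, which at 16 phantoms and desk capacity is
out of reach (the classical estimators are the quantitative route).

## 5. Synthetic cohorts and the classifier

`sample_cohort()` inverts the published group summaries — median and
interquartile range per parameter per group — into distribution
parameters: log-normal (µ = ln median, σ = ln(q3/q1)/(2 · 0.67449)) for
the strictly positive, skew-reported AC/ESD/ESC; normal for SoS, whose
relative spread is narrow. Parameters are drawn independently within a
group: inter-parameter correlations are not recoverable from the
published summaries. This is the generator's main limitation — the AUC
of the fixed clinical model on such cohorts need not equal the clinical
0.90 point estimate, only respect its published confidence band (lower
bound 0.78), which is exactly what the acceptance target checks. A
Gaussian-copula hook accepts a correlation matrix; it ships as identity.

The packaged classifier carries the published coefficients
(−31.7558; AC 10.6396; SoS 0.0210; ESD −0.0975; ESC 0.0805);
`probability()` is the sigmoid; the classification threshold is 0.5
(no threshold is printed; 0.5 is the sigmoid's natural midpoint).
`fit_logistic()` delegates the maximum-likelihood fit to
`stats::glm(binomial)` and reports Wald inference (odds ratios, both
coefficient- and OR-scale standard errors — published tables use the
OR scale — z, two-sided p, 95% CI). Quasi-perfect separation is
detected from degenerate fitted probabilities and flagged with a
warning rather than silently returning a diverged fit. Mann–Whitney U
uses the exact distribution for small untied samples and the
tie-corrected normal approximation otherwise; AUC is trapezoidal
(identically the rank statistic — both are computed and compared in the
tests); its CI is a stratified percentile bootstrap (2000 resamples,
seed mandatory); Clopper–Pearson intervals come from beta quantiles.

## 6. Numerical choices and degenerate inputs

- Rasterization marks pixels whose centers fall inside the shape; the
  rasterized area converges to the analytic area as the pitch shrinks
  (tested at two pitches).
- The coherence search breaks ties toward the lowest candidate speed; a
  clamped search (truth outside the candidate range) warns and flags.
- Spectral fits guard against empty/noise-floored windows by flooring
  subtracted power at 2% of the noise floor; ESD is floored at 10 µm;
  ESC is clipped to [10⁻³, 50].
- All generators and the simulator are pure functions of their seeds;
  helper RNG use saves and restores the caller's RNG state.
- Identical groups give Mann–Whitney p = 1; zero RF gives a zero
  B-mode image; an empty scatterer field gives pure noise at the
  configured SNR.

## 7. Known limitations

- Straight-ray propagation: no refraction-induced aberration beyond the
  layered Snell correction, no multiple scattering.
- The ESC absolute scale is biased high (section 3); ranks are reliable.
- ESD inherits sensitivity to residual attenuation-compensation error
  (≈ ±10 µm at desk geometry) — the dominant term in its error budget.
- The synthetic cohort ignores inter-parameter correlation and
  age/size/BI-RADS structure; it emulates marginals only.
- The network's desk capacity demonstrates architecture and
  conditioning, not clinical reconstruction quality.
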