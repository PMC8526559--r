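---
title: "From valve mechanics to murmur classification: models and methods"
author: "stethosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From valve mechanics to murmur classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stethosim)
```

# Overview

`stethosim` is a desk-scale laboratory for a clinical question: can a simple,
transparent machine-learning stack detect anomalous aortic-valve function —
mild stenosis secondary to reduced leaflet motion (RLM), the signature of
early leaflet thrombosis in bioprosthetic valves — from heart sounds recorded
on the chest wall? The package chains four stages:

1. **Reduced degree-of-freedom valve model** — each of the three leaflets
   carries one lumped displacement `c(t) ∈ [0, 1]` that interpolates the
   leaflet surface between its closed and open configurations.
2. **Synthetic acoustic sources** — a surrogate for resolved turbulent
   hemodynamics: the valve kinematics decide *when* things sound (ejection
   click, S2 closure impulses), a stiffness-scaled envelope-modulated noise
   decides *how loud* the systolic murmur is.
3. **Elastodynamic propagation** — the lumen-panel pressure fluctuations are
   carried to an epidermal monitor point through a homogeneous Kelvin–Voigt
   viscoelastic medium via the free-space Green's tensor.
4. **Classification** — sup-norm normalization and ensemble centering, SMOTE
   balancing, SVD/PCA reduction with cross-validated mode count, and a Fisher
   linear discriminant with an exclusion-based midpoint threshold.

# The valve model

## Kinematic ansatz

Leaflet node displacement is `d(x, t) = b(x) ξ(x, c(t))`, where
`b(x) = x_open − x_close` is the per-node range-of-motion vector and `ξ` a
mapping function with `ξ(x, 0) = 0`, `ξ(x, 1) = 1`. Two mappings are
provided: linear (`ξ = c`) and power (`ξ = c^β(x)`, belly-first opening
shapes). Differentiating gives the node velocity
`v = (dc/dt) (∂ξ/∂c) b`.

Substituting the ansatz into the normal component of the leaflet momentum
balance and integrating over the leaflet surface yields one second-order ODE
per leaflet:

```
d²c/dt² = (F_P − F_S − F_mV) / (α ∫ (∂ξ/∂c) b·n ds)
F_P  = ∫ Δp ds                      (pressure load)
F_S  = ∫ κ (ξ(c) − ξ(0)) b·n ds     (elastic restoring force)
F_mV = α ∫ (∂²ξ/∂c²) (dc/dt)² b·n ds (nonlinear-mapping inertia)
```

with areal inertia `α = 40 kg/m²` and stiffness `κ = 10,600 Pa/m` for a
healthy leaflet. Stenosis is imposed as a per-leaflet stiffness multiplier
(≥ 1). With the linear mapping and a constant load the equation is an exact
harmonic oscillator with `ω₀ = √(κ/α) = √265 ≈ 16.28 rad/s`; the test suite
holds the integrator to < 1e−4 relative error against that closed form.

## Numerical choices

* **Integrator**: explicit RK4 at `dt = 1e−4 s`, matching the 10 kHz
  acoustic output grid. Self-convergence of order ≥ 4 is asserted in tests.
* **Contact**: the physical constraint `0 ≤ c ≤ 1` is enforced by clamping
  with the rate zeroed on contact (perfectly inelastic stop). Valve sounds
  in this pipeline originate from pressure sources, not from leaflet impact,
  so the contact law only needs to be stable.
* **Power-mapping derivatives** are singular at `c = 0` for `β < 2`; they
  are evaluated at `max(c, 1e−6)`. `ξ` itself is always exact.
* **Geometry**: a single-parameter cylindrical-sector construction — closed
  leaflets funnel to a coaptation apex at depth `√(L_f² − R²)`, open
  leaflets sweep onto the annulus cylinder; element normals and areas are
  evaluated on the open configuration (the closed funnel is degenerate at
  the apex). PVOA magnitudes are therefore convention-dependent; the default
  valve (annulus 23 mm, leaflet 15 mm) opens to ≈ 4.1 cm².
* **Projected valve open area** (PVOA) is the shoelace area of the
  free-edge polyline projected on the annulus plane. Because projected
  free-edge vertices scale linearly from the annulus center with fixed
  azimuths, PVOA is *exactly* a quadratic form in the three leaflet
  openings; the coupled simulation exploits this for O(1) evaluation, and a
  test pins the two routes together to 1e−12.

## Event detection

Per leaflet: the first direction reversal (`dc/dt` crossing + → − after
opening onset), the closure instant (first `c` below the closure tolerance,
default 0.02, after peak opening), and the halfway-closure instant. Leaflets
that never open report absent events rather than errors.

# The hemodynamic load surrogate

The full-field transvalvular pressure is replaced by a leaflet-uniform
quasi-steady orifice law

```
Δp(t) = ½ ρ₀ (Q/A_eff)² sign(Q) + L dQ/dt,
```

with blood density `ρ₀ = 1060 kg/m³`, `A_eff = max(PVOA, area_floor)` and
inertance `L = ρ₀ ℓ / A_ref`. The flow waveform `Q(t)` is a two-piece
raised-cosine ejection pulse peaking at `t/T = 0.12` and ending at
`t/T = 0.35`, scaled so its integral equals the stroke volume (60 or 72 ml
at 60 bpm, i.e. cardiac outputs of 3.6 and 4.32 l/min).

Two constants were calibrated once against the closure phenomenology the
model should reproduce and then frozen:

* `area_floor = 1.5 cm²` — the effective relief area (LVOT and
  paravalvular pathways) seen by the decelerating blood column when the
  valve is nearly closed. Smaller values produce an unphysically large
  opening-phase pressure spike that slams even heavily stiffened leaflets
  fully open.
* `ℓ = 1 cm`, `A_ref = 3 cm²` — a short blood-column inertance. Larger
  values close the healthy valve too early in deceleration.

With these defaults a healthy valve closes synchronously at `t/T ≈ 0.33`,
a strongly stiffened leaflet (multiplier 20) reverses direction at
`t/T ≈ 0.06` (the ejection-click instant) and closes early, and the
remaining healthy leaflets of an RLM valve are held open past the end of
ejection by the elevated orifice gradient — the mechanism behind the
diminished, split S2 of stenotic valves.

**Known limitation.** A leaflet-uniform `Δp` cannot redirect load away from
a stiffened leaflet the way a resolved 3-D jet does, so mild and moderate
multipliers still reach full opening; reduced leaflet motion expresses
itself mainly in timing (early reversal/closure, delayed partner closure)
rather than in a large peak-PVOA deficit. Only strong stiffening
(multiplier ≈ 20 on one or two leaflets) shows a visibly reduced peak
opening.

# Synthetic acoustic sources

`synthesize_panel_pressures()` paints onto each of the 180 aorta-lumen
panels a zero-mean pressure-fluctuation series with four ingredients:

* **Murmur** — band-limited (100–600 Hz) noise under a piecewise-linear
  crescendo–decrescendo envelope (zero before `t/T = 0.06`, peak at 0.18,
  zero after 0.35), with pressure amplitude
  `murmur_gain × (Σ multipliers − 3)` — zero for a healthy valve, linear in
  total stiffness excess (the simplest monotone severity law). Half of the
  murmur energy (`murmur_coherence = 0.5`) is a fixed, flow-phase-locked
  waveform shared across panels and cases, standing in for the repeatable
  large-scale jet-impingement structures; the rest is fine-scale turbulence
  independent across panels and cases. The coherent fraction is what gives
  the linear classifier a severity axis: a purely incoherent murmur changes
  only the variance of the records, which no linear projection can track.
* **Ejection click** — a critically damped wavelet `(u/τ) e^{1−u/τ}`
  (τ = 1.25 ms, ≈ 5 ms width) at the stiffest leaflet's first
  direction-reversal instant, amplitude `click_gain × (max multiplier − 1)`,
  coherent across panels.
* **S2 closure impulses** — the same wavelet at each leaflet's closure
  instant, amplitude `s2_gain × exp(−delay/s2_decay)` where `delay` is the
  closure lag past the end of ejection (`t/T = 0.35`): leaflets closing
  after forward flow has ceased sound diminished. Synchronous healthy
  closure yields a single S2; asynchronous RLM closure yields a split S2.
* **Noise floor** — broadband (20–900 Hz) background, independent across
  panels, equal for all scenarios up to a ±10% per-case jitter.

Default gains (`s2_gain = 40 Pa`, `click_gain = 1.5 Pa` per unit excess,
`murmur_gain = 0.5 Pa` per unit excess, `noise_floor = 2 Pa`) were chosen
once so that (i) the S2 impulse remains the sup-norm of the record over the
whole severity grid — keeping the normalized feature path approximately
linear in severity — and (ii) the mildest stenotic condition in the grid
(multiplier 2) remains separable from healthy records. Coherent sources
(clicks, S2) add across the 180 panels ≈ 13× more efficiently than the
incoherent murmur, which is why the murmur gain is numerically small.

**What the generator does and does not emulate.** It reproduces the timing
phenomenology (quiet laminar acceleration in healthy beats, diamond murmur
over `t/T ∈ [0.06, 0.35]`, early ejection click, split and diminished S2)
and a monotone severity–loudness law. It does not contain real turbulence
spectra, spatial source coherence structure, aortic compliance, respiration
or ambient noise — so green tests here demonstrate algorithmic correctness
and recoverability under the stated source model, not clinical performance.

# Wave propagation

Propagation through the thorax is modeled as a homogeneous, isotropic
Kelvin–Voigt medium (density `ρ_s`, Lamé parameters `λ`, `μ`, viscosity
`η`). The frequency-domain displacement Green's tensor of such a medium is

```
G_ij = (i k_p / 12π(λ+2μ)) [δ_ij h₀(k_p r) + Δ_ij h₂(k_p r)]
     + (i k_s / 12πμ)      [2 δ_ij h₀(k_s r) − Δ_ij h₂(k_s r)],
Δ_ij = δ_ij − 3 x_i x_j / r²,
```

with spherical Hankel functions `h₀`, `h₂` (closed forms, valid for complex
argument) and wavenumbers `k_p = ω √(ρ_s/(λ*+2μ*))`,
`k_s = ω √(ρ_s/μ*)`. Viscosity enters through the complex shear modulus
`μ* = μ − iωη` (`λ* = λ`; the viscous stress has the shear form), which
places the wavenumbers on the decaying branch. The acceleration component
`n` at the monitor is

```
â_n(ω) = 2 Σ_k (−iω)² G_nj(r_k, ω) n_{j,k} P̂_k(ω) ΔA_k
```

summed over the 180 lumen panels, evaluated on positive FFT bins up to
1 kHz with the DC bin zeroed (sources are zero-mean fluctuations; the
tensor is singular at ω = 0), conjugate symmetry enforced, and
inverse-transformed. The factor 2 is the traction-free half-space image
correction. R's FFT synthesizes with `e^{+iωt}` while the tensor lives in
the `e^{−iωt}` convention, so the transfer function is conjugated; a test
pins a monochromatic single-panel record to the direct analytic phasor
evaluation at machine precision.

Tissue defaults are calibration values, not measured quantities:
`ρ_s = 1000 kg/m³`, `μ = 2.5 kPa` (shear speed 1.58 m/s), `λ` such that the
bulk speed `√(K/ρ_s)` is 30 m/s, `η = 1 Pa·s`. Note two distinct derived
speeds coexist: the bulk-modulus speed `c_bulk = √((λ + 2μ/3)/ρ_s)` and the
P-wave speed `c_p = √((λ+2μ)/ρ_s)`; the wavenumber uses `c_p`. The monitor
sits at `(0, 8, 4) cm` — 4 cm downstream of and 8 cm anterior of the valve
center, the aortic auscultation post — and the anterior (y) acceleration
component is recorded at 10 kHz for 0.5 s (N = 5000) per beat.

# The classifier

Given M raw records (rows of a matrix):

1. **Normalize and center**: each row is divided by its sup-norm, then the
   ensemble mean of normalized rows is subtracted. The mean is stored and
   reused for prospective cases — the only choice available at prediction
   time.
2. **SMOTE balancing** (development set only): synthetic healthy signals
   `x + λ(x_nn − x)` with `λ ~ U(0,1)` and `x_nn` among the k = 5 nearest
   neighbors, applied to *raw* signals before normalization, bringing
   7 + 22 to a balanced 44.
3. **SVD/PCA**: thin SVD of the centered matrix; features are projections
   on the first P right singular vectors.
4. **Mode count by cross-validation**: stratified 5-fold validation
   accuracy of the downstream LDA for each candidate P (the SVD is
   recomputed per training fold); `P_cv` is the smallest maximizer, and
   training uses `P_train = P_cv + 1` — one extra mode to absorb the
   variance the validation folds add when they rejoin the development set.
   On this generator's well-separated records `P_cv` is small (1–2); the
   convention matters more than the value.
5. **Fisher LDA**: `w ∝ S_W⁻¹(μ_sten − μ_heal)` with ridge
   `1e−6 · tr(S_W)/P · I` (the within-class scatter is singular when
   P approaches M), unit-normalized, oriented so stenotic projects higher.
6. **Threshold**: while the largest healthy and smallest stenotic training
   projections overlap, that pair is excluded; the threshold is the
   midpoint of the surviving extremes. Excluded cases are, by construction,
   misclassified in training — the price of a midpoint rule robust to
   borderline cases.

Diagnostics: `mode_importance()` ranks modes by `|w_p|`, and
`energy_ratio()` computes the stenotic-to-healthy ratio of mean squared
single-mode reconstruction norms, `ER_j > 1` flagging murmur-carrying
modes; both mirror how one audits which temporal features the classifier
actually uses.

# Reproducibility and problem sizes

Every stochastic stage receives an explicit seed; one master seed fans out
to per-stage, per-case children via
`child = (seed·100003 + stage·1009 + index) mod (2³¹−1)`, so datasets are
extensible without perturbing earlier cases, and regeneration is
bit-identical. The default study conditions are 7 healthy + 22 stenotic
development beats (stiffness multipliers spread over [2, 20] on one or two
leaflets, stroke volumes alternating 60/72 ml), SMOTE to 44; prospective
evaluation uses freshly simulated mildly stenotic beats (multipliers drawn
from (1.8, 6]) plus newly synthesized healthy signals. The test suite runs
the full pipeline at these sizes (under five minutes of simulation on one
CPU); the stochastic generalization check averages prospective accuracy
over 20 regenerated test sets and verifies that the LDA projection
increases with total stiffness excess (Spearman ρ > 0.8) along a fixed-seed
severity sweep.

# Limitations

* The source model is a phenomenological surrogate; its gains are not
  traceable to measured turbulent pressure levels.
* The leaflet-uniform pressure load under-represents peak-opening reduction
  (see above); severity is expressed mostly through timing and source
  amplitudes.
* The homogeneous half-space medium ignores ribs, lungs and layering; the
  factor-2 image correction is exact only for a true half-space.
* Classification results quantify recoverability under this generator, not
  clinical accuracy.
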