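---
title: "Quantifying membrane-receptor dynamics and pharmacology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-receptor dynamics and pharmacology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdyn)
```

This vignette is the package's account of the science behind its three
analysis modules — static chemical-shift-anisotropy (CSA) lineshapes,
dipolar order parameters, and depletion-aware binding pharmacology — the
assumptions each model makes, the tunable parameters that matter, and the
design choices taken where the methodology was genuinely open.

## Static ¹⁵N powder lineshapes and the mobile fraction

A membrane protein undergoing fast axially symmetric rotational diffusion
about the bilayer normal averages its ¹⁵N amide chemical-shift tensors to
axial symmetry (asymmetry η = 0). The observable shift at polar angle β
between the symmetry axis and the field is

$$\sigma(\beta) = \sigma_\mathrm{iso} + \Delta\sigma\,\frac{3\cos^2\beta - 1}{3},$$

with span Δσ = σ∥ − σ⊥. Averaged over an isotropic powder, the frequency
density is $p(\sigma) \propto [\Delta\sigma(\sigma-\sigma_\perp)]^{-1/2}$
on the support between the perpendicular edge σ_iso − Δσ/3 (where the
integrable singularity puts the lineshape maximum) and the parallel edge
σ_iso + 2Δσ/3. `powder_pattern()` evaluates this average on a
deterministic grid uniform in cos β (default 512 points; a uniform-cos β
grid carries equal solid-angle weights) crossed with a uniform azimuth
grid used only when η ≠ 0. A deterministic grid was chosen over
random or optimized orientation sets because the average is then exactly
reproducible and directly checkable against the analytic density
(`powder_density_axial()`), which the test suite does to 1%.

Sign convention: the reported span of a motionally averaged amide tensor
is a magnitude; we default to positive Δσ (parallel edge downfield) and
keep the sign configurable, since only the mirror orientation of the
pattern depends on it. The absolute ¹⁵N referencing is cosmetic; fixtures
centre the amide pattern at σ_iso ≈ 119 ppm.

Highly mobile residues average their tensors to (near) isotropy and
appear as narrow lines at their isotropic shifts. `lineshape_model()`
therefore composes a spectrum from unit-area anisotropic components
(Gaussian-broadened — inhomogeneous broadening dominates rigid sites) and
unit-area isotropic lines (Lorentzian — motional narrowing), both
selectable per component. Because each component profile is normalized to
unit area before weighting, weights *are* areas, and the mobile fraction
is pure weight arithmetic,
$f_\mathrm{mobile} = \sum w_\mathrm{iso} / \sum w$, invariant under
global intensity rescaling. Whether one or several anisotropic
components and which broadening model best describe a given spectrum is
not prescribed by the data we emulate; both are configuration.

`fit_lineshape()` is a bounded Levenberg–Marquardt least-squares fit
(via `minpack.lm`) of spans, isotropic shifts, broadenings, centers and
weights, with η held fixed. Default bounds keep isotropic centers within
±8 ppm and spans within ±50% of their initialization — wide enough for
honest recovery tests from 10%-perturbed starts, tight enough to prevent
component swapping. Convergence is only reported when the optimizer
terminates regularly *and* the relative residual stays below a
configurable gate (default 0.5); degenerate inputs such as an all-zero
spectrum yield a flagged, non-converged result rather than an error.

## DipShift dephasing and order parameters

Molecular motions faster than roughly 40 µs scale the ¹H–¹³C dipolar
coupling; the ratio of the motionally averaged coupling to its
rigid-limit value is the order parameter S (1 = rigid, 0 = isotropic).
Under magic-angle spinning the heteronuclear coupling is modulated as

$$\omega(t) = \pi d_\mathrm{eff}\left[\sin^2\beta\,\cos 2(\omega_r t + \gamma)
  - \sqrt{2}\,\sin 2\beta\,\cos(\omega_r t + \gamma)\right],$$

and the separated-local-field (DipShift) observable is the powder average
of the cosine of the accumulated phase over one rotor period.
`mas_dipolar_phase()` integrates ω(t) in closed form; the test suite
verifies the closed form against direct numerical quadrature to below
10⁻⁸ rad. The resulting curves refocus exactly at the rotor period, are
symmetric about τ_r/2 after azimuthal averaging, and deepen monotonically
with |d_eff| — all asserted as properties.

`fit_dipshift()` minimizes over d_eff ∈ [0, 1.2·κ·d_rigid], scanning a
coarse grid before local refinement; when minima tie, the smallest
coupling wins, because noise can alias near-rigid couplings onto larger
ones. An optional single exponential damping amplitude can absorb
relaxation decay (off by default; whether published analyses co-fitted
such a nuisance parameter is generally unstated). The homonuclear
decoupling applied during evolution scales the coupling by κ (FSLG:
1/√3 ≈ 0.577). Because rigid-limit couplings are calibrated
experimentally under the same sequence, κ cancels in the ratio; the
package exposes an effective pre-scaling rigid limit (default 21.5 kHz
for a C–H pair) and applies κ consistently to numerator and denominator,
so order-parameter semantics are independent of absolute calibration.
The short-contact-time, distortion-compensated DipShift variant is
treated as the same dephasing model with a condition label; its
pulse-level corrections are not simulated.

### Cone amplitudes

To express S as a motional amplitude we use diffusion-in-a-cone,
$S = \cos\theta_c(1+\cos\theta_c)/2$, inverted in closed form. The choice
of cone over, e.g., Gaussian axial fluctuation is deliberate: it is the
standard minimal model for segmental wobble and maps the backbone range
S = 0.56–0.69 onto semi-angles of ≈48–42°, i.e. amplitudes of 40–50°.
The conversion is isolated in `cone_angle()` so an alternative
S-to-amplitude model can be swapped in without touching the fits. S = 0
is rejected (the 90° asymptote carries no information — an isotropic
distribution also gives S = 0).

### r-PDLF doublets

INEPT-based polarization transfer only survives for highly mobile, long-T₂
segments (termini). The rotor-encoded proton-detected local-field
experiment yields a symmetric doublet whose splitting is the scaled
coupling, S·κ_R·d_rigid with κ_R = 0.315 for the R18¹₇ symmetry sequence
(the standard theoretical factor; it is configurable because published
work rarely prints it). `simulate_rpdlf()` renders two Lorentzian lines at
±splitting/2; `rpdlf_splitting()` peak-picks the halves; the round trip
recovers S to within one grid step (5 Hz ≈ 0.0007 in S).

## Depletion-aware binding pharmacology

With a fluorescent tracer at L_total = 100 nM against a sub-nanomolar
K_d, free-ligand approximations fail badly. All binding arithmetic
therefore uses exact mass balance. For saturation, the bound tracer is
the quadratic root

$$[RL] = \tfrac{1}{2}\left[(R+L+K_d) - \sqrt{(R+L+K_d)^2 - 4RL}\right],$$

evaluated in its numerically stable product form. Half-maximal signal
falls at receptor concentration L_total/2 + K_d — hence the assay cannot
resolve affinities below L_total/2 (50 nM at 100 nM tracer) no matter how
tight the binding. Fluorescence is modelled as
F = F₀(1 + ε·[RL]/L_total), normalized to the unbound state (100%).
The receptor concentration is treated as *active* receptor; no
active-fraction parameter is fitted by default, so a gap between the
theoretical half-max and an observed inflection is left visible rather
than absorbed.

Competition data are described by the full ternary equilibrium, solved
as a bracketed one-dimensional root in free receptor with Newton
polishing to < 10⁻¹⁰ relative mass balance — exactly checkable, which is
why the numerical equilibrium was chosen over reproducing any specific
closed-form correction algebra: it subsumes the Cheng–Prusoff shift and
ligand depletion simultaneously. `ki_from_ic50()` inverts the model IC₅₀
for K_i and always reports the simple Cheng–Prusoff value
IC₅₀/(1 + L/K_d) alongside. Which arithmetic a given published K_i used
is often ambiguous; at 3.16 µM receptor the two pathways differ by
almost two orders of magnitude, so the package reports both and leaves
the interpretation to the analyst. Root searches bracket
log-concentration over [10⁻⁶, 10⁹] nM.

Hill fits (`fit_hill()`) run on linear response versus log₁₀
concentration, replicates fitted jointly. Under strong depletion the
displacement curve is *not* Hill-shaped; a Hill EC₅₀ is then a biased
IC₅₀ estimator. `ic50_from_data()` (direct half-displacement crossing)
and, preferably, `fit_competition()` (full-curve least squares of the
equilibrium model) are provided for that regime.

## The synthetic-data generators

No raw spectra are available for the system the package targets, so the
`fixture_scenarios()` family generates every input with the statistical
structure the analyses assume, at the reported parameter values: a static
DMPC spectrum with span 133 ppm, 25% isotropic area in narrow lines at
108/116/124 ppm (backbone amides) plus Lys/Arg side-chain lines upfield,
SNR 50; dephasing curves (16 points over one rotor period at 5 kHz MAS,
additive noise sd 0.02, duplicate preparations) at directly excited
backbone order parameters of 0.60–0.67 (POPC) and 0.56–0.65 range (DMPC),
with ligand-bound states within experimental error of apo; r-PDLF
doublets at S = 0.09 and 0.05; and binding assays with multiplicative
CV 5% noise in 9 replicate columns (three independent assays in
triplicate, combined into one curve). The competitor grid spans
10⁰–10⁸ nM because at 3.16 µM receptor the displacement floor is only
reached above ~10⁷ nM.

Two design rules matter for interpreting test results. First, noise-free
generation *is* the corresponding analysis module's forward model — the
generators call `synthesize_composite()`, `simulate_dipshift()`,
`simulate_rpdlf()` and the equilibrium solvers rather than reimplementing
them — so recovery tests probe inversion quality, not model mismatch.
Consequently, passing recovery tests demonstrate that the fits invert
their own forward models under realistic noise; they cannot demonstrate
robustness to physics the forward models omit (multi-spin couplings,
relaxation during evolution, probe backgrounds, baseline roll,
active-receptor fractions). Second, every config carries a mandatory
seed and regenerates bit-identically; true experimental noise levels for
this system are unpublished, so the defaults are plausible stand-ins
chosen once to visually match typical data quality.

Noise-derived test tolerances were established by repeated-seed
Monte-Carlo before being frozen: order-parameter recovery ±0.03 at noise
sd 0.02; mobile-fraction recovery ±0.02 at SNR 50; competition K_i
recovery ±20% (the estimator's spread is ~7% sd under the 9-replicate,
CV 5% design, and ±20% is ≈3 sd — single-crossing IC₅₀ estimates are
about three times noisier, which is why `fit_competition()` exists).

## Numerical choices and problem sizes

* Powder grids: 512 cos β points for simulation, 128–256 during fitting
  (the broadened patterns are smooth, so the coarser fit grid changes
  recovered spans by ≪ 0.1 ppm); 256 × 32 for dephasing simulation.
* Lineshape and Hill fits: Levenberg–Marquardt, ftol/ptol 10⁻¹⁰,
  maximum 200–500 iterations.
* Coupling fits: 61-point bracketing scan plus golden-section refinement,
  tolerance 10⁻⁶ of the search width; ties break to the smallest
  coupling.
* Equilibrium roots: `uniroot` at machine tolerance plus ≤ 8 Newton
  steps; mass-balance failure above 10⁻¹⁰ relative raises an error with
  diagnostics rather than returning a degraded solution.
* Default axes: 0.5 ppm spectral grid, 5 Hz r-PDLF grid, 16 rotor-period
  samples — the scales on which the test suite and the reproduction
  script run in seconds.

## Known limitations

Single-spin-pair dephasing only (no multi-spin or radio-frequency
imperfection effects); no relaxation beyond the optional scalar damping;
no cross-polarization build-up modelling — contact time is metadata used
to label excitation bias, not a modelled quantity; the cone model is one
of several defensible S-to-amplitude mappings; binding is strictly
1:1 equilibrium (no kinetics, cooperativity, or two-site models).
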