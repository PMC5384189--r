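# memdyn

Quantitative analysis of membrane-protein dynamics and pharmacology from
solid-state NMR and fluorescence binding data.

G protein-coupled receptors reconstituted into lipid bilayers are not rigid
bodies: they undergo axially symmetric rotational diffusion in the membrane,
and large parts of the molecule — loops and termini — fluctuate with
amplitudes of tens of degrees. `memdyn` implements the complete analysis
chain needed to quantify this picture from three classes of raw data:

1. **Static ¹⁵N CSA powder patterns.** A static spectrum of a uniformly
   ¹⁵N-labelled receptor is modelled as a sum of an axially symmetric
   (η = 0) chemical-shift-anisotropy powder component — the signature of
   axial rotational diffusion, with observable shift
   σ(β) = σ_iso + Δσ(3cos²β − 1)/3 — and narrow isotropic lines from
   highly mobile residues. Fitting the composite quantifies the *mobile
   fraction*, the share of spectral area in the narrow lines.
2. **DipShift / r-PDLF dipolar couplings.** Under magic-angle spinning, the
   ¹H–¹³C dipolar dephasing over one rotor period is simulated by powder
   averaging the accumulated phase of the rotor-modulated coupling, and the
   motionally averaged coupling d_eff is fitted. The order parameter
   S = d_eff /(κ·d_rigid) (κ the decoupling-sequence scaling, 1/√3 for
   FSLG; 0.315 for the R18¹₇ sequence of r-PDLF) converts to a
   wobbling-in-a-cone amplitude via S = cos θ_c (1 + cos θ_c)/2.
3. **Fluorescence binding assays.** Saturation and displacement data are
   modelled with the exact, depletion-aware 1:1 equilibrium: bound tracer
   from the quadratic mass-balance root, half-maximal signal at receptor
   concentration L_total/2 + K_d, Hill fits of saturation curves, and K_i
   from competition IC₅₀ by both the Cheng–Prusoff correction
   K_i = IC₅₀/(1 + L/K_d) and the exact ternary-equilibrium inversion.

A seeded synthetic-data module generates every input the pipeline consumes
(noisy powder spectra, dephasing curves, r-PDLF doublets, dose–response
tables) together with its generating truth, so the whole chain is testable
by parameter recovery.

## Worked example

```r
library(memdyn)

# Competition pharmacology: IC50 of 6870 nM measured with a 100 nM tracer
# of K_d = 0.15 nM, receptor at 3160 nM
ki_from_ic50(6870, binding_model(k_d = 0.15, l_total = 100,
                                 r_total = 3160, k_i = 10))
#> K_i (depletion-corrected): 0.1813 nM
#> K_i (Cheng-Prusoff):       10.29 nM

# Backbone dynamics: fit a 5 kHz-MAS dephasing curve and convert the order
# parameter to a cone amplitude
dp    <- dipolar_params()                       # d_rigid 21.5 kHz, FSLG 1/sqrt(3)
curve <- simulate_dipshift(0.65 * dp$seq_scaling * dp$d_rigid, dp)
fit   <- fit_dipshift(curve, dp)
fit
#> Order parameter S = 0.650 (d_eff = 8068 Hz, residual 7.73e-11)
cone_angle(fit$order_parameter)
#> Cone semi-angle: 41.8 degrees
cone_angle(0.56)
#> Cone semi-angle: 47.9 degrees

# Mobile fraction of a synthetic static 15N spectrum (truth 25%)
g <- gen_static_spectrum(fixture_scenarios(1)$dmpc_cp8ms)
mobile_fraction(g$truth)
#> Mobile fraction: 25.0% (iso area 0.25, aniso area 0.75)
```

The two K_i values bracket the correction arithmetic: the Cheng–Prusoff
pathway corrects only for tracer occupancy (≈10 nM here), while the exact
ternary equilibrium additionally accounts for receptor/tracer depletion at
3.16 µM receptor, which moves the implied affinity substantially — both are
always reported. The cone semi-angles translate backbone order parameters
in the 0.56–0.65 range into average motional amplitudes of roughly 42–48°.

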