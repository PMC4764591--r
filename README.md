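# mtcontract

Quantitative tools for the bulk contraction of stabilized microtubule
networks in confined channels, treated as an **active fluid** driven by
motor-generated stresses.

## The science

Networks of Taxol-stabilized microtubules in *Xenopus* egg extract
spontaneously contract: dynein clusters microtubule minus ends, pulling the
network together until steric interactions between filaments halt the
compaction at a preferred density. In a thin rectangular channel the
contraction is uniform along the channel length, so the dynamics reduce to
one dimension across the width. The package implements that theory:

- **Mass conservation** — ∂ₜρ = −∂ₓ(ρv), with ρ the microtubule density
  and v the network velocity (density is conserved because the filaments
  are stabilized).
- **Force balance** — η ∂ₓ²v − γv = ∂ₓσ, balancing network viscosity η,
  drag γ against the channel wall, and the gradient of the active stress.
- **Active stress** — σ = s·ρ(ρ − ρ₀): contractile (negative) below the
  preferred density ρ₀, extensile above it. The strength s is proportional
  to the number of active motors; ρ₀ is set by motor–filament geometry
  alone, so inhibiting motors slows contraction without changing the final
  density.

The network edges are free boundaries carrying zero total stress
(η ∂ₓv = σ). The solver is a Lagrangian finite-volume scheme — material
nodes advect with the force-balance velocity and cell masses are conserved
exactly — with adaptive Heun time stepping.

Measured by the fraction contracted ε(t) = (W₀ − W(t))/W₀ and its
exponential-relaxation fit ε(t) ≃ ε∞(1 − e^−(t−Tc)/τ), the theory predicts
the contraction timescale

τ(W₀) = α·η/(sρ₀²) + β·γ/(sρ₀²)·W₀²,

which interpolates between a width-independent viscous regime and a
drag-dominated regime quadratic in channel width, with dimensionless
constants α and β determined numerically from full simulations. The
package also provides the estimation procedures used around this model:
exponential-relaxation curve fits (timepoints with ε > 0.1), least-squares
matching of simulated to measured cross-width density profiles,
four-parameter-logistic (EC50) fits of τ against motor-inhibitor dose, and
projection of fluorescence ratios to the final network tubulin
concentration. An image-analysis chain turns fluorescence stacks into
widths, length-averaged density profiles, and single-pass PIV velocity
fields, and seeded synthetic-microscopy generators produce movies with
known ground truth for end-to-end validation.

## Worked example

Simulate a 1.4 mm channel at the experimentally fitted reduced ratios and
fit the contraction curve:

```r
library(mtcontract)

params <- model_params_from_ratios(eta_ratio = 0.82, gamma_ratio = 1e-5)
geom   <- channel_geometry(W0 = 1400, H0 = 125)
sim    <- simulate_contraction(params, geom, rho_init_ratio = 0.32, t_end = 15)
sim
#> Contraction simulation: W0 = 1400 um, rho_init/rho0 = 0.32
#>   46 snapshots over 15 min (405 internal steps)
#>   final epsilon = 0.6800

fit_contraction_curve(sim$times, sim$epsilon)
#> Contraction fit: eps_inf = 0.7057, tau = 3.096 min, Tc = 0.697 min
#>   rss = 0.0142 over 43 points (epsilon > 0.1)
```

The network contracts to ε ≈ 0.68 — exactly 1 − ρ_init/ρ₀, since the final
density is ρ₀ everywhere — with a characteristic time of ~3 min at this
width. Determining the scaling constants from a full width scan
(eight log-spaced widths, 100–3000 µm) and evaluating the law at the
experimental widths:

```r
sc <- determine_alpha_beta(params)
sc
#> Scaling constants: alpha = 1.987, beta = 0.09195 (fit residual 0.0418)

tau_of_width(c(160, 440, 900, 1400), 0.82, 1e-5, sc)
#> [1] 1.652621 1.807098 2.373883 3.431317

active_stress_scale(2e2, 0.82)   # s*rho0^2 in Pa, from eta ~ 2e2 Pa s
#> [1] 4.065041
```

τ grows from ~1.7 min in a 160 µm channel to ~3.4 min at 1400 µm, and the
fitted reduced viscosity together with an independent viscosity estimate
puts the active-stress scale near 4 Pa.

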