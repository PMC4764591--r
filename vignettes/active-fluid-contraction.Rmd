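---
title: "An active-fluid model of microtubule network contraction: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-fluid model of microtubule network contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# code chunks are illustrative; some run full simulation protocols
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

Stabilized microtubule networks in confined channels contract because
minus-end-directed motors (dynein) pull filament minus ends together, while
steric interactions between filaments resist compaction beyond a preferred
density. `mtcontract` implements the continuum form of this picture in one
dimension across the channel width:

* mass conservation, $\partial_t \rho = -\partial_x(\rho v)$ — the
  filaments are drug-stabilized, so no polymer is gained or lost;
* quasi-static force balance,
  $\eta\,\partial_x^2 v - \gamma v = \partial_x \sigma$ — the network is
  treated as a viscous fluid on the timescales of interest (minutes), with
  drag $\gamma v$ against the static channel wall in the lab frame;
* active stress, $\sigma = s\,\rho(\rho - \rho_0)$ — contractile below the
  preferred density $\rho_0$, extensile above it. Both the contractile and
  the extensile parts scale with the number of active motors, so motor
  inhibition rescales $s$ but leaves $\rho_0$ unchanged. This is the
  model's central testable structure: timescales scale as $1/s$, the final
  density does not move.

The reduction to one dimension rests on two observations about the
experiments this model describes: contraction is uniform along the channel
length, and tears in the network do not perturb the contraction far from
the tear (an effective Poisson ratio near zero), so the width dynamics
decouple. Channel height never enters the dynamics; it is carried as
metadata only.

**Boundary conditions.** The network edges are free boundaries that move
with the material. An unloaded free edge carries zero *total* stress, so
the viscous and active stresses cancel there: $\eta\,\partial_x v = \sigma$
at both edges. This is the unique choice consistent with an unloaded free
boundary, and it is what makes an initially uniform network contract from
its edges: the density discontinuity at the edge concentrates the stress
gradient there.

**Units.** Lengths are micrometres, times minutes, and densities are
normalized so $\rho_0 = 1$. The dynamics of the fraction contracted depend
on $(\eta, \gamma, s)$ only through the reduced ratios
$\eta/(s\rho_0^2)$ (minutes) and $\gamma/(s\rho_0^2)$ (min/µm²);
`model_params_from_ratios()` constructs parameter sets directly on that
two-parameter surface, and the reduced-parameter equivalence is asserted by
a property test.

## Discretization and time stepping

The solver is a **Lagrangian finite-volume scheme**: $N+1$ material nodes
carry $N$ cells of fixed mass; densities are recomputed from conserved
masses and current cell widths. We chose this over a fixed-grid (Eulerian)
scheme for two reasons: total mass is conserved to machine precision by
construction, and the free boundary stays sharp — on a fixed grid the edge
discontinuity smears over cells, and in our experiments with a naive
upwind scheme the smeared edge (plus spurious viscous coupling through
empty cells) underestimates the contraction rate badly at any affordable
resolution.

Each step solves the force-balance two-point boundary-value problem on the
current non-uniform grid (an exact tridiagonal solve, implemented in C++)
and advances node positions with **Heun's method** (explicit trapezoidal,
second order). The adaptive step is

$$\mathrm{d}t \le \min\!\left(c_1\,\frac{\min_i h_i}{\max_i |\Delta v_i|},\;
 c_2\,\frac{\eta}{s\rho_0^2}\right),\qquad c_1 = 0.2,\; c_2 = 0.05 .$$

The first control prevents node crossing; the second resolves the fastest
physical relaxation rate, which is bounded by $s\rho_0^2/\eta$ for all
wavenumbers (viscosity caps the growth rate of short-wavelength modes), so
the explicit scheme is unconditionally within its stability region at
these settings. A node crossing, which would indicate a violated bound,
raises an error rather than being silently repaired.

When $\gamma = 0$ the force-balance problem is a pure Neumann problem,
singular up to a rigid translation; the solver pins the node nearest the
mass centroid and then removes the mass-weighted mean velocity, so the
centre of mass is stationary — the physically distinguished frame.

**Validation.** Three independent oracles cross-check the stepper in the
test suite: (i) for $\gamma = 0$ the density stays uniform and $W(t)$
obeys a scalar ODE integrated with `deSolve` (agreement ≤ 1e−4 relative);
(ii) for $\gamma > 0$ an independent method-of-lines integration (dense
force-balance assembly in R, `lsoda` time integration) reproduces
$\varepsilon(t)$ to ≤ 1e−4; (iii) the linearized spectrum matches closed
forms in both limits (below). Grid convergence is asserted by doubling
`n_cells` from 256 to 512 (≤ 0.1% change in final $\varepsilon$).

## The timescale scaling law and its constants

Near equilibrium the relaxation timescale obeys
$\tau(W_0) = \alpha\,\eta/(s\rho_0^2) + \beta\,\gamma/(s\rho_0^2) W_0^2$.
`determine_alpha_beta()` determines $\alpha$ and $\beta$ the way the
experimental pipeline measures $\tau$: simulate the full nonlinear model
for each width, fit the exponential-relaxation form
$\varepsilon(t) \simeq \varepsilon_\infty(1 - e^{-(t-T_c)/\tau})$ using
only timepoints with $\varepsilon > 0.1$, and regress $\tau$ on
$(1, W_0^2)$. Defaults: $\rho_\mathrm{init}/\rho_0 = 0.32$ (the value the
density-profile fits recover), eight log-spaced widths from 100 to
3000 µm, 200 cells, snapshots every 20 s.

**The fit window is a real choice.** The simulated curves are not exactly
exponential — especially in the drag-dominated regime — so the fitted
$\tau$ depends on how much of the post-contraction plateau the fit sees.
Each width is therefore simulated to a *completion fraction*: the run
stops when $\varepsilon$ reaches 99.9% of its mass-conservation asymptote
$1 - \rho_\mathrm{init}/\rho_0$. We chose this rule because it is
self-contained (it does not presuppose the scaling constants when choosing
a horizon) and mirrors recording a contraction to completion.
`alpha_beta_sensitivity()` tabulates $\alpha$ and $\beta$ over completion
fractions and initial density ratios rather than hiding the dependence;
across completions 0.99–0.9999 the constants move by roughly ±10–15%
around the default protocol's values ($\alpha \approx 2.0$,
$\beta \approx 0.092$, recomputed by `scripts/acceptance.R`).

```{r}
library(mtcontract)
p <- model_params_from_ratios(0.82, 1e-5)
alpha_beta_sensitivity(p, rho_init_ratios = c(0.2, 0.32, 0.5),
                       completions = c(0.99, 0.999, 0.9999))
```

**Linearized spectrum.** `linear_relaxation_time()` builds the Jacobian of
the discrete Lagrangian dynamics about the uniform state $\rho = \rho_0$
(numerically, by central differences of the force-balance velocity) and
returns the reciprocal of the slowest decay rate. Rigid translation is an
exact neutral mode — shifting every node leaves densities and forces
unchanged — and is removed by identifying the eigenvector closest to a
constant, which is far more reliable than an eigenvalue-magnitude cutoff
once finite-difference noise enters. The two limits have closed forms that
the tests check to 1%: $\tau \to \eta/(s\rho_0^2)$ as $\gamma \to 0$
(uniform dilation), and $\tau \to \gamma W^2/(\pi^2 s \rho_0^2)$ as
$\eta \to 0$ (density diffusion with $D = s\rho_0^2/\gamma$ and absorbing
zero-stress edges). Note the nonlinear protocol's $\alpha$ exceeds the
linear value 1: relaxing from a far-from-equilibrium uniform state through
the $\varepsilon > 0.1$ fit window is slower than the asymptotic
near-equilibrium mode.

## Estimation procedures

**Exponential-relaxation fits.** `fit_contraction_curve()` fits
$\max(0, \varepsilon_\infty(1 - e^{-(t-T_c)/\tau}))$ by Levenberg–
Marquardt on the points with $\varepsilon > 0.1$ only (the model curve is
clamped at zero before the lag time; the pre-contraction phase carries no
information about the relaxation). Starting values form a deterministic
grid — $\varepsilon_\infty \in \{0.5, 0.7, 0.9\}$, $\tau \in$
$\{0.5, 1, 2\}\times$ the time to half-maximal contraction, $T_c \in$
$\{0,$ first crossing$\}$ — with the best residual sum of squares winning
and ties broken toward the smaller $\tau$, so fits are bit-reproducible
without random seeds.

**Density-profile fits.** `fit_density_profiles()` adjusts
$(\eta/(s\rho_0^2), \gamma/(s\rho_0^2), \rho_\mathrm{init}/\rho_0)$ so
simulated profiles match measured ones in summed squared difference, with
simulation time zero aligned to the first measured profile (the lag before
contraction is absorbed by that alignment). Two estimator-design details
matter more than the optimizer:

* profiles are compared on the **full channel-width pixel grid**, with the
  measured profile extended by zeros outside its support. Comparing only
  on the measured support makes the objective one-sided — a simulation
  that contracts too slowly (larger $\gamma$) is never penalized for being
  too wide — which under multiplicative pixel noise biased the fitted
  $\gamma$ upward by 10–20%. The symmetric support penalty removes the
  bias (recovery within ~0.5% at 2% noise in the acceptance test);
* the simulated density is **integrated over each pixel footprint**
  (`density_pixels()`), so a pixel partially covered by the network gets
  its covered mass fraction. Point sampling instead makes the objective a
  staircase as the free edge crosses pixel boundaries, and derivative-free
  optimizers stall on its terraces.

Optimization is Nelder–Mead on transformed coordinates (log10 for the two
ratios, logit for the density ratio) from two fixed starts plus a
refinement pass; standard errors come from the numeric Hessian at the
optimum. Static, uniform profile sets are flagged as degenerate — with no
dynamics there is no information about viscosity or drag.

**Dose–response.** `fit_sigmoid_dose_response()` uses the full
four-parameter logistic
$\tau(c) = \tau_\mathrm{low} + (\tau_\mathrm{high} - \tau_\mathrm{low}) /
(1 + (\mathrm{EC}_{50}/c)^{h})$ with $\tau(0) = \tau_\mathrm{low}$. The
parameterization (no plateau fixed, slope free) is a choice and is
recorded in the fit object; at $c = \mathrm{EC}_{50}$ the response is
midway between the plateaus for any Hill coefficient, which the tests use
as a parameterization-independent anchor. Because $\tau \propto 1/s$, the
ratio of timescales between conditions is an inverse ratio of
active-stress strengths (`relative_stress_from_tau()`).

**Final density.** `estimate_final_density()` converts mean network and
monomer fluorescence into a fractional tubulin concentration
$(\rho_N - \rho_M)/(\rho_N + \rho_M)$ at $t = \tau + T_c$, and projects to
$t = \infty$ with the factor
$\left(\frac{1 - \varepsilon_\infty(1 - e^{-1})}{1 - \varepsilon_\infty}\right)^2$,
assuming the network contracts in the vertical direction as it does across
the width. We fixed the orientation of this squared width ratio to the one
that *increases* density as the network contracts (factor > 1): the
flattened form in which the formula is usually written is ambiguous, and
only this orientation is physically consistent with a compacting network.
Multiplying by the extract tubulin concentration (default 18 µM) gives the
final network concentration; note the projected *fraction* can exceed 1
because the network locally concentrates tubulin above the extract
average.

## The image-analysis chain

`analyze_movie()` chains the stages, naming the failing stage in any
error. Individual choices, each exposed as a parameter:

* **Flat-field**: corrected = (raw − offset)/illumination, clipped at 0.
* **Segmentation**: Otsu's threshold by default (an absolute threshold is
  available for reproducibility); the largest connected component is kept.
  A frame whose foreground is less than 1.5× brighter than its background
  is rejected as empty — thresholding pure noise would otherwise always
  "find" something.
* **Rotation**: if the mean of the fitted top and bottom edge slopes
  exceeds one pixel of drift across the image length (|slope| > 1/N
  columns), frames are rebuilt by rotating pixel sub-areas into the new
  grid — a conservative (intensity-preserving to better than 1e−6)
  area-weighted reassignment approximated by 4×4 supersampling. Below the
  threshold, frames pass through bit-identical. Angles above 10° warn:
  that is a fixturing problem, not a rotation to silently fix.
* **Profiles**: frames are averaged along the channel length; the monomer
  background (median intensity outside the network mask, assumed uniform)
  is subtracted; the profile is cropped between the density maxima nearest
  the two network boundaries (accepting maxima above 5% of the profile
  peak; for a flat-topped uniform network the band endpoints are the
  peaks) and normalized to unit integral.
* **PIV**: single-pass, 16 px windows with 8 px step. Correlation is by
  direct multiplication in the frequency domain with zero padding, so the
  correlation is linear, not circular — circular wrap-around systematically
  biases displacements toward zero. The integer peak is taken from the raw
  correlation (robust to noise); the three-point Gaussian sub-pixel
  refinement uses overlap-normalized values, where the triangular overlap
  factor would otherwise bias the fit. Flat windows are marked invalid
  and never interpolated; `mask_piv()` then drops vectors outside the
  network or within 8 px of its edges (box erosion of the mask).

## The synthetic-data generators

Every generator is a deterministic function of its parameters and a seed,
and attaches the generating ground truth. `generate_movie()` renders a
simulation as
`offset + illumination × (gain·ρ + monomer) + noise`, with a separable
vignette for the illumination and Gaussian noise of variance
`poisson_scale × signal + read_noise²` — a Gaussian approximation to shot
noise plus read noise appropriate to EMCCD-scale intensities. Default
geometry mirrors the experiments: channel widths 160–1400 µm, height
125 µm, 3.25 µm pixels (a 2× objective), 20 s frame interval. An optional
**material-attached speckle texture** (a random field in mass-fraction
coordinates, advected exactly with the network) makes the movies
trackable by PIV; a continuum density field alone has no features to
track. The PIV pair generator uses Gaussian speckles of σ = 1 px,
following the standard particle-image-size guidance (2–3 px diameter) for
subpixel correlation accuracy.

What the generators deliberately do not emulate: photobleaching,
aster-scale texture, network tearing, z-sectioning, and real camera gain
statistics (the noise figures are plausible placeholders, exposed in
`optics_model()`). Passing end-to-end tests on these movies therefore
shows the *pipeline* is faithful — rendering a known field and
re-extracting it returns the truth — not that real movies are free of the
excluded effects.

## Problem sizes and determinism

The test suite runs full width scans at 96–200 cells, profile-fit recovery
studies with 50 noisy replicates at 128 cells, and end-to-end movie
analyses on ~300×100 px frames; these sizes keep every check comfortably
converged (the convergence test pins the discretization error) while the
whole suite completes in a few minutes. All stochastic tests fix their
seeds; the width-scan protocol itself is seed-free and bit-reproducible.

## Known limitations

* The exponential-relaxation form is a description, not a solution, of the
  model: fitted $\varepsilon_\infty$ and $\tau$ from simulated curves
  drift by a few percent with the fit window, most visibly in the
  drag-dominated regime. The model's exact statements — final density
  $\rho_0$, final fraction $1 - \rho_\mathrm{init}/\rho_0$, $\tau \propto
  1/s$ — are tested directly on the simulated fields instead.
* Late-time behaviour: the simulated edge-density peaks dissipate as the
  network approaches uniform density $\rho_0$; long-term network aging
  that might preserve such inhomogeneities is outside the model.
* The microscopic origin of $\sigma = s\rho(\rho-\rho_0)$ (motor–filament
  geometry) is taken as given; only the continuum form is implemented.
* Two-pass window-deformation PIV, drift registration, and 2-D/3-D
  simulation are out of scope.
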