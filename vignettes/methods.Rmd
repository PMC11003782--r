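---
title: "Methods: lattice Boltzmann haemodynamics with polynomial chaos uncertainty quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice Boltzmann haemodynamics with polynomial chaos uncertainty quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemouq)
```

# Scope and model

`hemouq` quantifies how uncertainty in the physical and numerical
parameters of a pulsatile blood-flow simulation propagates into wall
shear stress (WSS) risk factors for aneurysm growth and rupture, and
into the accuracy of outlet flow-ratio control used to model peripheral
arterial disease. The pipeline has three layers:

1. a D3Q19 two-relaxation-time (TRT) lattice Boltzmann solver with a
   pressure-responsive elastic wall model, a pulsatile velocity inlet
   parameterized by the Reynolds and Womersley numbers, and two-element
   Windkessel (WK2) outlets that impose Murray-law flow fractions;
2. risk-factor extraction: the WSS vector over a measurement window, and
   the derived fields TAWSS, OSI, ECAP and RRT with their clinical
   threshold masks;
3. a regression polynomial chaos expansion (PCE) over the nine-dimensional
   uncertain input space, giving moments, coefficients of variation (CV),
   coefficient-of-variation ratios (CVR), and variance-based Sobol'
   sensitivity indices, cross-checked against a Saltelli Monte Carlo
   estimator.

Everything runs on synthetic voxel phantoms so the full analysis is
reproducible on one CPU in minutes; no patient geometry is needed.

## Flow solver

Populations $f_i$ on the 19-velocity lattice evolve by collision and
streaming. The TRT operator splits populations into symmetric and
antisymmetric halves over opposite-velocity pairs,
$f_i^\pm = (f_i \pm f_{\bar i})/2$, relaxed with $\tau^+$ and $\tau^-$.
The symmetric time carries the shear viscosity,
$\mu = \rho c_s^2 (\tau^+ - \Delta t/2)$, with
$c_s = \Delta x / (\sqrt3\,\Delta t)$; the antisymmetric time is fixed by
the magic parameter
$\Lambda = (\tau^+/\Delta t - \tfrac12)(\tau^-/\Delta t - \tfrac12)$,
which controls truncation error and stability. At
$\Lambda = (\tau^+/\Delta t - \tfrac12)^2$ the model reduces exactly to
BGK (asserted to round-off in the tests); $\Lambda = 3/16$ places the
bounce-back wall midway between lattice sites and is the default for
validation runs. Macroscopic fields are moment sums with
$P = \rho c_s^2$. The solver monitors the Mach number; a run that
reaches $\mathrm{Ma} = 0.2$ anywhere is flagged invalid, since
compressibility errors scale with $\mathrm{Ma}^2$.

Two implementations exist deliberately: pure-R operations
(`equilibrium()`, `trt_collide()`, `stream()`, the `apply_*()` boundary
functions) that define the scheme readably and serve as the oracle, and
a fused C++ kernel that `run_simulation()` drives. A test asserts both
paths agree to round-off on a phantom exercising every boundary type.

### Boundary conditions

**Walls.** All wall links use one interpolated (Bouzidi linear)
bounce-back rule parameterized by the sub-voxel intersection fraction
$q \in (0,1]$, computed by bisection on the phantom's analytic surface
(0.5 for imported label grids, where the rule reduces exactly to
halfway bounce-back). The elastic response enters through the
thin-walled vessel law
$\Delta r = (1-\sigma^2)\hat r^2 (P - P_0)/(Eh)$ as an outward offset of
the effective wall location, $q \mapsto q + \Delta r/\Delta x$ (clamped
to half a spacing), and through a tangential slip velocity
$u_w = F\,u_t$ where $u_t$ is the adjacent fluid site's tangential
velocity and $F \in (0,1)$ the boundary velocity ratio. $P_0$ is frozen
as the domain-mean pressure at the end of the warm-up, when the elastic
terms switch on. With $F = 0$ and rigid walls the scheme is
bit-identical to plain bounce-back (tested).

**Inlet.** A velocity bounce-back imposes
$u(x,t) = w(x)\,u_c(t)\,\hat n$ with parabolic spatial weights
(1 at the centre, 0 at the rim). The temporal pulse is a documented
analytic stand-in for a measured heartbeat: the first three Fourier
harmonics (plus mean) of a von-Mises bump pair, giving a sharp systolic
peak, a mild diastolic backflow lobe, and a positive beat-averaged flow
(a pure sine-harmonic sum pinned to zero at phase zero integrates to
zero over a beat — no net perfusion — which is physiologically wrong
and makes flow-balance measurements meaningless). The peak velocity and
period derive from $Re = \rho U_{max} r/\mu$ and
$Wo = r\sqrt{\rho\omega_0/\mu}$ as written; a half-cosine ramp lasting
one period joins the rest state to the periodic orbit.

**Outlets.** Each outlet plane is coupled to a WK2 model
$P + RC\,dP/dt = RQ$, integrated by backward Euler at the lattice step.
The resistances scale inversely with the desired Murray fractions
$\phi_j = (r_j/r_{ref})^m$, $R_j = \gamma_R Z_0/\phi_j$, so that equal
outlet pressures enforce the flow split increasingly well as $\gamma_R$
grows; capacitances set a common RC time against the pulsation,
$\omega_0 R_j C_j = \gamma_C$. Pressures are imposed through
anti-bounce-back as gauge differences about their instantaneous mean
(only pressure differences steer the split; the mean would otherwise
push the lattice density far from its reference).

Two numerical choices here deserve justification:

* *Semi-implicit coupling.* The plane flows are measured on the current
  field and the WK2 update is applied within the same step. With a
  one-step lag, the loop formed by the branch inertance
  $L_h \approx \rho\ell/A$ and the Windkessel capacitance rings at
  $\omega \approx 1/\sqrt{L_h C}$; at desk scale and large $\gamma_R$
  (small $C$) that frequency approaches the reciprocal timestep and the
  lagged loop diverges. Removing the lag costs nothing and leaves the
  fixed point $P = RQ$ untouched.
* *Impedance scale.* $Z_0 = s\,\rho c_s/A_{inlet}$ with the fixed
  prefactor $s = 2^{-6}$ (`characteristic_impedance()`). The bare scale
  makes $C = \gamma_C/(\omega_0 R)$ so small at the top of the
  $\gamma_R$ range that the ring frequency exceeds the discrete limit; a
  corner scan over $\Lambda \times \gamma_R \times \gamma_C$ confirmed
  stability with the prefactor at all eight corners. Every property the
  construction must deliver survives: the measured-ratio error decreases
  as $\gamma_R$ grows and is far below 10% at $\gamma_R = 2^{12}$, and
  $\omega_0$ enters the determination of $R$ and $C$.

### Flow measurement

Flow rates are the discrete surface integrals
$Q = \sum (U\cdot\hat n)\,w\,\Delta x^2$ over the plane sites, where the
weight $w$ is the fluid-area fraction of each rim cell at the boundary
face (16-point subsampling of the analytic surface). Without the
weights, the midpoint quadrature overcounts small outlet planes by
several percent. For the global mass-closure check the mass-weighted
flux $\sum \rho\,U\cdot\hat n\,w\,\Delta x^2$ is used: with a
pulse-to-mean flow ratio around six, the volumetric sum misses the
acoustic $\langle\rho'u'\rangle$ correlation and shows an apparent ~4%
imbalance even though the lattice mass does not drift; the mass flux
closes within about 1–2%.

## Risk factors

The WSS vector is extracted locally from the non-equilibrium
populations: the deviatoric second moment scaled by
$-(1 - \Delta t/2\tau^+)$ gives the viscous stress tensor, the traction
against the outward wall normal is projected tangentially. No
finite-difference velocity gradients are formed. Per wall element and
measurement window (trapezoidal quadrature):

* TAWSS $= \frac{1}{T_f-T_s}\int \lVert\tau_w\rVert\,dt$,
* OSI $= \tfrac12(1 - \lVert\int\tau_w dt\rVert / \int\lVert\tau_w\rVert dt)
  \in [0, \tfrac12]$,
* ECAP $= $ OSI/TAWSS, RRT $= [(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}]^{-1}$.

Thresholds (strict comparisons): TAWSS < 0.11 Pa, OSI > 0.30,
ECAP > 2.7 Pa$^{-1}$, RRT > 22.7 Pa$^{-1}$ — the last two follow from
substituting the first two into their definitions. Degenerate cases: an
identically zero traction series has OSI defined as 0; vanishing TAWSS
or OSI $= \tfrac12$ produce infinite ECAP/RRT sentinels that ensemble
means exclude (finite values only).

The measurement window starts between the last four and three beats,
$T_s = t_f - 4T_0 + u\,T_0$ with the phase fraction $u \in [0,1]$ an
uncertain input, and lasts $3T_0$. $t_f$ is derived as warm-up plus
`n_beats` periods rather than hard-coded, since $T_0$ itself depends on
the sampled Womersley number.

## Synthetic phantoms

`build_fusiform_phantom()` voxelizes a straight tube with an
axisymmetric Gaussian bulge $r(z) = r_0 + a e^{-(z-L/2)^2/2w^2}$ — a
smooth single-parameter dilation that produces the circulatory
(non-impinging) flow regime in which the low-shear risk pathway applies;
the tests confirm TAWSS is lower over the bulge than over the necks.
`build_branching_phantom()` runs a trunk into 2–10 parallel child
vessels of distinct radii terminating on a common outlet face, giving
exact axis-aligned outlet planes for ratio control. Site centres sit at
$(i-\tfrac12)\Delta x$; a minimum of 6 sites per radius is enforced
(the reference configuration resolves its smallest vessel with ~11).
Generation is deterministic; connectivity from the inlet is guaranteed
by flood fill (unreachable pockets become solid), and fully enclosed
fluid sites are an error.

What the phantoms do *not* emulate: patient-specific curvature,
tortuosity, branch angles, non-circular lumens and wall-property
heterogeneity. Passing tests therefore demonstrate correctness of the
numerics and the pipeline, not clinical fidelity of any particular
geometry.

## Uncertainty machinery

The default `parameter_space()` is the published nine-input space:
$\Lambda$ log-uniform $[0.0036, 0.25]$, $Re$ uniform $[540, 660]$, $Wo$
uniform $[10.1, 12.3]$, $E$ uniform $[3.32, 27.57]$ MPa (the interval
produced by `e_range_helper()` from the modulus, radius and thickness
uncertainties combined through the group $Eh/\hat r^2$), $F$ uniform
$[0.32, 0.76]$, $m$ uniform $[1, 4]$, $\gamma_R$ log-uniform
$[2^8, 2^{12}]$, $\gamma_C$ log-uniform $[2^{-4}, 2^0]$, and the window
phase fraction uniform $[0, 1]$. The phase-fraction parameterization is
what makes the published CV of the start time reproducible (a uniform
unit interval has CV $1/\sqrt3 \approx 0.577$); CVs are computed from
the closed forms of each distribution, and the CVR of a QoI divides its
CV by the average input CV (0.481 for this space).

Sampling is a seeded Latin hypercube on the unit cube (better-conditioned
regression at $2N_p$ points than plain Monte Carlo), mapped through each
marginal; log-uniform inputs enter the basis through their logarithm so
the transformed marginals are uniform and the tensor-Legendre basis
stays orthonormal. The PCE of total degree $p$ has
$N_p = \binom{n+p}{p}$ terms ($n = 9$: 55 at $p=2$, 220 at $p=3$;
designs use $2N_p$ samples). Least squares goes through a QR
factorization shared across QoIs (one factorization, many right-hand
sides — this is what makes per-wall-element field fits tractable); the
condition number is recorded and rank deficiency is a typed error. On
the orthonormal basis the mean is the constant coefficient, the variance
the sum of squared remaining coefficients, and Sobol' indices are
coefficient-group sums; `mc_sobol_oracle()` (Saltelli pick-freeze with
the Jansen total-order estimator) provides the independent cross-check,
and both routes agree within 0.02 on the Ishigami benchmark.

## Desk-scale study conditions

The published campaign ran a 44.3M-site patient aorta on a
supercomputer; that is out of reach and out of scope here. The
package's campaigns run on phantoms of $10^4$–$10^5$ sites with the
same pipeline semantics. Two condition changes follow from the scale,
both made once:

* `desk_parameter_space()` re-centres $Re$ to 10 and $Wo$ to 6 with the
  same $\pm10\%$ bands (the published centres would give lattice Mach
  numbers far above 0.2 on a millimetre phantom); all other inputs keep
  their published ranges.
* The default campaign runs one warm-up period plus 4 beats (the flow
  reaches a quasi-stationary state after roughly one beat at these
  Womersley numbers; a test confirms window averages shift by under 1%
  when the window moves by a full period), with problem sizes of about
  2–3 × 10^4 fluid sites and 1–2 × 10^3 steps per beat.

Failed samples (divergence at extreme $\Lambda$/$\gamma_C$ corners, or a
Mach breach) are recorded in the run ledger with their reason and
excluded from the regression, with a warning when they exceed 5% of the
design. Campaigns are resumable from the per-sample CSV and are
bit-reproducible under a fixed seed.

## Known limitations

* Newtonian rheology, single lattice (D3Q19), no turbulence model.
* The elastic wall is a local slip approximation of wall motion, not a
  coupled solid; wall inertia and longitudinal tension are absent.
* The high-WSS/impinging-flow risk pathway (WSS gradients), vorticity
  and helicity indicators, and wall normal stress are out of scope.
* Wall averages weight elements uniformly (voxel wall elements are
  near-uniform in area); no area weighting is attempted on the
  staircase surface.
* The WK2 constants are a reconstruction constrained by their stated
  qualitative properties, so absolute outlet pressures are meaningful
  only relative to each other; all reported quantities are ratios or
  wall-shear fields, which do not depend on the absolute scale.

## A minimal session

```{r example, eval = FALSE}
dom <- build_branching_phantom(15e-4, c(6e-4, 6.6e-4), length = 40e-4,
                               dx = 1e-4)
spec <- lattice_spec(1e-4, 1.25e-4, Lambda = 3 / 16)
prof <- inlet_from_numbers(10, 6, r_inlet = dom$inlet_plane$equivalent_radius,
                           n_beats = 4, spec = spec)
phi <- murray_fractions(sapply(dom$outlet_planes, `[[`, "equivalent_radius"))
wk <- windkessel_parameters(phi, prof$omega0, 2^10, 1,
                            Z0 = characteristic_impedance(spec, dom))
st <- run_simulation(dom, spec, inlet = prof, wk = wk,
                     measure = list(start = prof$warmup + prof$T0,
                                    end = prof$warmup + 4 * prof$T0,
                                    sample_every = 4),
                     collect_wss = TRUE)
field <- risk_factor_field(st$wss_series, dom)
summary(field$tawss)
```
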