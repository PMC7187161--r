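---
title: "A four-compartment multiscale model of tumour fluid and drug transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-compartment multiscale model of tumour fluid and drug transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumourperf)
```

## The model

`tumourperf` simulates blood and chemotherapy transport in a vascularised
tumour observed in a dorsal skinfold chamber, idealised as a 1 cm square of
tissue in 2D. The vasculature is split into four interpenetrating continua:
arterioles, venules, capillaries and interstitium. Three length scales
organise the physics - the intercapillary separation $d \approx 50\,\mu$m,
the interarteriole/intervenule separation $s \approx 10^3\,\mu$m, and the
chamber scale $L = 1$ cm - with ratios $\nu = d/s \approx 0.05$ and
$\eta = s/L \approx 0.1$ small enough that periodic averaging applies twice:
once from the capillary scale up to the arteriole/venule scale, once more up
to the chamber scale. Each averaging step replaces explicit vessels by a
porous medium whose permeability tensor is fixed by a unit-cell problem.

On the chamber scale the pressures obey three coupled elliptic equations
(the interstitial pressure coincides with the capillary pressure at this
order):

$$
\nabla\!\cdot\!(h \nabla p_a) = \gamma_a (p_a - p_c), \qquad
\nabla\!\cdot\!(h \nabla p_v) = \gamma_v (p_v - p_c), \qquad
\nabla\!\cdot\!(P \nabla p_c) = \beta (2 p_c - p_a - p_v),
$$

with Darcy velocities $u_a = -(h/\mu)\nabla p_a$,
$u_c = -(\eta P/\mu)\nabla p_c$, $u_t = -(\eta^2 C/\mu)\nabla p_t$. A seeded
artery (upper half of a small circle, 50 mmHg) and vein (lower half,
10 mmHg) drive the flow; all other boundaries are no-flux. The single knob
linking capillary architecture to chamber-scale perfusion is
$P = k\nu^2/\eta^2 = k L^2 d^2 / s^4$, combining the capillary permeability
$k$ with the capillary density (through $d$).

## Coupling coefficients

The exchange coefficients deserve care because the published parameter set
mixes unit systems. We pose the coupled system in chamber units (lengths
measured against $L$) with network permeabilities on their natural $s^2$
scale, and recompute the arteriole/venule coupling ratio from its defining
formula $r = R_a\, s\, S_a/V_p \approx 9.9\times10^{-4}$. In dimensional
form this gives

$$
\gamma_a = \gamma_v = \frac{\eta\, r\, s^2}{n\, L^2}, \qquad
\beta = \frac{r\, s^2}{L^2},
$$

both dimensionless weights on the pressure differences in the
conservation-form equations above. This choice fixes the arteriole pressure
decay length at $\sqrt{h n L^2 /(\eta r s^2)} \approx 2.4$ mm - pressure
variation across the whole chamber, as observed - and makes the capillary
boundary-layer width $\sqrt{P L^2/(2 r s^2)}$ shrink from hundreds of
micrometres near $P \sim 10^{-12}\,$m$^2$ to tens of micrometres at
$P = 10^{-14}\,$m$^2$, where the capillary pressure locks onto the
inter-vessel background of $\approx 30$ mmHg except very near the vessel
circle. A literal reading of the coefficients as $(\eta r/hn)$ and $(r/P)$
per square metre (with the tabulated composite $r = 0.986$) puts every
decay length on the micron scale, so all four fields collapse onto each
other within micrometres of the arcs and the inter-region fluxes vanish;
that reading is still available (`coupling_mode = "literal"`, or explicit
`coupling` overrides) but cannot produce the documented flow regimes. The
tabulated $r$ is kept on the parameter object as `r_literal`; it is not
reproducible from its own formula with any tabulated $s$ (it equals
$(S_a/V_p)\,L$ exactly, suggesting a units slip), which is why the
recomputed value drives the defaults.

Two further unit conflicts are resolved the same way - prefer the value
that reproduces the published derived quantities, keep the literal
available. The separation $s$ defaults to $10^3\,\mu$m (the tabulated
$100\,\mu$m reproduces none of the printed dimensionless groups), and the
interstitial permeability defaults to $4\times10^{-18}\,$m$^2$, the lower
end of the experimentally derived range (the tabulated $0.4\,\mu$m$^2$ is
inconsistent with the printed range of the dimensionless permeability
$\kappa$). The composite $C$ is stored as its printed literal
$4\times10^{-9}\,$m$^2$ with the formula value also exposed.

## Geometry

Region 1 (the tumour) is a central disk of area 0.4948 cm$^2$; the
remainder of the square is region 2, whose capillary bed is held at
$P_2 = k_2 L^2 d^2/s^4 \approx 9.36\times10^{-12}\,$m$^2$. The published
description places the seeded vessel circle asymmetrically but does not
give coordinates. The position matters more than it may appear: if the
circle is displaced only horizontally, the configuration remains
mirror-symmetric about the horizontal axis through its centre, the
reflection maps $(p_a, p_v, p_c) \mapsto (60\,\mathrm{mmHg} - p_v,\;
60 - p_a,\; 60 - p_c)$, and the net interface fluxes $Q_c$, $Q_t$ vanish
identically for every $P$. Our default therefore offsets the circle
diagonally, $(-0.1, +0.1)$ cm from the chamber centre with radius 0.1 cm,
which breaks the symmetry; with this geometry the flux-versus-$P$ curve is
unimodal with an interior maximum near $P \approx 10^{-12}\,$m$^2$ and a
sign change a few $10^{-12}\,$m$^2$ higher, the same locations as in the
published sweep. Geometry and coefficients are fully overridable, and the
mirror-symmetric configuration is kept as a numerical oracle in the test
suite.

## Discretisation

The chamber is meshed by a ray-structured conforming triangulation: rays
from the vessel-circle centre to the outer square, a node layer pinned
exactly on the region interface $\Gamma$, geometric grading towards the
vessel wall, and each quad split into four triangles through its centroid
(so a centred geometry meshes mirror-symmetrically, which the symmetry
oracle exploits). The three pressure fields are discretised with P1 finite
elements assembled into one sparse block system; exchange terms use lumped
masses, the $P$ jump at $\Gamma$ enters through per-element coefficients,
and flux continuity is natural in the weak form. The default resolution is
96 rays with 16 + 24 radial layers (about 7,800 nodes); sweeps and the drug
runs use 48 rays with 8 + 12 layers. Interface fluxes are evaluated in
residual (conservative) form - summing the discrete capillary equations
over the nodes strictly inside $\Gamma$ equates the $\Gamma$ flux to the
exchange source over region 1 - which converges at the scheme's full
second order and makes $Q_t = (\eta C/P)\,Q_c$ hold to machine precision by
construction; a direct edge-quadrature flux is also reported as a
cross-check. The sampled maximum of $Q_c(P)$ is refined by golden-section
search in $\log_{10} P$, with ties resolved to the smaller $P$.

## Unit-cell problems

Capillary and arteriole/venule network permeabilities come from
Poiseuille-network upscaling: each segment of a periodic vessel graph
carries fully developed Poiseuille flow (conductance $\pi r^4/8\mu\ell$,
the exact creeping-flow solution in a tube; the capillary Reynolds number
is $\sim 3\times10^{-4}$), nodal mass balance is solved under a unit
macroscopic pressure gradient with periodic jump conditions, and the
averaged flux yields the tensor. Intrinsic normalisation (divide by vessel
volume) is the default; bulk normalisation (divide by cell volume) is a
flag. A straight tube spanning the cell gives the analytic intrinsic
permeability $r^2/8$ exactly, which the tests assert. Eight fixture
topologies are generated deterministically: a 3x3 square lattice, a
honeycomb, two irregular variants (a documented diagonal-reinforced and a
documented jittered lattice - the published irregular cells are shown only
graphically), and four pruned grids formed by removing one link at a time
in a fixed, recorded order chosen to keep both directions percolating.
Vessel radii are not part of the published geometries; fixtures default to
one tenth of the spacing. Percolation is reported, not assumed.

The interstitial tensor E solves a periodic Laplace-Neumann cell problem
with vessel cross-sections as impermeable inclusions, and the
porous-matrix tensor F the analogous variable-coefficient Darcy problem;
both use cell-centred two-point finite volumes with harmonic face
coefficients on a regular periodic grid, with the zero-mean constraint
projected out. The staircase wall representation makes the scheme
nominally first-order on smooth inclusions. Under intrinsic (1/V_t)
normalisation a dilute square array of insulating disks tends to
$1/(1+\phi)$; under bulk normalisation to the classical 2D Maxwell value
$(1-\phi)/(1+\phi)$, which is the quantity effective-medium formulas
describe and the benchmark the tests use (within 3% at area fraction
0.05 on a 128$^2$ grid, approaching the limit at first order under
refinement).

## Drug transport

Vinblastine is treated as a passive tracer (no decay or binding). The
plasma boundary condition on the artery arc is either a four-exponential
bolus decay or a constant perfusion (8 nM for 120 h). The bolus phases
have half-lives of 1 s, 4 min, 53 min and 1173 min - the printed rate
constants $(41.6, 0.17, 1.3\times10^{-2}, 5.9\times10^{-4})$ min$^{-1}$
correspond to these, and both the printed and recomputed $\ln 2/t_{1/2}$
rates are selectable. Amplitudes solve the full 4x4 linear system from the
2700 nM dose and the three later conditions (700 nM at 4 min, 150 nM at
53 min, 10 nM at 1173 min), giving (1565, 855, 260, 20) nM against the
reported (1557, 862, 261, 20) nM; the sub-1% differences come from the
rounding of the printed rates.

Chamber transport couples the three concentration fields through advection
by the frozen fluid velocities and wall exchange. The advection operator
uses the concentration form $u\cdot\nabla c$: the homogenised velocity
fields are not divergence-free (fluid leaks between compartments), and a
parcel losing fluid at its own concentration keeps its concentration, so
advecting $c$ - rather than conserving $cu$ - is the physically correct
reading and the one that admits the uniform constant-perfusion equilibrium
(all compartments at 8 nM), which the solver reproduces to round-off via a
direct steady solve. Spatially we use P1 Galerkin convection with
algebraic upwind stabilisation (the discrete operator annihilates
constants and has the M-matrix sign pattern), a small stabilising
diffusion $D_{num} = \eta^2 U L = 2.5\times10^{-9}\,$m$^2$s$^{-1}$
standing in for the neglected next-order terms, lumped-mass exchange and
implicit Euler in time (positivity-preserving at any step size) on
piecewise-constant step blocks graded from 10 s during the bolus transient
to 4 h in the tail.

The wall transfer coefficient is the least constrained parameter in the
model: its printed value $23.1\times10^{-12}$ is quoted in s$^{-1}$ while
the membrane law that defines it uses velocity units, and no measurement
exists. We default to the dimensionally closed velocity reading in SI
($2.31\times10^{-11}\,$m/s divided by $\eta^2$), giving exchange rates
$S_a T_a/V_a \approx 1.5\times10^{-6}\,$s$^{-1}$ and
$S_a T_a/V_p \approx 2.3\times10^{-7}\,$s$^{-1}$; the plain-rate reading
is selectable (`drug_transfer_units = "rate"`). Varying it shifts the
timing and peak of the capillary concentration, not the qualitative
conclusions.

## Cell kill and treatment comparison

Drug exposure converts to cell kill through the saturating law
$M(c) = \rho_1 c/(\rho_2 + c)$ with maximal rate $\rho_1 = 1/24$ h$^{-1}$
and half-maximal concentration $\rho_2 = 2$ nM. The interstitial volume
fraction evolves pointwise by $\partial_t\phi = (K - M(c_c))\,\phi$ with
proliferation rate $K \in \{1/29, 1/31, 1/33\}$ h$^{-1}$ and initial
condition $\phi(x, 0) = n_t$, the interstitial volume fraction of the
region-1 unit cell ($n_t = x/(1+x)$ for tabulated $V_t/V_c = x$; the
tabulated ratios for the eight networks are packaged as inputs). The ODE
is linear in $\phi$, so each stored-output interval is integrated exactly
with $c$ linear in time (the integral of $M$ along a linear segment has a
closed form); for constant exposure the integrator matches the closed form
to $10^{-6}$ relative by construction, and for spatially uniform exposure
$\phi^{av}$ scales exactly with the initial condition - the ratio of
final $\phi^{av}$ between the honeycomb and most-pruned-grid initial
conditions is $0.8678/0.6287 = 1.380$ for any uniform exposure history.
Both regimes run over the same 712 h horizon for comparability. The
second-dose time is the global minimum of $\phi^{av}(t)$, earliest-time
tie-break, with boundary minima flagged explicitly.

## Known limitations

* **Second-dose timing.** With the four-exponential bolus gone by
  $\sim$100 h and symmetric wall exchange, the capillary exposure budget is
  bounded by $\int c_c\,dt \le \tfrac12\int\sigma\,dt \approx 490$ nM h
  regardless of the transfer coefficient: the capillary concentration
  cannot stay above the $\approx 6.9$ nM needed for $M > K$ for more than a
  few days, and at the default transfer rates it peaks below 1 nM, so
  $\phi^{av}$ grows monotonically and the model reports a boundary minimum
  rather than an interior one at two weeks. `second_dose_time()` flags
  this honestly. An interior minimum requires either a much faster wall
  transfer (pushing the kill into saturation, which reverses the regime
  ordering below) or drug kinetics with tissue retention, which are out of
  scope here.
* **Regime ordering.** At the default (slow) transfer rates the kill term
  stays in its linear range, where the earlier-delivered injection
  exposure strictly dominates the equal-total-dose perfusion - the
  injection-beats-perfusion ordering holds for all three proliferation
  rates, but the margin is small because the two exposures integrate to
  nearly the same plasma dose (985 vs 960 nM h).
* The printed flux magnitudes at the perfusion optimum are not reproduced
  (and are mutually inconsistent with the exact ratio
  $Q_t/Q_c = \eta C/P$); the sweep's shape, maximum location and
  sign-change location are.
* One-way coupling only: the fluid solution is frozen during drug
  transport; no lymphatics, no vascular remodelling, no tumour growth
  mechanics, no non-Newtonian blood rheology, 2D only.
* The synthetic unit-cell fixtures reproduce topology classes, not imaged
  vasculature; passing tests demonstrate correctness of the upscaling
  machinery, not fidelity to any particular tumour's network.

## Problem sizes

Default runs use the 7,800-node chamber mesh for single pressure solves
and a 2,000-node mesh for parameter sweeps and drug transport; unit-cell
problems use $128^2$ periodic grids and 4-9-node vessel graphs. These
resolutions keep a full pipeline run (fluid solve, 15-point sweep, both
dosing regimes, three proliferation rates) under a minute on one CPU while
leaving the reported quantities mesh-converged at the percent level.
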