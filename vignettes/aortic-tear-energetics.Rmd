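---
title: "Energetics of aortic dissection tear propagation: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics of aortic dissection tear propagation: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortafract)
```

## The problem

In an aortic dissection, a tear in the inner wall lets pressurized blood
split the wall into a true lumen and a false lumen, separated by an intimal
flap. Whether the tear keeps growing is a fracture-mechanics question: the
tear advances when the energy release rate $G$ — the drop in total potential
energy per unit of new crack area — reaches the tissue's fracture energy
$\Gamma$. `aortafract` computes $G$ semi-analytically for a plane-strain
cross-section of a type-B-like dissection, in the longitudinal direction
(normal slices converting to dissected slices) and the circumferential
direction (the tear widening within a slice).

Everything is deterministic. Dimensionless runs use shear modulus $\mu = 1$
and mean radius $R = 1$; pressures are reported as $P/\mu$ and release rates
as $G/(\mu R)$. Dimensional inputs are handled transparently because only
these ratios enter the results (a property the test suite checks to
$10^{-8}$).

## Cross-section models

**Geometry.** The stress-free cross-section is an annulus of mean radius
$R$, wall thickness $H_2$ (true-lumen wall thickness), inner radius
$R_{in} = R - H_2/2$, outer radius $R_{out} = R + H_2/2$. The tear spans the
angle $2\alpha_{lim}$ and leaves a false-lumen wall of thickness
$H_1 \le H_2$ outside the crack surface at
$R_c = R + H_2/2 - H_1$. "Tear depth" grows as $H_1/H_2$ falls.

**Materials.** Incompressible plane strain reduces all kinematics to one
circumferential stretch $\lambda$ (with $\lambda_r = 1/\lambda$,
$\lambda_z = 1$):

* Neo-Hookean: $\hat W = \tfrac{\mu}{2}(\lambda^2 + \lambda^{-2} - 2)$;
* Gent: $\hat W = -\tfrac{\mu J_m}{2}\ln[1 - (\lambda^2 + \lambda^{-2} -
  2)/J_m]$, with strain capped by $J_m$ (limiting stretch
  $\lambda_{max}$ solves $\lambda^2 + \lambda^{-2} - 2 = J_m$; for
  $J_m = 1$ it is the golden ratio);
* HGO: Neo-Hookean matrix plus a tension-only exponential fiber term
  $(K_1/K_2)(e^{K_2 (I-1)^2} - 1)$ with
  $I = \lambda^2\cos^2\beta + \sin^2\beta$. The default fiber angle
  $\beta = 45^\circ$ (representative of the media) gives
  $I = \lambda^2/2 + 1/2$. The general-$\beta$ form is implemented and
  tested; $\beta = 90^\circ$ degenerates exactly to Neo-Hookean because the
  fibers then never stretch in plane.

**Normal section** (`solve_normal_ring`). The uncracked annulus is solved
exactly: incompressibility forces $r(\rho) = \sqrt{a^2 - R_{in}^2 +
\rho^2}$, and the deformed inner radius $a$ is the root of
$\int_{R_{in}}^{R_{out}} \lambda \hat W'(\lambda)\, \rho/r^2\, d\rho = P$.
The total potential energy per unit length is
$U_I = W_{SE} - P\,\Delta A_{in}$ with $W_{SE}$ integrated over the
*reference* wall area (by incompressibility equal to the deformed area) and
$\Delta A_{in} = \pi(a^2 - R_{in}^2)$ the lumen gain. Equilibrium is
equivalently the minimum of $U_I(a)$ over the kinematic family, which the
oracle module exploits as an independent check.

**Dissected section** (`solve_dissected_section`, the default
`single_circle` model). The dissected cross-section is treated as a closed
thin-wall membrane with two segments: the intact wall ($H_2$, reference
mid-surface arc $L_2 = (2\pi - 2\alpha_{lim})R$) and the false-lumen wall
($H_1$, $L_1 = 2\alpha_{lim} R_{fl}$ at its mid-surface
$R_{fl} = R + H_2/2 - H_1/2$). The flap carries no load (equal pressure on
both sides), so at the two junctions tension and tangent must be continuous
— two membrane segments meeting at a point can balance in no other way —
and the deformed mid-surface is a single circle of radius $\rho$. Each
segment obeys $T = H_i \hat W'(\lambda_i)$ and Laplace's relation
$T = P\rho$; $T$ solves the closure equation
$\lambda_1(T) L_1 + \lambda_2(T) L_2 = 2\pi T/P$. The reported
$U_{II} = W_{SE} - P\,\Delta A_{in}$ accounts the lumen area on *inner*
surfaces (reference inner surfaces at $R_{in}$ and $R_c$, deformed at
$\rho - h_i/2$ with $h_i = H_i/\lambda_i$), since the pressurized region is
bounded by the inner aortic wall.

A work-conjugacy subtlety is worth recording: the variational principle
whose Euler--Lagrange condition is exactly $T_1 = T_2 = P\rho$ uses the
*mid-surface* enclosed area $\pi\rho^2$ in the pressure term. Minimizing
the inner-surface-bookkept $U_{II}$ instead would shift the stationary
point at relative order $(H/R)^2 \sim 10^{-4}$. The solver therefore
implements the mechanical equilibrium (tension continuity + Laplace), and
the constrained-minimization oracle minimizes the work-conjugate potential,
comparing the reported $U_{II}$ at the minimizer; they agree to better than
$10^{-9}$ relative.

**Mixed fidelity.** Following standard practice for this configuration,
$U_I$ comes from the thick-wall solver and $U_{II}$ from the membrane
model; `normal_model = "membrane"` switches the normal section to the
uniform membrane for an all-membrane consistency mode (the two agree within
1% at $H_2/R = 0.01$, a tested thin-wall limit).

## Energy release rates

* Longitudinal: $G = (U_I - U_{II}) / (R_c \cdot 2\alpha_{lim})$. The crack
  length is the reference (stress-free) arc length of the crack surface,
  and $U_I$ always uses the full-thickness ring regardless of $H_1$.
* Circumferential: an upwind (forward) difference,
  $G = [U_{II}(\alpha_{lim}) - U_{II}(\alpha_{lim} + \Delta\alpha)] /
  (R_c \cdot 2\Delta\alpha)$, with $\Delta\alpha = 4^\circ$ by default. The
  scheme is first-order; a centered-difference oracle and a
  $4^\circ \to 2^\circ$ refinement check are part of the test suite.

Both are reported as $G/(\mu R)$, the same normalization under which the
clinical fracture energies become $\Gamma/(\mu R)$ (with
$\Gamma = 76$ and $51\,\mathrm{J/m^2}$ longitudinally and
circumferentially, $\mu = 157$ kPa, $R = 20$ mm: about 0.024 and 0.016,
see `gamma_over_muR`).

## The alternative dissected-section model

The two-segment single-circle membrane is the cleanest reading of a
force-free flap, and it satisfies every qualitative trend the model family
is expected to show (see below). It has, however, a structural consequence:
as $H_1 \to H_2$ the dissected section degenerates smoothly to the uniform
ring, so the energy released by the *presence* of the tear itself vanishes
and shallow tears release almost nothing. Finite-element solutions of
dissected sections instead show the freed false-lumen wall bulging outward
even without a thickness deficit.

`solve_dissected_bulge` (`dissected_model = "bulge"`) implements that
alternative: the intact wall keeps the thick-ring solution over its angular
extent, while the false-lumen wall is a membrane arc pinned at the deformed
crack edges (material points at $R_c$), bulging outward as a circular arc
with its own Laplace radius $\rho_b = T/P$. The bulge half-angle solves the
tension balance $H_1 \hat W'(\lambda_1) = P c/(2\sin\varphi)$ with pin
chord $c$.

Quantitatively the two models bracket the physics: at the clinical
operating point (Gent $J_m = 1$, $\alpha_{lim} = 30^\circ$, $H_2/R = 0.2$)
the single-circle model needs $P/\mu \approx 0.31$ before even the
shallowest tears ($H_1/H_2 = 0.9$) reach the longitudinal threshold
$\Gamma/(\mu R) = 0.024$, while the pinned-bulge model needs
$P/\mu \approx 0.18$ and shows a much flatter depth dependence. Clinical
threshold estimates for this configuration sit lower still
($P/\mu \approx 0.12$), suggesting the true compliance of the dissected
section lies beyond both reconstructions; the package keeps the
single-circle model as the default because it satisfies the full set of
qualitative orderings in both propagation directions (the bulge model
violates the circumferential thickness and angle orderings, a consequence
of its fixed-ring intact sector), and ships the bulge model as an explicit,
tested option rather than a silent replacement.

## Parameter studies and the safety map

`run_figure_sweeps` packages the standard trend studies as named presets
(`"3a"`–`"6d"`): release rate versus pressure while varying wall thickness
$H_2/R \in \{0.15, 0.2, 0.25\}$, tear depth
$H_1/H_2 \in \{0.3, 0.5, 0.7, 0.9\}$, Gent $J_m \in \{1, 10, 100\}$, HGO
$K_1/\mu \in \{0, 0.05, 0.2\}$ (at $K_2 = 1$) and $K_2 \in \{0.5, 1, 2\}$
(at $K_1/\mu = 0.05$), plus release rate versus crack angle
($10^\circ$–$160^\circ$) at $P/\mu \in \{0.05, 0.1, 0.15\}$. Gent sweeps
run to $P/\mu = 0.15$; Neo-Hookean sweeps stop at $P/\mu = 0.10$ because
the thick ring reaches its inflation limit point near
$P/\mu = \ln(R_{out}/R_{in})$ ($\approx 0.15$ at $H_2/R = 0.15$) and the
membrane at $P/\mu = H/R$. The qualitative expectations, all enforced by
the acceptance tests:

* $G$ increases with pressure, in both directions;
* $G$ falls as $H_2/R$ rises (thicker walls stretch less);
* $G$ rises as $H_1/H_2$ falls (deeper tears leave a thinner false-lumen
  wall);
* stiffening suppresses $G$: smaller $J_m$, larger $K_1/\mu$, larger $K_2$;
* versus crack angle, longitudinal $G$ is non-monotonic with an interior
  minimum (crack length grows linearly while the energy gap grows faster at
  wide angles, and diverges as $1/\alpha$ at narrow ones), while
  circumferential $G$ increases monotonically.

`build_safety_map` evaluates $G/(\mu R)$ on a pressure × tear-depth grid
(defaults $P/\mu \in [0.01, 0.15]$ step 0.005, $H_1/H_2 \in [0.3, 0.9]$
step 0.05) and shades the region at or above $\Gamma/(\mu R)$;
`critical_pressure` bisects (tolerance $10^{-3}$ on $P/\mu$) for the
smallest pressure at which the *entire* depth range propagates, i.e. the
worst-case shallow tear. The safety-map boundary and the bisection are
cross-checked against each other in the tests.

## Numerical choices

* Quadrature: adaptive Gauss–Kronrod (`stats::integrate`) at absolute
  tolerance $10^{-10}$ on dimensionless integrands, always in the reference
  variable $\rho$ so the domain is fixed. Near the Gent strain limit the
  integrand is log-singular; the quadrature wrapper retries at reduced
  tolerance before accepting the last estimate.
* Ring root: bracket from $R_{in}$, geometric expansion toward the cap
  ($R_{in}\lambda_{max}$ for Gent, $100 R_{in}$ otherwise), Brent's method
  to $10^{-12}$ relative; converged residuals are below $10^{-9}\mu$.
  Pressure sweeps can warm-start from the previous solution.
* Membrane root: the closure function is positive at $T \to 0^+$ and its
  root is bracketed by doubling; at or above the inflation limit point the
  closure gap decays like $\lambda^{-3}$ and rounding noise could fake a
  root, so stretches beyond 50 (far outside any soft-tissue regime,
  reachable only within $\sim 10^{-7}$ of the limit pressure) are treated
  as no-equilibrium.
* Tension inversion to $10^{-12}$; for Gent the bracket is capped just
  below $\lambda_{max}$, where the derivative diverges, so a solution
  exists for any finite tension.
* Degenerate inputs: $P = 0$ returns reference states exactly (no
  degenerate root solve); $H_1 = H_2$ makes the two membrane segments
  identical, $U_{II}$ independent of $\alpha_{lim}$ and circumferential $G$
  exactly zero.
* The oracle minimizers use deterministic multi-start Nelder–Mead; the
  whole package is seed-free and bit-reproducible.

## What the parameter grids emulate — and what they do not

The built-in grids represent a healthy-to-dissected descending aorta:
$H_2/R \approx 0.15$–$0.25$, physiological-to-hypertensive pressures
$P/\mu \lesssim 0.15$ (with $\mu \approx 157$ kPa, $P/\mu = 0.1$ is about
118 mmHg), strain-stiffening in the clinically fitted range. Passing all
trend tests on these grids shows the model family is internally coherent
and reproduces the directional physics; it does not validate patient-level
prediction. Real aortas add residual stress, axial pre-stretch,
through-thickness layering, flap contact and hemodynamic loading, all
outside this model (and deliberately so: plane strain, no residual stress,
no axial stretch, quasi-static pressure). Problem sizes in the tests are
small by design — single solves take milliseconds, the full qualitative
battery a few hundred solves — so the entire suite runs in well under a
minute of CPU.

## Known limitations

* The dissected-section compliance is bounded by two idealizations
  (single-circle and pinned-bulge); absolute $G$ levels at shallow depth
  carry model-form uncertainty of roughly a factor two, and threshold
  pressures inherit it.
* The membrane treatment smooths the thick-wall stress concentration at
  the crack edges; no stress-intensity or process-zone information is
  produced.
* Neo-Hookean sections cease to exist above their inflation limit points;
  the solvers report this as a classed no-equilibrium error rather than
  extrapolating.
* The HGO variant uses a single mean-fiber family; dispersion and the
  two-family form are not implemented.
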