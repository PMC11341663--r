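# aortafract

Fracture mechanics of aortic dissection tear propagation.

In an aortic dissection, a tear in the intima lets pressurized blood split
the aortic wall into a true and a false lumen. Whether the tear propagates
is governed by the Griffith balance between the energy release rate *G* —
the drop of total potential energy per unit of new crack area — and the
tissue's fracture energy Γ: propagation is favored when G ≥ Γ. `aortafract`
computes *G* semi-analytically for a plane-strain cross-section of the
dissected aorta, for researchers in cardiovascular biomechanics and soft
tissue fracture who want a fast, transparent alternative to finite-element
models for parameter studies.

## Model

The cross-section is described by mean radius *R*, wall thickness *H₂*,
false-lumen wall thickness *H₁* and crack half-angle *α_lim* (the tear
spans 2 α_lim, its surface sits at *R_c = R + H₂/2 − H₁*). The wall is an
incompressible hyperelastic solid in plane strain (λ_z = 1), with
Neo-Hookean, Gent (strain limit *J_m*) or HGO (fiber parameters *K₁, K₂*,
angle β) strain-energy density Ŵ(λ).

Total potential energy per unit axial length, for a section at pressure
*P*:

    U = W_SE − P ΔA_in

* Normal section: exact thick-wall solution. Incompressibility gives
  r(ρ) = √(a² − R_in² + ρ²); the deformed inner radius *a* solves
  ∫ λ Ŵ′(λ) ρ/r² dρ = P. This yields *U_I*.
* Dissected section: two-segment thin-wall membrane (intact wall H₂,
  false-lumen wall H₁), force-free intimal flap, common tension
  T = H_i Ŵ′(λ_i) = P ρ on a single deformed circle closed by
  λ₁L₁ + λ₂L₂ = 2πT/P. This yields *U_II*. (A pinned-bulge alternative,
  `dissected_model = "bulge"`, is also implemented; see the methods
  vignette.)

Energy release rates, normalized by μR:

* longitudinal: G = (U_I − U_II) / (R_c · 2 α_lim)
* circumferential (upwind, Δα = 4° by default):
  G = [U_II(α_lim) − U_II(α_lim + Δα)] / (R_c · 2 Δα)

Clinical thresholds enter as Γ/(μR) (`gamma_over_muR`); safety maps and
critical pressures compare G/(μR) against them.

## Worked example

The published operating point: Gent material with J_m = 1, H₂/R = 0.2,
H₁/H₂ = 0.5, α_lim = 30°, at pressure P/μ = 0.1.

```r
library(aortafract)

g <- geometry_from_ratios(0.2, 0.5, 30)   # H2/R, H1/H2, alpha in degrees
m <- material("gent", Jm = 1)

solve_normal_ring(g, m, p = 0.1)
#> <ring_state> p/mu = 0.1: a = 1.0752562 (a/R_in = 1.19473)
#>   W_SE = 0.059524805, dA_in = 1.0875439, U = -0.049229581, residual = 2.78e-17

solve_dissected_section(g, m, p = 0.1)
#> <membrane_state> p/mu = 0.1: T = 0.12022048, rho = 1.2022048
#>   lam_fl = 1.304575, lam_wall = 1.168685, U = -0.060158429, closure = 0.00e+00

energy_release_longitudinal(g, m, p = 0.1)
#> <energy_release> longitudinal: G/(mu R) = 0.0104363  (p/mu = 0.1)

energy_release_circumferential(g, m, p = 0.1)
#> <energy_release> circumferential: G/(mu R) = 0.0109244  (p/mu = 0.1)
```

Reading the numbers: pressurization inflates the ring (inner radius grows
19%, hoop stretch largest at the inner wall) and lowers its potential
energy to U_I = −0.0492 (pressure work outruns stored strain energy). The
dissected section is softer — the thinned false-lumen wall stretches to
λ = 1.30 versus 1.17 for the intact wall — so U_II = −0.0602 is lower
still; the gap, divided by the reference crack length R_c·2α_lim ≈ 1.047,
gives G/(μR) ≈ 0.0104 for converting normal to dissected slices, and the
upwind widening of the same tear gives ≈ 0.0109.

With the clinical fracture energies (76 and 51 J/m², μ = 157 kPa,
R = 20 mm), `gamma_over_muR` gives thresholds Γ/(μR) = 0.0242
(longitudinal) and 0.0162 (circumferential): at this pressure and geometry
neither direction would propagate. `build_safety_map()` and
`critical_pressure()` map where in (pressure × tear depth) space that
changes, and `run_figure_sweeps()` reproduces the standard trend studies
(pressure, thickness, tear depth, strain stiffening, fiber anisotropy,
crack angle).

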