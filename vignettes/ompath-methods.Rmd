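---
title: "Methods: transition paths on two-well elastic-network surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transition paths on two-well elastic-network surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ompath)
```

## The two-well picture

`ompath` models a conformational change as motion on two intersecting
harmonic wells, one centred at each experimentally determined end-state
structure. Each well's energy is the quadratic form
`U(x) = 1/2 (x − a)ᵀ H (x − a)` with `H` an elastic-network Hessian built
around the equilibrium coordinates `a`. The assumptions inherited from that
choice are the usual elastic-network ones: the energy surface near each
minimum is quadratic, the network topology is frozen at the equilibrium
geometry, and the absolute energy scale is arbitrary (the two wells share a
zero at their own minima). Everything downstream — barriers, times, free
energies — is therefore *relative*; no absolute rates are attempted.

## Hessian flavors and their parameters

Three stiffness models are provided.

**ANM.** Identical Hookean springs between every atom pair within a cutoff.
Defaults: `k_anm = 1` (reduced energy/Å²) and cutoff 12 Å for all-atom
models, 15 Å for CA-only models — standard elastic-network practice, both
exposed as arguments. The cutoff trades sparsity against connectivity; a
disconnected network is refused with the component count.

**ANM + torsion.** Plain distance springs cannot distinguish backbone from
side-chain flexibility; adding harmonic dihedral restraints is known to
recover most of the gap to full force-field normal modes at negligible cost.
Each dihedral contributes `k_torsion (∇θ)(∇θ)ᵀ` at equilibrium (the second
term of the chain rule vanishes because `θ = θ₀` there). The Cartesian
gradient `∇θ` uses the standard normal-vector formulas and is validated
against finite differences; collinear (degenerate) dihedrals are skipped
with a warning, since `θ` is undefined there. `k_torsion` defaults to 1 in
reduced units, applied uniformly to φ, ψ and χ; it is a single global scale
because the network model's `k_anm` is equally schematic, and both can be
rescaled per run. For CA-only structures, where φ/ψ/χ do not exist, the
package enumerates pseudo-dihedrals over every four consecutive CA sites —
the torsional-network-model convention for coarse-grained chains — so the
torsion-augmented flavor remains meaningful at CA resolution.

**AMWEH.** For CA-only work the pair stiffness follows an empirical,
distance-dependent law fitted to all-atom molecular-dynamics fluctuations:
linear (`8.6e5·r − 2.39e5` kJ mol⁻¹ nm⁻²) below 0.4 nm and `128·r⁻⁶` above.
The two branches deliberately do not meet at 0.4 nm; the discontinuity is
part of the published fit and is reproduced as printed rather than smoothed.
The law is positive only above 0.278 nm; physical CA–CA contacts sit well
above this, and a violation triggers a warning. Pair constants are weighted
by `√(mᵢmⱼ)/m̄` — the geometric mean keeps the matrix symmetric, and the
normalisation by the mean site mass keeps the weight dimensionless and of
order one (a uniform rescaling of all masses cancels exactly). Whether mass
weighting should multiply or divide is not fixed by the verbal description
we reconstruct; the multiplicative choice lives in one isolated expression
in `build_amweh_hessian()`. The law is stated per nm; the assembled Hessian
is converted once to Å⁻² units so energies combine with the package-wide Å
coordinates.

## Mode spectra and mean force constants

Hessians are diagonalised densely (`eigen`, symmetric path). Eigenvalues
below `1e-9 × λ_max` are flagged as rigid-body modes — six for a
non-collinear structure, five for the collinear diatomic — and covariance
eigenvalues are the reciprocals of the vibrational eigenvalues
(pseudo-inverse convention). An eigenvalue below `−1e-8 × λ_max` signals a
broken Hessian and is an error, not a warning.

The mean force constant `k̄` that sets the time scale can be estimated three
ways: the arithmetic mean of the vibrational eigenvalues (*trace*), the
softest vibrational mode (*FPC* — the mode of largest amplitude, hence the
largest covariance eigenvalue), or the *inverse mean*: sort covariance
eigenvalues in decreasing order, keep the leading modes whose cumulative sum
first reaches a variance fraction (default 0.95), and invert the mean of the
kept values. The variance fraction is read against the *equilibrium*
covariance spectrum; reading it along the trajectory instead would reweight
modes by the end-state displacement, and we note this as the plausible
alternative. The trace estimator excludes zero modes so that all three
estimators act on the same support (a flag restores the literal trace over
3N if wanted). The three satisfy `FPC ≤ IM ≤ trace`, with equality only for
a flat spectrum, and `IM` at fraction 1 is exactly the harmonic mean.

## The in-well path and the transition state

The most probable path of an overdamped system inside one quadratic well,
between pinned states `x₁` at `t₁` and `x₂` at `t₂`, separates in the
well's normal modes; each vibrational modal coordinate obeys
`q'' = Γ² q` and the boundary conditions, giving
`q(t) = [q₁ sinh(Γ(t₂−t)) + q₂ sinh(Γ(t−t₁))]/sinh(Γ(t₂−t₁))`. Zero modes
interpolate linearly. This form is the unique solution of the modal
boundary-value problem, which is how the implementation pins it down (and
how the tests check it: an ODE-residual oracle plus exact boundary
conditions). For stiff modes the sinh ratio is evaluated as
`exp(u−U)(1−e^{−2u})/(1−e^{−2U})`, exact and overflow-free for arbitrarily
large `ΓΔt`.

The transition state is defined on the iso-energy seam
`{x : U_l(x) = U_r(x)}` — the locus where the climbing left-well path can
hand over to the descending right-well path at equal energy — as the point
of minimum common energy. The constrained stationarity conditions collapse
to a one-parameter family `x(λ) = [(1−λ)H_l + λH_r]⁺ [(1−λ)H_l a_l + λH_r a_r]`,
and `U_l − U_r` has opposite signs at the two ends of `λ ∈ (0,1)`, so a
scalar root-finder locates the seam point; the pseudo-inverse solve is
anchored at the straight-line midpoint, which doubles as the tie-break when
several seam minima exist (the one nearest the direct path wins). Because
both wells are zero-referenced quadratics, the converged barrier heights
`U‡_l` and `U‡_r` agree to solver precision, and their difference `ΔE` is a
tiny residual rather than a well-depth gap; the free-energy difference
between the end states is carried instead by the stiffness asymmetry of the
two wells through the time (equivalently force-constant) ratio. `ΔE` is
retained in the output both as a solver diagnostic and so that the
free-energy formula keeps its full published form.

Convergence is checked the way the method defines it: the seam-crossing
point of the left-well escape trajectory must be invariant to giving the
system more time. The modal time window defaults to 12 periods of the
slowest vibrational mode; the check recomputes the crossing with the window
doubled and requires the structure to move by less than 1e-4 Å RMSD (a hard
error otherwise). The window multiple is a numerical convergence control:
for window `T` the escape-path shape deviates from its limit by `~e^{−Γ_min T}`,
so 12 periods puts the check comfortably inside the tolerance while staying
cheap.

## Energy-domain time

Computed as a function of time, the path spends almost all of its window
near equilibrium, and more of it in the *stiffer* well — backwards, by
statistical mechanics. Re-timing in the energy domain,
`t(U) = (1/k̄)(X + ½ ln(U/U‡))`, counts time only while the structure is
displaced. `X` defaults to 2.303 so that the time from the 1 %-energy state
(10 % displacement in a quadratic well) to the barrier is exactly the
closed-form heuristic `t̄ = 2.303/k̄`; the parameter is exposed because the
formulation holds for any `X`. Energies below a clamp fraction
(`epsilon_U`, default 0.01 of `U‡`) are assigned the clamp time — the path
"begins" at the 1 %-energy displacement. The emitted trajectory samples each
branch between the clamp energy and the barrier, stitches the branches at
the transition state, and is monotone in time with a single energy maximum.

With heuristic times the free-energy difference
`ΔG_conf = −ΔE − k_BT ln(t̄_r/t̄_l)` is algebraically identical to the rate
form `−k_BT ln(k̄_l/k̄_r) − ΔE`; the implementation computes both and warns
if they disagree, which would mean the supplied times did not derive from
the mean force constants. `k_BT` defaults to 1: with a schematic network
potential the energy scale is arbitrary, so absolute calibration is out of
scope and all free energies are reported in reduced units.

## What the synthetic generators emulate

* `diatomic_pair()` — the minimal two-well system (two atoms, separations
  2 Å and 1 Å), used for closed-form checks of the modal path and times.
* `polymer_pair()` — an ideal CA helix (rise 1.5 Å, radius 2.3 Å,
  100°/residue) hinge-bent rigidly at its midpoint: the cleanest cartoon of
  a two-domain conformational change, with a closed-form displacement field
  for testing. Sites carry the mean residue mass, 110 amu.
* `perturb_variants()` — stand-ins for locally remodelled point mutants:
  per-site Gaussian displacement fields damped over a 6 Å neighbourhood and
  rescaled to a target all-atom RMSD of 0.1 Å per site, applied identically
  to both end states, over all 2^k presence/absence combinations.
* `simulate_kinetics()` — responses `y = Xβ + N(0, σ²)` over a factorial
  design, for calibrating the regression layer.

All generators are pure functions of their arguments and seed. What they do
*not* emulate: real side-chain chemistry or rotamer repacking (perturbations
are geometric), sequence-dependent stiffness, solvent, or any coupling
between a "mutation" and the hinge direction. Green tests on these fixtures
therefore demonstrate that the algorithmic machinery is correct and
internally consistent — not that the model reproduces any particular
protein's kinetics, which additionally requires realistic variant structures
and measured rates.

## The regression layer

`factorial_design()` builds 2^k presence/absence combinations with
interaction columns as element-wise products (orthogonal under ±1 coding,
where each coefficient is its contrast mean). `fit_ols()` is classical
least squares with t-based inference — no robust errors, matching how such
mutant regressions are usually reported. `table1_model()` fits the
four-term form (ΔG_conf, ⟨U‡⟩, −ln t̄_l, and ΔG_conf·(−ln t̄_l), plus
intercept) that links path parameters to measured activation free energies.
When parameter sets from the all-atom torsional and CA-only empirical
models are pooled to gain degrees of freedom, their arbitrary unit scales
differ; `stack_model_estimates()` reconstructs the pooling by regressing
one set on the other and stacking the rescaled values — a deliberate,
documented simplification of "scaled by regression methods".

## Numerical choices and problem sizes

Zero-mode threshold `1e-9 λ_max`; seam membership enforced to
`1e-8 · max(U‡, 1)`; seam root-finder tolerance near machine precision;
superposition by SVD with the determinant guard against reflections;
altloc resolution by highest occupancy (ties to file order); hydrogens
excluded by default. Identical inputs give bit-identical outputs — the core
has no randomness.

The test suite exercises the full pipeline at sizes a laptop handles in
seconds: finite-difference Hessian oracles on ≤ 10 atoms, seam oracles in
one and two dimensions against an augmented-Lagrangian solver, 16-variant
panels on 40-residue chains with 500 regression replicates, and a
100-residue hinge transition with the window-doubling invariance check.

## Known limitations

* The quadratic-well picture has no anharmonicity; barrier *heights* are
  network-model quantities, not calorimetric ones.
* On the iso-energy seam of zero-referenced wells, `ΔE` is structurally
  near zero; discrimination between variants comes from `⟨U‡⟩`, the times,
  and `ΔG_conf`.
* Ring planarity/size restraints are not modelled; aromatic rings can
  deform unphysically near the transition state in all-atom runs.
* No pass-through of forced intermediate states; exactly two wells.
* mmCIF input and sequence-alignment-based atom matching are not supported;
  variant structures must share residue numbering.
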