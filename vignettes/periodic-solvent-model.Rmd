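---
title: "A periodic 3D-RISM solvent model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A periodic 3D-RISM solvent model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `periodicrism`, the
assumptions behind it, the tunable parameters, and the numerical and
design choices that were genuinely open during development. It states no
empirical results beyond what the package's own test-suite and
`scripts/acceptance.R` compute.

## The model

The reference interaction site model (RISM) describes a molecular
solvent through site-based density distributions. Around a fixed solute,
each solvent site type $\gamma$ (water oxygen, water hydrogen, dissolved
ions, ...) has a scalar field $g_\gamma(\mathbf r) = h_\gamma(\mathbf r) + 1$
giving the local density relative to bulk, $\rho_\gamma g_\gamma(\mathbf r)$.
Two relations close the theory:

* an Ornstein–Zernike (OZ) convolution relating the total correlation
  $h_\gamma$ to the direct correlations $c_\alpha$ through the bulk
  susceptibility,
  $\hat h_\gamma(\mathbf k) = \sum_\alpha \hat c_\alpha(\mathbf k)\,
  \hat\chi_{\alpha\gamma}(k)$, with
  $\hat\chi_{\alpha\gamma} = \hat\omega_{\alpha\gamma} +
  \rho_\alpha \hat h^{vv}_{\alpha\gamma}$ precomputed for the pure
  solvent by a radial (1D) RISM stage;
* a closure tying $h$, $c$ and the solute–solvent potential
  $u_\gamma(\mathbf r)$. The package implements the hypernetted-chain
  (HNC) family with zero bridge function: writing
  $t_\gamma = -\beta u_\gamma + h^{OZ}_\gamma - c_\gamma$, HNC is
  $h = e^t - 1$, and PSE-$n$ replaces the divergence-prone $t \ge 0$
  branch by the order-$n$ Taylor truncation $\sum_{i\le n} t^i/i!$.
  PSE-1 is the Kovalenko–Hirata (KH) closure; HNC is the
  $n \to \infty$ member.

What distinguishes this package from the established open-boundary
3D-RISM codes is that **everything is periodic**: the solute is a full
crystallographic unit cell (triclinic supported), the potential is
synthesized by smooth particle-mesh Ewald (SPME), the OZ convolution
runs on the unit-cell FFT grid with no asymptotic boundary corrections,
and net-charged solutes are handled by a background-charge
renormalization so that the converged solvent distribution carries
exactly $-Q_\mathrm{solute}$ per cell.

### Charged solutes: the background shift

SPME zeroes the $\mathbf k = 0$ mode of the electrostic potential,
which silently adds a uniform neutralizing background of density
$-Q_\mathrm{solute}/V_\mathrm{cell}$. Solving the plain OZ + closure
system with that potential would produce a *neutral* solvent response —
wrong for a charged solute. The remedy follows the renormalization idea:
group the (divergent) background interaction with the direct
correlation, $\tilde c_\gamma = c_\gamma - \beta q_\gamma \phi^{bk}$,
and carry its effect through the OZ equation as a constant per-site
shift
$$
h^{bk}_\gamma = -4\pi\beta C\,\frac{Q_\mathrm{solute}}{V_\mathrm{cell}}
\lim_{k\to 0}\sum_\alpha q_\alpha\,\frac{\hat\chi_{\alpha\gamma}(k)}{k^2},
$$
with $C$ the Coulomb conversion constant. The limit exists because an
ionic solvent screens: the charge-weighted susceptibility vanishes as
$k^2$ (the second Stillinger–Lovett moment), and it is evaluated
numerically by Neville polynomial extrapolation of the sequence at the
$m = 5$ smallest radial nodes (degrees 3 and 4 are compared as a
convergence check). The same extrapolated $k \to 0^+$ values are used
for the $\mathbf k = 0$ coefficient of the gridded susceptibility, so
the shift and the convolution are internally consistent. The solver then
iterates on $\tilde c$ with
$h^{OZ}_\gamma = \sum_\alpha \tilde c_\alpha * \chi_{\alpha\gamma} + h^{bk}_\gamma$.

The Stillinger–Lovett algebra makes the mechanism exact: summing
$\rho_\gamma q_\gamma h^{bk}_\gamma$ gives $-Q/V$, and the remaining
$\hat{\tilde c}(0)\hat\chi(0)$ contributions cancel by local
electroneutrality of the bulk, so the converged distribution neutralizes
the cell to the accuracy of the 1D stage. The test-suite verifies this
for solute charges between $+1e$ and $+6e$ and for an anion lattice.

For an ion-free polar solvent the corresponding limits are *small but
not exactly zero* in the plain XRISM bulk stage used here (the residual
is tied to the approximate dielectric response of site–site HNC theory);
a dielectrically consistent bulk stage would be needed to make them
vanish identically. Charged-solute work should use a solvent containing
mobile ions, which is also the physically meaningful setting.

### Excess chemical potential and its background term

The HNC family admits a closed-form excess chemical potential. Carrying
the renormalized $\tilde c$ through the usual Singer–Chandler
manipulation, with the background shift held fixed under variations
(it depends only on $Q$, $V$ and the bulk), gives
$$
\Delta\mu = k_BT\sum_\gamma \rho_\gamma \int_{V}\!\Big[
\tfrac{1}{2}h_\gamma^2 - \big(1 + \tfrac{1}{2}h^{bk}_\gamma\big)\tilde c_\gamma
- \tfrac{1}{2}h_\gamma \tilde c_\gamma
- \Theta(t_\gamma)\,\tfrac{t_\gamma^{n+1}}{(n+1)!}\Big]\,d\mathbf r ,
$$
where the last term applies to PSE-$n$ only ($\Theta$ the unit step) and
the $h^{bk}$ piece is the *background correction term*, reported
separately by `excess_chemical_potential()`. Two remarks:

* The sign of the $h^{bk}$ term is fixed by the shift convention
  $h^{OZ} = \tilde c * \chi + h^{bk}$ used by the solver. We derived the
  bracket from first principles for that convention and verified it
  numerically: a finite-difference variation of the full self-consistent
  cycle matches $\sum_\gamma \rho_\gamma \int g_\gamma\,\delta u_\gamma$
  only with the sign above. With the opposite shift convention both
  signs flip together and observables are unchanged.
* The PSE-$n$ truncation correction follows the standard closure
  literature form.

The package validates the closed form against an independent Kirkwood
charging route (`charging_quadrature_oracle()`): the potential is scaled
by $\lambda$, the equations re-solved at Gauss–Legendre nodes, and
$\int_0^1 d\lambda\,\sum_\gamma \rho_\gamma \int u_\gamma g_\gamma^{(\lambda)}$
accumulated. Two details make this oracle exact rather than merely
approximate. First, the linearly scaled Lennard-Jones core gives the
integrand an integrable $\lambda^{-3/4}$ singularity at $\lambda = 0$;
the quadrature substitutes $\lambda = s^4$, which removes it. Second,
the background shift — like the susceptibility — is a property of the
path, not of the coupling, so it is held at full strength along the
path; the $\lambda = 0$ end point is then not pure bulk but a uniform
"shift-only" state, whose closed-form value is computable from a small
scalar fixed-point problem and enters as the constant of integration.
For neutral solutes both subtleties vanish.

### Solvation forces

The gradient of $\Delta\mu$ with respect to a solute atom position has
the same closed form for every member of the closure family and is
independent of $h^{bk}$:
$$
\frac{\partial \Delta\mu}{\partial \mathbf R_i}
= \sum_\gamma \rho_\gamma \int_V g_\gamma(\mathbf r)\,
\frac{\partial u_\gamma(\mathbf r)}{\partial \mathbf R_i}\,d\mathbf r .
$$
The reciprocal-space part is evaluated through the adjoint of the
particle-mesh operator: the charge-weighted solvent field
$\sum_\gamma \rho_\gamma q_\gamma g_\gamma$ is convolved once with the
Ewald kernel and the result interpolated at the atom with B-spline
derivatives; erfc and Lennard-Jones parts are direct sums over the
voxels within the cutoff. `solvation_forces()` returns the gradient as
defined (a minimizer or MD caller negates it). Finite-difference
validation (`finite_difference_gradient()`, two full re-solves per
Cartesian component, warm-started) reproduces the analytic values on
charged toys, and deliberately omitting the background term from the
differenced $\Delta\mu$ degrades the agreement by more than an order of
magnitude — the documented failure mode of ignoring the correction.

Because the reciprocal-space term uses the *exact adjoint* of the mesh
operator rather than a second mesh interpolation, the analytic gradient
is the exact derivative of the discrete free-energy functional: the
analytic/finite-difference mismatch sits at the finite-difference noise
floor at every grid spacing, rather than improving gradually with mesh
refinement as it does for interpolated force paths.

### Finite-size behavior of single ions

For a single ion in a cubic box of edge $L$ with the uniform background,
the periodic excess chemical potential differs from the
infinite-dilution value by the Wigner lattice self-energy:
$\Delta\mu^\mathrm{ion} = \Delta\mu^\mathrm{periodic} - C q^2\zeta/(2L)$
with $\zeta \approx 2.837297$. `wigner_constant()` recomputes $\zeta$
from a converged direct Ewald summation (and checks invariance to the
splitting width); `wigner_correct()` applies the correction, refusing
non-cubic cells for which the constant as implemented does not apply.
The acceptance suite runs a $+1e$ toy ion at $L = 40, 60, 80, 120$ Å and
checks both that the raw values are linear in $1/L$ with slope
$C q^2 \zeta/2$ and that the corrected series is box-size stable. The
slope is *unscreened* even in a salt solvent: the correction is a
uniform potential offset inside the cell acting on the fixed total
screening-cloud charge $-q$, which neither the ionic atmosphere nor the
dielectric can reduce.

## The bulk (1D) stage

`solve_rism1d()` solves the site–site OZ equations for rigid multi-site
solvents with an HNC/KH/PSE-$n$ closure. Sites are one per atom (the two
water hydrogens are separate sites with equal parameters; the 3D stage
collapses such symmetry-equivalent sites into classes after verifying
their correlation rows agree numerically). Electrostatics are
renormalized with an erf-split: the iteration variable
$\tau = h - c_s$, $c_s = c + \beta u^{lr}$,
$u^{lr} = C q q\,\mathrm{erf}(\kappa r)/r$ is short-ranged, with the
analytic reciprocal form of $u^{lr}$ inserted in the OZ matrix solve —
bare truncation never converges for dissolved salt. Plain XRISM is
solved; a dielectric-consistency correction is not applied (the stored
`dielectric_target` is metadata). The radial grid defaults to 32768
points at 0.025 Å and tolerance $10^{-12}$; the test-suite uses 2048 or
4096 points, which is converged for the toy solvents (screening lengths
of a few Å against a 50–100 Å extent).

The fast sine transform uses the grid convention $r_i = i\,\Delta r$,
$k_j = j\,\Delta k$, $\Delta k = \pi/(n\Delta r)$, self-inverse to
machine precision. The OZ matrix solve at every $k$ is batched into one
sparse block-diagonal LU factorization, which is what makes the stage
fast enough to iterate hundreds of times in seconds.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| grid spacing | 0.5 | Å | 3D resolution; dims auto-selected FFT-friendly (2^a3^b5^c7^d) |
| closure | KH | — | robustness/accuracy trade-off; HNC, PSE-n available |
| MDIIS depth / damping | 5 / 0.7 | — | acceleration; solution is path-independent |
| tolerance | 1e-6 | — | pooled RMS of Δc; use 1e-10 when forces are needed |
| real-space cutoff | 9 | Å | erfc + LJ truncation (warn + exact 27-image fallback if > half cell) |
| Ewald direct tolerance | 1e-9 | — | fixes the splitting width from the cutoff |
| spline order | 6 | — | charge spreading / force interpolation (4 allowed) |
| potential clamp | 500 | kT | caps βu before exponentiation; observable-free (g = 0 there) |
| 1D grid | 32768 × 0.025 | pts × Å | bulk stage resolution |

Units throughout: Å, kcal/mol, elementary charges, with
$C = 332.0522173$ kcal Å/(mol e²) — the Amber ecosystem convention, as
are the Lorentz–Berthelot (arithmetic $r_{min}$, geometric $\epsilon$)
mixing rules.

## Numerical choices

* **Voxel origin.** Real-space voxel centers sit at fractional
  coordinates $(i/n_1, j/n_2, k/n_3)$ starting at the origin. This only
  fixes phase conventions; observables are unaffected, but anyone
  comparing grids voxel-by-voxel with another code must account for it.
* **Quadrature.** Cell integrals use the mean-value rule
  $\sum f \cdot V/N$, exact for band-limited periodic integrands.
* **Zero-mean potential.** The SPME potential includes the compensating
  Gaussian term $-C\pi Q/(V\beta_s^2)$ so the cell mean is zero
  (tin-foil convention) and the result is independent of the splitting
  width; this *is* the background the $h^{bk}$ machinery corrects for.
* **LJ truncation.** Plain truncation at the cutoff (no shift). The
  gradient contraction and the finite-difference route agree because
  both see the same truncated potential; absolute $\Delta\mu$ values are
  mildly sensitive to this choice.
* **Clamp.** βu is capped at 500 kT before exponentiation. Closure
  branches make $g = 0$ wherever the cap engages, so no observable
  depends on the cap value.
* **Convergence control.** The residual is the pooled RMS over all site
  classes and voxels. MDIIS keeps a ring-buffer history with
  worst-case restarts (ill-conditioned Gram matrix, or residual growing
  100× past the best seen); a 10× sustained divergence aborts with
  diagnostics. The $t \ge 0$ boundary belongs to the polynomial branch;
  both branches agree there, making the choice observable-free.
* **Degenerate inputs.** Solutes with zero charge and zero LJ depth
  yield exactly zero potentials, one-iteration convergence and
  $\Delta\mu = 0$; voxels coinciding with atoms are distance-capped at
  $10^{-4}$ Å, inside the clamped core.
* **Memory.** Fields are held as one matrix column per site class and
  the closure is evaluated branch-free with full-length vector
  operations, which keeps allocation behavior flat over hundreds of
  iterations on multi-million-voxel grids; the MDIIS history is the
  dominant memory consumer, and depth 3 is a reasonable choice on grids
  beyond ~2M voxels (the converged solution does not depend on depth).

## The toy systems, and what they do not show

`make_toy()` generates the deterministic study systems: an ideal-gas
probe (for which $g = e^{-\beta u}$ exactly), a neutral LJ atom in a LJ
fluid, cations of charge $+1$ to $+6e$ and a $-4e$ anion lattice in
0.5 M salt water, a rigid bent triatomic, and the cubic box series
$L = 40$–$120$ Å. The toy water is a cSPC/E-like 3-site model (OH 1.0 Å,
HOH 109.47°, charges ∓0.8476/+0.4238, with a small hydrogen core so
site–site potentials stay bounded) at 0.03332 Å⁻³, with Joung–Cheatham-
like monovalent ion parameters; these are realistic force-field-grade
numbers, chosen once.

The validation suite sizes these deliberately at desk scale: unit-test
solutes live in 12–14 Å cells at 0.5 Å spacing (16³–28³ grids), the
force/finite-difference comparisons run at 0.75/0.5/0.25 Å, and the box
series runs at 0.75 Å spacing (54³ up to 160³) with a residual
tolerance of 10⁻⁵ and history depth 3 on the largest grid — a
thermodynamics-only setting under which Δμ is converged far below the
quantities being tested, while forces use 10⁻¹⁰ throughout.

Passing the toy suite demonstrates the correctness of the machinery —
electroneutrality, force consistency, thermodynamic-route agreement,
finite-size scaling — on systems small enough to solve in seconds to
minutes. It does not demonstrate accuracy against experiment for real
crystals: the toys have no macromolecular geometry, no Amber
parameterization of real residues, the bulk stage is plain XRISM rather
than a dielectrically consistent one, and the desk-scale boxes are far
from crystallographic unit-cell sizes. Reproducing published
macromolecular numbers additionally requires the same topology,
preparation and DRISM solvent files as the original calculations.

## Known limitations

* No dielectric-consistency (DRISM) correction in the bulk stage, so
  the pure-water dielectric is the HNC-level one and ion-free solvents
  retain small residual background shifts (see above).
* No space-group symmetry: the solute must be the full unit-cell
  content.
* No dispersion PME; LJ is cutoff-truncated.
* Cubic cells only for the finite-size correction constant.
* No energy/entropy decomposition, pressure routes, or PMF machinery.
* Performance: pure-R FFT pipeline; a 160³ grid with four site classes
  runs a few seconds per iteration and needs a few GB of memory.
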