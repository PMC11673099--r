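---
title: "microdft: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{microdft: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microdft` is a restricted closed-shell Kohn–Sham DFT engine built so that
every performance mechanism of a modern Gaussian-basis code — integral
screening, mixed-precision dispatch, block-sparse quadrature, DIIS — exists
at a scale where an independent oracle can check it. This vignette explains
the model, the numerical choices, and what the tests do and do not
demonstrate.

## The electronic-structure model

For a closed-shell molecule with N electrons the density matrix carries the
double occupation, P = 2 C_occ C_occᵀ, and the Kohn–Sham Fock matrix is

    F = H + J − (c_x / 2) K + Vxc,

with total energy

    E = E_nuc + tr(PH) + ½ tr(PJ) − ¼ c_x tr(PK) + Exc.

This factor set makes two limits exact and testable: with c_x = 0 the K
term vanishes (pure functionals), and with c_x = 1 and no functional the
equations are restricted Hartree–Fock — verified in the test suite against
a from-scratch closed-form RHF on H₂ to 1e-9 hartree. Open-shell inputs are
rejected: the restricted formalism is the only spin treatment implemented,
and accepting multiplicity > 1 silently would produce wrong physics.

Elements H–Kr are accepted; heavier elements need effective core
potentials, which are out of scope, so they are rejected at parse time with
a clear error.

## Basis sets

AOs are pure spherical harmonics, 2l+1 per shell ordered m = −l..+l, built
from Cartesian monomial Gaussians through a transformation matrix computed
once per l by exact least squares against orthonormal real spherical
harmonics on a product quadrature of the sphere (the harmonics lie in the
monomial span, so the construction is exact to round-off; no hand-typed
coefficient tables). Primitives are normalized individually and each
contracted shell is renormalized so that the self-overlap of every AO is
exactly 1 — which turns `diag(S) == 1` into a package invariant.

Three sets ship with the package:

* **sto-3g** — genuine: generated from the published three-Gaussian fits of
  Slater 1s/2s/2p functions with the standard per-element zeta values.
* **def2-svp / def2-tzvpp** — *synthetic stand-ins*. The shell
  compositions are authentic (H 2s1p and 3s2p1d; C, N, O 3s2p1d and
  5s3p2d1f), so spherical AO counts match the genuine def2 sets exactly —
  one water gives 59 AOs at the triple-zeta composition, five give 295, 139
  give 8,201. The exponents, however, are even-tempered sequences anchored
  to the magnitudes typical of split-valence and triple-zeta sets, and the
  contraction coefficients are the lowest hydrogenic eigenvector of the
  same-center primitive space (closed-form s/p integrals). Consequence:
  every AO-counting result is exact, all internal consistency checks
  (oracle equivalence, screening, precision, grids) are meaningful, but
  absolute energies in these bases are *not* comparable to calculations
  with the genuine def2 sets. The files are named `*-synthetic.json` and
  carry the same caveat in their headers; `tools/make_basis.R` regenerates
  them.

## Integrals

One recursion family — McMurchie–Davidson Hermite expansion — covers
overlap, kinetic, nuclear-attraction and electron-repulsion integrals for
all angular classes up to g. Correctness is defined by oracles, not by the
recursion: the tests compare S/T/V against direct numerical quadrature of
explicitly evaluated AOs on 100 seeded two-atom s/p/d systems (1e-7
elementwise), ERIs against closed-form Boys-function values for s quartets,
and everything against permutational symmetry, translation invariance and
rigid-rotation invariance of SCF energies (the latter exercising the d and
f transformation blocks to ~1e-13).

The Boys function uses the downward series recursion for T ≤ 35 and the
asymptotic/upward form above, where the neglected e^{−T} terms are below
round-off relative to F₀.

## Screening and mixed precision

The shell-pair bound is Q_ab = √max_{μν∈(ab)} (μν|μν), the largest diagonal
element of the (ab|ab) quartet block; Cauchy–Schwarz then gives
|(μν|λσ)| ≤ Q_ab Q_cd for every element of every quartet. Bounds are
computed from contracted blocks in double precision; primitive-level
screening would be an optimization, not a correctness change.

Each canonical (8-fold-unique) quartet is classified by the three-rule
dispatcher with bound b, tolerance τ (default 1e-12) and factor 1e5:

* b < τ — skipped;
* τ ≤ b < τ·1e5 — evaluated by the single-precision kernel;
* b ≥ τ·1e5 — evaluated in double.

The boundaries are resolved inclusive-below/exclusive-above so the three
rules form a total partition. The single-precision path is the same
templated recursion instantiated on 32-bit floats — not a rounded copy of
the double result — and its contributions are accumulated into
double-precision J/K, which bounds error growth and yields the observed
≤1e-6 hartree agreement between mixed and all-double SCF energies. On very
compact molecules (one water) no bound falls inside the single window and
the two paths coincide exactly; the water dimer populates the window (tens
of quartets) and is used to exercise the float kernel end to end.

Evaluation order is a deterministic serial loop over canonical quartets;
the batching layer groups surviving quartets by (angular class, contraction
signature, precision) for inspection and reporting, mirroring how a batched
scheduler would organize them.

## Exchange-correlation quadrature

Atom-centred grids use a Treutler–Ahlrichs M4 radial map over
Gauss–Chebyshev nodes (size parameter ~0.8–1.8 for H–Ne, 1.0 beyond) and
product spherical angular rules: Gauss–Legendre in cos θ × an equally
spaced, uniformly weighted azimuth. Angular weights therefore sum to 4π
exactly. The reference level (3, the default) uses 60 radial × 434 angular
points per first-row atom and 90 × 590 per second-row atom; 434 factors as
14 × 31 and 590 as 10 × 59. A fixed, deterministic rigid rotation of the
angular rule per radial shell (golden-angle-driven Euler sequence) averages
the residual angular error across shells; this staggering improves the
electron-count integration on water from ~2e-6 to ~3e-8 and is what makes
the 1e-6 grid-fidelity bound comfortable. Level 4 uses 80 × 512 for
first-row atoms because the 590-point factorization (polar order 10) is
weaker than its size suggests; levels 0–2 scale the sizes down. No pruning
is applied: per-atom point counts are exactly radial × angular.

Becke fuzzy-cell partitioning uses three iterations of the standard
smoothing polynomial and no atomic-size adjustment; partition factors sum
to one at every point by construction, pinned in the tests by an
independently written-out reference formula.

AO collocation is stored as 32 × 32 tiles (zero-padded at the edges); a
tile is dropped iff all its entries are below ε (default 1e-12), and shells
are skipped entirely for points beyond their cutoff radius — the radius
where a sound envelope (r^l × contracted radial part × the max column sum
of the spherical transform) falls below the AO threshold (default 1e-12).
Setting both thresholds to zero reproduces the dense path exactly, which is
the anchor for the sparsity tests. Tiny negative densities from round-off
are clamped to zero before functional evaluation.

In-house functionals: Slater exchange (`"slater"`), Slater+VWN5 (`"lda"`),
PBE (`"pbe"`), PBE0 as a c_x = 0.25 hybrid (`"pbe0"`), and `"hf"`.
Potentials are analytic derivatives (verified by finite differences to
1e-7); meta-GGAs such as M06-2X would require an external functional
backend, which is not present, so requesting them raises a capability
error rather than a silent substitution.

## SCF

The superposition-of-atomic-densities guess solves each element's isolated
atom in the same basis (core-Hamiltonian eigenvectors, aufbau filling with
occupation averaging across degenerate levels, which makes the density
spherical) and assembles the block-diagonal molecular P₀; the core guess
diagonalizes H directly. DIIS stores up to 8 (Fock, FPS−SPF) pairs with
the error expressed in the orthonormalized basis, solves the Pulay system
with Σc = 1, and drops the oldest entries if the B matrix becomes
ill-conditioned; with a single stored pair it is the identity.
Diagonalization is canonical orthogonalization with overlap eigenvalues
below 1e-10 removed — exact duplicate basis functions are handled, not
fatal.

Convergence is declared on |ΔE| ≤ τ_E (default 1e-8 hartree) **and**
max|FPS−SPF| ≤ √τ_E. A single energy criterion can be met spuriously while
the density still moves; the commutator criterion closes that hole. This
dual test is a package choice — the mechanism it guards is standard — and
both thresholds are settable. Non-convergence returns a result object with
the iteration trace rather than throwing; no damping or level shifting is
applied by default (an optional mixing factor exists for pathological
cases). Incremental Fock builds are deliberately absent so that every
iteration is idempotent and testable in isolation.

## Tasks

The five-task layer reduces everything to single-point energies: `spf` is
central finite differences of the energy (default step 1e-3 bohr, six
displacements per atom), `fh` central differences of those forces with
symmetrization, `go` a Cartesian BFGS with a 0.3-bohr step cap,
backtracking, and convergence at max|force| ≤ 4.5e-4 hartree/bohr plus
ΔE ≤ 1e-6, and `bomd` velocity-Verlet with zero or Maxwell–Boltzmann
(seed-required) initial velocities. Analytical gradients are not
implemented; the finite-difference baseline keeps the task contract intact
and is itself verifiable — the kernels accept arbitrary potential
closures, so the tests drive them with exact quadratic surrogates where
forces, Hessians and energy conservation are known in closed form
(Hessian recovery to 1e-8, Verlet drift below 1e-8 over 1000 steps at
Δt = 0.002 au). Grid-weight derivative contributions to forces are an
approximation inherent to differentiating fixed-grid energies; at the
1e-3-bohr step and 1e-10 SCF convergence used in the tests the
translational force sum stays below 1e-5 hartree/bohr.

Results serialize to a QCSchema-style JSON document; SCF matrices go to an
RDS container with stable names (`coefficients`, `density`, `fock`,
`overlap`, `orbital_energies`, `occupations`). An HDF5 container would be
the cross-language choice, but no HDF5 R binding is available in the
supported dependency set, and RDS preserves the matrices bit-exactly.
`fh` is incompatible with solvation or dispersion corrections simply
because neither is implemented.

## Fixtures and what the tests show

`make_water_cluster(n)` places rigid monomers (r(OH) = 0.9572 Å, angle
104.52°) on an integer cubic lattice with 2.8 Å spacing and
parity-alternating orientation — deterministic to the bit. These are
synthetic lattices, not benchmark cluster geometries: AO counts depend only
on composition, so the counting results (59 / 295 / 8,201) are exact, but
no energy for these geometries is claimed to match any published cluster
value. `random_molecule()` does seeded rejection sampling under a minimum
interatomic distance; `toy_density()` builds seeded PSD matrices with a
prescribed tr(PS).

Problem sizes were chosen so the full suite runs in minutes on one core:
SCF-level tests use water, small hydrides and 2–3-water clusters in
minimal basis (with one water at the def2-SVP composition for the dense
ERI oracle, ~24 AOs), the integral oracles use single-primitive two-atom
systems, and triple-zeta-composition work beyond AO counting is limited to
a single water. Passing tests demonstrate internal consistency of the
screening/precision/sparsity machinery and exactness of the limits above;
they do not demonstrate basis-set quality (the def2 stand-ins are
synthetic), large-molecule performance, open-shell behaviour, or
agreement with any external code's absolute energies.

## Known limitations

Restricted closed-shell only; FD gradients (no Pulay terms needed, but
6N SCF solves per force evaluation); no ECPs, no range-separated hybrids,
no density fitting, no meta-GGAs without an external backend; product
angular rules rather than Lebedev tables (counts and 4π normalization are
honored; octahedral-symmetry efficiency is not); dense-oracle memory grows
as n⁴ and is capped at 150 AOs.
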