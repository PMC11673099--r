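# microdft

Desk-scale restricted Kohn–Sham density functional theory over contracted
Gaussian basis sets, in R with C++ integral kernels.

## The problem

Kohn–Sham DFT determines the electronic structure of a molecule by solving
one-particle equations self-consistently. Each iteration builds the Fock
matrix

    F = H + J − (c_x / 2) K + Vxc

where **H** is the one-electron core Hamiltonian (kinetic + nuclear
attraction), **J** and **K** are the Coulomb and exact-exchange matrices
obtained by contracting the four-index electron-repulsion integrals (ERIs)
(μν|λσ) with the density matrix **P**, c_x is the exact-exchange fraction of
the functional, and **Vxc** is the exchange-correlation potential evaluated
by numerical quadrature. The expensive steps — ERI evaluation/contraction
and the XC quadrature — dominate the cost, and production codes attack them
with integral screening, reduced precision, and sparsity. `microdft`
implements those mechanisms at a scale where every one of them can be tested
against an independent oracle:

* **McMurchie–Davidson integrals** (one recursion family for overlap,
  kinetic, nuclear attraction and ERIs, s through g shells, pure spherical
  AOs ordered m = −l..+l), templated in C++ over `double`/`float`.
* **Cauchy–Schwarz screening**: shell-pair bounds Q_ab = √max(μν|μν)
  guarantee |(μν|λσ)| ≤ Q_ab·Q_cd; quartets are classified by the
  **three-rule mixed-precision dispatcher** — skipped below a tolerance
  (default 1e-12), evaluated in single precision up to tolerance·1e5,
  in double precision above — and accumulated in double.
* **Block-sparse XC quadrature**: Becke-partitioned atom-centred grids
  (Treutler–Ahlrichs radial maps × product spherical rules; the reference
  level uses 60×434 points per first-row atom and 90×590 per second-row
  atom), AO collocation stored as 32×32 tiles with a drop threshold, and
  tiled multiplications for the density and Vxc.
* **SCF driver**: superposition-of-atomic-densities or core guess,
  DIIS-accelerated iterations, canonical orthogonalization with
  linear-dependence removal, dual energy/commutator convergence test.
* **Five tasks** over QCSchema-style JSON documents: `spe` (energy), `spf`
  (finite-difference forces), `fh` (seminumerical Hessian), `go` (BFGS
  geometry optimization), `bomd` (velocity-Verlet molecular dynamics), plus
  a thin command-line front end.

Bundled basis sets: a genuine STO-3G (generated from the published
three-Gaussian Slater fits) and synthetic stand-ins for def2-SVP /
def2-TZVPP that reproduce the authentic shell compositions exactly
(H 2s1p / 3s2p1d; C, N, O 3s2p1d / 5s3p2d1f) — so spherical AO counts match
the genuine sets (e.g. 59 AOs for one water at the triple-zeta composition,
295 for five, 8,201 for 139) — while the exponents and contraction
coefficients are even-tempered constructions, not the published values. See
`vignettes/microdft-methods.Rmd` for what that does and does not let you
conclude.

## Worked example

```r
library(microdft)

mol <- parse_xyz("3
water
O 0.0 0.0 0.1173
H 0.0 0.7572 -0.4692
H 0.0 -0.7572 -0.4692")

scf <- run_scf(mol, method = "lda", basis = "def2-svp")
print(scf)
#> <mdft_scf> lda/def2-svp, 24 AOs: converged in 8 iterations,
#> E = -75.0928321452 hartree

d <- density_on_grid(scf$P, scf$ao)
sum(scf$grid$weights * d$rho)
#> [1] 10
```

The run converges the Slater–VWN5 density in 8 DIIS iterations over 24
spherical AOs; integrating the converged density over the reference grid
(60 radial × 434 angular points per atom, Becke-partitioned) recovers the
10 electrons of water to better than 1e-6 — the standard check that grid,
partition weights and density agree.

A single-point task through the document interface:

```r
doc <- task_document("spe", mol, method = "pbe", basis = "def2-svp")
res <- run_task(doc)
serialize_result(res, "water-pbe.json")   # JSON + RDS matrix container
```

or from a shell:

```sh
Rscript inst/cli/microdft.R run --xyz water.xyz --task spe \
    --method pbe --basis def2-svp --out water-pbe.json
```

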