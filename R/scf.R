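# Self-consistent field driver: initial guesses, Fock assembly, generalized
# diagonalization with linear-dependence handling, DIIS extrapolation, and
# the restricted closed-shell SCF loop.
#
# Conventions (closed shell): the density matrix P includes the double
# occupation, P = 2 C_occ C_occ^T, so
#   F = H + J - (c_x/2) K + Vxc
#   E = E_nuc + tr(PH) + 1/2 tr(PJ) - 1/4 c_x tr(PK) + Exc
# and c_x = 1 with no functional reproduces restricted Hartree-Fock.

#' SCF settings
#'
#' Convergence is declared when BOTH the energy change falls below
#' `conv_energy` AND the DIIS error norm (max |FPS - SPF| in the orthonormal
#' basis) falls below `conv_diis` (default sqrt(conv_energy)).
#'
#' @param conv_energy energy convergence threshold in hartree (default 1e-8)
#' @param conv_diis DIIS error-norm threshold (default sqrt(conv_energy))
#' @param eri_tolerance Schwarz screening tolerance (default 1e-12)
#' @param mixed_precision enable the single/double ERI dispatcher
#' @param max_iter maximum SCF iterations (default 100)
#' @param diis_depth DIIS history depth (default 8, minimum 2)
#' @param guess initial-guess mode, "sad" or "core"
#' @param lindep_cutoff overlap eigenvalue cutoff for canonical
#'   orthogonalization (default 1e-10)
#' @param grid_level XC quadrature level 0..4 (default 3, the reference
#'   level: 60x434 first-row / 90x590 second-row points per atom)
#' @param ao_threshold AO distance-screening threshold (default 1e-12)
#' @param block_eps zero-block threshold for collocation (default 1e-12)
#' @param damping optional linear mixing factor in (0,1]; 1 = off
#' @return an `mdft_scf_settings` list
#' @export
scf_settings <- function(conv_energy = 1e-8, conv_diis = sqrt(conv_energy),
                         eri_tolerance = 1e-12, mixed_precision = TRUE,
                         max_iter = 100L, diis_depth = 8L,
                         guess = c("sad", "core"), lindep_cutoff = 1e-10,
                         grid_level = 3L, ao_threshold = 1e-12,
                         block_eps = 1e-12, damping = 1.0) {
  guess <- match.arg(guess)
  stopifnot(conv_energy > 0, conv_diis > 0, max_iter >= 1, diis_depth >= 2,
            lindep_cutoff > 0, damping > 0, damping <= 1)
  structure(list(conv_energy = conv_energy, conv_diis = conv_diis,
                 eri_tolerance = eri_tolerance,
                 mixed_precision = isTRUE(mixed_precision),
                 max_iter = as.integer(max_iter),
                 diis_depth = as.integer(diis_depth), guess = guess,
                 lindep_cutoff = lindep_cutoff,
                 grid_level = as.integer(grid_level),
                 ao_threshold = ao_threshold, block_eps = block_eps,
                 damping = damping),
            class = "mdft_scf_settings")
}

#' Assemble the Kohn-Sham Fock matrix
#'
#' F = H + J - (c_x/2) K + Vxc under the doubled-density closed-shell
#' convention; pure functionals (c_x = 0) carry no K term, and c_x = 1 with
#' Vxc = 0 is restricted Hartree-Fock.
#'
#' @param H core Hamiltonian
#' @param J,K Coulomb and exchange matrices
#' @param Vxc exchange-correlation potential matrix (or NULL)
#' @param cx exact-exchange fraction in [0, 1]
#' @return Fock matrix
#' @export
build_fock <- function(H, J, K, Vxc = NULL, cx = 0) {
  dims <- vapply(list(H, J, K), dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("H, J, K dimension mismatch", call. = FALSE)
  F <- H + J
  if (cx != 0) F <- F - (cx / 2) * K
  if (!is.null(Vxc)) {
    if (!all(dim(Vxc) == dim(H))) stop("Vxc dimension mismatch", call. = FALSE)
    F <- F + Vxc
  }
  F
}

#' Solve the Roothaan generalized eigenproblem
#'
#' Canonical orthogonalization: S-eigenvectors with eigenvalue below
#' `cutoff` are dropped; the Fock matrix is diagonalized on the retained
#' space. Returned coefficients satisfy C^T S C = I.
#'
#' @param F Fock matrix
#' @param S overlap matrix
#' @param cutoff linear-dependence eigenvalue cutoff
#' @return list: `C` (n x n_retained), `energies` (ascending), `n_dropped`
#' @export
solve_roothaan <- function(F, S, cutoff = 1e-10) {
  es <- eigen(S, symmetric = TRUE)
  keep <- es$values > cutoff
  if (!any(keep))
    stop("all overlap eigenvalues below the linear-dependence cutoff",
         call. = FALSE)
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  Fp <- crossprod(X, F %*% X)
  ef <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
  ord <- order(ef$values)
  list(C = X %*% ef$vectors[, ord, drop = FALSE],
       energies = ef$values[ord], n_dropped = sum(!keep))
}

#' DIIS extrapolation step
#'
#' Solves the Pulay least-squares system over the stored (Fock, error)
#' pairs with the constraint sum(c) = 1; with a single stored pair the Fock
#' matrix is returned unchanged. An ill-conditioned B matrix is handled by
#' dropping the oldest entries.
#'
#' @param focks list of Fock matrices (oldest first)
#' @param errors list of error matrices (FPS - SPF in the orthonormal basis)
#' @return list: `F` (extrapolated Fock), `coef` (coefficients, sum 1)
#' @export
diis_step <- function(focks, errors) {
  m <- length(focks)
  stopifnot(m >= 1, length(errors) == m)
  if (m == 1L) return(list(F = focks[[1]], coef = 1.0))
  repeat {
    m <- length(focks)
    B <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in i:m) {
      B[i, j] <- sum(errors[[i]] * errors[[j]])
      B[j, i] <- B[i, j]
    }
    A <- rbind(cbind(B, -1), c(rep(-1, m), 0))
    rhs <- c(rep(0, m), -1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    ok <- !is.null(sol) && all(is.finite(sol)) &&
      (m <= 2 || kappa(A, exact = FALSE) < 1e14)
    if (ok || m == 1L) break
    focks <- focks[-1]; errors <- errors[-1]
  }
  if (is.null(sol)) return(list(F = focks[[length(focks)]], coef = 1.0))
  cf <- sol[seq_len(length(focks))]
  Fx <- Reduce(`+`, Map(`*`, focks, cf))
  list(F = Fx, coef = cf)
}

# spherically averaged atomic density for the SAD guess, cached per
# (element, basis); occupation-averaged over degenerate eigenvalue groups
sad_atomic_density <- function(symbol, basis) {
  cacheable <- inherits(basis, "character")
  key <- paste0("sad:", if (cacheable) basis else "custom", ":", symbol)
  if (cacheable && !is.null(.microdft_cache[[key]])) return(.microdft_cache[[key]])
  Z <- element_number(symbol)
  mult <- if (Z %% 2L == 0L) 1L else 2L
  atom <- molecule(symbol, matrix(0, 1, 3), multiplicity = mult)
  ab <- assign_basis(atom, basis)
  core <- core_hamiltonian(ab)
  sol <- solve_roothaan(core$H, core$S)
  nmo <- ncol(sol$C)
  occ <- numeric(nmo)
  rem <- Z
  i <- 1L
  while (rem > 0 && i <= nmo) {
    grp <- which(abs(sol$energies - sol$energies[i]) < 1e-6 &
                   seq_len(nmo) >= i)
    fill <- min(rem, 2 * length(grp))
    occ[grp] <- fill / length(grp)
    rem <- rem - fill
    i <- max(grp) + 1L
  }
  P <- sol$C %*% (occ * t(sol$C))
  if (cacheable) .microdft_cache[[key]] <- P
  P
}

#' Initial density guess
#'
#' "sad": block-diagonal superposition of spherically averaged atomic
#' densities (each atom solved in the same basis, occupation-averaged over
#' degenerate levels). "core": diagonalize the core Hamiltonian and occupy
#' the lowest orbitals.
#'
#' @param basis an `mdft_basis`
#' @param core an `mdft_core` (from [core_hamiltonian()])
#' @param mode "sad" or "core"
#' @return density matrix P0 (doubled-occupation convention)
#' @export
initial_guess <- function(basis, core, mode = c("sad", "core")) {
  mode <- match.arg(mode)
  mol <- basis$molecule
  nel <- n_electrons(mol)
  if (nel %% 2L != 0L || mol$multiplicity != 1L)
    stop("restricted closed-shell only: need an even electron count and ",
         "multiplicity 1 (got ", nel, " electrons, multiplicity ",
         mol$multiplicity, ")", call. = FALSE)
  if (mode == "core") {
    sol <- solve_roothaan(core$H, core$S)
    Cocc <- sol$C[, seq_len(nel %/% 2L), drop = FALSE]
    return(2 * tcrossprod(Cocc))
  }
  P <- matrix(0, basis$n_ao, basis$n_ao)
  off <- 1L
  for (a in seq_along(mol$symbols)) {
    Pa <- sad_atomic_density(mol$symbols[a],
                             if (basis$name == "<custom>") basis$definition else basis$name)
    na <- nrow(Pa)
    idx <- off:(off + na - 1L)
    P[idx, idx] <- Pa
    off <- off + na
  }
  P
}

#' Run a restricted Kohn-Sham (or Hartree-Fock) SCF
#'
#' The full loop: initial guess, screened mixed-precision J/K, block-sparse
#' XC quadrature, DIIS-extrapolated Fock, canonical-orthogonalization
#' diagonalization, density update, dual energy/commutator convergence test.
#' Non-convergence returns a result with `converged = FALSE` (no error).
#'
#' @param mol an `mdft_molecule` (closed shell)
#' @param method functional name (see [functional_spec()])
#' @param basis basis-set name or an `mdft_basis`
#' @param settings an [scf_settings()]
#' @param verbose print the per-iteration trace
#' @return `mdft_scf` object: `energy` (hartree), `converged`, `n_iter`,
#'   `C`, `orbital_energies`, `P`, `F`, `S`, components (`e_nuc`, `e_one`,
#'   `e_coulomb`, `e_exchange`, `e_xc`), `n_ao`, `trace` (data.frame),
#'   `occupied` count, plus the grid/collocation when XC was used
#' @export
run_scf <- function(mol, method = "lda", basis = "sto-3g",
                    settings = scf_settings(), verbose = FALSE) {
  fun <- functional_spec(method)
  bas <- if (inherits(basis, "mdft_basis")) basis else assign_basis(mol, basis)
  n <- bas$n_ao  # basis-count gate: known before any SCF work
  nel <- n_electrons(mol)
  core <- core_hamiltonian(bas)
  P <- initial_guess(bas, core, settings$guess)
  nocc <- nel %/% 2L
  e_nuc <- nuclear_repulsion(mol)
  eri <- eri_settings(settings$eri_tolerance,
                      mixed_precision = settings$mixed_precision)
  bounds <- schwarz_bounds(bas)
  grid <- NULL; ao <- NULL
  if (fun$needs_xc) {
    grid <- becke_partition(mol, settings$grid_level)
    ao <- eval_ao_block_sparse(grid, bas, threshold = settings$ao_threshold,
                               eps = settings$block_eps,
                               deriv = fun$needs_grad)
  }
  # orthonormalizer for the DIIS error metric
  es <- eigen(core$S, symmetric = TRUE)
  keep <- es$values > settings$lindep_cutoff
  X <- es$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(es$values[keep]), sum(keep))
  focks <- list(); errors <- list()
  E_old <- Inf
  trace <- data.frame(iter = integer(0), energy = numeric(0),
                      dE = numeric(0), diis_error = numeric(0))
  converged <- FALSE
  comps <- NULL
  C <- NULL; eps_orb <- NULL; F <- NULL
  for (it in seq_len(settings$max_iter)) {
    jk <- build_JK(P, bas, eri, bounds)
    xc <- NULL
    if (fun$needs_xc) {
      dens <- density_on_grid(P, ao)
      pot <- xc_energy_potential(dens$rho, dens$sigma, fun)
      xc <- assemble_vxc(grid, ao, pot, dens)
    }
    F <- build_fock(core$H, jk$J, jk$K, if (is.null(xc)) NULL else xc$Vxc,
                    fun$cx)
    e_one <- sum(P * core$H)
    e_j <- 0.5 * sum(P * jk$J)
    e_k <- if (fun$cx != 0) -0.25 * fun$cx * sum(P * jk$K) else 0
    e_xc <- if (is.null(xc)) 0 else xc$Exc
    E <- e_nuc + e_one + e_j + e_k + e_xc
    err <- crossprod(X, (F %*% P %*% core$S - core$S %*% P %*% F) %*% X)
    diis_err <- max(abs(err))
    dE <- E - E_old
    trace <- rbind(trace, data.frame(iter = it, energy = E, dE = dE,
                                     diis_error = diis_err))
    if (verbose)
      cat(sprintf("iter %3d  E = %18.10f  dE = %10.2e  diis = %8.2e\n",
                  it, E, dE, diis_err))
    if (abs(dE) <= settings$conv_energy && diis_err <= settings$conv_diis) {
      converged <- TRUE
      comps <- list(e_nuc = e_nuc, e_one = e_one, e_coulomb = e_j,
                    e_exchange = e_k, e_xc = e_xc)
      sol <- solve_roothaan(F, core$S, settings$lindep_cutoff)
      C <- sol$C; eps_orb <- sol$energies
      E_old <- E
      break
    }
    E_old <- E
    focks <- c(focks, list(F)); errors <- c(errors, list(err))
    if (length(focks) > settings$diis_depth) {
      focks <- focks[-1]; errors <- errors[-1]
    }
    Fd <- diis_step(focks, errors)$F
    sol <- solve_roothaan(Fd, core$S, settings$lindep_cutoff)
    C <- sol$C; eps_orb <- sol$energies
    Pn <- 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
    P <- if (settings$damping < 1) {
      settings$damping * Pn + (1 - settings$damping) * P
    } else Pn
    # idempotency check tr(PS) = N_e
    tps <- sum(P * core$S)
    if (abs(tps - nel) > 1e-6)
      stop("tr(PS) = ", tps, " departed from the electron count ", nel,
           call. = FALSE)
  }
  if (!converged)
    comps <- list(e_nuc = e_nuc, e_one = NA_real_, e_coulomb = NA_real_,
                  e_exchange = NA_real_, e_xc = NA_real_)
  structure(
    list(energy = E_old, converged = converged, n_iter = nrow(trace),
         C = C, orbital_energies = eps_orb, P = P, F = F, S = core$S,
         H = core$H, components = comps, n_ao = n, occupied = nocc,
         trace = trace, method = fun$name, basis_name = bas$name,
         grid = grid, ao = ao, functional = fun),
    class = "mdft_scf"
  )
}

#' @export
print.mdft_scf <- function(x, ...) {
  cat("<mdft_scf> ", x$method, "/", x$basis_name, ", ", x$n_ao, " AOs: ",
      if (x$converged) "converged" else "NOT converged", " in ", x$n_iter,
      " iterations, E = ", sprintf("%.10f", x$energy), " hartree\n", sep = "")
  invisible(x)
}
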