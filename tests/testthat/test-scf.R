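test_that("restricted Hartree-Fock matches the independent closed-form
           oracle on H2", {
  E_oracle <- oracle_rhf_h2(1.4)
  scf <- run_scf(h2_molecule(1.4), "hf", "sto-3g",
                 scf_settings(conv_energy = 1e-12, guess = "core"))
  expect_true(scf$converged)
  expect_equal(scf$energy, E_oracle, tolerance = 1e-9)
  # total energy decomposition is consistent
  cm <- scf$components
  expect_equal(cm$e_nuc + cm$e_one + cm$e_coulomb + cm$e_exchange + cm$e_xc,
               scf$energy, tolerance = 1e-12)
})

test_that("build_fock follows the documented convention", {
  n <- 4
  set.seed(3)
  H <- crossprod(matrix(rnorm(n * n), n)); J <- crossprod(matrix(rnorm(n * n), n))
  K <- crossprod(matrix(rnorm(n * n), n)); V <- crossprod(matrix(rnorm(n * n), n))
  expect_equal(build_fock(H, 0 * J, 0 * K), H)
  expect_equal(build_fock(H, J, K, cx = 0), H + J)     # no K for pure DFT
  expect_equal(build_fock(H, J, K, cx = 1), H + J - K / 2)
  expect_equal(build_fock(H, J, K, V, cx = 0.25), H + J - K / 8 + V)
  expect_error(build_fock(H, J, matrix(0, 2, 2)), "mismatch")
})

test_that("solve_roothaan returns S-orthonormal ascending solutions and
           survives exact linear dependence", {
  b <- assign_basis(water_molecule(), "sto-3g")
  core <- core_hamiltonian(b)
  sol <- solve_roothaan(core$H, core$S)
  expect_lt(max(abs(crossprod(sol$C, core$S %*% sol$C) - diag(ncol(sol$C)))),
            1e-10)
  expect_true(all(diff(sol$energies) >= -1e-12))
  # S = I reduces to the ordinary symmetric eigenproblem
  A <- crossprod(matrix(rnorm(25), 5))
  sol2 <- solve_roothaan(A, diag(5))
  expect_equal(sol2$energies, sort(eigen(A, symmetric = TRUE)$values),
               tolerance = 1e-12)
  expect_error(solve_roothaan(A, diag(5) * 1e-14), "cutoff")
  # duplicated basis function: one vector dropped, SCF still converges
  def <- jsonlite::fromJSON(system.file("extdata", "basis", "sto-3g.json",
                                        package = "microdft"),
                            simplifyVector = FALSE)$elements
  def$H <- c(def$H, def$H)  # exact duplicate shell on every H
  mol <- h2_molecule()
  b2 <- assign_basis(mol, list(elements = def))
  core2 <- core_hamiltonian(b2)
  sol3 <- solve_roothaan(core2$H, core2$S, cutoff = 1e-10)
  expect_equal(sol3$n_dropped, 2L)
  scf <- run_scf(mol, "hf", b2, scf_settings(guess = "core"))
  expect_true(scf$converged)
  ref <- run_scf(mol, "hf", "sto-3g", scf_settings(guess = "core"))
  expect_equal(scf$energy, ref$energy, tolerance = 1e-8)
})

test_that("DIIS honours its constraint and fixed points", {
  set.seed(9)
  F1 <- crossprod(matrix(rnorm(16), 4))
  # single history entry: identity mapping
  one <- diis_step(list(F1), list(matrix(0.1, 4, 4)))
  expect_identical(one$F, F1)
  # coefficients sum to one for random histories
  focks <- lapply(1:5, function(i) crossprod(matrix(rnorm(16), 4)))
  errs <- lapply(1:5, function(i) matrix(rnorm(16), 4))
  st <- diis_step(focks, errs)
  expect_equal(sum(st$coef), 1, tolerance = 1e-12)
  # linear model problem: err(F) = M .* (F - F*) with one expanding mode,
  # relaxation F <- F_diis - err(F_diis); plain iteration diverges in the
  # 1.6 mode, DIIS reaches the fixed point within the history depth
  Fstar <- matrix(c(2, -1, -1, 3), 2)
  M <- matrix(c(1.6, 0.8, 0.3, 0.1), 2)
  hist_f <- list(); hist_e <- list()
  Fcur <- Fstar + matrix(1, 2, 2)
  for (it in 1:8) {
    hist_f <- c(hist_f, list(Fcur))
    hist_e <- c(hist_e, list(M * (Fcur - Fstar)))
    Fd <- diis_step(hist_f, hist_e)$F
    Fcur <- Fd - M * (Fd - Fstar)
    if (max(abs(Fcur - Fstar)) < 1e-12) break
  }
  expect_lte(it, 8L)
  expect_lt(max(abs(Fcur - Fstar)), 1e-10)
})

test_that("initial guesses are sane and lead to the same fixed point", {
  mol <- water_molecule()
  b <- assign_basis(mol, "sto-3g")
  core <- core_hamiltonian(b)
  P_core <- initial_guess(b, core, "core")
  expect_equal(sum(P_core * core$S), 10, tolerance = 1e-8)
  P_sad <- initial_guess(b, core, "sad")
  expect_equal(sum(P_sad * core$S), 10, tolerance = 0.1)
  # single atom in SAD mode: exactly the stored atomic density
  he <- molecule("He", matrix(0, 1, 3))
  bhe <- assign_basis(he, "sto-3g")
  Phe <- initial_guess(bhe, core_hamiltonian(bhe), "sad")
  expect_equal(sum(Phe * core_hamiltonian(bhe)$S), 2, tolerance = 1e-10)
  s1 <- run_scf(mol, "hf", "sto-3g", scf_settings(guess = "sad"))
  s2 <- run_scf(mol, "hf", "sto-3g", scf_settings(guess = "core"))
  expect_true(s1$converged && s2$converged)
  expect_equal(s1$energy, s2$energy, tolerance = 1e-8)
})

test_that("SCF is rotationally invariant and stable under an extra
           iteration", {
  mol <- water_molecule()
  R <- rotation_matrix(c(2, 1, -1), 0.9)
  rot <- molecule(mol$symbols, mol$coords %*% t(R))
  e1 <- run_scf(mol, "hf", "sto-3g")
  e2 <- run_scf(rot, "hf", "sto-3g")
  expect_equal(e1$energy, e2$energy, tolerance = 1e-8)
  # variational stability: restarting from the converged density moves the
  # energy by less than the threshold
  jk <- build_JK(e1$P, assign_basis(mol, "sto-3g"))
  F <- build_fock(e1$H, jk$J, jk$K, cx = 1)
  E_again <- e1$components$e_nuc + sum(e1$P * e1$H) +
    0.5 * sum(e1$P * jk$J) - 0.25 * sum(e1$P * jk$K)
  expect_equal(E_again, e1$energy, tolerance = 1e-8)
})

test_that("fixture molecules converge within 50 iterations with both
           guesses", {
  fixtures <- list(
    h2 = h2_molecule(),
    he = molecule("He", matrix(0, 1, 3)),
    h2o = water_molecule(),
    nh3 = parse_xyz(paste("4", "ammonia", "N 0 0 0.1173",
                          "H 0 0.9377 -0.2739", "H 0.8121 -0.4689 -0.2739",
                          "H -0.8121 -0.4689 -0.2739", sep = "\n")),
    ch4 = parse_xyz(paste("5", "methane", "C 0 0 0", "H 0.629 0.629 0.629",
                          "H -0.629 -0.629 0.629", "H -0.629 0.629 -0.629",
                          "H 0.629 -0.629 -0.629", sep = "\n")),
    w2 = make_water_cluster(2)
  )
  for (nm in names(fixtures)) {
    for (g in c("sad", "core")) {
      r <- run_scf(fixtures[[nm]], "hf", "sto-3g",
                   scf_settings(guess = g, max_iter = 50L))
      expect_true(r$converged, label = paste(nm, g, "converged"))
      expect_lte(r$n_iter, 50L)
    }
  }
  # a larger cluster with the default guess
  r3 <- run_scf(make_water_cluster(3), "hf", "sto-3g",
                scf_settings(max_iter = 50L))
  expect_true(r3$converged)
})

test_that("screening and mixed precision leave the converged energy intact", {
  mol <- water_molecule()
  base <- run_scf(mol, "hf", "sto-3g")
  unscreened <- run_scf(mol, "hf", "sto-3g", scf_settings(eri_tolerance = 0))
  expect_lt(abs(base$energy - unscreened$energy), 1e-8)
  # mixed on vs off, on a system spread out enough to populate the
  # single-precision window
  w2 <- make_water_cluster(2)
  m_on <- run_scf(w2, "hf", "sto-3g")
  m_off <- run_scf(w2, "hf", "sto-3g", scf_settings(mixed_precision = FALSE))
  expect_lt(abs(m_on$energy - m_off$energy), 1e-6)
})

test_that("non-convergence is reported, not thrown", {
  r <- run_scf(water_molecule(), "hf", "sto-3g",
               scf_settings(max_iter = 2L))
  expect_false(r$converged)
  expect_equal(nrow(r$trace), 2L)
})

test_that("the AO count gate reports 59 for water at the triple-zeta
           composition before SCF work", {
  r <- run_scf(water_molecule(), "hf", "def2-tzvpp",
               scf_settings(max_iter = 1L))
  expect_equal(r$n_ao, 59L)
})
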