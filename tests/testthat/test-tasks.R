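test_that("task documents validate their fields", {
  mol <- h2_molecule()
  expect_error(task_document("nmr", mol, "hf", "sto-3g"),
               "spe, spf, fh, go, bomd")
  expect_error(task_document("spe", mol, "hf", "sto-3g",
                             keywords = list(bogus = 1)), "unknown keyword")
  doc <- task_document("spe", qcschema_molecule(mol), "hf", "sto-3g")
  expect_s3_class(doc$molecule, "mdft_molecule")
})

test_that("spe delegates to run_scf and surfaces structured errors", {
  mol <- h2_molecule()
  doc <- task_document("spe", mol, "hf", "sto-3g")
  res <- run_task(doc)
  expect_true(res$success)
  ref <- run_scf(mol, "hf", "sto-3g")
  expect_identical(res$energy, ref$energy)
  bad <- run_task(task_document("spe", mol, "hf", "no-such-basis"))
  expect_false(bad$success)
  expect_match(bad$error, "basis")
})

test_that("finite-difference kernels recover an exact quadratic surrogate", {
  surr <- quadratic_surrogate(3)
  x <- surr$minimum + 0.2
  f <- fd_forces(surr$energy, x, h = 1e-4)
  expect_lt(max(abs(f - surr$force(x))), 1e-6)
  H <- fd_hessian(surr$force, x, h = 1e-4)
  expect_lt(max(abs(H - surr$Hq)), 1e-8)
  expect_lt(attr(H, "asymmetry"), 1e-8)
})

test_that("spf forces are translationally consistent and physically signed", {
  mol <- water_molecule()
  f <- forces_spf(mol, "hf", "sto-3g",
                  scf_settings(conv_energy = 1e-10))
  expect_equal(dim(f), c(3L, 3L))
  expect_lt(max(abs(colSums(f))), 1e-5)
  # single atom: exactly zero
  expect_equal(forces_spf(molecule("He", matrix(0, 1, 3)), "hf", "sto-3g"),
               matrix(0, 1, 3))
  # stretched H2 pulls back inward
  h2s <- h2_molecule(2.2)
  fs <- forces_spf(h2s, "hf", "sto-3g", scf_settings(conv_energy = 1e-10))
  expect_gt(fs[1, 3], 0)  # atom at z=0 pulled toward +z
  expect_lt(fs[2, 3], 0)
  # force matches the derivative of a local polynomial fit of E(R)
  rs <- seq(1.32, 1.48, by = 0.04)
  es <- vapply(rs, function(r) run_scf(h2_molecule(r), "hf", "sto-3g",
                                       scf_settings(conv_energy = 1e-12,
                                                    guess = "core"))$energy,
               numeric(1))
  fit <- lm(es ~ poly(rs, 4, raw = TRUE))
  dEdR <- sum(coef(fit)[2:5] * (1:4) * 1.4^(0:3))
  f14 <- forces_spf(h2_molecule(1.4), "hf", "sto-3g",
                    scf_settings(conv_energy = 1e-12, guess = "core"))
  expect_lt(abs(-f14[2, 3] - dEdR), 1e-5)
})

test_that("the seminumerical Hessian of H2 has soft translations", {
  H <- hessian_fh(h2_molecule(1.4), "hf", "sto-3g",
                  scf_settings(conv_energy = 1e-11, guess = "core"))
  expect_equal(dim(H), c(6L, 6L))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  # translations (and here rotations of a diatomic): small eigenvalues
  expect_lt(max(abs(sort(abs(ev))[1:3])), 1e-4)
  expect_lt(attr(H, "asymmetry"), 1e-4)
})

test_that("BFGS optimization descends and is start-point consistent", {
  surr <- quadratic_surrogate(2, seed = 5)
  # start at the optimum: zero steps
  at_min <- bfgs_optimize(surr$energy, surr$force, surr$minimum)
  expect_equal(at_min$n_steps, 0L)
  expect_true(at_min$converged)
  # from a displaced start the quadratic is solved to high accuracy
  opt <- bfgs_optimize(surr$energy, surr$force, surr$minimum + 0.5)
  expect_true(opt$converged)
  expect_lt(max(abs(opt$coords - surr$minimum)), 1e-3)
  expect_true(all(diff(opt$trajectory$energy) <= 1e-12))
  # H2 from two starting lengths agrees to 1e-3 bohr
  go <- function(r0) {
    doc <- task_document("go", h2_molecule(r0), "hf", "sto-3g",
                         keywords = list(scf_conv = 1e-10))
    res <- run_task(doc)
    expect_true(res$success)
    expect_true(res$converged_opt)
    expect_lte(res$energy, run_scf(h2_molecule(r0), "hf", "sto-3g")$energy)
    sqrt(sum((res$molecule$coords[1, ] - res$molecule$coords[2, ])^2))
  }
  expect_equal(go(1.2), go(1.6), tolerance = 1e-3)
})

test_that("velocity Verlet conserves energy on a quadratic surrogate", {
  surr <- quadratic_surrogate(2, seed = 8)
  x0 <- surr$minimum + 0.3
  masses <- c(1836.15, 1836.15)
  # motionless at a stationary point with zero velocities
  still <- velocity_verlet(surr$force, surr$minimum, matrix(0, 2, 3),
                           masses, dt = 0.5, n_steps = 20,
                           energy_fn = surr$energy)
  expect_lt(max(abs(attr(still, "coords") - surr$minimum)), 1e-12)
  # 1000 steps: total-energy drift at the symplectic-integrator level
  tr <- velocity_verlet(surr$force, x0, matrix(0, 2, 3), masses,
                        dt = 0.002, n_steps = 1000, energy_fn = surr$energy)
  drift <- max(abs(tr$e_tot - tr$e_tot[1]))
  expect_lt(drift, 1e-8)
})

test_that("BOMD on H2 is deterministic and near-conservative with FD
           forces", {
  doc <- task_document("bomd", h2_molecule(1.45), "hf", "sto-3g",
                       keywords = list(n_steps = 20L, dt_fs = 0.25,
                                       scf_conv = 1e-10))
  res <- run_task(doc)
  expect_true(res$success)
  tr <- res$trajectory
  expect_equal(nrow(tr), 21L)
  expect_lt(max(abs(tr$e_tot - tr$e_tot[1])), 1e-4)
  # pure function of the document: identical rerun
  res2 <- run_task(doc)
  expect_identical(res$trajectory$e_tot, res2$trajectory$e_tot)
  # thermal initialization needs a seed and is reproducible with one
  expect_false(run_task(task_document("bomd", h2_molecule(1.45), "hf",
                                      "sto-3g",
                                      keywords = list(n_steps = 2L,
                                                      temperature = 300)))$success)
  t1 <- run_task(task_document("bomd", h2_molecule(1.45), "hf", "sto-3g",
                               keywords = list(n_steps = 3L, temperature = 300,
                                               seed = 4L)))
  t2 <- run_task(task_document("bomd", h2_molecule(1.45), "hf", "sto-3g",
                               keywords = list(n_steps = 3L, temperature = 300,
                                               seed = 4L)))
  expect_identical(t1$trajectory$e_tot, t2$trajectory$e_tot)
})

test_that("results serialize to JSON + artifact and reload faithfully", {
  doc <- task_document("spe", h2_molecule(), "hf", "sto-3g")
  res <- run_task(doc)
  tmp <- tempfile(fileext = ".json")
  out <- serialize_result(res, tmp)
  back <- load_result(tmp)
  expect_identical(back$energy, res$energy)  # bit-exact energy round trip
  expect_null(back$forces)                   # spe carries no forces field
  art <- back$artifact_data
  n <- res$scf$n_ao
  expect_equal(dim(art$density), c(n, n))
  expect_equal(dim(art$fock), c(n, n))
  expect_equal(dim(art$overlap), c(n, n))
  expect_length(art$orbital_energies, n)
  expect_lt(max(abs(art$density - res$scf$P)), 1e-15)
  expect_equal(sum(art$occupations), 2)
  unlink(c(tmp, out$artifact_path))
})

test_that("the CLI front end runs an XYZ single point end to end", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(write_xyz(h2_molecule()), xyz)
  out <- tempfile(fileext = ".json")
  capture.output(status <- suppressMessages(
    microdft_main(c("run", "--xyz", xyz, "--task", "spe", "--method", "hf",
                    "--basis", "sto-3g", "--out", out))))
  expect_identical(status, 0L)
  got <- load_result(out)
  expect_equal(got$energy, run_scf(h2_molecule(), "hf", "sto-3g")$energy,
               tolerance = 1e-10)
  unlink(c(xyz, out, sub("\\.json$", ".rds", out)))
})
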