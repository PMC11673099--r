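test_that("four identical normalized s primitives match the closed-form Boys
           value", {
  m1 <- molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  def <- list(elements = list(H = list(list(l = 0, exponents = 1.3,
                                            coefficients = 1))))
  b <- assign_basis(m1, def)
  v <- eri_quartet(b, 1, 1, 1, 1)[1, 1, 1, 1]
  a <- 1.3
  N <- (2 * a / pi)^0.75
  closed <- 2 * pi^2.5 / ((2 * a)^2 * sqrt(4 * a)) * N^4
  expect_equal(v, closed, tolerance = 1e-12)
  # two-center (ss|ss) with separated centers, F0 via erf
  m2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.1)))
  b2 <- assign_basis(m2, def)
  v2 <- eri_quartet(b2, 1, 1, 2, 2)[1, 1, 1, 1]
  f0 <- function(t) 0.5 * sqrt(pi / t) * erf_local(sqrt(t))
  closed2 <- 2 * pi^2.5 / ((2 * a)^2 * sqrt(4 * a)) * N^4 *
    f0((2 * a) * (2 * a) / (4 * a) * 1.1^2)
  expect_equal(v2, closed2, tolerance = 1e-12)
})

test_that("quartet blocks have permutational and translational symmetry", {
  mol <- water_molecule()
  b <- assign_basis(mol, "def2-svp")
  # shells 2 (s), 4 (p), 6 (d) on O and 7 (s on H1): a mixed-l quartet
  q <- function(bb, i, j, k, l) eri_quartet(bb, i, j, k, l)
  blk <- q(b, 4, 2, 6, 7)
  expect_equal(blk, aperm(q(b, 2, 4, 6, 7), c(2, 1, 3, 4)), tolerance = 1e-12)
  expect_equal(blk, aperm(q(b, 4, 2, 7, 6), c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_equal(blk, aperm(q(b, 6, 7, 4, 2), c(3, 4, 1, 2)), tolerance = 1e-12)
  shifted <- molecule(mol$symbols, sweep(mol$coords, 2, c(3.3, -1.7, 0.4), "+"))
  b2 <- assign_basis(shifted, "def2-svp")
  expect_equal(blk, q(b2, 4, 2, 6, 7), tolerance = 1e-12)
})

test_that("the single-precision kernel tracks the double kernel to float
           accuracy", {
  b <- assign_basis(water_molecule(), "sto-3g")
  expect_error(eri_quartet(b, 1, 1, 1, 9), "out of range")
  for (idx in list(c(1, 1, 1, 1), c(3, 2, 3, 2), c(3, 4, 3, 5))) {
    vd <- do.call(eri_quartet, c(list(b), as.list(idx), precision = "double"))
    vs <- do.call(eri_quartet, c(list(b), as.list(idx), precision = "single"))
    expect_lt(max(abs(vd - vs)) / max(abs(vd)), 1e-5)
  }
})

test_that("Schwarz bounds are sound and tight over full random-molecule
           tensors", {
  worst <- -Inf
  n_quartets <- 0L
  for (seed in 1:2) {
    mol <- random_molecule(4, seed = seed, box = 7)
    b <- assign_basis(mol, "sto-3g")
    sb <- schwarz_bounds(b)
    T4 <- eri_dense_oracle(b)
    ns <- length(b$shells)
    ls <- vapply(b$shells, `[[`, integer(1), "l")
    off <- b$ao_offset
    for (A in 1:ns) for (B in 1:ns) for (C in 1:ns) for (D in 1:ns) {
      ia <- off[A]:(off[A] + 2 * ls[A]); ib <- off[B]:(off[B] + 2 * ls[B])
      ic <- off[C]:(off[C] + 2 * ls[C]); id <- off[D]:(off[D] + 2 * ls[D])
      mx <- max(abs(T4[ia, ib, ic, id, drop = FALSE]))
      worst <- max(worst, mx - sb$Q[A, B] * sb$Q[C, D])
      n_quartets <- n_quartets + 1L
    }
    # Cauchy-Schwarz equality case: for (ab|ab) the bound is attained
    expect_equal(sb$Q[1, 2]^2,
                 max(abs(eri_quartet(b, 1, 2, 1, 2))), tolerance = 1e-12)
  }
  expect_gt(n_quartets, 5000)
  expect_lt(worst, 1e-14)
})

test_that("well-separated shell pairs screen out every containing quartet", {
  mol <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 50)))
  def <- list(elements = list(H = list(list(l = 0, exponents = 1,
                                            coefficients = 1))))
  b <- assign_basis(mol, def)
  sb <- schwarz_bounds(b)
  expect_lt(sb$Q[1, 2], 1e-12)
  bt <- batch_by_class(b, eri_settings())
  quartets <- do.call(rbind, lapply(bt$batches, `[[`, "quartets"))
  cross <- apply(quartets, 1, function(q) {
    (1 %in% q[c(1, 2)] && 2 %in% q[c(1, 2)]) ||
      (1 %in% q[c(3, 4)] && 2 %in% q[c(3, 4)])
  })
  expect_false(any(cross))
})

test_that("the three-rule dispatcher matches direct inequality evaluation", {
  set.seed(11)
  bounds <- 10^runif(10000, -20, 2)
  s <- eri_settings()
  got <- classify_quartet(bounds, s)
  want <- ifelse(bounds < 1e-12, "skip",
                 ifelse(bounds < 1e-12 * 1e5, "single", "double"))
  expect_identical(got, want)
  # boundary values: lower bound inclusive for single, upper exclusive
  expect_identical(classify_quartet(c(1e-12, 1e-7), s), c("single", "double"))
  expect_identical(classify_quartet(0, s), "skip")
  # mixed precision off: everything surviving is double
  s2 <- eri_settings(mixed_precision = FALSE)
  expect_identical(unique(classify_quartet(bounds, s2)[bounds >= 1e-12]),
                   "double")
})

test_that("batching partitions canonical quartets by class, signature and
           precision", {
  b <- assign_basis(h2_molecule(), "sto-3g")  # s shells only
  bt <- batch_by_class(b)
  expect_true(all(vapply(bt$batches, function(x)
    all(x$l_class == 0L), logical(1))))
  szs <- vapply(bt$batches, function(x) nrow(x$quartets), integer(1))
  expect_equal(sum(szs) + bt$n_skipped, bt$n_quartets)
  # combinatorial count oracle: npair = ns(ns+1)/2 pairs, npair(npair+1)/2
  ns <- length(b$shells)
  npair <- ns * (ns + 1) / 2
  expect_equal(bt$n_quartets, npair * (npair + 1) / 2)
  # different angular classes never share a batch
  b2 <- assign_basis(water_molecule(), "def2-svp")
  bt2 <- batch_by_class(b2)
  keys <- vapply(bt2$batches, function(x)
    paste(paste(x$l_class, collapse = ","), x$precision,
          paste(x$signature, collapse = ",")), character(1))
  expect_equal(anyDuplicated(keys), 0L)
  ls <- vapply(b2$shells, `[[`, integer(1), "l")
  for (bt_i in bt2$batches) {
    q <- bt_i$quartets
    expect_true(all(ls[q[, 1]] == bt_i$l_class[1] &
                      ls[q[, 2]] == bt_i$l_class[2] &
                      ls[q[, 3]] == bt_i$l_class[3] &
                      ls[q[, 4]] == bt_i$l_class[4]))
  }
})

test_that("build_JK reproduces the dense oracle and respects trivial limits", {
  b <- assign_basis(water_molecule(), "sto-3g")
  n <- b$n_ao
  P0 <- matrix(0, n, n)
  jk0 <- build_JK(P0, b)
  expect_equal(max(abs(jk0$J)), 0)
  expect_equal(max(abs(jk0$K)), 0)
  P <- toy_density(b, seed = 3, target = 10)
  jk <- build_JK(P, b)
  expect_lt(max(abs(jk$J - t(jk$J))), 1e-10)
  expect_lt(max(abs(jk$K - t(jk$K))), 1e-10)
  T4 <- eri_dense_oracle(b)
  Jd <- apply(T4, c(1, 2), function(m) sum(m * P))
  Kd <- matrix(0, n, n)
  for (mu in 1:n) for (nu in 1:n) Kd[mu, nu] <- sum(T4[mu, , nu, ] * P)
  expect_lt(max(abs(jk$J - Jd)), 1e-10)
  expect_lt(max(abs(jk$K - Kd)), 1e-10)
  # Coulomb positivity for PSD densities
  expect_gte(sum(P * jk$J), 0)
  expect_error(build_JK(matrix(0, 2, 2), b), "density matrix")
})

test_that("lowering the tolerance to zero reproduces the dense-oracle J/K", {
  b <- assign_basis(random_molecule(3, seed = 5), "sto-3g")
  P <- toy_density(b, seed = 6, target = 8)
  jk <- build_JK(P, b, eri_settings(tolerance = 0, mixed_precision = FALSE))
  T4 <- eri_dense_oracle(b)
  n <- b$n_ao
  Jd <- apply(T4, c(1, 2), function(m) sum(m * P))
  Kd <- matrix(0, n, n)
  for (mu in 1:n) for (nu in 1:n) Kd[mu, nu] <- sum(T4[mu, , nu, ] * P)
  expect_lt(max(abs(jk$J - Jd)), 1e-11)
  expect_lt(max(abs(jk$K - Kd)), 1e-11)
})

test_that("the dense oracle refuses over-cap systems and is self-consistent", {
  b <- assign_basis(make_water_cluster(3), "def2-tzvpp")
  expect_error(eri_dense_oracle(b), "cap")
  b2 <- assign_basis(h2_molecule(), "sto-3g")
  T4 <- eri_dense_oracle(b2)
  for (pp in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2), c(4, 3, 2, 1)))
    expect_equal(T4, aperm(T4, pp), tolerance = 1e-12)
})

test_that("the screening report counts every canonical quartet once", {
  b <- assign_basis(water_molecule(), "def2-svp")
  rep <- screening_report(b)
  ns <- length(b$shells)
  npair <- ns * (ns + 1) / 2
  expect_equal(sum(rep$skipped + rep$single + rep$double),
               npair * (npair + 1) / 2)
  expect_true(all(grepl("^\\([spdfg]{2}\\|[spdfg]{2}\\)$", rep$class)))
})
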