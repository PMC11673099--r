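test_that("reference-level atomic grids honor the per-row sizes", {
  g_first <- atomic_grid(8, level = 3)   # O: first row
  expect_equal(g_first$n_radial, 60)
  expect_equal(g_first$n_angular, 434)
  expect_equal(nrow(g_first$points), 60 * 434)
  g_second <- atomic_grid(14, level = 3) # Si: second row
  expect_equal(g_second$n_radial, 90)
  expect_equal(g_second$n_angular, 590)
  expect_equal(nrow(g_second$points), 90 * 590)
  expect_error(angular_grid(433), "supported")
  expect_error(atomic_grid(99, 3), "unsupported")
})

test_that("angular weights sum to 4*pi and integrate harmonics to zero", {
  for (n in c(50, 434, 590)) {
    ang <- angular_grid(n)
    expect_equal(sum(ang$weights), 4 * pi, tolerance = 1e-12)
    # odd monomials and Y_2-type integrands vanish on the sphere
    expect_lt(abs(sum(ang$weights * ang$points[, 1])), 1e-12)
    expect_lt(abs(sum(ang$weights *
                        (3 * ang$points[, 3]^2 - 1))), 1e-11)
  }
})

test_that("the radial rule integrates the Gaussian moment to sqrt(pi)/4", {
  for (Z in c(1, 8)) {
    g <- atomic_grid(Z, level = 3)
    rad <- microdft:::radial_grid(g$n_radial, microdft:::radial_xi(Z))
    val <- sum(rad$w * exp(-rad$r^2))
    expect_equal(val, sqrt(pi) / 4, tolerance = 1e-8)
  }
})

test_that("Becke partition is a partition of unity with 0.5 factors on the
           midplane", {
  one <- becke_partition(molecule("He", matrix(0, 1, 3)), level = 1)
  ga <- atomic_grid(2, level = 1)
  # single atom: partition factors all exactly 1
  expect_equal(one$weights, ga$weights, tolerance = 0)
  # smoothing function written out independently: three iterations of
  # f(mu) = 1.5 mu - 0.5 mu^3, s = (1 - f)/2
  s_ref <- function(mu) {
    f <- mu
    f <- 1.5 * f - 0.5 * f^3
    f <- 1.5 * f - 0.5 * f^3
    f <- 1.5 * f - 0.5 * f^3
    0.5 * (1 - f)
  }
  expect_equal(s_ref(0), 0.5)     # midplane splits evenly
  expect_equal(s_ref(-1), 1)      # deep inside cell A
  expect_equal(s_ref(1), 0)
  # homonuclear diatomic: every atom-1 point weight is w_quad * s(mu), the
  # factors for the two atoms summing to 1 at every point
  h2 <- h2_molecule(1.4)
  g <- becke_partition(h2, level = 1)
  ga1 <- atomic_grid(1, level = 1)
  n1 <- nrow(ga1$points)
  pts1 <- g$points[seq_len(n1), ]
  d <- function(p, cc) sqrt(rowSums(sweep(p, 2, cc, "-")^2))
  mu <- (d(pts1, h2$coords[1, ]) - d(pts1, h2$coords[2, ])) / 1.4
  expect_equal(g$weights[seq_len(n1)], ga1$weights * s_ref(mu),
               tolerance = 1e-12)
  # heteronuclear three-centre case: factors renormalized to sum exactly 1
  mol <- water_molecule()
  gw <- becke_partition(mol, level = 0)
  gaO <- atomic_grid(8, level = 0)
  nO <- nrow(gaO$points)
  ptsO <- gw$points[seq_len(nO), ]
  dd <- vapply(1:3, function(a) d(ptsO, mol$coords[a, ]), numeric(nO))
  P <- matrix(1, nO, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    Rij <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    s <- s_ref((dd[, i] - dd[, j]) / Rij)
    P[, i] <- P[, i] * s
    P[, j] <- P[, j] * (1 - s)
  }
  expect_equal(gw$weights[seq_len(nO)], gaO$weights * P[, 1] / rowSums(P),
               tolerance = 1e-12)
})

test_that("AO cutoff radii invert the closed form and behave monotonically", {
  sh1 <- gaussian_shell(1, 0, 1.2, 1.0)
  th <- 1e-10
  r <- ao_cutoff_radius(sh1, th)
  # closed form: value(r) = value(0) * exp(-a r^2)
  peak <- abs(sh1$norm_coefs) * max(colSums(abs(microdft:::spherical_transform(0))))
  expect_equal(r, sqrt(log(peak / th) / 1.2), tolerance = 1e-10)
  # halving the exponent increases the radius
  sh2 <- gaussian_shell(1, 0, 0.6, 1.0)
  expect_gt(ao_cutoff_radius(sh2, th), r)
  # lowering the threshold increases the radius
  expect_gt(ao_cutoff_radius(sh1, 1e-14), r)
  # over-threshold case: radius 0
  expect_equal(ao_cutoff_radius(sh1, 1e6), 0)
  # beyond the radius, evaluated AOs are below threshold (p shell)
  shp <- gaussian_shell(1, 1, 0.8, 1.0)
  rp <- ao_cutoff_radius(shp, th)
  mol <- molecule("H", matrix(0, 1, 3), multiplicity = 2L)
  def <- list(elements = list(H = list(list(l = 1, exponents = 0.8,
                                            coefficients = 1))))
  b <- assign_basis(mol, def)
  pts <- matrix(c(rp + 0.01, 0, 0, 0, rp + 0.5, 0, 1, 1, rp), 3, 3, byrow = TRUE)
  grid <- list(points = pts, weights = rep(1, 3), atom = rep(1L, 3))
  ao <- eval_ao_block_sparse(structure(grid, class = "mdft_grid"), b,
                             threshold = 0, eps = 0)
  expect_lt(max(abs(bs_dense(ao$ao)[1:2, ])), th)
})
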