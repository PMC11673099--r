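# Shared fixtures and independent oracles for the test suite.
# The oracles here deliberately avoid the package's recursion kernels:
# one-electron integrals are done by direct numerical quadrature of
# explicitly evaluated AOs, the H2 reference is a from-scratch closed-form
# restricted Hartree-Fock, and task kernels are exercised on exact quadratic
# surrogates.

WATER_XYZ <- "3\nwater\nO 0.0 0.0 0.1173\nH 0.0 0.7572 -0.4692\nH 0.0 -0.7572 -0.4692"

water_molecule <- function() parse_xyz(WATER_XYZ)

h2_molecule <- function(r_bohr = 1.4) {
  molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, r_bohr)))
}

rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  ct * diag(3) + st * rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]),
                            c(-a[2], a[1], 0)) + (1 - ct) * outer(a, a)
}

# ---- explicit AO evaluation (pure R, no recursion kernels) -----------------

# value of every spherical AO of a shell at points (n x 3), plus the
# Laplacian when requested; direct monomial arithmetic
oracle_eval_shell <- function(shell, center, pts, laplacian = FALSE) {
  l <- shell$l
  ex <- cart_exponents_oracle(l)
  Tm <- microdft:::spherical_transform(l)
  x <- pts[, 1] - center[1]; y <- pts[, 2] - center[2]; z <- pts[, 3] - center[3]
  r2 <- x^2 + y^2 + z^2
  np <- length(shell$exponents)
  val <- matrix(0, nrow(pts), nrow(ex))
  lap <- if (laplacian) matrix(0, nrow(pts), nrow(ex)) else NULL
  pw <- function(v, k) if (k <= 0) rep(1, length(v)) else v^k
  for (p in seq_len(np)) {
    a <- shell$exponents[p]; cc <- shell$norm_coefs[p]
    g <- exp(-a * r2)
    for (k in seq_len(nrow(ex))) {
      i <- ex[k, 1]; j <- ex[k, 2]; m <- ex[k, 3]
      mono <- pw(x, i) * pw(y, j) * pw(z, m)
      val[, k] <- val[, k] + cc * mono * g
      if (laplacian) {
        # Laplacian of x^i y^j z^m e^{-a r^2}, per dimension:
        # d2/dx2 = [i(i-1) x^{i-2} - 2a(2i+1) x^i + 4a^2 x^{i+2}] y^j z^m
        dd <- function(v, k1, rest) {
          out <- -2 * a * (2 * k1 + 1) * pw(v, k1) + 4 * a^2 * pw(v, k1 + 2)
          if (k1 >= 2) out <- out + k1 * (k1 - 1) * pw(v, k1 - 2)
          out * rest
        }
        lp <- dd(x, i, pw(y, j) * pw(z, m)) + dd(y, j, pw(x, i) * pw(z, m)) +
          dd(z, m, pw(x, i) * pw(y, j))
        lap[, k] <- lap[, k] + cc * lp * g
      }
    }
  }
  out <- list(val = val %*% Tm)
  if (laplacian) out$lap <- lap %*% Tm
  out
}

cart_exponents_oracle <- function(l) {
  out <- NULL
  for (ax in seq.int(l, 0)) for (ay in seq.int(l - ax, 0))
    out <- rbind(out, c(ax, ay, l - ax - ay))
  out
}

# spherical quadrature grid centred at `center`: Gauss-Legendre radial map
# r = rmax (1+x)/2 would cluster badly; use r = -log((1-x)/2)/gamma to reach
# the tail, with the r^2 volume factor folded into the weights
oracle_sphere_grid <- function(center, n_rad = 100, n_th = 16, gamma = 0.9) {
  gl <- microdft:::gauss_legendre(n_rad)
  r <- -log((1 - gl$nodes) / 2) / gamma
  wr <- gl$weights / (gamma * (1 - gl$nodes)) * r^2
  glt <- microdft:::gauss_legendre(n_th)
  nph <- 2 * n_th + 1
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  ct <- rep(glt$nodes, each = nph)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_th)
  u <- cbind(st * cos(ph), st * sin(ph), ct)
  wa <- rep(glt$weights, each = nph) * (2 * pi / nph)
  pts <- kronecker(r, u)
  w <- as.numeric(outer(wa, wr))
  list(points = sweep(pts, 2, center, "+"), weights = w)
}

# numerical-quadrature one-electron matrices between two shells
oracle_one_electron_pair <- function(shA, cA, shB, cB, Zs, centers) {
  mid <- (cA + cB) / 2
  g <- oracle_sphere_grid(mid, n_rad = 110, n_th = 16)
  A <- oracle_eval_shell(shA, cA, g$points, laplacian = FALSE)
  B <- oracle_eval_shell(shB, cB, g$points, laplacian = TRUE)
  S <- crossprod(A$val, g$weights * B$val)
  T <- -0.5 * crossprod(A$val, g$weights * B$lap)
  V <- 0
  for (ic in seq_along(Zs)) {
    gc <- oracle_sphere_grid(centers[ic, ], n_rad = 110, n_th = 16)
    Ac <- oracle_eval_shell(shA, cA, gc$points)
    Bc <- oracle_eval_shell(shB, cB, gc$points)
    rr <- sqrt(rowSums(sweep(gc$points, 2, centers[ic, ], "-")^2))
    V <- V - Zs[ic] * crossprod(Ac$val, (gc$weights / rr) * Bc$val)
  }
  list(S = S, T = T, V = V)
}

# ---- closed-form H2/STO-3G restricted Hartree-Fock oracle ------------------
# All integrals between contracted s functions from textbook closed forms
# (Boys F0 via erf), simple fixed-point SCF with no DIIS.
oracle_rhf_h2 <- function(r_bohr = 1.4) {
  bs <- jsonlite::fromJSON(system.file("extdata", "basis", "sto-3g.json",
                                       package = "microdft"),
                           simplifyVector = FALSE)
  a <- unlist(bs$elements$H[[1]]$exponents)
  d <- unlist(bs$elements$H[[1]]$coefficients)
  d <- d * (2 * a / pi)^0.75  # normalized primitives
  centers <- rbind(c(0, 0, 0), c(0, 0, r_bohr))
  f0 <- function(t) ifelse(t < 1e-12, 1 - t / 3,
                           0.5 * sqrt(pi / t) * erf_local(sqrt(t)))
  prim_s <- function(ai, A, aj, B) {
    p <- ai + aj
    (pi / p)^1.5 * exp(-ai * aj / p * sum((A - B)^2))
  }
  prim_t <- function(ai, A, aj, B) {
    mu <- ai * aj / (ai + aj); R2 <- sum((A - B)^2)
    mu * (3 - 2 * mu * R2) * prim_s(ai, A, aj, B)
  }
  prim_v <- function(ai, A, aj, B, C) {
    p <- ai + aj
    P <- (ai * A + aj * B) / p
    -2 * pi / p * exp(-ai * aj / p * sum((A - B)^2)) * f0(p * sum((P - C)^2))
  }
  prim_eri <- function(ai, A, aj, B, ak, C, al, D) {
    p <- ai + aj; q <- ak + al
    P <- (ai * A + aj * B) / p; Q <- (ak * C + al * D) / q
    2 * pi^2.5 / (p * q * sqrt(p + q)) *
      exp(-ai * aj / p * sum((A - B)^2)) * exp(-ak * al / q * sum((C - D)^2)) *
      f0(p * q / (p + q) * sum((P - Q)^2))
  }
  nb <- 2L
  idx <- function(b) centers[b, ]
  S <- T <- V <- matrix(0, nb, nb)
  for (b1 in 1:nb) for (b2 in 1:nb) for (i in seq_along(a)) for (j in seq_along(a)) {
    cc <- d[i] * d[j]
    S[b1, b2] <- S[b1, b2] + cc * prim_s(a[i], idx(b1), a[j], idx(b2))
    T[b1, b2] <- T[b1, b2] + cc * prim_t(a[i], idx(b1), a[j], idx(b2))
    for (n in 1:nb)
      V[b1, b2] <- V[b1, b2] + cc * prim_v(a[i], idx(b1), a[j], idx(b2), idx(n))
  }
  ERI <- array(0, c(nb, nb, nb, nb))
  for (b1 in 1:nb) for (b2 in 1:nb) for (b3 in 1:nb) for (b4 in 1:nb) {
    s <- 0
    for (i in seq_along(a)) for (j in seq_along(a))
      for (k in seq_along(a)) for (l in seq_along(a))
        s <- s + d[i] * d[j] * d[k] * d[l] *
          prim_eri(a[i], idx(b1), a[j], idx(b2), a[k], idx(b3), a[l], idx(b4))
    ERI[b1, b2, b3, b4] <- s
  }
  H <- T + V
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  P <- matrix(0, nb, nb)
  E_old <- 0
  for (it in 1:200) {
    G <- matrix(0, nb, nb)
    for (mu in 1:nb) for (nu in 1:nb)
      G[mu, nu] <- sum(P * (ERI[mu, nu, , ] - 0.5 * ERI[mu, , nu, ]))
    F <- H + G
    E <- sum(P * (H + F)) / 2 + 1 / r_bohr
    ev <- eigen(t(X) %*% F %*% X, symmetric = TRUE)
    C <- X %*% ev$vectors[, order(ev$values), drop = FALSE]
    P <- 2 * tcrossprod(C[, 1, drop = FALSE])
    if (abs(E - E_old) < 1e-13 && it > 3) break
    E_old <- E
  }
  E
}

erf_local <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# ---- quadratic surrogate potential for the task kernels --------------------
# E(x) = 1/2 (x - x0)^T Hq (x - x0) + e0, exact forces/Hessian known
quadratic_surrogate <- function(n_atoms, seed = 42, e0 = -1) {
  set.seed(seed)
  n3 <- 3L * n_atoms
  A <- matrix(rnorm(n3 * n3), n3)
  Hq <- crossprod(A) / n3 + diag(n3)
  x0 <- rnorm(n3)
  list(
    Hq = Hq, x0 = x0, e0 = e0,
    energy = function(coords) {
      d <- as.numeric(t(coords)) - x0
      e0 + 0.5 * sum(d * (Hq %*% d))
    },
    force = function(coords) {
      d <- as.numeric(t(coords)) - x0
      matrix(-as.numeric(Hq %*% d), ncol = 3, byrow = TRUE)
    },
    minimum = matrix(x0, ncol = 3, byrow = TRUE)
  )
}
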