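# Real-spherical-harmonic machinery: Gauss-Legendre rules, real Y_lm
# evaluation, and the Cartesian-monomial -> solid-harmonic transformation
# used to emit pure spherical AOs (2l+1 per shell, m = -l..+l).

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' Golub-Welsch: eigendecomposition of the Jacobi matrix of the Legendre
#' recurrence.
#'
#' @param n number of nodes
#' @return list with `nodes` (ascending) and `weights`
#' @keywords internal
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0.0, weights = 2.0))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(i, i + 1L)] <- b
  Jm[cbind(i + 1L, i)] <- b
  ev <- eigen(Jm, symmetric = TRUE)
  ord <- order(ev$values)
  list(nodes = ev$values[ord], weights = 2 * ev$vectors[1, ord]^2)
}

# Associated Legendre P_l^m(x), no Condon-Shortley phase, for scalars/vectors x
assoc_legendre <- function(l, m, x) {
  pmm <- rep(1.0, length(x))
  if (m > 0) {
    somx2 <- sqrt(pmax(0, (1 - x) * (1 + x)))
    fact <- 1.0
    for (i in seq_len(m)) {
      pmm <- pmm * fact * somx2
      fact <- fact + 2.0
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  pll <- pmmp1
  for (ll in seq.int(m + 2L, l)) {
    pll <- ((2 * ll - 1) * x * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# Orthonormal real spherical harmonic Y_lm at unit vectors (ct = cos(theta),
# phi = azimuth); m in -l..l, cosine branch for m>0, sine for m<0.
real_sph_harm <- function(l, m, ct, phi) {
  am <- abs(m)
  norm <- sqrt((2 * l + 1) / (4 * pi) * exp(lfactorial(l - am) - lfactorial(l + am)))
  p <- assoc_legendre(l, am, ct)
  if (m == 0) return(norm * p)
  if (m > 0) sqrt(2) * norm * p * cos(am * phi)
  else sqrt(2) * norm * p * sin(am * phi)
}

# Cartesian monomial exponent list for angular momentum l, matching the C++
# kernel ordering: lx descending, then ly descending.
cart_exponents <- function(l) {
  out <- list()
  for (ax in seq.int(l, 0)) {
    for (ay in seq.int(l - ax, 0)) {
      out[[length(out) + 1L]] <- c(ax, ay, l - ax - ay)
    }
  }
  do.call(rbind, out)
}

#' Cartesian-to-spherical shell transformation
#'
#' Matrix T (ncart x (2l+1)) such that the real solid harmonics
#' r^l Y_lm, m = -l..+l, equal the Cartesian monomial vector times T.
#' Obtained by exact weighted least squares on a product quadrature of the
#' sphere (the harmonics lie in the monomial span, so the residual is zero);
#' cached per l.
#'
#' @param l angular momentum (0..4)
#' @return numeric matrix ncart(l) x (2l+1)
#' @keywords internal
spherical_transform <- function(l) {
  stopifnot(l >= 0, l <= 4)
  key <- paste0("sphT", l)
  if (!is.null(.microdft_cache[[key]])) return(.microdft_cache[[key]])
  nth <- 12L; nph <- 25L
  gl <- gauss_legendre(nth)
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  ct <- rep(gl$nodes, each = nph)
  ph <- rep(phi, times = nth)
  w <- rep(gl$weights, each = nph) * (2 * pi / nph)
  st <- sqrt(pmax(0, 1 - ct^2))
  x <- st * cos(ph); y <- st * sin(ph); z <- ct
  ex <- cart_exponents(l)
  M <- vapply(seq_len(nrow(ex)), function(k) {
    x^ex[k, 1] * y^ex[k, 2] * z^ex[k, 3]
  }, numeric(length(x)))
  M <- matrix(M, nrow = length(x))
  Y <- vapply(seq.int(-l, l), function(m) real_sph_harm(l, m, ct, ph),
              numeric(length(x)))
  Y <- matrix(Y, nrow = length(x))
  A <- crossprod(M, w * M)
  B <- crossprod(M, w * Y)
  T <- solve(A, B)
  T[abs(T) < 1e-13] <- 0
  .microdft_cache[[key]] <- T
  T
}
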