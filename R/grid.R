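# Molecular quadrature grids: Treutler-Ahlrichs-mapped radial rules, product
# spherical angular rules, Becke fuzzy-cell partitioning, and AO distance
# cutoffs for sparse collocation.
#
# Angular rules are product Gauss-Legendre (polar) x equal-spaced (azimuth)
# grids; the bundled sizes include 434 = 14 x 31 and 590 = 10 x 59 points so
# that the reference level reproduces the 60x434 (first-row) and 90x590
# (second-row) per-atom sizes. Weights sum to 4*pi exactly.

# supported angular point counts -> (n_polar, n_azimuth)
ANGULAR_TABLE <- local({
  m <- c(3:16)
  tab <- cbind(n = 2 * m^2, nth = m, nph = 2 * m)
  tab <- rbind(tab, c(434, 14, 31), c(590, 10, 59))
  tab[order(tab[, 1]), ]
})

# per-level (radial, angular) sizes; level 3 is the reference level
GRID_LEVELS <- list(
  row1 = list(radial = c(25, 40, 50, 60, 80), angular = c(50, 128, 288, 434, 512)),
  row2 = list(radial = c(35, 55, 75, 90, 110), angular = c(72, 162, 338, 590, 722))
)

#' Spherical angular quadrature rule
#'
#' Product rule: Gauss-Legendre in cos(theta) times an equally spaced,
#' uniformly weighted azimuthal rule. Exact for spherical harmonics up to
#' degree min(2*n_polar - 1, n_azimuth - 1); weights sum to 4*pi.
#'
#' @param n total point count; must be one of the supported sizes
#' @return list: `points` (n x 3 unit vectors), `weights` (sum 4*pi)
#' @export
angular_grid <- function(n) {
  row <- ANGULAR_TABLE[ANGULAR_TABLE[, "n"] == n, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unsupported angular grid size ", n, "; supported sizes: ",
         paste(ANGULAR_TABLE[, "n"], collapse = ", "), call. = FALSE)
  nth <- row[1, "nth"]; nph <- row[1, "nph"]
  gl <- gauss_legendre(nth)
  phi <- 2 * pi * (seq_len(nph) - 1) / nph
  ct <- rep(gl$nodes, each = nph)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = nth)
  list(points = cbind(st * cos(ph), st * sin(ph), ct),
       weights = rep(gl$weights, each = nph) * (2 * pi / nph))
}

# Treutler-Ahlrichs M4 radial map over Gauss-Chebyshev (2nd kind) nodes;
# returns nodes r and weights including the r^2 volume factor, i.e.
# sum(w * f(r)) ~ int_0^inf f(r) r^2 dr.
radial_grid <- function(n, xi = 1.0) {
  i <- seq_len(n)
  theta <- i * pi / (n + 1)
  x <- cos(theta)
  wgc <- pi / (n + 1) * sin(theta)^2
  alpha <- 0.6
  ln2 <- log(2)
  r <- (xi / ln2) * (1 + x)^alpha * log(2 / (1 - x))
  drdx <- (xi / ln2) * (alpha * (1 + x)^(alpha - 1) * log(2 / (1 - x)) +
                          (1 + x)^alpha / (1 - x))
  w <- wgc / sqrt(1 - x^2) * drdx * r^2
  ord <- order(r)
  list(r = r[ord], w = w[ord])
}

# TA size parameter per element (bohr); light-atom values, defaulted beyond
radial_xi <- function(Z) {
  xi <- c(0.8, 0.9, 1.8, 1.4, 1.3, 1.1, 0.9, 0.9, 0.9, 0.9)
  if (Z <= length(xi)) xi[Z] else 1.0
}

#' Per-atom quadrature grid
#'
#' At the reference level (3), first-row atoms (Z <= 10) get 60 radial x 434
#' angular points and heavier supported atoms 90 x 590, before pruning (no
#' pruning is applied).
#'
#' @param Z atomic number (1..36)
#' @param level integer grid quality 0..4 (default 3 = reference)
#' @return list: `points` (n x 3, atom at origin), `weights` (radial x
#'   angular product weights), `n_radial`, `n_angular`
#' @export
atomic_grid <- function(Z, level = 3L) {
  if (Z < 1 || Z > 36) stop("unsupported element Z = ", Z, call. = FALSE)
  if (level < 0L || level > 4L) stop("grid level must be 0..4", call. = FALSE)
  lv <- if (Z <= 10) GRID_LEVELS$row1 else GRID_LEVELS$row2
  nrad <- lv$radial[level + 1L]; nang <- lv$angular[level + 1L]
  rad <- radial_grid(nrad, radial_xi(Z))
  ang <- angular_grid(nang)
  # stagger: a fixed, deterministic rigid rotation of the angular rule per
  # radial shell averages its residual angular error across shells
  pts <- matrix(0, nrad * nang, 3)
  for (i in seq_len(nrad)) {
    R <- shell_rotation(i)
    pts[((i - 1L) * nang + 1L):(i * nang), ] <-
      rad$r[i] * (ang$points %*% t(R))
  }
  w <- as.numeric(outer(ang$weights, rad$w))  # angular fastest, matches rows
  list(points = pts, weights = w, n_radial = nrad, n_angular = nang)
}

# deterministic rigid rotation for radial shell i (z-y-z Euler angles on
# incommensurate sequences; the golden angle drives the azimuth)
shell_rotation <- function(i) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, byrow = TRUE)
  Rz(i * 2.399963229728653) %*% Ry(i * 1.2312) %*% Rz(i * 0.7416)
}

# Becke smoothing: three iterations of f(mu) = 1.5 mu - 0.5 mu^3
becke_s <- function(mu) {
  f <- mu
  for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
  0.5 * (1 - f)
}

#' Becke-partitioned molecular grid
#'
#' Atom-centred grids combined with Becke fuzzy-cell partition-of-unity
#' weights (three smoothing iterations, no atomic size adjustment). At every
#' point the partition factors over atoms sum to 1.
#'
#' @param mol an `mdft_molecule` with at least one atom
#' @param level grid level 0..4 (default 3 = reference)
#' @return object of class `mdft_grid`: `points` (n x 3 bohr), `weights`
#'   (quadrature x partition), `atom` (owning atom per point), `level`,
#'   `n_points`
#' @export
becke_partition <- function(mol, level = 3L) {
  nat <- length(mol$Z)
  if (nat < 1L) stop("molecular grid needs at least one atom", call. = FALSE)
  pts_l <- list(); w_l <- list(); atom_l <- list()
  for (a in seq_len(nat)) {
    g <- atomic_grid(mol$Z[a], level)
    pts <- sweep(g$points, 2, mol$coords[a, ], "+")
    w <- g$weights
    if (nat > 1L) {
      # cell functions for all atoms at this atom's points
      d <- vapply(seq_len(nat), function(b) {
        sqrt(rowSums(sweep(pts, 2, mol$coords[b, ], "-")^2))
      }, numeric(nrow(pts)))
      Pcell <- matrix(1, nrow(pts), nat)
      for (i in seq_len(nat - 1L)) for (j in seq.int(i + 1L, nat)) {
        Rij <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
        mu <- (d[, i] - d[, j]) / Rij
        s <- becke_s(mu)
        Pcell[, i] <- Pcell[, i] * s
        Pcell[, j] <- Pcell[, j] * (1 - s)
      }
      w <- w * Pcell[, a] / rowSums(Pcell)
    }
    pts_l[[a]] <- pts; w_l[[a]] <- w; atom_l[[a]] <- rep(a, nrow(pts))
  }
  structure(
    list(points = do.call(rbind, pts_l), weights = unlist(w_l),
         atom = unlist(atom_l), level = as.integer(level),
         n_points = sum(vapply(pts_l, nrow, integer(1)))),
    class = "mdft_grid"
  )
}

#' @export
print.mdft_grid <- function(x, ...) {
  cat("<mdft_grid> level ", x$level, ", ", x$n_points, " points\n", sep = "")
  invisible(x)
}

#' Export a molecular grid as tabular text
#' @param grid an `mdft_grid`
#' @param file connection or path passed to [utils::write.table()]
#' @return invisibly, the data.frame written (x, y, z, w, atom)
#' @export
export_grid <- function(grid, file = stdout()) {
  df <- data.frame(x = grid$points[, 1], y = grid$points[, 2],
                   z = grid$points[, 3], w = grid$weights, atom = grid$atom)
  utils::write.table(df, file, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Distance cutoff radius of a shell
#'
#' Radius beyond which every AO of the shell is guaranteed below `threshold`
#' in magnitude, using the radial envelope
#' \eqn{g(r) = r^l \sum_i |c_i| e^{-\alpha_i r^2} \max_m \sum |T|}.
#' Monotone: decreasing threshold enlarges the radius; halving the smallest
#' exponent enlarges it.
#'
#' @param shell an `mdft_shell`
#' @param threshold positive AO magnitude threshold
#' @return radius in bohr (0 if the envelope never reaches the threshold)
#' @export
ao_cutoff_radius <- function(shell, threshold) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  Tm <- spherical_transform(shell$l)
  tmax <- max(colSums(abs(Tm)))
  env_fun <- function(r) {
    r^shell$l * as.numeric(abs(shell$norm_coefs) %*%
                             exp(-outer(shell$exponents, r^2))) * tmax
  }
  # peak of the envelope, then root-find outward
  rpk <- if (shell$l == 0) 0 else sqrt(shell$l / (2 * min(shell$exponents)))
  if (env_fun(rpk) < threshold) return(0)
  hi <- rpk + 1
  while (env_fun(hi) >= threshold && hi < 200) hi <- hi * 1.5
  if (hi >= 200) return(200)
  stats::uniroot(function(r) env_fun(r) - threshold, c(rpk, hi),
                 tol = 1e-12)$root
}
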