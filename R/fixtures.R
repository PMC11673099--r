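# Deterministic input generators: rigid water clusters on an integer
# lattice, seeded random molecules, and toy density matrices, so every
# component is testable without external structure downloads.

#' Rigid water cluster on a deterministic lattice
#'
#' `n` water monomers with fixed internal geometry (r(OH) = 0.9572 Angstrom,
#' HOH angle 104.52 degrees) placed on a cubic lattice with 2.8 Angstrom
#' O-O spacing (>= 2.5 by construction); orientation alternates
#' deterministically with the lattice parity. Purely integer lattice
#' arithmetic, so identical n gives bitwise identical molecules.
#'
#' @param n number of monomers (>= 1)
#' @return an `mdft_molecule` with 3n atoms
#' @export
make_water_cluster <- function(n) {
  stopifnot(n >= 1)
  r_oh <- 0.9572 * BOHR_PER_ANGSTROM
  half <- (104.52 / 2) * pi / 180
  # monomer in its local frame (O at origin, C2v axis = z)
  mono <- rbind(
    O = c(0, 0, 0),
    H1 = c(r_oh * sin(half), 0, r_oh * cos(half)),
    H2 = c(-r_oh * sin(half), 0, r_oh * cos(half))
  )
  flip <- mono
  flip[, 3] <- -flip[, 3]
  a <- 2.8 * BOHR_PER_ANGSTROM  # lattice constant
  k <- ceiling(n^(1 / 3))
  syms <- character(0)
  coords <- NULL
  placed <- 0L
  for (iz in 0:(k - 1)) for (iy in 0:(k - 1)) for (ix in 0:(k - 1)) {
    if (placed >= n) break
    origin <- a * c(ix, iy, iz)
    m <- if ((ix + iy + iz) %% 2L == 0L) mono else flip
    coords <- rbind(coords, sweep(m, 2, origin, "+"))
    syms <- c(syms, c("O", "H", "H"))
    placed <- placed + 1L
  }
  molecule(syms, coords)
}

#' Seeded random molecule
#'
#' Rejection sampling of atom positions in a cubic box under a minimum
#' interatomic distance constraint; deterministic per seed.
#'
#' @param n_atoms number of atoms
#' @param palette element symbols to draw from (default H, C, N, O)
#' @param box box edge length in bohr (default 6)
#' @param min_dist minimum interatomic distance in bohr (default 1.6)
#' @param seed integer RNG seed
#' @param charge,multiplicity passed to [molecule()]; default multiplicity
#'   is chosen to match the electron-count parity
#' @return an `mdft_molecule`
#' @export
random_molecule <- function(n_atoms, palette = c("H", "C", "N", "O"),
                            box = 6, min_dist = 1.6, seed = 1L,
                            charge = 0L, multiplicity = NULL) {
  stopifnot(n_atoms >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  syms <- sample(palette, n_atoms, replace = TRUE)
  coords <- matrix(NA_real_, n_atoms, 3)
  for (i in seq_len(n_atoms)) {
    ok <- FALSE
    for (attempt in seq_len(2000L)) {
      p <- runif(3, 0, box)
      if (i == 1L ||
          min(sqrt(rowSums(sweep(coords[seq_len(i - 1L), , drop = FALSE],
                                 2, p, "-")^2))) >= min_dist) {
        coords[i, ] <- p
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place atom ", i, " after 2000 attempts; ",
           "increase the box length", call. = FALSE)
  }
  if (is.null(multiplicity)) {
    nel <- sum(element_number(syms)) - charge
    multiplicity <- if (nel %% 2L == 0L) 1L else 2L
  }
  molecule(syms, coords, charge, multiplicity)
}

#' Toy density matrix with a prescribed tr(P S)
#'
#' Symmetric positive semidefinite matrix scaled so that
#' tr(P S) equals `target` exactly; unit-test input for J/K builds and
#' grid densities.
#'
#' @param basis an `mdft_basis`
#' @param seed integer RNG seed
#' @param target requested tr(P S) (>= 0); 0 returns the zero matrix
#' @return symmetric PSD matrix (n_ao x n_ao)
#' @export
toy_density <- function(basis, seed = 1L, target = 0) {
  stopifnot(target >= 0)
  n <- basis$n_ao
  if (target == 0) return(matrix(0, n, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- matrix(rnorm(n * n), n, n)
  P <- tcrossprod(X) / n
  S <- core_hamiltonian(basis)$S
  P * (target / sum(P * S))
}
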