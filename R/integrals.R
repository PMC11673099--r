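# One-electron integrals: overlap, kinetic, nuclear attraction -> core
# Hamiltonian H = T + V.

#' Core Hamiltonian and overlap matrices
#'
#' Computes the overlap S, kinetic T and nuclear-attraction V matrices over
#' the spherical AOs of `basis` via McMurchie-Davidson recursion, and the
#' core Hamiltonian H = T + V.
#'
#' @param basis an `mdft_basis`
#' @return object of class `mdft_core`: list with `S`, `T`, `V`, `H`
#' @export
core_hamiltonian <- function(basis) {
  mol <- basis$molecule
  env <- shell_env(basis)
  res <- cpp_one_electron(env, as.numeric(mol$Z), mol$coords)
  for (nm in c("S", "T", "V")) {
    if (any(!is.finite(res[[nm]]))) {
      bad <- which(!is.finite(res[[nm]]), arr.ind = TRUE)[1, ]
      stop("non-finite ", nm, " element at AO indices (", bad[1], ", ", bad[2],
           ")", call. = FALSE)
    }
  }
  structure(list(S = res$S, T = res$T, V = res$V, H = res$T + res$V),
            class = "mdft_core")
}
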