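# Physical constants and element data (atomic units throughout).

#' @keywords internal
BOHR_PER_ANGSTROM <- 1.8897261246257702

# Elements H..Kr; heavier elements would require effective core potentials,
# which are out of scope and rejected at parse time.
ELEMENTS <- c(
  "H", "He",
  "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar",
  "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

# standard atomic masses (amu), needed only by BOMD
ELEMENT_MASSES <- c(
  1.008, 4.0026,
  6.94, 9.0122, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948,
  39.098, 40.078, 44.956, 47.867, 50.942, 51.996, 54.938, 55.845,
  58.933, 58.693, 63.546, 65.38,
  69.723, 72.630, 74.922, 78.971, 79.904, 83.798
)

AMU_TO_ME <- 1822.888486209      # electron masses per amu
FS_TO_AUT <- 41.341373335182114  # atomic time units per femtosecond

#' Atomic number for an element symbol
#' @param symbol character vector of element symbols (case sensitive, "H".."Kr")
#' @return integer atomic numbers
#' @keywords internal
element_number <- function(symbol) {
  z <- match(symbol, ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbol[is.na(z)])
    stop("unknown or unsupported element symbol(s): ", paste(bad, collapse = ", "),
         " (supported: H..Kr; heavier elements need ECPs, which are not implemented)",
         call. = FALSE)
  }
  as.integer(z)
}
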