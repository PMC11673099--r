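# Molecular structure handling: construction, XYZ and QCSchema-style parsing,
# nuclear repulsion.

#' Construct a molecule
#'
#' Coordinates are stored in bohr. Validates atomic numbers, electron count
#' and the consistency of charge with spin multiplicity.
#'
#' @param symbols character vector of element symbols
#' @param coords numeric matrix (n_atoms x 3) of Cartesian positions in bohr
#' @param charge integer total charge (elementary charges)
#' @param multiplicity integer spin multiplicity 2S+1
#' @return an object of class `mdft_molecule` with fields `symbols`, `Z`,
#'   `coords` (bohr), `charge`, `multiplicity`
#' @export
molecule <- function(symbols, coords, charge = 0L, multiplicity = 1L) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0L) {
    coords <- matrix(numeric(0), 0L, 3L)
  } else {
    coords <- matrix(as.numeric(coords), ncol = 3L)
  }
  if (nrow(coords) != length(symbols))
    stop("coords must have one row per atom", call. = FALSE)
  if (length(symbols) && !all(is.finite(coords)))
    stop("non-finite coordinates", call. = FALSE)
  Z <- if (length(symbols)) element_number(symbols) else integer(0)
  nel <- sum(Z) - as.integer(charge)
  if (nel < 0)
    stop("negative electron count: sum(Z) - charge = ", nel, call. = FALSE)
  multiplicity <- as.integer(multiplicity)
  if (multiplicity < 1L)
    stop("multiplicity must be >= 1", call. = FALSE)
  if ((nel - (multiplicity - 1L)) %% 2L != 0L)
    stop("electron count ", nel, " inconsistent with multiplicity ",
         multiplicity, call. = FALSE)
  structure(
    list(symbols = symbols, Z = Z, coords = coords,
         charge = as.integer(charge), multiplicity = multiplicity),
    class = "mdft_molecule"
  )
}

#' Number of electrons in a molecule
#' @param mol an `mdft_molecule`
#' @return integer electron count
#' @export
n_electrons <- function(mol) sum(mol$Z) - mol$charge

#' @export
print.mdft_molecule <- function(x, ...) {
  cat("<mdft_molecule> ", length(x$symbols), " atoms, charge ", x$charge,
      ", multiplicity ", x$multiplicity, ", ", n_electrons(x), " electrons\n",
      sep = "")
  invisible(x)
}

#' Parse an XYZ-format structure
#'
#' Standard XYZ: first line is the atom count, second a comment, then one
#' `symbol x y z` line per atom with coordinates in Angstrom (converted to
#' bohr on input).
#'
#' @param text a single string or character vector of lines
#' @param charge,multiplicity values not representable in plain XYZ, supplied
#'   alongside (defaults 0 and 1)
#' @return an `mdft_molecule`
#' @export
parse_xyz <- function(text, charge = 0L, multiplicity = 1L) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 1L) stop("empty XYZ input", call. = FALSE)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 0L)
    stop("XYZ parse error at line 1: expected a nonnegative atom count",
         call. = FALSE)
  if (nat == 0L)
    return(molecule(character(0), matrix(numeric(0), 0, 3), charge, multiplicity))
  first <- 3L  # line 2 is the comment line
  if (length(lines) < first + nat - 1L)
    stop("XYZ parse error: expected ", nat, " coordinate lines, found ",
         max(0L, length(lines) - 2L), call. = FALSE)
  symbols <- character(nat)
  coords <- matrix(NA_real_, nat, 3L)
  for (i in seq_len(nat)) {
    ln <- first + i - 1L
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 4L)
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z'",
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(xyz))
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate",
           call. = FALSE)
    symbols[i] <- toks[1]
    coords[i, ] <- xyz
  }
  molecule(symbols, coords * BOHR_PER_ANGSTROM, charge, multiplicity)
}

#' Write a molecule as an XYZ string (Angstrom)
#' @param mol an `mdft_molecule`
#' @param comment comment line content
#' @return a single string in XYZ format
#' @export
write_xyz <- function(mol, comment = "") {
  ang <- mol$coords / BOHR_PER_ANGSTROM
  body <- vapply(seq_along(mol$symbols), function(i) {
    sprintf("%-3s %18.12f %18.12f %18.12f", mol$symbols[i],
            ang[i, 1], ang[i, 2], ang[i, 3])
  }, character(1))
  paste(c(length(mol$symbols), comment, body), collapse = "\n")
}

#' Parse a QCSchema-style molecule document
#'
#' Accepts a list (already-parsed JSON) or a JSON string with fields
#' `symbols`, `geometry` (flat, bohr), `molecular_charge`,
#' `molecular_multiplicity`.
#'
#' @param doc list or JSON string
#' @return an `mdft_molecule`
#' @export
parse_qcschema_molecule <- function(doc) {
  if (is.character(doc)) doc <- jsonlite::fromJSON(doc, simplifyVector = TRUE)
  if (is.null(doc$symbols)) stop("molecule document lacks 'symbols'", call. = FALSE)
  geom <- as.numeric(unlist(doc$geometry))
  nsym <- length(doc$symbols)
  if (length(geom) != 3L * nsym)
    stop("geometry length ", length(geom), " != 3 x ", nsym, " symbols",
         call. = FALSE)
  charge <- if (is.null(doc$molecular_charge)) 0L else as.integer(round(doc$molecular_charge))
  mult <- if (is.null(doc$molecular_multiplicity)) 1L else as.integer(doc$molecular_multiplicity)
  molecule(as.character(doc$symbols),
           matrix(geom, ncol = 3L, byrow = TRUE), charge, mult)
}

#' Serialize a molecule to the QCSchema-style canonical field set
#' @param mol an `mdft_molecule`
#' @return a list with `symbols`, `geometry` (flat, bohr), `molecular_charge`,
#'   `molecular_multiplicity`
#' @export
qcschema_molecule <- function(mol) {
  list(
    symbols = mol$symbols,
    geometry = as.numeric(t(mol$coords)),
    molecular_charge = mol$charge,
    molecular_multiplicity = mol$multiplicity
  )
}

#' Nuclear repulsion energy
#'
#' \eqn{\sum_{A<B} Z_A Z_B / R_{AB}} in hartree; invariant under rigid
#' rotation and translation.
#'
#' @param mol an `mdft_molecule`
#' @return energy in hartree
#' @export
nuclear_repulsion <- function(mol) {
  n <- length(mol$Z)
  if (n < 2L) return(0.0)
  e <- 0.0
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      r <- sqrt(sum((mol$coords[a, ] - mol$coords[b, ])^2))
      if (r < 1e-8)
        stop("coincident nuclei: atoms ", a, " and ", b, call. = FALSE)
      e <- e + mol$Z[a] * mol$Z[b] / r
    }
  }
  e
}
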