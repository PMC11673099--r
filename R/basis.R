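# Basis-set handling: bundled per-element shell definitions, shell/AOBasis
# construction, normalization, and the flat "shell environment" handed to the
# C++ integral kernels.
#
# Bundled sets: sto-3g (genuine, generated from the published three-Gaussian
# Slater fits with standard zeta values) and def2-svp / def2-tzvpp stand-ins
# with the authentic def2 shell compositions but synthetic even-tempered
# exponents (files are labelled *-synthetic; see the basis JSON headers).
# Spherical AO counts per element therefore match the genuine def2 sets
# exactly (e.g. def2-tzvpp: H 3s2p1d = 14 AOs, O 5s3p2d1f = 31 AOs).

BASIS_FILES <- c(
  "sto-3g" = "sto-3g.json",
  "def2-svp" = "def2-svp-synthetic.json",
  "def2-tzvpp" = "def2-tzvpp-synthetic.json"
)

#' Load a bundled basis-set definition
#' @param name basis name ("sto-3g", "def2-svp", "def2-tzvpp")
#' @return list: per-element lists of shells (`l`, `exponents`, `coefficients`)
#' @export
load_basis_set <- function(name) {
  key <- tolower(name)
  if (!key %in% names(BASIS_FILES))
    stop("unknown basis '", name, "'; bundled sets: ",
         paste(names(BASIS_FILES), collapse = ", "), call. = FALSE)
  cached <- .microdft_cache[[paste0("basis:", key)]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "basis", BASIS_FILES[[key]], package = "microdft")
  if (!nzchar(path)) stop("bundled basis file missing for ", name, call. = FALSE)
  def <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .microdft_cache[[paste0("basis:", key)]] <- def
  def
}

#' Construct a contracted Gaussian shell
#'
#' Primitives are normalized individually, then the contracted shell is
#' renormalized so that the self-overlap of each spherical AO is exactly 1.
#'
#' @param center_index 1-based atom index the shell sits on
#' @param l angular momentum (0..4)
#' @param exponents primitive exponents (bohr^-2), all > 0
#' @param coefficients contraction coefficients w.r.t. normalized primitives
#' @return an object of class `mdft_shell`; field `norm_coefs` carries the
#'   final coefficients (primitive norms and contracted renormalization
#'   folded in) used by the integral kernels
#' @export
gaussian_shell <- function(center_index, l, exponents, coefficients) {
  exponents <- as.numeric(exponents)
  coefficients <- as.numeric(coefficients)
  if (length(exponents) != length(coefficients))
    stop("exponent/coefficient length mismatch", call. = FALSE)
  if (any(exponents <= 0)) stop("primitive exponents must be > 0", call. = FALSE)
  l <- as.integer(l)
  if (l < 0L || l > 4L)
    stop("angular momentum ", l, " unsupported (s..g)", call. = FALSE)
  # norm of a solid-harmonic primitive: N^2 = 2 (2a)^{l+3/2} / Gamma(l+3/2)
  prim_norm <- sqrt(2 * (2 * exponents)^(l + 1.5) / gamma(l + 1.5))
  # overlap of normalized primitives (same center, same l, any m)
  ae <- outer(exponents, exponents, function(a, b) (2 * sqrt(a * b) / (a + b))^(l + 1.5))
  self <- as.numeric(t(coefficients) %*% ae %*% coefficients)
  if (self <= 0) stop("degenerate contraction (nonpositive self-overlap)", call. = FALSE)
  renorm <- 1 / sqrt(self)
  structure(
    list(center_index = as.integer(center_index), l = l,
         exponents = exponents, coefficients = coefficients,
         norm_coefs = renorm * coefficients * prim_norm),
    class = "mdft_shell"
  )
}

#' Assign a basis set to a molecule
#'
#' Shells are ordered by atom index, then as listed in the element's basis
#' definition; each shell contributes 2l+1 pure spherical AOs ordered
#' m = -l..+l.
#'
#' @param mol an `mdft_molecule`
#' @param basis a basis name (see [load_basis_set()]) or an already-loaded
#'   definition list
#' @return an object of class `mdft_basis`: `shells`, `ao_offset` (1-based
#'   first AO per shell), `n_ao`, `molecule`, `name`
#' @export
assign_basis <- function(mol, basis) {
  name <- if (is.character(basis)) basis else attr(basis, "name", exact = TRUE)
  def <- if (is.character(basis)) load_basis_set(basis) else basis
  eldefs <- def$elements
  shells <- list()
  for (a in seq_along(mol$symbols)) {
    sym <- mol$symbols[a]
    ed <- eldefs[[sym]]
    if (is.null(ed))
      stop("element ", sym, " not present in basis '",
           if (is.null(name)) "<custom>" else name, "'", call. = FALSE)
    for (sh in ed) {
      shells[[length(shells) + 1L]] <- gaussian_shell(
        a, sh$l, unlist(sh$exponents), unlist(sh$coefficients))
    }
  }
  nsph <- vapply(shells, function(s) 2L * s$l + 1L, integer(1))
  ao_offset <- if (length(shells)) cumsum(c(1L, head(nsph, -1L))) else integer(0)
  structure(
    list(shells = shells, ao_offset = ao_offset,
         n_ao = sum(nsph), molecule = mol,
         name = if (is.null(name)) "<custom>" else name,
         definition = def),
    class = "mdft_basis"
  )
}

#' @export
print.mdft_basis <- function(x, ...) {
  cat("<mdft_basis> ", x$name, ": ", length(x$shells), " shells, ",
      x$n_ao, " spherical AOs\n", sep = "")
  invisible(x)
}

#' Number of spherical AOs in a basis
#' @param basis an `mdft_basis`
#' @return integer AO count
#' @export
n_basis_functions <- function(basis) basis$n_ao

# Flat representation consumed by the C++ kernels (0-based offsets).
shell_env <- function(basis) {
  sh <- basis$shells
  mol <- basis$molecule
  nprim <- vapply(sh, function(s) length(s$exponents), integer(1))
  lmax <- if (length(sh)) max(vapply(sh, `[[`, integer(1), "l")) else 0L
  list(
    l = vapply(sh, `[[`, integer(1), "l"),
    cx = vapply(sh, function(s) mol$coords[s$center_index, 1], numeric(1)),
    cy = vapply(sh, function(s) mol$coords[s$center_index, 2], numeric(1)),
    cz = vapply(sh, function(s) mol$coords[s$center_index, 3], numeric(1)),
    pstart = as.integer(cumsum(c(0L, head(nprim, -1L)))),
    pcount = nprim,
    exps = unlist(lapply(sh, `[[`, "exponents")),
    coefs = unlist(lapply(sh, `[[`, "norm_coefs")),
    ao_off = as.integer(basis$ao_offset - 1L),
    nao = as.integer(basis$n_ao),
    trans = lapply(0:max(lmax, 0L), spherical_transform)
  )
}
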