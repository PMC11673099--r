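# Electron repulsion integrals: Cauchy-Schwarz shell-pair bounds, the
# three-rule mixed-precision dispatcher, angular-momentum batching, J/K
# assembly, and a dense unscreened all-double oracle.

#' ERI evaluation settings
#'
#' @param tolerance Schwarz screening tolerance; a shell quartet whose bound
#'   is below it is skipped entirely (default 1e-12)
#' @param single_double_factor boundary factor between the single- and
#'   double-precision paths: quartets with bound in
#'   `[tolerance, tolerance * factor)` run in single precision (default 1e5)
#' @param mixed_precision logical; disable to evaluate every surviving
#'   quartet in double precision
#' @return an `mdft_eri_settings` list
#' @export
eri_settings <- function(tolerance = 1e-12, single_double_factor = 1e5,
                         mixed_precision = TRUE) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (single_double_factor <= 1) stop("factor must be > 1", call. = FALSE)
  structure(list(tolerance = tolerance,
                 single_double_factor = single_double_factor,
                 mixed_precision = isTRUE(mixed_precision)),
            class = "mdft_eri_settings")
}

#' Cauchy-Schwarz shell-pair bounds
#'
#' For every unordered shell pair (a, b), computes
#' \eqn{Q_{ab} = \sqrt{\max_{\mu\nu} (\mu\nu|\mu\nu)}} over the AOs of the
#' pair, evaluated in double precision. The quartet bound
#' \eqn{Q_{ab} Q_{cd}} then dominates every element of the quartet block.
#'
#' @param basis an `mdft_basis`
#' @return list: `Q` (nshell x nshell symmetric matrix of bounds) and
#'   `pairs`, a data.frame with one row per unordered pair (a, b, bound)
#' @export
schwarz_bounds <- function(basis) {
  env <- shell_env(basis)
  Q <- cpp_schwarz(env)
  ns <- length(basis$shells)
  idx <- which(upper.tri(Q, diag = TRUE), arr.ind = TRUE)
  pairs <- data.frame(a = idx[, 1], b = idx[, 2], bound = Q[idx])
  list(Q = Q, pairs = pairs)
}

#' Classify one quartet bound under the three-rule dispatcher
#'
#' skip if bound < tolerance; single precision if
#' tolerance <= bound < tolerance * factor; double precision otherwise.
#' With mixed precision disabled, every surviving quartet is double.
#'
#' @param bound nonnegative Schwarz bound(s) Q_ab * Q_cd (vectorized)
#' @param settings an [eri_settings()] object
#' @return character vector in {"skip", "single", "double"}
#' @export
classify_quartet <- function(bound, settings = eri_settings()) {
  if (any(bound < 0)) stop("bounds must be nonnegative", call. = FALSE)
  tol <- settings$tolerance
  hi <- tol * settings$single_double_factor
  out <- rep("double", length(bound))
  if (settings$mixed_precision) out[bound < hi] <- "single"
  out[bound < tol] <- "skip"
  out
}

# canonical shell quartets (8-fold-symmetry unique) as a data.frame
canonical_quartets <- function(nshell) {
  out <- vector("list", 64L)
  k <- 0L
  for (a in seq_len(nshell)) for (b in seq_len(a)) for (cc in seq_len(a)) {
    dmax <- if (cc == a) b else cc
    k <- k + 1L
    d <- seq_len(dmax)
    out[[k]] <- cbind(a, b, cc, d)
  }
  m <- do.call(rbind, out[seq_len(k)])
  colnames(m) <- c("a", "b", "c", "d")
  m
}

#' Batch surviving quartets by angular class, contraction signature and
#' precision
#'
#' Canonical (8-fold-unique) shell quartets that survive screening are
#' partitioned into batches sharing the angular-momentum class
#' (la, lb, lc, ld), the contraction signature (primitive counts), and the
#' precision class assigned by the dispatcher, mirroring the
#' angular-momentum reordering of a batched ERI scheduler.
#'
#' @param basis an `mdft_basis`
#' @param settings an [eri_settings()]
#' @param bounds optional precomputed [schwarz_bounds()] result
#' @return list with `batches` (each: `l_class`, `signature`, `precision`,
#'   integer matrix `quartets`) and `n_skipped`
#' @export
batch_by_class <- function(basis, settings = eri_settings(), bounds = NULL) {
  if (is.null(bounds)) bounds <- schwarz_bounds(basis)
  Q <- bounds$Q
  quart <- canonical_quartets(length(basis$shells))
  b <- Q[quart[, c("a", "b")]] * Q[quart[, c("c", "d")]]
  cls <- classify_quartet(b, settings)
  keep <- cls != "skip"
  ls <- vapply(basis$shells, `[[`, integer(1), "l")
  np <- vapply(basis$shells, function(s) length(s$exponents), integer(1))
  lab <- function(m) paste(ls[m[, 1]], ls[m[, 2]], ls[m[, 3]], ls[m[, 4]], sep = ",")
  sig <- function(m) paste(np[m[, 1]], np[m[, 2]], np[m[, 3]], np[m[, 4]], sep = ",")
  key <- paste(lab(quart), sig(quart), cls, sep = "|")[keep]
  kq <- quart[keep, , drop = FALSE]
  groups <- split(seq_len(nrow(kq)), key)
  batches <- lapply(names(groups), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    list(l_class = as.integer(strsplit(parts[1], ",")[[1]]),
         signature = as.integer(strsplit(parts[2], ",")[[1]]),
         precision = parts[3],
         quartets = kq[groups[[k]], , drop = FALSE])
  })
  list(batches = batches, n_skipped = sum(!keep),
       n_quartets = nrow(quart))
}

#' Evaluate one shell-quartet ERI block
#'
#' @param basis an `mdft_basis`
#' @param a,b,c,d 1-based shell indices
#' @param precision "double" or "single"; the single path runs the full
#'   recursion in 32-bit floats
#' @return numeric array of dim (2la+1, 2lb+1, 2lc+1, 2ld+1)
#' @export
eri_quartet <- function(basis, a, b, c, d, precision = "double") {
  precision <- match.arg(precision, c("double", "single"))
  ns <- length(basis$shells)
  idx <- c(a, b, c, d)
  if (any(idx < 1L | idx > ns))
    stop("shell index out of range 1..", ns, call. = FALSE)
  env <- shell_env(basis)
  v <- cpp_eri_quartet(env, a - 1L, b - 1L, c - 1L, d - 1L,
                       precision == "single")
  aperm(v, 4:1)
}

#' Coulomb and exchange matrices from a density matrix
#'
#' \eqn{J_{\mu\nu} = \sum P_{\lambda\sigma} (\mu\nu|\lambda\sigma)},
#' \eqn{K_{\mu\nu} = \sum P_{\lambda\sigma} (\mu\lambda|\nu\sigma)},
#' assembled from canonical shell quartets with 8-fold permutational
#' symmetry. Quartets are screened and dispatched to the single- or
#' double-precision kernel by [classify_quartet()]; single-precision blocks
#' are accumulated into double-precision results.
#'
#' @param P symmetric density matrix (n_ao x n_ao)
#' @param basis an `mdft_basis`
#' @param settings an [eri_settings()]
#' @param bounds optional precomputed [schwarz_bounds()]
#' @return `mdft_jk` list: `J`, `K`, and `stats` (per-angular-class counts of
#'   skipped / single / double quartets)
#' @export
build_JK <- function(P, basis, settings = eri_settings(), bounds = NULL) {
  n <- basis$n_ao
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n)
    stop("density matrix must be ", n, " x ", n, call. = FALSE)
  if (is.null(bounds)) bounds <- schwarz_bounds(basis)
  env <- shell_env(basis)
  res <- cpp_build_jk(env, P, bounds$Q, settings$tolerance,
                      settings$single_double_factor, settings$mixed_precision)
  cnt <- res$class_counts
  nz <- which(rowSums(cnt) > 0)
  lm1 <- 5L
  dec <- function(i0) {
    i <- i0 - 1L
    c(i %/% (lm1^3), (i %/% (lm1^2)) %% lm1, (i %/% lm1) %% lm1, i %% lm1)
  }
  stats <- do.call(rbind, lapply(nz, function(i) {
    l4 <- dec(i)
    data.frame(la = l4[1], lb = l4[2], lc = l4[3], ld = l4[4],
               skipped = cnt[i, 1], single = cnt[i, 2], double = cnt[i, 3])
  }))
  structure(list(J = res$J, K = res$K, stats = stats), class = "mdft_jk")
}

#' Screening and precision-dispatch report
#'
#' Per angular class, the counts of skipped, single- and double-precision
#' canonical shell quartets for a molecule/basis at a given tolerance.
#'
#' @param basis an `mdft_basis`
#' @param settings an [eri_settings()]
#' @return data.frame with columns `class` ("(ss|pp)"-style label),
#'   `skipped`, `single`, `double`
#' @export
screening_report <- function(basis, settings = eri_settings()) {
  P <- matrix(0, basis$n_ao, basis$n_ao)
  jk <- build_JK(P, basis, settings)
  st <- jk$stats
  lt <- c("s", "p", "d", "f", "g")
  st$class <- sprintf("(%s%s|%s%s)", lt[st$la + 1], lt[st$lb + 1],
                      lt[st$lc + 1], lt[st$ld + 1])
  st[, c("class", "skipped", "single", "double")]
}

#' Dense unscreened ERI tensor (test oracle)
#'
#' Full (n, n, n, n) tensor in double precision with no screening and no
#' mixed-precision dispatch; quadratic in memory, so refused above `cap` AOs.
#'
#' @param basis an `mdft_basis`
#' @param cap maximum AO count (default 150)
#' @return 4-index numeric array, `(mu,nu,lambda,sigma)`
#' @export
eri_dense_oracle <- function(basis, cap = 150L) {
  if (basis$n_ao > cap)
    stop("eri_dense_oracle refused: ", basis$n_ao, " AOs exceeds cap ", cap,
         call. = FALSE)
  env <- shell_env(basis)
  cpp_eri_dense(env)
}
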