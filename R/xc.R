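# Exchange-correlation: functional specifications, in-house LDA (Slater
# exchange + VWN5 correlation) and PBE GGA forms, sparse AO collocation, and
# assembly of Exc / Vxc from per-point ingredients.

#' Exchange-correlation functional specification
#'
#' Built-in: `"hf"` (no functional, full exact exchange), `"slater"`
#' (exchange-only LDA), `"lda"`/`"svwn5"` (Slater + VWN5), `"pbe"`,
#' `"pbe0"` (PBE hybrid, 25% exact exchange). Meta-GGAs such as M06-2X need
#' an external functional backend and raise a capability error.
#'
#' @param name functional name (case insensitive)
#' @return `mdft_functional`: `name`, `family`, `cx` (exact-exchange
#'   fraction), `needs_grad`, `needs_xc`
#' @export
functional_spec <- function(name) {
  key <- tolower(name)
  spec <- switch(key,
    "hf" = list(family = "hf", cx = 1, needs_grad = FALSE, needs_xc = FALSE),
    "slater" = list(family = "lda", cx = 0, needs_grad = FALSE, needs_xc = TRUE),
    "lda" = ,
    "svwn5" = list(family = "lda", cx = 0, needs_grad = FALSE, needs_xc = TRUE),
    "pbe" = list(family = "gga", cx = 0, needs_grad = TRUE, needs_xc = TRUE),
    "pbe0" = list(family = "hybrid-gga", cx = 0.25, needs_grad = TRUE,
                  needs_xc = TRUE),
    "m06-2x" = ,
    "m06" = ,
    "tpss" = stop("functional '", name, "' is a meta-GGA; it requires the ",
                  "external functional backend, which is not available",
                  call. = FALSE),
    stop("unknown functional '", name, "'; built-in: hf, slater, lda/svwn5, ",
         "pbe, pbe0", call. = FALSE)
  )
  structure(c(list(name = key), spec), class = "mdft_functional")
}

#' Sparse AO collocation on a molecular grid
#'
#' Evaluates every spherical AO (and Cartesian gradients when requested) at
#' the grid points as 32x32 block-sparse matrices. Shells are skipped
#' entirely for points beyond their [ao_cutoff_radius()]; blocks whose
#' entries all fall below `eps` are dropped.
#'
#' @param grid an `mdft_grid`
#' @param basis an `mdft_basis`
#' @param threshold AO magnitude threshold for the distance cutoff
#'   (default 1e-12; 0 disables distance screening)
#' @param eps zero-block threshold (default 1e-12; 0 stores all blocks)
#' @param deriv logical: also return d/dx, d/dy, d/dz AO matrices
#' @return list of `mdft_bsm`: `ao` and, if `deriv`, `dx`, `dy`, `dz`
#' @export
eval_ao_block_sparse <- function(grid, basis, threshold = 1e-12, eps = 1e-12,
                                 deriv = FALSE) {
  cutoffs <- if (threshold > 0) {
    vapply(basis$shells, ao_cutoff_radius, numeric(1), threshold = threshold)
  } else {
    rep(Inf, length(basis$shells))
  }
  env <- shell_env(basis)
  res <- cpp_eval_ao(env, grid$points, deriv, cutoffs)
  out <- list(ao = block_sparse(res$ao, eps))
  if (deriv) {
    out$dx <- block_sparse(res$dx, eps)
    out$dy <- block_sparse(res$dy, eps)
    out$dz <- block_sparse(res$dz, eps)
  }
  out
}

#' Electron density (and gradient) on the grid
#'
#' \eqn{\rho_g = \sum_{\mu\nu} \phi_\mu(r_g) P_{\mu\nu} \phi_\nu(r_g)} via
#' block-sparse products; with gradients,
#' \eqn{\nabla\rho = 2 \sum \nabla\phi_\mu P_{\mu\nu} \phi_\nu}.
#'
#' @param P symmetric density matrix
#' @param ao collocation list from [eval_ao_block_sparse()]
#' @return list: `rho`, and when gradients are present `gx`, `gy`, `gz`,
#'   `sigma` (= |grad rho|^2)
#' @export
density_on_grid <- function(P, ao) {
  X <- block_sparse_gemm(ao$ao, P)
  rho <- bs_hadamard_rowsum(ao$ao, X)
  out <- list(rho = rho)
  if (!is.null(ao$dx)) {
    out$gx <- 2 * bs_hadamard_rowsum(ao$dx, X)
    out$gy <- 2 * bs_hadamard_rowsum(ao$dy, X)
    out$gz <- 2 * bs_hadamard_rowsum(ao$dz, X)
    out$sigma <- out$gx^2 + out$gy^2 + out$gz^2
  }
  out
}

# ---- functional forms (closed shell, total density) ------------------------

RHO_FLOOR <- 1e-12

# Slater exchange: e = -(3/4)(3/pi)^{1/3} rho^{4/3}; v = de/drho
xc_slater <- function(rho) {
  cx <- (3 / 4) * (3 / pi)^(1 / 3)
  list(e = -cx * rho^(4 / 3), vrho = -(4 / 3) * cx * rho^(1 / 3))
}

# VWN5 correlation (unpolarized), epsilon_c per electron
xc_vwn5 <- function(rho) {
  A <- 0.0310907; x0 <- -0.10498; b <- 3.72744; c0 <- 12.9352
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- x^2 + b * x + c0
  X0 <- x0^2 + b * x0 + c0
  Q <- sqrt(4 * c0 - b^2)
  Xp <- 2 * x + b
  atq <- atan(Q / Xp)
  eps <- A * (log(x^2 / X) + 2 * b / Q * atq -
                b * x0 / X0 * (log((x - x0)^2 / X) + 2 * (b + 2 * x0) / Q * atq))
  deps_dx <- A * (2 / x - Xp / X - 4 * b / (Q^2 + Xp^2) -
                    b * x0 / X0 * (2 / (x - x0) - Xp / X -
                                     4 * (b + 2 * x0) / (Q^2 + Xp^2)))
  # v = eps - (rs/3) deps/drs = eps - (x/6) deps/dx
  list(e = rho * eps, vrho = eps - (x / 6) * deps_dx)
}

# PW92 unpolarized correlation, eps and deps/drs
pw92_eps <- function(rs) {
  A <- 0.031091; a1 <- 0.21370
  b1 <- 7.5957; b2 <- 3.5876; b3 <- 1.6382; b4 <- 0.49294
  x <- sqrt(rs)
  Q1 <- 2 * A * (b1 * x + b2 * x^2 + b3 * x^3 + b4 * x^4)
  Q0 <- -2 * A * (1 + a1 * rs)
  lg <- log(1 + 1 / Q1)
  eps <- Q0 * lg
  dQ1 <- 2 * A * (b1 / (2 * x) + b2 + 1.5 * b3 * x + 2 * b4 * x^2)
  deps <- -2 * A * a1 * lg - Q0 * dQ1 / (Q1^2 + Q1)
  list(eps = eps, deps = deps)
}

# PBE exchange: e, vrho, vsigma
xc_pbe_x <- function(rho, sigma) {
  kappa <- 0.804; mu <- 0.2195149727645171
  c0 <- -(3 / 4) * (3 / pi)^(1 / 3)
  a <- 1 / (4 * (3 * pi^2)^(2 / 3))
  s2 <- a * sigma * rho^(-8 / 3)
  u <- mu * s2 / kappa
  FF <- 1 + kappa - kappa / (1 + u)
  dF_ds2 <- mu / (1 + u)^2
  e <- c0 * rho^(4 / 3) * FF
  vrho <- (4 / 3) * c0 * rho^(1 / 3) * FF +
    c0 * rho^(4 / 3) * dF_ds2 * (-8 / 3) * a * sigma * rho^(-11 / 3)
  vsigma <- c0 * rho^(4 / 3) * dF_ds2 * a * rho^(-8 / 3)
  list(e = e, vrho = vrho, vsigma = vsigma)
}

# PBE correlation: e, vrho, vsigma
xc_pbe_c <- function(rho, sigma) {
  gam <- (1 - log(2)) / pi^2
  beta <- 0.06672455060314922
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  pw <- pw92_eps(rs)
  eps <- pw$eps
  kf <- (3 * pi^2 * rho)^(1 / 3)
  ks2 <- 4 * kf / pi
  # y = t^2 = sigma / (4 ks^2 rho^2)
  y <- sigma / (4 * ks2 * rho^2)
  E <- exp(-eps / gam)
  A <- (beta / gam) / (E - 1)
  Nu <- y * (1 + A * y)
  D <- 1 + A * y + (A * y)^2
  g <- Nu / D
  H <- gam * log(1 + (beta / gam) * g)
  pre <- beta / (1 + (beta / gam) * g)
  g_y <- ((1 + 2 * A * y) * D - Nu * (A + 2 * A^2 * y)) / D^2
  g_A <- (y^2 * D - Nu * (y + 2 * A * y^2)) / D^2
  dA_deps <- (beta / gam^2) * E / (E - 1)^2
  drs_drho <- -rs / (3 * rho)
  dy_drho <- -(7 / 3) * y / rho
  dy_dsigma <- ifelse(sigma > 0, y / sigma,
                      1 / (4 * ks2 * rho^2))
  deps_drho <- pw$deps * drs_drho
  dH_drho <- pre * (g_y * dy_drho + g_A * dA_deps * deps_drho)
  dH_dsigma <- pre * g_y * dy_dsigma
  e <- rho * (eps + H)
  vrho <- eps + H + rho * (deps_drho + dH_drho)
  vsigma <- rho * dH_dsigma
  list(e = e, vrho = vrho, vsigma = vsigma)
}

#' Per-point exchange-correlation energy density and potential ingredients
#'
#' Tiny negative densities from quadrature round-off are clamped to zero
#' before evaluation. Energy density `e` is per unit volume, so
#' \eqn{E_{xc} = \sum_g w_g e_g}; `vrho` = de/drho and, for GGA,
#' `vsigma` = de/dsigma with \eqn{\sigma = |\nabla\rho|^2}.
#'
#' @param rho per-point density (clamped at 0)
#' @param sigma per-point squared density gradient (GGA only)
#' @param functional an [functional_spec()]
#' @return list `e`, `vrho`, `vsigma` (NULL for LDA)
#' @export
xc_energy_potential <- function(rho, sigma = NULL, functional) {
  rho <- pmax(rho, 0)
  live <- rho > RHO_FLOOR
  n <- length(rho)
  e <- numeric(n); vrho <- numeric(n)
  vsigma <- if (functional$needs_grad) numeric(n) else NULL
  if (!any(live)) return(list(e = e, vrho = vrho, vsigma = vsigma))
  r <- rho[live]
  if (functional$family == "lda") {
    sx <- xc_slater(r)
    e[live] <- sx$e; vrho[live] <- sx$vrho
    if (functional$name != "slater") {
      cv <- xc_vwn5(r)
      e[live] <- e[live] + cv$e
      vrho[live] <- vrho[live] + cv$vrho
    }
  } else if (functional$family %in% c("gga", "hybrid-gga")) {
    s <- pmax(if (is.null(sigma)) numeric(length(r)) else sigma[live], 0)
    px <- xc_pbe_x(r, s); pc <- xc_pbe_c(r, s)
    e[live] <- px$e + pc$e
    vrho[live] <- px$vrho + pc$vrho
    vsigma[live] <- px$vsigma + pc$vsigma
  } else {
    stop("functional family '", functional$family,
         "' has no quadrature form", call. = FALSE)
  }
  list(e = e, vrho = vrho, vsigma = vsigma)
}

#' Assemble the exchange-correlation energy and potential matrix
#'
#' \eqn{V^{xc}_{\mu\nu} = \sum_g w_g [v_\rho \phi_\mu\phi_\nu +
#' 2 v_\sigma \nabla\rho \cdot \nabla(\phi_\mu\phi_\nu)]} via block-sparse
#' tiles; \eqn{E_{xc} = \sum_g w_g e_g}. For hybrids the exact-exchange part
#' is not included here (it enters the Fock matrix through K with fraction
#' c_x).
#'
#' @param grid an `mdft_grid`
#' @param ao collocation list from [eval_ao_block_sparse()]
#' @param pot list from [xc_energy_potential()]
#' @param dens list from [density_on_grid()] (needed for GGA gradient terms)
#' @return `mdft_xc` list: `Exc` (hartree), `Vxc` (n x n symmetric)
#' @export
assemble_vxc <- function(grid, ao, pot, dens = NULL) {
  w <- grid$weights
  Exc <- sum(w * pot$e)
  V <- bs_crossprod_weighted(ao$ao, w * pot$vrho, ao$ao)
  if (!is.null(pot$vsigma) && !is.null(ao$dx)) {
    if (is.null(dens))
      stop("GGA Vxc assembly needs the density gradient", call. = FALSE)
    for (d in c("x", "y", "z")) {
      wd <- 2 * w * pot$vsigma * dens[[paste0("g", d)]]
      Gd <- ao[[paste0("d", d)]]
      Vd <- bs_crossprod_weighted(Gd, wd, ao$ao)
      V <- V + Vd + t(Vd)
    }
  }
  V <- (V + t(V)) / 2
  structure(list(Exc = Exc, Vxc = V), class = "mdft_xc")
}
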