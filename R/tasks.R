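# The five-task front end: spe, spf, fh, go, bomd, over QCSchema-style task
# documents, plus generic finite-difference / integrator kernels that also
# accept model potentials (used both by the tasks and, with quadratic
# surrogates, by the test suite).

TASKS <- c("spe", "spf", "fh", "go", "bomd")
ALLOWED_KEYWORDS <- c("grid_level", "scf_conv", "eri_tol", "mixed_precision",
                      "max_iter", "guess", "fd_step", "dt_fs", "n_steps",
                      "temperature", "seed", "opt_max_steps", "opt_fmax",
                      "opt_econv")
KB_HARTREE <- 3.166811563e-6  # Boltzmann constant, hartree / K

#' Construct and validate a task document
#'
#' @param task one of "spe", "spf", "fh", "go", "bomd"
#' @param molecule an `mdft_molecule` or QCSchema-style molecule list
#' @param method functional name (see [functional_spec()])
#' @param basis basis-set name
#' @param keywords named list of overrides; unknown keywords are rejected,
#'   not ignored (allowed: grid_level, scf_conv, eri_tol, mixed_precision,
#'   max_iter, guess, fd_step, dt_fs, n_steps, temperature, seed,
#'   opt_max_steps, opt_fmax, opt_econv)
#' @return an `mdft_task_document`
#' @export
task_document <- function(task, molecule, method, basis, keywords = list()) {
  if (length(task) != 1L || !task %in% TASKS)
    stop("unknown task '", paste(task, collapse = ","),
         "'; allowed tasks: ", paste(TASKS, collapse = ", "), call. = FALSE)
  if (!inherits(molecule, "mdft_molecule"))
    molecule <- parse_qcschema_molecule(molecule)
  bad <- setdiff(names(keywords), ALLOWED_KEYWORDS)
  if (length(bad))
    stop("unknown keyword(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(ALLOWED_KEYWORDS, collapse = ", "),
         call. = FALSE)
  structure(list(schema_name = "mdft_task", schema_version = 1L,
                 task = task, molecule = molecule,
                 model = list(method = method, basis = basis),
                 keywords = keywords),
            class = "mdft_task_document")
}

#' Parse a task document from JSON
#' @param json JSON string or file path
#' @return an `mdft_task_document`
#' @export
parse_task_document <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  kw <- if (is.null(doc$keywords)) list() else as.list(doc$keywords)
  task_document(doc$task %||% doc$driver, doc$molecule,
                doc$model$method, doc$model$basis, kw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# settings assembled from keyword overrides
task_settings <- function(kw) {
  scf_settings(
    conv_energy = kw$scf_conv %||% 1e-8,
    eri_tolerance = kw$eri_tol %||% 1e-12,
    mixed_precision = kw$mixed_precision %||% TRUE,
    max_iter = kw$max_iter %||% 100L,
    guess = kw$guess %||% "sad",
    grid_level = kw$grid_level %||% 3L
  )
}

# ---- generic kernels (work with any energy/force closure) ------------------

#' Central-difference forces from an energy function
#'
#' Six displacements per atom with step `h`; forces are the negative
#' gradient, in hartree/bohr.
#'
#' @param energy_fn function(coords matrix) -> energy (hartree)
#' @param coords n_atoms x 3 matrix (bohr)
#' @param h displacement step in bohr (default 1e-3)
#' @return n_atoms x 3 force matrix
#' @export
fd_forces <- function(energy_fn, coords, h = 1e-3) {
  g <- matrix(0, nrow(coords), 3)
  for (a in seq_len(nrow(coords))) for (d in 1:3) {
    cp <- coords; cp[a, d] <- cp[a, d] + h
    cm <- coords; cm[a, d] <- cm[a, d] - h
    g[a, d] <- (energy_fn(cp) - energy_fn(cm)) / (2 * h)
  }
  -g
}

#' Central-difference Hessian from a force function
#'
#' Seminumerical Hessian: central differences of forces, symmetrized as
#' (H + t(H)) / 2.
#'
#' @param force_fn function(coords) -> n_atoms x 3 force matrix
#' @param coords n_atoms x 3 matrix (bohr)
#' @param h displacement step in bohr (default 1e-3)
#' @return 3n x 3n symmetric Hessian (hartree/bohr^2), ordered
#'   (atom1 x, y, z, atom2 x, ...); attribute `asymmetry` carries the
#'   pre-symmetrization residual
#' @export
fd_hessian <- function(force_fn, coords, h = 1e-3) {
  n3 <- 3L * nrow(coords)
  H <- matrix(0, n3, n3)
  k <- 0L
  for (a in seq_len(nrow(coords))) for (d in 1:3) {
    k <- k + 1L
    cp <- coords; cp[a, d] <- cp[a, d] + h
    cm <- coords; cm[a, d] <- cm[a, d] - h
    # H column = d(gradient)/dx = -d(forces)/dx
    H[, k] <- -as.numeric(t(force_fn(cp) - force_fn(cm))) / (2 * h)
  }
  asym <- max(abs(H - t(H)))
  Hs <- (H + t(H)) / 2
  attr(Hs, "asymmetry") <- asym
  Hs
}

#' Velocity-Verlet trajectory
#'
#' @param force_fn function(coords) -> force matrix (hartree/bohr)
#' @param coords starting n_atoms x 3 coordinates (bohr)
#' @param velocities starting velocities (bohr per atomic time unit)
#' @param masses per-atom masses (electron masses)
#' @param dt time step (atomic units)
#' @param n_steps number of steps
#' @param energy_fn optional function(coords) -> potential energy, recorded
#'   per step when given
#' @return data.frame trace (step, time, e_pot, e_kin, e_tot) with the final
#'   state in attributes `coords` and `velocities`, and the full positions
#'   in attribute `positions` (list of matrices)
#' @export
velocity_verlet <- function(force_fn, coords, velocities, masses, dt, n_steps,
                            energy_fn = NULL) {
  stopifnot(dt > 0)
  m <- matrix(rep(masses, 3), ncol = 3)
  f <- force_fn(coords)
  rec <- vector("list", n_steps + 1L)
  pos <- vector("list", n_steps + 1L)
  snap <- function(step, coords, velocities) {
    ek <- 0.5 * sum(m * velocities^2)
    ep <- if (is.null(energy_fn)) NA_real_ else energy_fn(coords)
    data.frame(step = step, time = step * dt, e_pot = ep, e_kin = ek,
               e_tot = ep + ek)
  }
  rec[[1]] <- snap(0L, coords, velocities)
  pos[[1]] <- coords
  for (s in seq_len(n_steps)) {
    a <- f / m
    coords <- coords + velocities * dt + 0.5 * a * dt^2
    f_new <- force_fn(coords)
    velocities <- velocities + 0.5 * (a + f_new / m) * dt
    f <- f_new
    rec[[s + 1L]] <- snap(s, coords, velocities)
    pos[[s + 1L]] <- coords
  }
  out <- do.call(rbind, rec)
  attr(out, "coords") <- coords
  attr(out, "velocities") <- velocities
  attr(out, "positions") <- pos
  out
}

#' Cartesian BFGS geometry minimizer
#'
#' Quasi-Newton descent with an inverse-Hessian BFGS update, step-length cap
#' and backtracking; converged when max |force| <= `fmax` and the energy
#' change of the last accepted step <= `econv`. Checks convergence before
#' stepping, so a start at a stationary point takes zero steps.
#'
#' @param energy_fn function(coords) -> energy
#' @param force_fn function(coords) -> force matrix
#' @param coords starting coordinates (n_atoms x 3, bohr)
#' @param fmax force convergence threshold (default 4.5e-4 hartree/bohr)
#' @param econv energy-change threshold (default 1e-6 hartree)
#' @param max_steps step cap (default 100)
#' @param max_disp per-step displacement cap in bohr (default 0.3)
#' @return list: `coords`, `energy`, `converged`, `n_steps`, `trajectory`
#'   (data.frame step/energy/fmax)
#' @export
bfgs_optimize <- function(energy_fn, force_fn, coords, fmax = 4.5e-4,
                          econv = 1e-6, max_steps = 100L, max_disp = 0.3) {
  x <- as.numeric(t(coords))
  n <- length(x)
  shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  E <- energy_fn(shape(x))
  f <- as.numeric(t(force_fn(shape(x))))
  g <- -f
  traj <- data.frame(step = 0L, energy = E, fmax = max(abs(f)))
  Hinv <- diag(n)
  steps <- 0L
  converged <- max(abs(f)) <= fmax
  while (!converged && steps < max_steps) {
    p <- -as.numeric(Hinv %*% g)
    sl <- sqrt(sum(p^2))
    if (sl > max_disp) p <- p * (max_disp / sl)
    alpha <- 1.0
    repeat {
      xn <- x + alpha * p
      En <- energy_fn(shape(xn))
      if (En <= E + 1e-12 || alpha < 1 / 64) break
      alpha <- alpha / 2
    }
    fn <- as.numeric(t(force_fn(shape(xn))))
    gn <- -fn
    s <- xn - x
    yv <- gn - g
    sy <- sum(s * yv)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      Hinv <- (I - rho * outer(s, yv)) %*% Hinv %*% (I - rho * outer(yv, s)) +
        rho * outer(s, s)
    }
    dE <- En - E
    x <- xn; E <- En; g <- gn; f <- fn
    steps <- steps + 1L
    traj <- rbind(traj, data.frame(step = steps, energy = E, fmax = max(abs(f))))
    converged <- max(abs(f)) <= fmax && abs(dE) <= econv
  }
  list(coords = shape(x), energy = E, converged = converged,
       n_steps = steps, trajectory = traj)
}

# ---- SCF-backed task implementations ---------------------------------------

scf_energy_closure <- function(mol, method, basis, settings) {
  function(coords) {
    m <- molecule(mol$symbols, coords, mol$charge, mol$multiplicity)
    res <- run_scf(m, method, basis, settings)
    if (!res$converged)
      stop("SCF failed to converge at a displaced geometry", call. = FALSE)
    res$energy
  }
}

#' Single-point forces (finite-difference baseline)
#'
#' @param mol an `mdft_molecule`
#' @param method,basis model specification
#' @param settings an [scf_settings()]
#' @param h finite-difference step in bohr (default 1e-3)
#' @return n_atoms x 3 force matrix (hartree/bohr)
#' @export
forces_spf <- function(mol, method, basis, settings = scf_settings(),
                       h = 1e-3) {
  if (length(mol$symbols) == 1L) return(matrix(0, 1, 3))
  fd_forces(scf_energy_closure(mol, method, basis, settings), mol$coords, h)
}

#' Seminumerical Hessian (central differences of forces)
#'
#' @inheritParams forces_spf
#' @return 3n x 3n symmetric Hessian (hartree/bohr^2)
#' @export
hessian_fh <- function(mol, method, basis, settings = scf_settings(),
                       h = 1e-3) {
  efn <- scf_energy_closure(mol, method, basis, settings)
  ffn <- function(coords) fd_forces(efn, coords, h)
  fd_hessian(ffn, mol$coords, h)
}

#' Run one of the five tasks
#'
#' Dispatch: spe (single-point energy), spf (single-point forces), fh
#' (seminumerical Hessian), go (BFGS geometry optimization), bomd
#' (velocity-Verlet Born-Oppenheimer molecular dynamics). Errors are caught
#' and returned as a structured result with `success = FALSE`.
#'
#' @param doc an `mdft_task_document` (or arguments to [task_document()]
#'   via `...`)
#' @return an `mdft_task_result`; fields depend on the task (energy; forces;
#'   hessian; optimized geometry + trajectory; MD trace), plus `provenance`
#'   (settings actually used) and `scf` (the underlying SCF result for spe)
#' @export
run_task <- function(doc) {
  if (!inherits(doc, "mdft_task_document"))
    stop("run_task expects an mdft_task_document; see task_document()",
         call. = FALSE)
  kw <- doc$keywords
  out <- tryCatch({
    settings <- task_settings(kw)
    mol <- doc$molecule
    method <- doc$model$method
    basis <- doc$model$basis
    h <- kw$fd_step %||% 1e-3
    prov <- list(task = doc$task, method = method, basis = basis,
                 settings = unclass(settings), fd_step = h)
    res <- switch(doc$task,
      spe = {
        scf <- run_scf(mol, method, basis, settings)
        if (!scf$converged) stop("SCF did not converge", call. = FALSE)
        list(energy = scf$energy, scf = scf)
      },
      spf = {
        scf <- run_scf(mol, method, basis, settings)
        if (!scf$converged) stop("SCF did not converge", call. = FALSE)
        list(energy = scf$energy, scf = scf,
             forces = forces_spf(mol, method, basis, settings, h))
      },
      fh = {
        scf <- run_scf(mol, method, basis, settings)
        if (!scf$converged) stop("SCF did not converge", call. = FALSE)
        list(energy = scf$energy, scf = scf,
             hessian = hessian_fh(mol, method, basis, settings, h))
      },
      go = {
        efn <- scf_energy_closure(mol, method, basis, settings)
        ffn <- function(coords) fd_forces(efn, coords, h)
        opt <- bfgs_optimize(efn, ffn, mol$coords,
                             fmax = kw$opt_fmax %||% 4.5e-4,
                             econv = kw$opt_econv %||% 1e-6,
                             max_steps = kw$opt_max_steps %||% 100L)
        final <- molecule(mol$symbols, opt$coords, mol$charge,
                          mol$multiplicity)
        list(energy = opt$energy, molecule = final,
             converged_opt = opt$converged, trajectory = opt$trajectory)
      },
      bomd = {
        efn <- scf_energy_closure(mol, method, basis, settings)
        ffn <- function(coords) fd_forces(efn, coords, h)
        dt <- (kw$dt_fs %||% 0.25) * FS_TO_AUT
        nst <- kw$n_steps %||% 10L
        masses <- ELEMENT_MASSES[mol$Z] * AMU_TO_ME
        vel <- matrix(0, length(mol$Z), 3)
        if (!is.null(kw$temperature) && kw$temperature > 0) {
          if (is.null(kw$seed))
            stop("bomd with temperature > 0 requires a seed", call. = FALSE)
          old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
          set.seed(kw$seed)
          vel <- matrix(rnorm(3 * length(mol$Z)), ncol = 3) *
            sqrt(KB_HARTREE * kw$temperature / (masses))
          if (!is.null(old)) assign(".Random.seed", old, globalenv())
        }
        tr <- velocity_verlet(ffn, mol$coords, vel, masses, dt, nst,
                              energy_fn = efn)
        list(energy = tail(tr$e_pot, 1), trajectory = tr)
      }
    )
    c(list(success = TRUE, task = doc$task, provenance = prov), res)
  }, error = function(e) {
    list(success = FALSE, task = doc$task, error = conditionMessage(e))
  })
  structure(out, class = "mdft_task_result")
}

#' @export
print.mdft_task_result <- function(x, ...) {
  cat("<mdft_task_result> task ", x$task, ": ",
      if (isTRUE(x$success)) "success" else paste("FAILED -", x$error), "\n",
      sep = "")
  if (!is.null(x$energy)) cat("  energy:", sprintf("%.10f", x$energy), "hartree\n")
  invisible(x)
}

#' Serialize a task result
#'
#' Writes a QCSchema-style JSON output document (scalars and small arrays)
#' and, when the task carried a converged SCF, a binary artifact container
#' (RDS) with the stable dataset names `coefficients`, `density`, `fock`,
#' `overlap`, `orbital_energies`, `occupations`, from which the SCF state
#' can be rebuilt.
#'
#' @param result an `mdft_task_result`
#' @param path output JSON path
#' @param artifact_path optional RDS path for the matrix container (default:
#'   `path` with extension ".rds"); used only when SCF matrices are present
#' @return invisibly, a list with `path` and `artifact_path` (NULL if no
#'   artifact was written)
#' @export
serialize_result <- function(result, path, artifact_path = NULL) {
  doc <- list(schema_name = "mdft_task_result", schema_version = 1L,
              task = result$task, success = result$success)
  if (!is.null(result$error)) doc$error <- result$error
  if (!is.null(result$energy)) doc$energy <- result$energy
  if (!is.null(result$forces)) doc$forces <- result$forces
  if (!is.null(result$hessian)) doc$hessian <- result$hessian
  if (!is.null(result$molecule)) doc$molecule <- qcschema_molecule(result$molecule)
  if (!is.null(result$trajectory)) doc$trajectory <- result$trajectory
  if (!is.null(result$provenance)) doc$provenance <- result$provenance
  art <- NULL
  if (!is.null(result$scf) && isTRUE(result$scf$converged)) {
    if (is.null(artifact_path))
      artifact_path <- paste0(sub("\\.json$", "", path), ".rds")
    scf <- result$scf
    occ <- c(rep(2, scf$occupied), rep(0, ncol(scf$C) - scf$occupied))
    saveRDS(list(coefficients = scf$C, density = scf$P, fock = scf$F,
                 overlap = scf$S, orbital_energies = scf$orbital_energies,
                 occupations = occ),
            artifact_path)
    doc$artifact <- artifact_path
    art <- artifact_path
  }
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns")
    TRUE
  }, error = function(e) {
    stop("failed to write result to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(list(path = path, artifact_path = art))
}

#' Load a serialized task result
#' @param path JSON path written by [serialize_result()]
#' @return list: the parsed document, with `artifact` replaced by the loaded
#'   matrix container when present
#' @export
load_result <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(doc$artifact) && file.exists(doc$artifact))
    doc$artifact_data <- readRDS(doc$artifact)
  doc
}
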