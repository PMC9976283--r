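# Restricted Hartree-Fock engine used to generate quantum-mechanical
# reference densities and localized-orbital centers for hydrated-ion
# clusters. All internal quantities are in atomic units; the public surface
# converts to the package units (Angstrom, e/A^3).

#' Set up a quantum-chemistry system from a frame
#'
#' @param frame md_frame (cluster, positions in Angstrom)
#' @param charge total charge in e
#' @return qc_molecule: elements, coords (Bohr), Z, n_electrons
#' @export
qc_molecule <- function(frame, charge = 0) {
  at <- frame$atoms
  el <- at$element
  Z <- ATOMIC_NUMBERS[el]
  if (anyNA(Z)) stop("unknown element(s): ", paste(el[is.na(Z)], collapse = ", "))
  nelec <- sum(Z) - charge
  if (nelec %% 2 != 0)
    stop("odd electron count (", nelec, "): only closed-shell systems supported")
  b <- permeonics_constants()$bohr_A
  structure(list(elements = el, coords = cbind(at$x, at$y, at$z) / b,
                 Z = as.numeric(Z), charge = charge, n_electrons = nelec,
                 frame = frame), class = "qc_molecule")
}

.nuclear_repulsion <- function(mol) {
  n <- nrow(mol$coords)
  e <- 0
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    e <- e + mol$Z[i] * mol$Z[j] / r
  }
  e
}

#' Restricted Hartree-Fock with DIIS
#'
#' Solves the closed-shell self-consistent field equations in the package's
#' internally generated Gaussian basis (see the methods vignette for the
#' basis construction). Convergence: DIIS on the FDS-SDF commutator with a
#' generalized Wolfsberg-Helmholz starting guess.
#'
#' @param mol [qc_molecule()]
#' @param max_iter,conv_energy,conv_error convergence controls
#' @param verbose print per-iteration energies
#' @return object of class \code{scf_result}: energy (Hartree), orbital
#'   coefficients C, occupied count, density matrix P (doubled), overlap S,
#'   basis, molecule
#' @export
rhf <- function(mol, max_iter = 100, conv_energy = 1e-8, conv_error = 1e-6,
                verbose = FALSE, extra_shells = NULL) {
  .scf_run(mol, xc = NULL, max_iter = max_iter, conv_energy = conv_energy,
           conv_error = conv_error, verbose = verbose,
           extra_shells = extra_shells)
}

#' Restricted Kohn-Sham SCF (hybrid B3LYP-style functional)
#'
#' Same machinery as [rhf()] with the exchange-correlation energy evaluated
#' on a Becke quadrature grid ([becke_grid()]). The default functional is a
#' B3LYP-type hybrid (20 percent exact exchange, 0.72 B88 + 0.08 Slater
#' exchange mixing, 0.81 LYP + 0.19 VWN5 correlation).
#'
#' @param mol [qc_molecule()]
#' @param functional one of "b3lyp", "blyp", "svwn"
#' @param n_rad,n_theta grid controls, see [becke_grid()]
#' @param max_iter,conv_energy,conv_error convergence controls
#' @param verbose print per-iteration energies
#' @return an \code{scf_result} (with \code{functional} and \code{e_xc})
#' @export
rks <- function(mol, functional = "b3lyp", n_rad = 50, n_theta = 10,
                max_iter = 100, conv_energy = 1e-7, conv_error = 1e-5,
                verbose = FALSE, extra_shells = NULL, P0 = NULL) {
  xc <- XC_FUNCTIONALS[[functional]]
  if (is.null(xc)) stop("unknown functional: ", functional)
  .scf_run(mol, xc = xc, functional_name = functional, n_rad = n_rad,
           n_theta = n_theta, max_iter = max_iter, conv_energy = conv_energy,
           conv_error = conv_error, verbose = verbose,
           extra_shells = extra_shells, P0 = P0)
}

.scf_run <- function(mol, xc = NULL, functional_name = NULL, n_rad = 50,
                     n_theta = 10, max_iter = 100, conv_energy = 1e-8,
                     conv_error = 1e-6, verbose = FALSE, extra_shells = NULL,
                     P0 = NULL) {
  stopifnot(inherits(mol, "qc_molecule"))
  basis <- build_basis(mol$elements, mol$coords, extra_shells = extra_shells)
  ints <- ints_one_electron(basis$ijk, basis$center, basis$prim_start,
                            basis$alpha, basis$coef, mol$Z, mol$coords)
  S <- ints$S; H <- ints$T + ints$V
  n <- basis$n
  nocc <- mol$n_electrons / 2
  if (nocc > n) stop("basis too small: ", n, " functions for ", nocc,
                     " occupied orbitals")
  eri <- eri_packed(basis$ijk, basis$center, basis$prim_start,
                    basis$alpha, basis$coef)
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-7)
    warning("near-linear dependence in basis (min overlap eigenvalue ",
            sprintf("%.2e", min(es$values)), ")")
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  hfx <- if (is.null(xc)) 1.0 else xc$hfx
  grid <- NULL; Phi <- NULL
  if (!is.null(xc)) {
    grid <- becke_grid(mol, n_rad = n_rad, n_theta = n_theta)
    Phi <- eval_basis_grad(basis$ijk, basis$center, basis$prim_start,
                           basis$alpha, basis$coef, grid$points)
  }
  xc_term <- function(P) {
    PM <- Phi$val %*% P
    rho <- rowSums(PM * Phi$val)
    gx <- 2 * rowSums(PM * Phi$dx)
    gy <- 2 * rowSums(PM * Phi$dy)
    gz <- 2 * rowSums(PM * Phi$dz)
    ev <- .xc_eval(xc$f, pmax(rho, 0), gx^2 + gy^2 + gz^2)
    w <- grid$weights
    B <- Phi$val * (0.5 * w * ev$vrho) +
      (Phi$dx * gx + Phi$dy * gy + Phi$dz * gz) * (2 * w * ev$vgamma)
    V <- crossprod(Phi$val, B)
    list(V = V + t(V), E = sum(w * ev$f), n_el = sum(w * rho))
  }
  # generalized Wolfsberg-Helmholz guess
  F0 <- 0.875 * S * (matrix(diag(H), n, n) + matrix(diag(H), n, n, byrow = TRUE))
  diag(F0) <- diag(H)
  dens <- function(Fm) {
    Fp <- t(X) %*% Fm %*% X
    ev <- eigen(Fp, symmetric = TRUE)
    ord <- order(ev$values)  # eigen() sorts decreasing; want increasing
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    list(C = C, eps = ev$values[ord],
         P = 2 * C[, seq_len(nocc), drop = FALSE] %*%
           t(C[, seq_len(nocc), drop = FALSE]))
  }
  if (is.null(P0)) {
    d <- dens(F0)
    P <- d$P
  } else {
    if (!all(dim(P0) == n)) stop("P0 must be an nbf x nbf density matrix")
    P <- P0
  }
  e_nuc <- .nuclear_repulsion(mol)
  e_old <- 0
  diis_F <- list(); diis_e <- list()
  for (it in seq_len(max_iter)) {
    jk <- fock_jk(eri, P)
    Fm <- H + jk$J - 0.5 * hfx * jk$K
    e_elec <- sum(P * H) + 0.5 * sum(P * jk$J) - 0.25 * hfx * sum(P * jk$K)
    e_xc <- 0
    if (!is.null(xc)) {
      xce <- xc_term(P)
      Fm <- Fm + xce$V
      e_xc <- xce$E
      e_elec <- e_elec + e_xc
    }
    err <- Fm %*% P %*% S - S %*% P %*% Fm
    err <- t(X) %*% err %*% X
    maxerr <- max(abs(err))
    if (verbose)
      message(sprintf("iter %2d  E = %.10f  dE = %.2e  |err| = %.2e",
                      it, e_elec + e_nuc, e_elec + e_nuc - e_old, maxerr))
    if (abs(e_elec + e_nuc - e_old) < conv_energy && maxerr < conv_error) {
      d <- dens(Fm)
      return(structure(list(
        energy = e_elec + e_nuc, e_electronic = e_elec, e_nuclear = e_nuc,
        e_xc = e_xc, functional = if (is.null(xc)) "hf" else functional_name,
        C = d$C, eps = d$eps, n_occ = nocc, P = d$P, S = S, H = H,
        basis = basis, mol = mol, n_iter = it, converged = TRUE),
        class = "scf_result"))
    }
    e_old <- e_elec + e_nuc
    # DIIS (max 8 vectors)
    diis_F[[length(diis_F) + 1L]] <- Fm
    diis_e[[length(diis_e) + 1L]] <- err
    if (length(diis_F) > 8) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
    m <- length(diis_F)
    if (m >= 2) {
      B <- matrix(0, m + 1, m + 1)
      for (a in 1:m) for (b in 1:m)
        B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
      B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      w <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(w)) {
        Fm <- Reduce(`+`, Map(`*`, diis_F, w))
      }
    }
    d <- dens(Fm)
    P <- d$P
  }
  stop("SCF failed to converge in ", max_iter, " iterations")
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("scf_result: E = %.8f Hartree (%d bf, %d occ, %d iterations)\n",
              x$energy, x$basis$n, x$n_occ, x$n_iter))
  invisible(x)
}

#' Dipole moment expectation value of an SCF density
#'
#' @param scf scf_result
#' @return list(dipole_eA, magnitude_D): electronic + nuclear dipole
#' @export
scf_dipole <- function(scf) {
  dip <- ints_dipole(scf$basis$ijk, scf$basis$center, scf$basis$prim_start,
                     scf$basis$alpha, scf$basis$coef)
  el <- -c(sum(scf$P * dip$X), sum(scf$P * dip$Y), sum(scf$P * dip$Z))
  nuc <- colSums(scf$mol$coords * scf$mol$Z)
  k <- permeonics_constants()
  mu <- (el + nuc) * k$bohr_A  # e*Bohr -> e*A
  list(dipole_eA = mu, magnitude_D = sqrt(sum(mu^2)) * k$debye_per_eA)
}

#' Evaluate the SCF electron density on a cube grid
#'
#' @param scf scf_result
#' @param origin,voxel,shape grid spec in Angstrom (see [new_density_grid()])
#' @param P optional density matrix override (doubled, AO basis)
#' @param chunk points per evaluation block
#' @return a \code{density_grid} in e/A^3 with the molecule's atoms attached
#' @export
scf_density_grid <- function(scf, origin, voxel, shape, P = NULL,
                             chunk = 20000L) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  if (is.null(P)) P <- scf$P
  b <- permeonics_constants()$bohr_A
  g0 <- new_density_grid(origin, voxel, array(0, as.integer(shape)),
                         scf$mol$frame$atoms)
  pts <- grid_points(g0) / b  # Bohr
  np <- nrow(pts)
  rho <- numeric(np)
  bs <- scf$basis
  for (s in seq(1L, np, by = chunk)) {
    e <- min(s + chunk - 1L, np)
    Phi <- eval_basis(bs$ijk, bs$center, bs$prim_start, bs$alpha, bs$coef,
                      pts[s:e, , drop = FALSE])
    rho[s:e] <- rowSums((Phi %*% P) * Phi)
  }
  g0$values <- array(rho / b^3, as.integer(shape))  # e/Bohr^3 -> e/A^3
  g0
}

#' Boys localization of the occupied orbitals
#'
#' Maximizes the sum of squared orbital centroids by Jacobi 2x2 rotations,
#' yielding maximally localized (Wannier-style) orbitals for an isolated
#' system. Returns the orbital centers ("charge centers", each orbital
#' holding 2 electrons).
#'
#' @param scf scf_result
#' @param mo_idx orbitals to localize (default: all occupied)
#' @param max_sweeps,tol convergence controls
#' @param drop_core_radius centers closer than this (Angstrom) to a nucleus
#'   heavier than H are core orbitals; set to a positive value to drop them
#'   from the returned matrix (0 keeps everything)
#' @return list(centers: m x 3 matrix in Angstrom, C_loc: localized
#'   coefficients, all_centers: before core filtering)
#' @export
boys_centers <- function(scf, mo_idx = NULL, max_sweeps = 200, tol = 1e-10,
                         drop_core_radius = 0.1) {
  if (is.null(mo_idx)) mo_idx <- seq_len(scf$n_occ)
  dip <- ints_dipole(scf$basis$ijk, scf$basis$center, scf$basis$prim_start,
                     scf$basis$alpha, scf$basis$coef)
  C <- scf$C[, mo_idx, drop = FALSE]
  m <- ncol(C)
  # MO dipole matrices
  R <- list(t(C) %*% dip$X %*% C, t(C) %*% dip$Y %*% C, t(C) %*% dip$Z %*% C)
  for (sweep in seq_len(max_sweeps)) {
    change <- 0
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      A <- 0; Bv <- 0
      for (k in 1:3) {
        rij <- R[[k]][i, j]; rii <- R[[k]][i, i]; rjj <- R[[k]][j, j]
        A <- A + rij^2 - 0.25 * (rii - rjj)^2
        Bv <- Bv + rij * (rii - rjj)
      }
      if (A^2 + Bv^2 < tol^2) next
      ang <- 0.25 * atan2(Bv, -A)
      if (abs(ang) < 1e-12) next
      cs <- cos(ang); sn <- sin(ang)
      rot <- function(M) {
        ci <- M[, i] * cs + M[, j] * sn
        cj <- -M[, i] * sn + M[, j] * cs
        M[, i] <- ci; M[, j] <- cj
        ri <- M[i, ] * cs + M[j, ] * sn
        rj <- -M[i, ] * sn + M[j, ] * cs
        M[i, ] <- ri; M[j, ] <- rj
        M
      }
      for (k in 1:3) R[[k]] <- rot(R[[k]])
      ci <- C[, i] * cs + C[, j] * sn
      cj <- -C[, i] * sn + C[, j] * cs
      C[, i] <- ci; C[, j] <- cj
      change <- change + abs(ang)
    }
    if (change < 1e-9) break
  }
  b <- permeonics_constants()$bohr_A
  centers <- cbind(diag(R[[1]]), diag(R[[2]]), diag(R[[3]])) * b
  keep <- rep(TRUE, m)
  if (drop_core_radius > 0) {
    heavy <- which(scf$mol$elements != "H")
    if (length(heavy)) {
      hp <- scf$mol$coords[heavy, , drop = FALSE] * b
      for (q in seq_len(m)) {
        dmin <- min(sqrt(rowSums(sweep(hp, 2, centers[q, ])^2)))
        if (dmin < drop_core_radius) keep[q] <- FALSE
      }
    }
  }
  list(centers = centers[keep, , drop = FALSE], C_loc = C,
       all_centers = centers, is_core = !keep)
}
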