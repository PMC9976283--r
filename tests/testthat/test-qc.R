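# Validation of the quantum-chemistry engine against external references:
# closed-form integrals, published minimal-basis energies, and the He-atom
# exchange/correlation anchors the functionals were originally fit to.

bohr <- permeonics_constants()$bohr_A

# helper: build an explicit basis and run a bare SCF loop (independent of the
# package's basis generator, so published reference values apply)
manual_rhf <- function(shell_list, centers_bohr, Z, nocc) {
  dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))
  ijk <- list(); cen <- list(); pst <- 0L; alpha <- c(); coef <- c()
  for (s in shell_list) {
    comps <- if (s$l == 0) matrix(c(0L, 0L, 0L), 1) else
      rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
    for (r in seq_len(nrow(comps))) {
      ij <- comps[r, ]
      pn <- vapply(s$a, function(a) (2 * a / pi)^0.75 *
                     sqrt((4 * a)^sum(ij) / prod(vapply(ij, function(q)
                       dfact(2 * q - 1), 1))), 0)
      cc <- s$c * pn
      ov <- 0
      for (p in seq_along(s$a)) for (q in seq_along(s$a)) {
        g <- s$a[p] + s$a[q]
        ov <- ov + cc[p] * cc[q] * (pi / g)^1.5 *
          prod(vapply(ij, function(t) dfact(2 * t - 1), 1)) / (2 * g)^sum(ij)
      }
      cc <- cc / sqrt(ov)
      ijk[[length(ijk) + 1]] <- ij
      cen[[length(cen) + 1]] <- centers_bohr[s$atom, ]
      alpha <- c(alpha, s$a); coef <- c(coef, cc)
      pst <- c(pst, pst[length(pst)] + length(s$a))
    }
  }
  IJK <- do.call(rbind, ijk); CEN <- do.call(rbind, cen)
  oe <- permeonics:::ints_one_electron(IJK, CEN, as.integer(pst), alpha, coef,
                                       Z, centers_bohr)
  eri <- permeonics:::eri_packed(IJK, CEN, as.integer(pst), alpha, coef)
  S <- oe$S; H <- oe$T + oe$V
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  P <- matrix(0, nrow(S), nrow(S)); eo <- Inf; e <- 0
  enuc <- 0
  na <- nrow(centers_bohr)
  if (na > 1) for (i in 1:(na - 1)) for (j in (i + 1):na)
    enuc <- enuc + Z[i] * Z[j] / sqrt(sum((centers_bohr[i, ] - centers_bohr[j, ])^2))
  for (it in 1:100) {
    jk <- permeonics:::fock_jk(eri, P)
    Fm <- H + jk$J - 0.5 * jk$K
    e <- 0.5 * sum(P * (H + Fm)) + enuc
    if (abs(e - eo) < 1e-10 && it > 3) break
    eo <- e
    ev <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord]
    P <- 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE])
  }
  list(E = e, P = P, IJK = IJK, CEN = CEN, pst = as.integer(pst),
       alpha = alpha, coef = coef)
}

sto3g_h <- list(a = c(3.42525091, 0.62391373, 0.16885540),
                c = c(0.15432897, 0.53532814, 0.44463454))

test_that("primitive integrals match closed forms", {
  ijk <- matrix(0L, 1, 3); cen <- matrix(0, 1, 3)
  Nc <- (2 / pi)^0.75
  oe <- permeonics:::ints_one_electron(ijk, cen, c(0L, 1L), 1.0, Nc, 1.0,
                                       matrix(0, 1, 3))
  expect_equal(oe$S[1, 1], 1, tolerance = 1e-12)
  expect_equal(oe$T[1, 1], 1.5, tolerance = 1e-12)          # 3a/2
  expect_equal(oe$V[1, 1], -2 * sqrt(2 / pi), tolerance = 1e-10)
  eri <- permeonics:::eri_packed(ijk, cen, c(0L, 1L), 1.0, Nc)
  expect_equal(eri[1], 2 * sqrt(1 / pi), tolerance = 1e-10)
  # two-center: overlap and Coulomb of unit-exponent s pairs at R = 1.4
  ijk2 <- matrix(0L, 2, 3); cen2 <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  oe2 <- permeonics:::ints_one_electron(ijk2, cen2, c(0L, 1L, 2L), c(1, 1),
                                        rep(Nc, 2), c(1, 1), cen2)
  expect_equal(oe2$S[1, 2], exp(-0.5 * 1.4^2), tolerance = 1e-12)
  eri2 <- permeonics:::eri_packed(ijk2, cen2, c(0L, 1L, 2L), c(1, 1), rep(Nc, 2))
  # (11|22) = erf(sqrt(mu) R)/R with mu = p q/(p+q) = 1
  expect_equal(eri2[4], (2 * pnorm(1.4 * sqrt(2)) - 1) / 1.4, tolerance = 1e-10)
})

test_that("H2/STO-3G reproduces the published restricted Hartree-Fock energy", {
  cen <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  sh <- list(c(sto3g_h, atom = 1, l = 0), c(sto3g_h, atom = 2, l = 0))
  r <- manual_rhf(sh, cen, c(1, 1), nocc = 1)
  expect_equal(r$E, -1.1167, tolerance = 2e-4)  # Szabo & Ostlund value
})

test_that("water/STO-3G matches the literature energy and dipole", {
  fx <- gen_wannier_fixture(1.85)
  cen <- as.matrix(fx$frame$atoms[, c("x", "y", "z")]) / bohr
  o_s1 <- list(a = c(130.70932, 23.808861, 6.4436083),
               c = c(0.15432897, 0.53532814, 0.44463454))
  o_s2 <- list(a = c(5.0331513, 1.1695961, 0.3803890),
               c = c(-0.09996723, 0.39951283, 0.70011547))
  o_p <- list(a = o_s2$a, c = c(0.15591627, 0.60768372, 0.39195739))
  sh <- list(c(o_s1, atom = 1, l = 0), c(o_s2, atom = 1, l = 0),
             c(o_p, atom = 1, l = 1),
             c(sto3g_h, atom = 2, l = 0), c(sto3g_h, atom = 3, l = 0))
  r <- manual_rhf(sh, cen, c(8, 1, 1), nocc = 5)
  expect_equal(r$E, -74.9629, tolerance = 2e-4)
  dip <- permeonics:::ints_dipole(r$IJK, r$CEN, r$pst, r$alpha, r$coef)
  mu <- (-c(sum(r$P * dip$X), sum(r$P * dip$Y), sum(r$P * dip$Z)) +
           as.numeric(c(8, 1, 1) %*% cen)) * bohr * 4.80320
  expect_equal(sqrt(sum(mu^2)), 1.71, tolerance = 0.03)
})

test_that("the package basis gives a helium-anchor-consistent DFT layer", {
  # He: even-tempered 8s reference; HF limit -2.8617 Hartree
  al <- 0.12 * 3.0^(0:7)
  sh <- lapply(seq_along(al), function(i) list(a = al[i], c = 1, atom = 1, l = 0))
  r <- manual_rhf(sh, matrix(0, 1, 3), 2, nocc = 1)
  expect_equal(r$E, -2.8617, tolerance = 5e-4)
  # XC integrals on that density over the Becke grid: published anchors
  at <- data.frame(atom_id = 1, element = "He", role = "other",
                   molecule_id = 1, x = 0, y = 0, z = 0)
  mol <- structure(list(elements = "He", coords = matrix(0, 1, 3), Z = 2,
                        charge = 0, n_electrons = 2, frame = new_frame(at)),
                   class = "qc_molecule")
  g <- becke_grid(mol, n_rad = 70, n_theta = 10)
  Phi <- permeonics:::eval_basis_grad(r$IJK, r$CEN, r$pst, r$alpha, r$coef,
                                      g$points)
  PM <- Phi$val %*% r$P
  rho <- pmax(rowSums(PM * Phi$val), 1e-30)
  gam <- pmax((2 * rowSums(PM * Phi$dx))^2 + (2 * rowSums(PM * Phi$dy))^2 +
                (2 * rowSums(PM * Phi$dz))^2, 1e-30)
  w <- g$weights
  expect_equal(sum(w * rho), 2, tolerance = 1e-6)       # grid quadrature of N
  expect_lt(abs(sum(w * permeonics:::.f_x_slater(rho, gam)) + 0.884), 2e-3)
  expect_lt(abs(sum(w * (permeonics:::.f_x_slater(rho, gam) +
                           permeonics:::.f_x_b88(rho, gam))) + 1.025), 2e-3)
  expect_lt(abs(sum(w * permeonics:::.f_c_lyp(rho, gam)) + 0.0437), 5e-4)
  expect_lt(abs(sum(w * permeonics:::.f_c_vwn5(rho, gam)) + 0.112), 2e-3)
})

test_that("SCF observables are translation invariant", {
  fx <- gen_wannier_fixture(1.85)
  scf0 <- rhf(qc_molecule(fx$frame))
  fr <- fx$frame
  fr$atoms$x <- fr$atoms$x + 1.7
  fr$atoms$z <- fr$atoms$z - 0.9
  scf1 <- rhf(qc_molecule(fr))
  expect_equal(scf1$energy, scf0$energy, tolerance = 1e-7)
  expect_equal(scf_dipole(scf1)$magnitude_D, scf_dipole(scf0)$magnitude_D,
               tolerance = 1e-5)
})

test_that("B3LYP lowers the energy below Hartree-Fock and stays normalized", {
  fx <- gen_wannier_fixture(1.85)
  mol <- qc_molecule(fx$frame)
  hf <- rhf(mol)
  ks <- rks(mol)
  expect_true(ks$converged)
  expect_lt(ks$energy, hf$energy)          # correlation energy is negative
  expect_lt(ks$energy - hf$energy, -0.2)   # ~ -0.4 Hartree for water
  # density from the KS orbitals integrates to 10 electrons
  g <- scf_density_grid(ks, origin = rep(-5, 3), voxel = 0.12, shape = rep(84, 3))
  expect_equal(grid_integral(g), 10, tolerance = 0.15)  # core undersampling only
})

test_that("Boys localization of water yields bonds, lone pairs and the dipole", {
  fx <- gen_wannier_fixture(1.85)
  scf <- rks(qc_molecule(fx$frame))
  bc <- boys_centers(scf)
  expect_equal(nrow(bc$centers), 4)        # core orbital dropped
  expect_equal(sum(bc$is_core), 1)
  ws <- assign_and_classify_centers(bc$centers, fx$frame)
  expect_equal(sum(ws$centers$kind == "OH_bond"), 2)
  expect_equal(sum(ws$centers$kind == "lone_pair"), 2)
  # valence point-charge dipole from the centers reproduces the quantum
  # expectation value (trace invariance of the localization)
  md <- molecular_dipole(ws, 1)
  expect_equal(md$magnitude_D, scf_dipole(scf)$magnitude_D, tolerance = 0.05)
})
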