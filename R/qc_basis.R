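# Gaussian basis sets generated in-package.
#
# Construction: each occupied atomic shell is a Slater-type orbital whose
# exponent comes from Slater's screening rules (the standard single-zeta
# prescription; molecular-environment scaling 1.24 for H), expanded in a
# least-squares fit of n Gaussians (the classic STO-nG construction,
# performed numerically here). Valence shells are split (innermost fit
# primitives contracted, the most diffuse primitive left free) and
# polarization / acceptor shells are added: a d set on oxygen and
# low-exponent 4s/3d sets on calcium obtained from the Slater exponents of
# the singly-excited cation configurations.

# ---- STO-nG radial fit ------------------------------------------------------

# normalized Slater radial function r^(n-1) exp(-zeta r)
.slater_radial <- function(r, n, zeta) {
  nrm <- (2 * zeta)^(n + 0.5) / sqrt(factorial(2 * n))
  nrm * r^(n - 1) * exp(-zeta * r)
}

# fit nprim Gaussians (radial part r^l exp(-a r^2)) to the (n, l) Slater
# shell with zeta = 1; returns exponents and contraction coefficients for
# radially normalized primitives. Exponents scale as zeta^2.
.sto_fit <- function(nprim, n, l) {
  rmax <- 10 + 5 * n
  r <- seq(1e-4, rmax, length.out = 4000)
  w <- r^2 * (r[2] - r[1])
  target <- .slater_radial(r, n, 1)
  prim <- function(a) {
    g <- r^l * exp(-a * r^2)
    g / sqrt(sum(g^2 * w))
  }
  obj <- function(loga) {
    a <- exp(loga)
    G <- vapply(a, prim, numeric(length(r)))
    Sgg <- crossprod(G * sqrt(w))
    sg <- as.numeric(crossprod(G * w, target))
    co <- tryCatch(solve(Sgg, sg), error = function(e) rep(0, length(a)))
    -sum(co * sg)  # negative squared projection
  }
  init <- log(exp(seq(log(0.06), log(8), length.out = nprim)) / max(1, n - 0.5)^1.5)
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-13))
  a <- exp(fit$par)
  G <- vapply(a, prim, numeric(length(r)))
  Sgg <- crossprod(G * sqrt(w))
  sg <- as.numeric(crossprod(G * w, target))
  co <- solve(Sgg, sg)
  norm <- sqrt(as.numeric(t(co) %*% Sgg %*% co))
  ord <- order(a)
  list(alpha = a[ord], coef = (co / norm)[ord],
       overlap = sum(co * sg) / norm)
}

# memoised fits (zeta = 1); keyed by "nprim.n.l"
.sto_cache <- new.env(parent = emptyenv())
.sto_fit_cached <- function(nprim, n, l) {
  key <- paste(nprim, n, l, sep = ".")
  if (is.null(.sto_cache[[key]])) .sto_cache[[key]] <- .sto_fit(nprim, n, l)
  .sto_cache[[key]]
}

# Slater's screening rules for the shell exponents of atom Z (s/p shells);
# returns zeta for shell with principal quantum number nq given the
# electron configuration of the species
.slater_zeta <- function(Z, nq, config) {
  # config: named vector of electrons per principal shell, e.g. c(`1`=2,`2`=8)
  shield <- 0
  for (nm in names(config)) {
    n_i <- as.integer(nm)
    e_i <- config[[nm]]
    if (n_i == nq) shield <- shield + (e_i - 1) * if (nq == 1) 0.30 else 0.35
    else if (n_i == nq - 1) shield <- shield + e_i * 0.85
    else if (n_i < nq - 1) shield <- shield + e_i * 1.00
  }
  nstar <- c(1, 2, 3, 3.7, 4)[min(nq, 5)]
  (Z - shield) / nstar
}

# ---- variationally optimized atomic basis for the calcium ion ---------------

# bare restricted HF for a single atom given explicit uncontracted s/p sets
.atom_rhf <- function(alpha_s, alpha_p, Z, nelec) {
  nl <- c(rep(0L, length(alpha_s)), rep(1L, 3 * length(alpha_p)))
  ijk <- matrix(0L, length(nl), 3)
  r <- length(alpha_s)
  for (k in seq_along(alpha_p)) {
    ijk[r + 3 * (k - 1) + 1, 1] <- 1L
    ijk[r + 3 * (k - 1) + 2, 2] <- 1L
    ijk[r + 3 * (k - 1) + 3, 3] <- 1L
  }
  a <- c(alpha_s, rep(alpha_p, each = 3))
  cc <- vapply(seq_along(a), function(i) .prim_norm(a[i], ijk[i, ]), 0)
  n <- length(a)
  cen <- matrix(0, n, 3)
  pst <- as.integer(0:n)
  oe <- ints_one_electron(ijk, cen, pst, a, cc, Z, matrix(0, 1, 3))
  eri <- eri_packed(ijk, cen, pst, a, cc)
  S <- oe$S; H <- oe$T + oe$V
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) return(list(E = Inf))
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  nocc <- nelec / 2
  P <- matrix(0, n, n); eo <- Inf; e <- 0; C <- NULL
  for (it in 1:80) {
    jk <- fock_jk(eri, P)
    Fm <- H + jk$J - 0.5 * jk$K
    e <- 0.5 * sum(P * (H + Fm))
    if (abs(e - eo) < 1e-9 && it > 3) break
    eo <- e
    ev <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    P <- 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE])
  }
  list(E = e, C = C, P = P, n_s = length(alpha_s), n_p = length(alpha_p))
}

# even-tempered (a, b) exponent ladders for Ca2+ optimized variationally,
# then general-contracted to the atomic 1s/2s/3s and 2p/3p orbitals with the
# outermost two primitives of each ladder left free; memoised
.ca_basis_cached <- function() {
  key <- "ca_opt"
  if (!is.null(.sto_cache[[key]])) return(.sto_cache[[key]])
  ns <- 12L; np <- 8L
  obj <- function(par) {
    a_s <- exp(par[1]) * exp(par[2])^(0:(ns - 1))
    a_p <- exp(par[3]) * exp(par[4])^(0:(np - 1))
    if (exp(par[2]) < 1.8 || exp(par[4]) < 1.8) return(Inf)
    .atom_rhf(a_s, a_p, 20, 18)$E
  }
  # start: ladders spanning core to valence
  init <- c(log(0.09), log(2.8), log(0.20), log(3.0))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  a_s <- exp(fit$par[1]) * exp(fit$par[2])^(0:(ns - 1))
  a_p <- exp(fit$par[3]) * exp(fit$par[4])^(0:(np - 1))
  sol <- .atom_rhf(a_s, a_p, 20, 18)
  # radial contraction vectors from the density-matrix blocks (natural
  # orbitals of each angular channel; rank 3 in s, rank 2 in p)
  Ps <- sol$P[1:ns, 1:ns]
  es_s <- eigen(Ps, symmetric = TRUE)
  s_vecs <- es_s$vectors[, order(es_s$values, decreasing = TRUE)[1:3],
                         drop = FALSE]
  px_rows <- ns + seq(1, 3 * np, by = 3)
  Pp <- sol$P[px_rows, px_rows]
  es_p <- eigen(Pp, symmetric = TRUE)
  p_vecs <- es_p$vectors[, order(es_p$values, decreasing = TRUE)[1:2],
                         drop = FALSE]
  sh <- function(l, alpha, coef = 1) list(l = l, alpha = alpha, coef = coef)
  shells <- list()
  for (m in 1:3) shells[[length(shells) + 1]] <- sh(0, a_s, unname(s_vecs[, m]))
  shells[[length(shells) + 1]] <- sh(0, a_s[2])
  shells[[length(shells) + 1]] <- sh(0, a_s[1])
  for (m in 1:2) shells[[length(shells) + 1]] <- sh(1, a_p, unname(p_vecs[, m]))
  shells[[length(shells) + 1]] <- sh(1, a_p[2])
  shells[[length(shells) + 1]] <- sh(1, a_p[1])
  # d polarization/acceptor pair tracking the free valence p exponents
  shells[[length(shells) + 1]] <- sh(2, a_p[2])
  shells[[length(shells) + 1]] <- sh(2, a_p[1])
  .sto_cache[[key]] <- list(shells = shells, E_atom = sol$E,
                            a_s = a_s, a_p = a_p)
  .sto_cache[[key]]
}

# ---- element basis definitions ---------------------------------------------

# Shell specs per element: each entry is a resolved shell
# list(l, alpha, coef). Valence shells are split or fully uncontracted for
# polarization response; oxygen additionally gets a geometric-continuation
# diffuse p (alpha_min^2 / alpha_next) and a single-Gaussian polarization d.
.element_shells <- function(element) {
  sh <- function(l, alpha, coef = 1) list(l = l, alpha = alpha, coef = coef)
  scaled <- function(nprim, nq, l, zeta) {
    f <- .sto_fit_cached(nprim, nq, l)
    list(alpha = f$alpha * zeta^2, coef = f$coef)
  }
  switch(element,
    H = {
      f <- scaled(3, 1, 0, 1.24)   # standard molecular-scaled 1s
      list(sh(0, f$alpha[-1], f$coef[-1]),   # inner pair contracted
           sh(0, f$alpha[1]))                # most diffuse primitive free
    },
    O = {
      z1 <- .slater_zeta(8, 1, c(`1` = 2, `2` = 6))   # 7.70
      z2 <- .slater_zeta(8, 2, c(`1` = 2, `2` = 6))   # 2.275
      core <- scaled(4, 1, 0, z1)
      s2 <- scaled(3, 2, 0, z2)
      p2 <- scaled(3, 2, 1, z2)
      pd <- p2$alpha[1]^2 / p2$alpha[2]   # even-tempered continuation
      list(sh(0, core$alpha, core$coef),
           sh(0, s2$alpha[-1], s2$coef[-1]),
           sh(0, s2$alpha[1]),
           sh(1, p2$alpha[3]), sh(1, p2$alpha[2]), sh(1, p2$alpha[1]),
           sh(1, pd),
           sh(2, 0.8))                       # polarization d
    },
    Ca = {
      .ca_basis_cached()$shells
    },
    stop("no basis defined for element ", element)
  )
}

.cart_components <- function(l) {
  if (l == 0) return(matrix(c(0L, 0L, 0L), 1))
  if (l == 1) return(rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  if (l == 2) return(rbind(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
                           c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L)))
  stop("angular momenta above d are not supported")
}

.dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))

# primitive normalization for cartesian component (i,j,k), exponent a
.prim_norm <- function(a, ijk) {
  L <- sum(ijk)
  (2 * a / pi)^0.75 * sqrt((4 * a)^L /
    (.dfact(2 * ijk[1] - 1) * .dfact(2 * ijk[2] - 1) * .dfact(2 * ijk[3] - 1)))
}

# contracted self-overlap for same-center primitives of component ijk
.contr_self_overlap <- function(alpha, coef, ijk) {
  L <- sum(ijk)
  f <- .dfact(2 * ijk[1] - 1) * .dfact(2 * ijk[2] - 1) * .dfact(2 * ijk[3] - 1)
  s <- 0
  for (p in seq_along(alpha)) for (q in seq_along(alpha)) {
    g <- alpha[p] + alpha[q]
    s <- s + coef[p] * coef[q] * (pi / g)^1.5 * f / (2 * g)^L
  }
  s
}

#' Build a Gaussian basis for a molecule
#'
#' @param elements character vector of element symbols (H, O, Ca supported)
#' @param coords_bohr n x 3 matrix of positions in Bohr
#' @return basis object: list with ijk (nbf x 3), center (nbf x 3, Bohr),
#'   atom (nbf), prim_start (nbf+1, 0-based), alpha, coef, and a label per bf
#' @keywords internal
build_basis <- function(elements, coords_bohr, extra_shells = NULL) {
  ijk_l <- list(); cen_l <- list(); atom_l <- c(); labels <- c()
  alpha <- c(); coef <- c(); pstart <- 0L
  add_bf <- function(ijk, center, atom, a, c_raw, label) {
    np <- .prim_norm
    cc <- c_raw * vapply(a, np, 0, ijk = ijk)
    s <- .contr_self_overlap(a, cc, ijk)
    cc <- cc / sqrt(s)
    ijk_l[[length(ijk_l) + 1L]] <<- ijk
    cen_l[[length(cen_l) + 1L]] <<- center
    atom_l <<- c(atom_l, atom)
    labels <<- c(labels, label)
    alpha <<- c(alpha, a)
    coef <<- c(coef, cc)
    pstart <<- c(pstart, pstart[length(pstart)] + length(a))
  }
  for (ia in seq_along(elements)) {
    shells <- .element_shells(elements[ia])
    if (!is.null(extra_shells[[elements[ia]]]))
      shells <- c(shells, extra_shells[[elements[ia]]])
    for (sh in shells) {
      comps <- .cart_components(sh$l)
      for (r in seq_len(nrow(comps)))
        add_bf(comps[r, ], coords_bohr[ia, ], ia, sh$alpha,
               rep(sh$coef, length.out = length(sh$alpha)),
               sprintf("%s%d l%d", elements[ia], ia, sh$l))
    }
  }
  list(ijk = do.call(rbind, ijk_l), center = do.call(rbind, cen_l),
       atom = atom_l, prim_start = as.integer(pstart),
       alpha = alpha, coef = coef, label = labels,
       n = length(atom_l))
}
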