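# Hybrid density-functional layer on top of the Hartree-Fock engine:
# Becke-partitioned atom-centered quadrature grid, Slater/VWN5/B88/LYP
# functionals combined B3LYP-style, and a restricted Kohn-Sham SCF.
# Exchange-correlation potentials are obtained by finite differences of the
# energy density (the functionals are smooth; relative steps of 1e-6 give
# potentials far more accurate than the SCF convergence threshold).

# ---- quadrature grid --------------------------------------------------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  bet <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- bet
  J[cbind(k + 1, k)] <- bet
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(x = ev$values[ord], w = 2 * ev$vectors[1, ord]^2)
}

# map radius scale per element (bohr); controls radial point placement only
.radial_scale <- function(element) {
  r_A <- c(H = 0.35, He = 0.30, O = 0.60, Ca = 1.80)
  r <- r_A[element]
  r[is.na(r)] <- 0.8
  unname(r / 0.529177210903)
}

# one atomic grid: Gauss-Chebyshev (2nd kind) radial shells mapped by
# r = rm (1+x)/(1-x), product Gauss-Legendre x uniform-phi angular shells,
# pruned near the nucleus
.atomic_grid <- function(rm, n_rad = 50, n_theta = 10) {
  i <- seq_len(n_rad)
  x <- cos(i * pi / (n_rad + 1))
  wgc <- pi / (n_rad + 1) * sin(i * pi / (n_rad + 1))^2
  r <- rm * (1 + x) / (1 - x)
  drdx <- 2 * rm / (1 - x)^2
  w_rad <- wgc / sqrt(1 - x^2) * drdx * r^2
  pts <- list(); wts <- list()
  for (s in seq_len(n_rad)) {
    nt <- if (r[s] < 0.25 * rm) 4L else if (r[s] < 1.0 * rm) 8L else n_theta
    gl <- .gauss_legendre(nt)
    nphi <- 2L * nt
    phi <- 2 * pi * (seq_len(nphi) - 1) / nphi
    ct <- rep(gl$x, each = nphi)
    st <- sqrt(pmax(0, 1 - ct^2))
    pp <- cbind(r[s] * st * cos(rep(phi, nt)), r[s] * st * sin(rep(phi, nt)),
                r[s] * ct)
    ww <- w_rad[s] * rep(gl$w, each = nphi) * (2 * pi / nphi)
    pts[[s]] <- pp; wts[[s]] <- ww
  }
  list(points = do.call(rbind, pts), weights = unlist(wts))
}

# Becke's smooth Voronoi partition weight (k = 3 iterations)
.becke_s <- function(mu) {
  p <- mu
  for (k in 1:3) p <- 1.5 * p - 0.5 * p^3
  0.5 * (1 - p)
}

#' Molecular quadrature grid (Becke partitioning)
#'
#' Atom-centered radial x angular product grids with Becke's fuzzy-cell
#' weights, used for exchange-correlation quadrature.
#'
#' @param mol [qc_molecule()]
#' @param n_rad radial shells per atom
#' @param n_theta polar nodes of the outer angular shells (azimuthal count
#'   is twice that)
#' @return list(points (n x 3, Bohr), weights (n), n)
#' @export
becke_grid <- function(mol, n_rad = 50, n_theta = 10) {
  coords <- mol$coords
  natom <- nrow(coords)
  rms <- .radial_scale(mol$elements)
  all_pts <- list(); all_w <- list()
  for (a in seq_len(natom)) {
    g <- .atomic_grid(rms[a], n_rad, n_theta)
    pp <- sweep(g$points, 2, coords[a, ], "+")
    if (natom > 1) {
      d <- vapply(seq_len(natom), function(b)
        sqrt((pp[, 1] - coords[b, 1])^2 + (pp[, 2] - coords[b, 2])^2 +
               (pp[, 3] - coords[b, 3])^2), numeric(nrow(pp)))
      P <- matrix(1, nrow(pp), natom)
      for (i in seq_len(natom)) for (j in seq_len(natom)) {
        if (i == j) next
        Rij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        P[, i] <- P[, i] * .becke_s((d[, i] - d[, j]) / Rij)
      }
      wb <- P[, a] / rowSums(P)
      w <- g$weights * wb
    } else w <- g$weights
    keep <- w > 1e-14
    all_pts[[a]] <- pp[keep, , drop = FALSE]
    all_w[[a]] <- w[keep]
  }
  pts <- do.call(rbind, all_pts)
  list(points = pts, weights = unlist(all_w), n = nrow(pts))
}

# ---- exchange-correlation functionals (closed shell) ------------------------
# inputs: total density rho (> 0) and gamma = |grad rho|^2; output: energy
# density per volume (Hartree / bohr^3)

.f_x_slater <- function(rho, gamma) {
  -(3 / 4) * (3 / pi)^(1 / 3) * rho^(4 / 3)
}

# Becke 1988 gradient correction to exchange (correction only, no LDA part)
.f_x_b88 <- function(rho, gamma) {
  beta <- 0.0042
  rs <- rho / 2
  xs <- sqrt(gamma) / 2 / rs^(4 / 3)
  -2 * beta * rs^(4 / 3) * xs^2 / (1 + 6 * beta * xs * asinh(xs))
}

# VWN parametrization V (paramagnetic) of the LSDA correlation energy
.f_c_vwn5 <- function(rho, gamma) {
  A <- 0.0310907; b <- 3.72744; c <- 12.9352; x0 <- -0.10498
  rs <- (3 / (4 * pi * rho))^(1 / 3)
  x <- sqrt(rs)
  X <- x^2 + b * x + c
  X0 <- x0^2 + b * x0 + c
  Q <- sqrt(4 * c - b^2)
  ec <- A * (log(x^2 / X) + 2 * b / Q * atan(Q / (2 * x + b)) -
               b * x0 / X0 * (log((x - x0)^2 / X) +
                                2 * (b + 2 * x0) / Q * atan(Q / (2 * x + b))))
  rho * ec
}

# Lee-Yang-Parr correlation (Miehlich et al. reformulation), closed shell
.f_c_lyp <- function(rho, gamma) {
  a <- 0.04918; b <- 0.132; c <- 0.2533; d <- 0.349
  cf <- 0.3 * (3 * pi^2)^(2 / 3)
  r13 <- rho^(-1 / 3)
  den <- 1 + d * r13
  om <- exp(-c * r13) / den * rho^(-11 / 3)
  del <- c * r13 + d * r13 / den
  ra <- rho / 2; rb <- rho / 2
  gaa <- gamma / 4; gbb <- gamma / 4; gab <- gamma / 4
  term <- ra * rb * (2^(11 / 3) * cf * (ra^(8 / 3) + rb^(8 / 3)) +
                       (47 / 18 - 7 * del / 18) * gamma -
                       (5 / 2 - del / 18) * (gaa + gbb) -
                       (del - 11) / 9 * (ra * gaa + rb * gbb) / rho) -
    2 / 3 * rho^2 * gamma +
    (2 / 3 * rho^2 - ra^2) * gbb + (2 / 3 * rho^2 - rb^2) * gaa
  -a * 4 * ra * rb / (rho * den) - a * b * om * term
}

# combined B3LYP-style energy density (VWN5 variant); the 0.20 exact-exchange
# admixture is handled in the SCF, not here
.f_b3lyp_dft <- function(rho, gamma) {
  0.80 * .f_x_slater(rho, gamma) + 0.72 * .f_x_b88(rho, gamma) +
    0.19 * .f_c_vwn5(rho, gamma) + 0.81 * .f_c_lyp(rho, gamma)
}

XC_FUNCTIONALS <- list(
  b3lyp = list(f = function(rho, gamma) .f_b3lyp_dft(rho, gamma), hfx = 0.20),
  blyp = list(f = function(rho, gamma)
    .f_x_slater(rho, gamma) + .f_x_b88(rho, gamma) + .f_c_lyp(rho, gamma),
    hfx = 0),
  svwn = list(f = function(rho, gamma)
    .f_x_slater(rho, gamma) + .f_c_vwn5(rho, gamma), hfx = 0)
)

# energy density + finite-difference potentials on the grid
.xc_eval <- function(fxc, rho, gamma) {
  eps <- rho > 1e-11
  f <- vr <- vg <- numeric(length(rho))
  r <- rho[eps]; g <- pmax(gamma[eps], 1e-30)
  f[eps] <- fxc(r, g)
  hr <- 1e-6 * r
  vr[eps] <- (fxc(r + hr, g) - fxc(r - hr, g)) / (2 * hr)
  hg <- 1e-6 * g
  vg[eps] <- (fxc(r, g + hg) - fxc(r, g - hg)) / (2 * hg)
  list(f = f, vrho = vr, vgamma = vg)
}
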