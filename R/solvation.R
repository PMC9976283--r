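#' Ion occupancy profile along the pore axis
#'
#' Accumulates ion positions over frames into axial bins (1D) or
#' axial-radial bins (2D, r measured from the pore axis x = y = 0, an
#' azimuthal average of the planar occupancy map). Number density uses the
#' true bin volume: for 1D bins the lateral cross-section is the box area or,
#' if \code{lateral_radius} is given, the cylinder cross-section; 2D bins are
#' annular shells.
#'
#' @param traj trajectory
#' @param ion_selection roles or atom row indices
#' @param z_edges axial bin edges (Angstrom), increasing
#' @param r_edges optional radial bin edges for 2D mode (Angstrom, from 0)
#' @param lateral_radius optional cylinder radius restricting counted ions
#'   (and setting the 1D bin cross-section)
#' @param temperature K, used by [boltzmann_invert()]
#' @return object of class \code{occupancy_profile}: bin edges/centers,
#'   counts, n_frames, density (A^-3), concentration (mol/L) and
#'   relative occupancy (density / max density)
#' @export
occupancy <- function(traj, ion_selection = "ion", z_edges,
                      r_edges = NULL, lateral_radius = NULL,
                      temperature = 303) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- if (is.numeric(ion_selection)) as.integer(ion_selection)
         else select_atoms(traj, ion_selection)
  if (!length(idx)) stop("empty ion selection")
  if (length(z_edges) < 2 || any(diff(z_edges) <= 0))
    stop("z_edges must be increasing with >= 2 values")
  nf <- n_frames(traj)
  z <- as.vector(traj$coords[, idx, 3])
  x <- as.vector(traj$coords[, idx, 1])
  y <- as.vector(traj$coords[, idx, 2])
  r <- sqrt(x^2 + y^2)
  keep <- rep(TRUE, length(z))
  if (!is.null(lateral_radius)) keep <- r <= lateral_radius
  area <- if (!is.null(lateral_radius)) pi * lateral_radius^2 else
    traj$box[1, 1] * traj$box[1, 2]
  dz <- diff(z_edges)
  if (is.null(r_edges)) {
    counts <- .bin_count_1d(z[keep], z_edges)
    vol <- area * dz
    if (any(vol <= 0)) stop("zero-volume bin")
    density <- counts / (nf * vol)
    dims <- list(z_centers = z_edges[-length(z_edges)] + dz / 2)
  } else {
    if (length(r_edges) < 2 || any(diff(r_edges) <= 0) || r_edges[1] < 0)
      stop("r_edges must be increasing, starting at >= 0")
    iz <- findInterval(z[keep], z_edges, rightmost.closed = TRUE)
    ir <- findInterval(r[keep], r_edges, rightmost.closed = TRUE)
    nzb <- length(z_edges) - 1L; nrb <- length(r_edges) - 1L
    ok <- iz >= 1 & iz <= nzb & ir >= 1 & ir <= nrb
    counts <- matrix(0, nzb, nrb)
    if (any(ok)) {
      tb <- table(factor(iz[ok], levels = 1:nzb), factor(ir[ok], levels = 1:nrb))
      counts <- matrix(as.numeric(tb), nzb, nrb)
    }
    shell_area <- pi * diff(r_edges^2)
    vol <- outer(dz, shell_area)
    if (any(vol <= 0)) stop("zero-volume bin")
    density <- counts / (nf * vol)
    dims <- list(z_centers = z_edges[-length(z_edges)] + dz / 2,
                 r_centers = r_edges[-length(r_edges)] + diff(r_edges) / 2)
  }
  structure(c(list(z_edges = z_edges, r_edges = r_edges, counts = counts,
                   n_frames = nf, density = density,
                   concentration = .density_to_molar(density),
                   relative = if (max(density) > 0) density / max(density)
                              else density,
                   free_energy_kT = NULL, free_energy_kJmol = NULL,
                   temperature = temperature), dims),
            class = "occupancy_profile")
}

.bin_count_1d <- function(v, edges) {
  i <- findInterval(v, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  tabulate(i[i >= 1 & i <= nb], nbins = nb)
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("occupancy_profile: %s, %d frames, %d ion samples\n",
              if (is.null(x$r_edges)) sprintf("%d z-bins", length(x$z_centers))
              else sprintf("%d x %d (z, r) bins", length(x$z_centers),
                           length(x$r_centers)),
              x$n_frames, sum(x$counts)))
  if (!is.null(x$free_energy_kT))
    cat(sprintf("  free energy filled (min 0, max %.3g kT)\n",
                max(x$free_energy_kT, na.rm = TRUE)))
  invisible(x)
}

#' Boltzmann inversion of an occupancy profile
#'
#' Fills the free-energy fields: F = -kT * ln(rho / rho_ref) with the
#' reference density taken as the most occupied bin, so the minimum over
#' occupied bins is exactly zero. Empty bins are left undefined (NA), not
#' infinite.
#'
#' @param profile \code{occupancy_profile}
#' @param temperature K (default: the profile's)
#' @return the profile with \code{free_energy_kT} and
#'   \code{free_energy_kJmol} filled
#' @export
boltzmann_invert <- function(profile, temperature = NULL) {
  stopifnot(inherits(profile, "occupancy_profile"))
  if (is.null(temperature)) temperature <- profile$temperature
  rho <- profile$density
  if (all(rho <= 0)) stop("all-empty profile: cannot invert")
  f <- ifelse(rho > 0, -log(rho / max(rho)), NA_real_)
  profile$free_energy_kT <- f
  profile$free_energy_kJmol <- f * permeonics_constants(temperature)$kT_kJmol
  profile$temperature <- temperature
  profile
}

#' Radial distribution function and running coordination number
#'
#' g(r) between center atoms (typically the permeant ion) and partner atoms
#' (typically water oxygens), with minimum-image distances in the
#' orthorhombic box. Optionally conditions on frames where the center lies
#' in an axial window (to probe solvation at a given pore depth). The
#' running coordination number n(r) is the mean partner count within r
#' obtained by direct counting, not by integrating g.
#'
#' The reference density defaults to (partner count) / (box volume); inside
#' a confined pore this is not a bulk density, so g(r) plateaus need not be
#' 1 there.
#'
#' @param traj trajectory
#' @param center_selection,partner_selection roles or atom row indices
#' @param r_max maximal distance (Angstrom), must be < half the smallest box
#'   edge
#' @param dr shell width (Angstrom)
#' @param condition_window optional c(zmin, zmax): only (frame, center)
#'   samples with center z inside the window contribute
#' @param reference_density override the normalization density (A^-3)
#' @return object of class \code{rdf_result}: r_edges, r_centers, g,
#'   n_running, reference_density, n_samples
#' @export
rdf <- function(traj, center_selection = "ion", partner_selection = "water_O",
                r_max, dr, condition_window = NULL,
                reference_density = NULL) {
  stopifnot(inherits(traj, "trajectory"), dr > 0, r_max > dr)
  ci <- if (is.numeric(center_selection)) as.integer(center_selection)
        else select_atoms(traj, center_selection)
  pi_ <- if (is.numeric(partner_selection)) as.integer(partner_selection)
         else select_atoms(traj, partner_selection)
  if (!length(ci)) stop("empty center selection")
  if (!length(pi_)) stop("empty partner selection")
  box <- traj$box[1, ]
  if (r_max >= min(box) / 2)
    stop("r_max must be below half the smallest box edge (",
         sprintf("%.3g", min(box) / 2), " A)")
  edges <- seq(0, r_max, by = dr)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  hist_counts <- numeric(nb)
  n_samples <- 0L
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    P <- traj$coords[f, pi_, , drop = FALSE]
    dim(P) <- c(length(pi_), 3)
    for (c1 in ci) {
      zc <- traj$coords[f, c1, 3]
      if (!is.null(condition_window) &&
          (zc < condition_window[1] || zc > condition_window[2])) next
      p0 <- traj$coords[f, c1, ]
      dist <- .mi_dist(p0, P, traj$box[f, ])
      dist <- dist[dist > 1e-9]  # exclude self if center is also a partner
      hist_counts <- hist_counts + .bin_count_1d(dist[dist <= r_max], edges)
      n_samples <- n_samples + 1L
    }
  }
  if (n_samples == 0L)
    stop("no (frame, center) samples satisfy the conditioning window")
  if (is.null(reference_density))
    reference_density <- length(pi_) / prod(box)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- hist_counts / (n_samples * shell_vol * reference_density)
  structure(list(r_edges = edges, r_centers = edges[-length(edges)] + diff(edges) / 2,
                 g = g, n_running = cumsum(hist_counts) / n_samples,
                 reference_density = reference_density, n_samples = n_samples),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("rdf_result: %d shells to %.3g A, %d samples; g peak %.3g at %.3g A\n",
              length(x$g), max(x$r_edges), x$n_samples, x$g[pk], x$r_centers[pk]))
  invisible(x)
}

#' Count coordinating partners within a cutoff
#'
#' Number of partner atoms within \code{cutoff} (closed boundary: a partner
#' exactly at the cutoff counts) of the center atom, using minimum-image
#' distances when the frame has a box.
#'
#' @param frame md_frame
#' @param center either an atom_id present in the frame or a length-3
#'   position
#' @param partner_selection roles (default water_O) or atom row indices
#' @param cutoff Angstrom
#' @return integer count
#' @export
coordination_count <- function(frame, center, partner_selection = "water_O",
                               cutoff = 3.2) {
  stopifnot(inherits(frame, "md_frame"), cutoff > 0)
  at <- frame$atoms
  if (length(center) == 1L) {
    row <- match(center, at$atom_id)
    if (is.na(row)) stop("center atom_id ", center, " not in frame")
    p0 <- c(at$x[row], at$y[row], at$z[row])
    self <- row
  } else {
    p0 <- as.numeric(center); self <- 0L
  }
  pi_ <- if (is.numeric(partner_selection)) as.integer(partner_selection)
         else which(at$role %in% partner_selection)
  pi_ <- setdiff(pi_, self)
  if (!length(pi_)) return(0L)
  d <- .mi_dist(p0, cbind(at$x[pi_], at$y[pi_], at$z[pi_]), frame$box)
  sum(d <= cutoff)
}

#' Hydration and protein-contact statistics along the pore axis
#'
#' For every (frame, ion) sample: the number of water oxygens within
#' \code{water_cutoff} and the number of distinct protein residues
#' (molecule_ids) with at least one oxygen within \code{protein_cutoff}.
#' Samples are binned by the ion's axial position; the profile reports the
#' mean and sample sd per bin (NA where a bin has no samples).
#'
#' @param traj trajectory
#' @param ion_selection roles or atom row indices
#' @param z_edges axial bin edges (Angstrom)
#' @param water_cutoff,protein_cutoff Angstrom (defaults 3.2, the first
#'   solvation-shell boundary beyond the 2.4 A contact peak)
#' @return object of class \code{hydration_profile}: data.frame with
#'   z_center, n (samples), water_mean, water_sd, protein_mean, protein_sd
#' @export
hydration_profile <- function(traj, ion_selection = "ion", z_edges,
                              water_cutoff = 3.2, protein_cutoff = 3.2) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- if (is.numeric(ion_selection)) as.integer(ion_selection)
         else select_atoms(traj, ion_selection)
  if (!length(idx)) stop("empty ion selection")
  if (length(z_edges) < 2 || any(diff(z_edges) <= 0))
    stop("z_edges must be increasing")
  wat <- select_atoms(traj, "water_O")
  prot_o <- which(traj$atoms$role == "protein" & traj$atoms$element == "O")
  nb <- length(z_edges) - 1L
  bin_of <- function(z) {
    i <- findInterval(z, z_edges, rightmost.closed = TRUE)
    ifelse(i >= 1 & i <= nb, i, NA_integer_)
  }
  samples <- list()
  for (f in seq_len(n_frames(traj))) {
    box <- traj$box[f, ]
    W <- traj$coords[f, wat, , drop = FALSE]; dim(W) <- c(length(wat), 3)
    P <- traj$coords[f, prot_o, , drop = FALSE]; dim(P) <- c(length(prot_o), 3)
    for (ii in idx) {
      p0 <- traj$coords[f, ii, ]
      b <- bin_of(p0[3])
      if (is.na(b)) next
      nw <- if (length(wat)) sum(.mi_dist(p0, W, box) <= water_cutoff) else 0L
      np <- if (length(prot_o)) {
        close <- .mi_dist(p0, P, box) <= protein_cutoff
        length(unique(traj$atoms$molecule_id[prot_o[close]]))
      } else 0L
      samples[[length(samples) + 1L]] <- c(b, nw, np)
    }
  }
  zc <- z_edges[-length(z_edges)] + diff(z_edges) / 2
  out <- data.frame(z_center = zc, n = 0L, water_mean = NA_real_,
                    water_sd = NA_real_, protein_mean = NA_real_,
                    protein_sd = NA_real_)
  if (length(samples)) {
    S <- do.call(rbind, samples)
    for (b in unique(S[, 1])) {
      sel <- S[, 1] == b
      out$n[b] <- sum(sel)
      out$water_mean[b] <- mean(S[sel, 2])
      out$water_sd[b] <- if (sum(sel) > 1) stats::sd(S[sel, 2]) else NA_real_
      out$protein_mean[b] <- mean(S[sel, 3])
      out$protein_sd[b] <- if (sum(sel) > 1) stats::sd(S[sel, 3]) else NA_real_
    }
  }
  class(out) <- c("hydration_profile", "data.frame")
  out
}
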