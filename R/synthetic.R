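#' Define a one-dimensional pore model for Brownian-dynamics simulation
#'
#' The model abstracts a cation channel as a sequence of Gaussian binding
#' wells along the pore axis plus a constant transmembrane field, sampled by
#' overdamped Langevin dynamics. Ions interact through a screened repulsion,
#' which is sufficient to produce loosely coupled knock-on conduction
#' (an ion's exit from the filter promotes the next ion's entry).
#'
#' Defaults emulate the simulated study conditions: divalent ions (+2 e),
#' 600 mV transmembrane voltage, 303 K, two principal binding sites
#' bracketing the filter.
#'
#' @param span [channel_span()] of the filter region
#' @param well_positions axial well positions (Angstrom)
#' @param well_depths well depths in kT (>= 0, one per well)
#' @param well_width Gaussian width sigma of the wells (Angstrom)
#' @param voltage transmembrane voltage (V), field E = voltage / box_z along +z
#' @param diffusion_coeff ion diffusion coefficient (A^2/ns)
#' @param ion_charge e
#' @param n_ions number of permeant ions
#' @param coupling_strength screened-repulsion prefactor A (kT * Angstrom);
#'   pair energy A * exp(-d/lambda) / d
#' @param screening_length lambda (Angstrom)
#' @param box orthorhombic box (Angstrom); z in [-box_z/2, box_z/2)
#' @param lateral_radius reflecting cylinder radius for lateral diffusion
#' @param temperature K
#' @param seed integer RNG seed
#' @return object of class \code{pore_model}
#' @export
pore_model <- function(span = channel_span(-10, 10),
                       well_positions = c(-5, 5),
                       well_depths = c(4, 4),
                       well_width = 1.5,
                       voltage = 0.6,
                       diffusion_coeff = 50,
                       ion_charge = 2,
                       n_ions = 1,
                       coupling_strength = 0,
                       screening_length = 3,
                       box = c(40, 40, 70),
                       lateral_radius = 4,
                       temperature = 303,
                       seed = 1) {
  if (length(well_depths) != length(well_positions))
    stop("well_depths and well_positions lengths differ")
  if (any(well_depths < 0)) stop("well_depths must be >= 0")
  if (diffusion_coeff <= 0) stop("diffusion_coeff must be positive")
  structure(as.list(environment()), class = "pore_model")
}

# axial force (kT/A) from wells + field at positions z (vectorized)
.pore_force <- function(z, model) {
  f <- rep(model$voltage / model$box[3] *
             permeonics_constants(model$temperature)$eV_kT * model$ion_charge,
           length(z))
  for (k in seq_along(model$well_positions)) {
    dz <- z - model$well_positions[k]
    f <- f - model$well_depths[k] * dz / model$well_width^2 *
      exp(-dz^2 / (2 * model$well_width^2))
  }
  f
}

#' Simulate an ion trajectory through the pore model
#'
#' Overdamped Langevin dynamics along z:
#' dz = D/kT * F(z) dt + sqrt(2 D dt) * eta, with F the well + field force
#' and the pairwise screened repulsion between ions (minimum-image along z).
#' Ions wrap periodically along z (the bulk reservoirs recycle permeated
#' ions) and diffuse laterally inside a reflecting cylinder. One frame is
#' recorded per step. Deterministic under the model's seed.
#'
#' @param model [pore_model()]
#' @param n_frames number of steps/frames
#' @param dt time step (ns); must satisfy sqrt(2 D dt) < well_width / 4 when
#'   wells are present (otherwise an error suggests a suitable dt)
#' @return a \code{trajectory} of \code{n_ions} ions
#' @export
gen_pore_trajectory <- function(model, n_frames, dt) {
  stopifnot(inherits(model, "pore_model"), n_frames >= 1, dt > 0)
  D <- model$diffusion_coeff
  step_sd <- sqrt(2 * D * dt)
  if (length(model$well_positions) && any(model$well_depths > 0) &&
      step_sd >= model$well_width / 4)
    stop(sprintf(
      "unstable dt: step sd %.3g A >= well_width/4 = %.3g A; use dt <= %.3g ns",
      step_sd, model$well_width / 4, (model$well_width / 4)^2 / (2 * D)))
  set.seed(model$seed)
  n <- model$n_ions
  Lz <- model$box[3]
  wrap_z <- function(z) z - Lz * round(z / Lz)
  z <- runif(n, -Lz / 2, Lz / 2)
  # start ions in the bulk, away from the span
  lo <- model$span$z_lower; hi <- model$span$z_upper
  z[z > lo & z < hi] <- wrap_z(hi + (z[z > lo & z < hi] - lo))
  xy <- matrix(0, n, 2)
  coords <- array(NA_real_, c(n_frames, n, 3))
  A <- model$coupling_strength; lam <- model$screening_length
  for (f in seq_len(n_frames)) {
    fz <- .pore_force(z, model)
    if (A > 0 && n > 1) {
      for (i in seq_len(n)) {
        dzj <- wrap_z(z[i] - z[-i])
        dxy <- sweep(xy[-i, , drop = FALSE], 2, xy[i, ], "-")
        d <- sqrt(dzj^2 + rowSums(dxy^2))
        d <- pmax(d, 0.5)
        fmag <- A * exp(-d / lam) * (1 / d^2 + 1 / (lam * d))
        fz[i] <- fz[i] + sum(fmag * dzj / d)
      }
    }
    z <- wrap_z(z + D * dt * fz + step_sd * rnorm(n))
    xy <- xy + step_sd * matrix(rnorm(2 * n), n, 2)
    r <- sqrt(rowSums(xy^2))
    over <- r > model$lateral_radius
    if (any(over))  # reflect off the cylinder wall
      xy[over, ] <- xy[over, , drop = FALSE] *
        (2 * model$lateral_radius - r[over]) / r[over]
    coords[f, , 1:2] <- xy
    coords[f, , 3] <- z
  }
  atoms <- data.frame(atom_id = seq_len(n), element = "Ca", role = "ion",
                      molecule_id = seq_len(n), stringsAsFactors = FALSE)
  new_trajectory(atoms, coords, seq_len(n_frames) * dt - dt, model$box)
}

#' Ideal-gas trajectory: uniform i.i.d. positions per frame
#'
#' @param n_atoms number of atoms
#' @param box length-3 box (Angstrom)
#' @param n_frames frames
#' @param seed RNG seed
#' @param element,role atom tagging (defaults "O" / "water_O" so the atoms
#'   are selectable as RDF partners)
#' @return a \code{trajectory}
#' @export
gen_ideal_gas <- function(n_atoms, box, n_frames, seed = 1,
                          element = "O", role = "water_O") {
  set.seed(seed)
  coords <- array(runif(n_frames * n_atoms * 3), c(n_frames, n_atoms, 3))
  for (k in 1:3) coords[, , k] <- coords[, , k] * box[k] - box[k] / 2
  atoms <- data.frame(atom_id = seq_len(n_atoms), element = element,
                      role = role, molecule_id = seq_len(n_atoms),
                      stringsAsFactors = FALSE)
  new_trajectory(atoms, coords, seq_len(n_frames) - 1, box)
}

# near-optimal unit direction sets for n coordinating ligands
.sphere_directions <- function(n) {
  s <- 1 / sqrt(2)
  switch(as.character(n),
         "1" = rbind(c(0, 0, 1)),
         "2" = rbind(c(0, 0, 1), c(0, 0, -1)),
         "3" = rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
         "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
         "5" = rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                     c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0)),
         "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1)),
         "7" = {  # pentagonal bipyramid
           th <- 2 * pi * (0:4) / 5
           rbind(c(0, 0, 1), c(0, 0, -1), cbind(cos(th), sin(th), 0))
         },
         "8" = {  # square antiprism at the max-min-distance latitude
           r8 <- sqrt(4 / (4 + sqrt(2))); h8 <- sqrt(1 - r8^2)
           th1 <- 2 * pi * (0:3) / 4; th2 <- th1 + pi / 4
           rbind(cbind(r8 * cos(th1), r8 * sin(th1), h8),
                 cbind(r8 * cos(th2), r8 * sin(th2), -h8))
         },
         stop("supported coordination numbers are 1..8"))
}

.perp_unit <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  w / sqrt(sum(w^2))
}

#' Hydrated-ion cluster geometry
#'
#' Builds a Ca(2+)(H2O)n cluster: the ion at the origin, water oxygens on a
#' near-optimal spherical arrangement at the given distance, each water
#' oriented with its oxygen toward the ion and hydrogens outward (the
#' favorable dipole orientation for cation coordination). Water internal
#' geometry: r(OH) = 0.9572 A, HOH angle 104.52 degrees.
#'
#' @param n_waters 1..8 coordinating waters
#' @param ca_o_distance ion-oxygen distance (Angstrom, default 2.4, the
#'   first-shell contact distance)
#' @param jitter Gaussian positional noise sd (Angstrom) applied to all
#'   atoms; 0 gives a bitwise-reproducible geometry
#' @param seed RNG seed (used only when jitter > 0)
#' @param ion_element ion symbol (default "Ca")
#' @return an \code{md_frame} (no box; isolated cluster), molecule 1 = ion,
#'   molecules 2..n+1 = waters
#' @export
gen_cluster_geometry <- function(n_waters, ca_o_distance = 2.4, jitter = 0,
                                 seed = 1, ion_element = "Ca") {
  stopifnot(n_waters >= 1)
  dirs <- .sphere_directions(n_waters)
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rows <- list(data.frame(atom_id = 1L, element = ion_element, role = "ion",
                          molecule_id = 1L, x = 0, y = 0, z = 0,
                          stringsAsFactors = FALSE))
  aid <- 1L
  for (w in seq_len(n_waters)) {
    u <- dirs[w, ]
    o <- u * ca_o_distance
    v <- .perp_unit(u)
    h1 <- o + r_oh * (cos(half) * u + sin(half) * v)
    h2 <- o + r_oh * (cos(half) * u - sin(half) * v)
    rows[[w + 1L]] <- data.frame(
      atom_id = aid + 1:3,
      element = c("O", "H", "H"),
      role = c("water_O", "water_H", "water_H"),
      molecule_id = w + 1L,
      x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
      z = c(o[3], h1[3], h2[3]), stringsAsFactors = FALSE)
    aid <- aid + 3L
  }
  at <- do.call(rbind, rows)
  if (jitter > 0) {
    set.seed(seed)
    at$x <- at$x + rnorm(nrow(at), 0, jitter)
    at$y <- at$y + rnorm(nrow(at), 0, jitter)
    at$z <- at$z + rnorm(nrow(at), 0, jitter)
  }
  new_frame(at, box = NULL, time = 0)
}

#' Analytic sum-of-Gaussians density grid
#'
#' Each component is an isotropic normalized Gaussian scaled by its electron
#' count, so the total integral is analytically the sum of electron counts.
#'
#' @param components list of \code{list(center, n_electrons, sigma)}
#' @param origin grid origin (Angstrom)
#' @param voxel length-3 voxel edges or a single spacing (Angstrom)
#' @param shape length-3 integer grid shape
#' @return a \code{density_grid} (no atoms attached)
#' @export
gen_gaussian_density <- function(components, origin, voxel, shape) {
  if (length(voxel) == 1) voxel <- rep(voxel, 3)
  shape <- as.integer(shape)
  vals <- array(0, shape)
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(shape[k]) - 1) * voxel[k])
  for (cmp in components) {
    s <- cmp$sigma
    if (s <= max(voxel))
      warning(sprintf("component sigma %.3g A <= voxel spacing: under-resolved",
                      s))
    amp <- cmp$n_electrons / ((2 * pi)^1.5 * s^3)
    gx <- exp(-(ax[[1]] - cmp$center[1])^2 / (2 * s^2))
    gy <- exp(-(ax[[2]] - cmp$center[2])^2 / (2 * s^2))
    gz <- exp(-(ax[[3]] - cmp$center[3])^2 / (2 * s^2))
    vals <- vals + amp * (gx %o% gy %o% gz)
  }
  new_density_grid(origin, voxel, vals)
}

#' Water + localized-center fixture with a prescribed dipole
#'
#' Places a single water (standard internal geometry) and four localized
#' centers - two on the O-H bond axes at a fixed distance from O, two lone
#' pairs symmetric about the molecular plane - with the lone-pair distance
#' solved so that [molecular_dipole()] returns the requested magnitude
#' along the bisector (inverting the valence point-charge dipole formula).
#'
#' @param target_dipole_D requested dipole magnitude in Debye
#' @param bond_center_dist bond-center distance from O along O-H (Angstrom)
#' @param lp_angle lone-pair polar angle from the anti-bisector axis (degrees)
#' @param r_oh,hoh_angle water internal geometry (Angstrom, degrees)
#' @return list(frame, centers): an \code{md_frame} with one water
#'   (molecule_id 1) and a 4 x 3 center matrix
#' @export
gen_wannier_fixture <- function(target_dipole_D, bond_center_dist = 0.5,
                                lp_angle = 54.7, r_oh = 0.9572,
                                hoh_angle = 104.52) {
  half <- hoh_angle / 2 * pi / 180
  gam <- lp_angle * pi / 180
  target_eA <- target_dipole_D / permeonics_constants()$debye_per_eA
  # mu_x = 2 r_oh cos(half) - 4 b cos(half) + 4 l cos(gam)  (e*A)
  l <- (target_eA - 2 * r_oh * cos(half) + 4 * bond_center_dist * cos(half)) /
    (4 * cos(gam))
  if (!is.finite(l) || l < 0 || l > 1.1)
    stop(sprintf(
      "infeasible target dipole %.3g D: lone-pair distance solves to %.3g A",
      target_dipole_D, l))
  o <- c(0, 0, 0)
  h1 <- r_oh * c(cos(half), sin(half), 0)
  h2 <- r_oh * c(cos(half), -sin(half), 0)
  b1 <- bond_center_dist * c(cos(half), sin(half), 0)
  b2 <- bond_center_dist * c(cos(half), -sin(half), 0)
  lp1 <- l * c(-cos(gam), 0, sin(gam))
  lp2 <- l * c(-cos(gam), 0, -sin(gam))
  at <- data.frame(atom_id = 1:3, element = c("O", "H", "H"),
                   role = c("water_O", "water_H", "water_H"),
                   molecule_id = 1L,
                   x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
                   z = c(o[3], h1[3], h2[3]), stringsAsFactors = FALSE)
  list(frame = new_frame(at), centers = rbind(b1, b2, lp1, lp2))
}

#' Knock-on coupling score: do filter entries promote exits?
#'
#' In knock-on conduction an ion's exit from the filter is tightly coupled
#' to another ion's entry: the newcomer's repulsion expels the occupant.
#' This statistic measures P(an ion exits the span through the top within
#' \code{lag} frames after an ion enters it from below). On its own the
#' value depends on occupancy bookkeeping, so the meaningful comparison is
#' against the same model without ion-ion coupling: a coupled pore in a
#' blocked regime (deep well, moderate voltage) shows a much larger value
#' than the uncoupled control.
#'
#' @param traj trajectory
#' @param span [channel_span()]
#' @param lag window length in frames
#' @param ion_selection roles or atom indices
#' @return list(p_exit_after_entry, p_exit_baseline (rate at uniformly
#'   placed reference windows), n_entries, n_exits)
#' @export
knockon_correlation <- function(traj, span, lag = 200, ion_selection = "ion") {
  idx <- if (is.numeric(ion_selection)) as.integer(ion_selection)
         else select_atoms(traj, ion_selection)
  nf <- n_frames(traj)
  box_z <- traj$box[1, 3]
  entry <- logical(nf); exit_top <- logical(nf)
  for (ii in idx) {
    z <- traj$coords[, ii, 3]
    st <- ifelse(z < span$z_lower, 1L, ifelse(z > span$z_upper, 3L, 2L))
    wrap <- c(FALSE, .wrap_jumps(z, box_z))
    entry <- entry | (c(0L, st[-nf]) == 1L & st == 2L & !wrap)
    exit_top <- exit_top | (c(0L, st[-nf]) == 2L & st == 3L & !wrap)
  }
  ent <- which(entry)
  ent <- ent[ent + lag <= nf]
  if (length(ent) < 5)
    stop("too few filter entries (", length(ent), ") to score coupling")
  p_ee <- mean(vapply(ent, function(f) any(exit_top[(f + 1):(f + lag)]), TRUE))
  ref <- as.integer(seq(1, nf - lag, length.out = min(2000, nf - lag)))
  p_base <- mean(vapply(ref, function(f) any(exit_top[(f + 1):(f + lag)]), TRUE))
  list(p_exit_after_entry = p_ee, p_exit_baseline = p_base,
       n_entries = length(ent), n_exits = sum(exit_top))
}
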