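#' Electron density difference between a complex and its fragments
#'
#' Computes the voxel-wise deformation density
#' drho = rho_complex - rho_ligand - rho_rest, where the three grids hold
#' the electron density of the full complex, of the isolated ion (ligand)
#' and of the complex without the ion (rest), all on the identical grid.
#' The atom list of the result is taken from the complex.
#'
#' @param complex,ligand,rest \code{density_grid} objects with identical
#'   origin, voxel vectors and shape (tolerance 1e-6 Angstrom)
#' @return a \code{density_grid} holding the signed difference density
#'   (positive = electron gain upon binding)
#' @export
density_difference <- function(complex, ligand, rest) {
  for (nm in c("complex", "ligand", "rest"))
    if (!inherits(get(nm), "density_grid")) stop(nm, " is not a density_grid")
  .check_congruent(complex, ligand, "ligand")
  .check_congruent(complex, rest, "rest")
  new_density_grid(complex$origin, complex$voxel,
                   complex$values - ligand$values - rest$values,
                   complex$atoms)
}

.check_congruent <- function(a, b, name, tol = 1e-6) {
  if (!identical(a$shape, b$shape))
    stop("grid mismatch: shape of ", name, " (",
         paste(b$shape, collapse = "x"), ") differs from complex (",
         paste(a$shape, collapse = "x"), ")")
  if (max(abs(a$origin - b$origin)) > tol)
    stop("grid mismatch: origin of ", name, " differs from complex")
  if (max(abs(a$voxel - b$voxel)) > tol)
    stop("grid mismatch: voxel vectors of ", name, " differ from complex")
}

#' Integrate a density grid over per-site Voronoi cells
#'
#' Every grid point is assigned to its nearest site (Euclidean distance,
#' ties broken by the lowest site index); the per-site integral is the sum
#' of assigned values times the voxel volume. The partition is exhaustive
#' and exclusive, so the per-site integrals sum exactly to the total grid
#' integral.
#'
#' @param grid density_grid
#' @param sites n x 3 matrix of site positions (Angstrom), or NULL to use
#'   the grid's atom positions
#' @return numeric vector of per-site integrals (electrons)
#' @export
voronoi_integrate <- function(grid, sites = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  if (is.null(sites)) {
    if (!nrow(grid$atoms)) stop("empty site list and grid has no atoms")
    sites <- cbind(grid$atoms$x, grid$atoms$y, grid$atoms$z)
  }
  sites <- as.matrix(sites)
  if (!nrow(sites)) stop("empty site list")
  if (ncol(sites) != 3) stop("sites must be an n x 3 matrix")
  assign_idx <- .nearest_site(grid, sites)
  v <- as.vector(grid$values)
  out <- numeric(nrow(sites))
  agg <- rowsum(v, group = assign_idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out * voxel_volume(grid)
}

# nearest-site index for every grid point; iterates sites in ascending order
# with strict improvement, so the lowest index wins exact ties
.nearest_site <- function(grid, sites) {
  pts <- grid_points(grid)
  n <- nrow(pts)
  best <- rep(1L, n)
  d2 <- (pts[, 1] - sites[1, 1])^2 + (pts[, 2] - sites[1, 2])^2 +
    (pts[, 3] - sites[1, 3])^2
  if (nrow(sites) > 1) for (s in 2:nrow(sites)) {
    ds <- (pts[, 1] - sites[s, 1])^2 + (pts[, 2] - sites[s, 2])^2 +
      (pts[, 3] - sites[s, 3])^2
    upd <- ds < d2
    best[upd] <- s
    d2[upd] <- ds[upd]
  }
  best
}

#' Per-atom charge transfer from a deformation density
#'
#' Integrates the density difference over per-atom Voronoi cells and
#' aggregates: per atom, per element and per molecule electron gains
#' (positive = electron gain). The ion's effective charge is its nominal
#' charge minus the electrons it gained. With a list of snapshot grids the
#' per-element and per-water statistics are averaged across snapshots and a
#' sample sd is reported.
#'
#' @param delta \code{density_grid} of the deformation density (atoms of the
#'   complex attached), or a list of such grids (snapshots)
#' @param ion_id atom_id of the ion in the grid atom table
#' @param nominal_charge ion charge in e (default +2)
#' @return object of class \code{charge_transfer_table}: per_atom (data.frame
#'   atom_id, element, molecule_id, dn_e), per_element (element, mean, sd),
#'   per_molecule (molecule_id, dn_e mean over snapshots),
#'   water_loss (mean electrons lost per water molecule, with sd across
#'   snapshots), effective_ion_charge, total_integral
#' @export
charge_transfer <- function(delta, ion_id, nominal_charge = 2) {
  grids <- if (inherits(delta, "density_grid")) list(delta) else delta
  if (!length(grids)) stop("no snapshots supplied")
  per_snap <- lapply(grids, .charge_transfer_one, ion_id = ion_id)
  elements <- per_snap[[1]]$per_atom$element
  el_mat <- do.call(rbind, lapply(per_snap, function(s)
    tapply(s$per_atom$dn_e, s$per_atom$element, sum)))
  ion_gain <- vapply(per_snap, function(s) s$ion_gain, 0)
  water_loss <- vapply(per_snap, function(s) s$water_loss_mean, 0)
  pa <- per_snap[[1]]$per_atom
  pa$dn_e <- rowMeans(vapply(per_snap, function(s) s$per_atom$dn_e,
                             numeric(nrow(pa))))
  pm <- aggregate(dn_e ~ molecule_id, data = pa, FUN = sum)
  structure(list(
    per_atom = pa,
    per_element = data.frame(
      element = colnames(el_mat),
      mean = colMeans(el_mat),
      sd = if (length(grids) > 1) apply(el_mat, 2, stats::sd) else NA_real_,
      row.names = NULL),
    per_molecule = pm,
    water_loss = mean(water_loss),
    water_loss_sd = if (length(grids) > 1) stats::sd(water_loss) else NA_real_,
    ion_gain = mean(ion_gain),
    effective_ion_charge = nominal_charge - mean(ion_gain),
    nominal_charge = nominal_charge,
    total_integral = mean(vapply(grids, grid_integral, 0)),
    n_snapshots = length(grids)), class = "charge_transfer_table")
}

.charge_transfer_one <- function(grid, ion_id) {
  at <- grid$atoms
  if (!nrow(at)) stop("grid carries no atoms")
  row <- match(ion_id, at$atom_id)
  if (is.na(row)) stop("ion atom_id ", ion_id, " not found in grid atoms")
  dn <- voronoi_integrate(grid)
  pa <- data.frame(atom_id = at$atom_id, element = at$element,
                   molecule_id = at$molecule_id, dn_e = dn)
  wat_mols <- unique(at$molecule_id[at$role %in% c("water_O", "water_H")])
  wl <- if (length(wat_mols)) {
    per_mol <- vapply(wat_mols, function(m) sum(dn[at$molecule_id == m]), 0)
    -mean(per_mol)
  } else NA_real_
  list(per_atom = pa, ion_gain = dn[row], water_loss_mean = wl)
}

#' @export
print.charge_transfer_table <- function(x, ...) {
  cat(sprintf("charge_transfer_table (%d snapshot%s)\n", x$n_snapshots,
              if (x$n_snapshots > 1) "s" else ""))
  cat(sprintf("  ion gain: %+.4f e -> effective charge %.3f e (nominal %g e)\n",
              x$ion_gain, x$effective_ion_charge, x$nominal_charge))
  if (!is.na(x$water_loss))
    cat(sprintf("  mean loss per water: %.4f e%s\n", x$water_loss,
                if (!is.na(x$water_loss_sd))
                  sprintf(" (sd %.4f)", x$water_loss_sd) else ""))
  cat("  per element (mean dn_e):\n")
  for (i in seq_len(nrow(x$per_element)))
    cat(sprintf("    %-2s %+ .4f%s\n", x$per_element$element[i],
                x$per_element$mean[i],
                if (!is.na(x$per_element$sd[i]))
                  sprintf(" +- %.4f", x$per_element$sd[i]) else ""))
  invisible(x)
}
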