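#' Construct a volumetric density grid
#'
#' Axis-aligned orthorhombic grid of scalar values (electron density, e/A^3)
#' plus the atom list the density belongs to. Grid point g(i,j,k) sits at
#' \code{origin + (i-1)*voxel[1]*ex + (j-1)*voxel[2]*ey + (k-1)*voxel[3]*ez}.
#'
#' @param origin length-3 origin (Angstrom)
#' @param voxel length-3 voxel edge lengths (Angstrom); axis-aligned
#' @param values numeric array \code{[nx, ny, nz]} in e/A^3
#' @param atoms data.frame (atom_id, element, role, molecule_id, x, y, z);
#'   may have zero rows
#' @return object of class \code{density_grid}
#' @export
new_density_grid <- function(origin, voxel, values, atoms = NULL) {
  stopifnot(length(origin) == 3L, length(voxel) == 3L)
  if (any(voxel <= 0)) stop("voxel edge lengths must be positive")
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  if (is.null(atoms))
    atoms <- data.frame(atom_id = integer(), element = character(),
                        role = character(), molecule_id = integer(),
                        x = numeric(), y = numeric(), z = numeric())
  structure(list(origin = as.numeric(origin), voxel = as.numeric(voxel),
                 shape = dim(values), values = values,
                 atoms = as.data.frame(atoms)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d x %d voxels of %.4g x %.4g x %.4g A, %d atoms\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel[1], x$voxel[2], x$voxel[3], nrow(x$atoms)))
  cat(sprintf("  integral = %.6g e\n", grid_integral(x)))
  invisible(x)
}

#' Volume of one voxel (A^3)
#' @param grid density_grid
#' @export
voxel_volume <- function(grid) prod(grid$voxel)

#' Integral of the grid values times the voxel volume (electrons)
#' @param grid density_grid
#' @export
grid_integral <- function(grid) sum(grid$values) * voxel_volume(grid)

#' Cartesian coordinates of all grid points
#' @param grid density_grid
#' @return n x 3 matrix, fastest index x (matching the values array layout)
#' @export
grid_points <- function(grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  cbind(rep(grid$origin[1] + (seq_len(nx) - 1) * grid$voxel[1], times = ny * nz),
        rep(rep(grid$origin[2] + (seq_len(ny) - 1) * grid$voxel[2], each = nx),
            times = nz),
        rep(grid$origin[3] + (seq_len(nz) - 1) * grid$voxel[3], each = nx * ny))
}

#' Read a Gaussian cube file
#'
#' Follows the cube standard: positive voxel counts signal Bohr units
#' (converted to Angstrom and e/A^3 internally), negative counts signal
#' Angstrom. Only axis-aligned (diagonal) voxel vectors are supported.
#'
#' @param path cube file
#' @param role_map rules for role assignment of the atom block
#' @return a \code{density_grid} with values in e/A^3 and coordinates in
#'   Angstrom
#' @export
read_cube <- function(path, role_map = default_role_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  num <- function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  h3 <- num(lines[3])
  natoms <- as.integer(h3[1])
  origin <- h3[2:4]
  vox <- matrix(0, 3, 4)
  for (k in 1:3) {
    v <- num(lines[3 + k])
    if (length(v) < 4) stop("cube parse error at line ", 3 + k)
    vox[k, ] <- v[1:4]
  }
  n <- as.integer(vox[, 1])
  bohr <- all(n > 0)
  n <- abs(n)
  vv <- vox[, 2:4, drop = FALSE]
  offdiag <- vv; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12))
    stop("unsupported grid: voxel vectors are not axis-aligned")
  voxel <- diag(vv)
  if (abs(natoms) > 0) {
    at_lines <- lines[7:(6 + abs(natoms))]
    am <- t(vapply(at_lines, function(l) num(l)[1:5], numeric(5)))
    zs <- as.integer(am[, 1])
    el <- names(ATOMIC_NUMBERS)[match(zs, ATOMIC_NUMBERS)]
    if (anyNA(el)) stop("cube atom block has unknown atomic number(s): ",
                        paste(zs[is.na(el)], collapse = ", "))
    apos <- am[, 3:5, drop = FALSE]
  } else {
    el <- character(); apos <- matrix(0, 0, 3)
  }
  vals <- scan(path, what = numeric(), skip = 6 + abs(natoms), quiet = TRUE)
  if (length(vals) != prod(n))
    stop("cube parse error: expected ", prod(n), " values, found ", length(vals))
  b <- permeonics_constants()$bohr_A
  if (bohr) {
    origin <- origin * b; voxel <- voxel * b; apos <- apos * b
    vals <- vals / b^3
  }
  # cube ordering: z fastest, x slowest -> array index [x, y, z]
  arr <- aperm(array(vals, dim = rev(n)), c(3, 2, 1))
  atoms <- if (length(el)) {
    rl <- .assign_roles_xyz(el, role_map)
    data.frame(atom_id = seq_along(el), element = el, role = rl$role,
               molecule_id = rl$molecule_id,
               x = apos[, 1], y = apos[, 2], z = apos[, 3],
               stringsAsFactors = FALSE)
  } else NULL
  new_density_grid(origin, voxel, arr, atoms)
}

#' Write a density grid as a Gaussian cube file (Bohr convention)
#'
#' @param grid density_grid (values e/A^3, coordinates Angstrom); written in
#'   Bohr / e per Bohr^3 with positive voxel counts, per the cube standard
#' @param path output path
#' @return invisibly, the path
#' @export
write_cube <- function(grid, path) {
  b <- permeonics_constants()$bohr_A
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("permeonics density grid", "electron density (e/bohr^3)"), con)
  o <- grid$origin / b
  writeLines(sprintf("%5d%16.9f%16.9f%16.9f", nrow(grid$atoms),
                     o[1], o[2], o[3]), con)
  for (k in 1:3) {
    v <- c(0, 0, 0); v[k] <- grid$voxel[k] / b
    writeLines(sprintf("%5d%16.9f%16.9f%16.9f", grid$shape[k],
                       v[1], v[2], v[3]), con)
  }
  if (nrow(grid$atoms)) {
    zs <- ATOMIC_NUMBERS[grid$atoms$element]
    if (anyNA(zs)) stop("atom element(s) without atomic number: ",
                        paste(grid$atoms$element[is.na(zs)], collapse = ", "))
    writeLines(sprintf("%5d%16.9f%16.9f%16.9f%16.9f", zs, as.numeric(zs),
                       grid$atoms$x / b, grid$atoms$y / b, grid$atoms$z / b),
               con)
  }
  # z fastest: emit values in cube order, 6 per line
  v <- aperm(grid$values, c(3, 2, 1)) * b^3
  v <- as.vector(v)
  nfull <- (length(v) %/% 6) * 6
  lines <- character(0)
  if (nfull > 0) {
    m <- matrix(sprintf("%20.11E", v[1:nfull]), ncol = 6, byrow = TRUE)
    lines <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  if (nfull < length(v))
    lines <- c(lines, paste0(sprintf("%20.11E", v[(nfull + 1):length(v)]),
                             collapse = ""))
  writeLines(lines, con)
  invisible(path)
}
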