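#' @useDynLib permeonics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd setNames optim rnorm runif aggregate
#' @importFrom utils head tail
NULL

ROLE_LEVELS <- c("ion", "water_O", "water_H", "protein", "other")

#' Construct a trajectory object
#'
#' A trajectory holds a fixed atom table (identities are consistent across
#' frames) plus per-frame coordinates, times and orthorhombic box vectors.
#' The pore axis is z; +z is the outward (extracellular) direction.
#'
#' @param atoms data.frame with columns \code{atom_id} (unique integers),
#'   \code{element} (chemical symbol), \code{role} (one of ion, water_O,
#'   water_H, protein, other) and \code{molecule_id} (integer grouping atoms
#'   into molecules; each water molecule groups one water_O and two water_H).
#' @param coords numeric array \code{[n_frames, n_atoms, 3]} in Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param box orthorhombic box edge lengths in Angstrom: either a length-3
#'   vector (constant box) or an \code{n_frames x 3} matrix.
#' @return An object of class \code{trajectory}.
#' @export
new_trajectory <- function(atoms, coords, times, box) {
  atoms <- as.data.frame(atoms)
  req <- c("atom_id", "element", "role", "molecule_id")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(atoms$atom_id))
    stop("atom_id values must be unique within a frame")
  bad_role <- setdiff(unique(atoms$role), ROLE_LEVELS)
  if (length(bad_role))
    stop("unknown roles: ", paste(bad_role, collapse = ", "))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_atoms, 3] array")
  n_frames <- dim(coords)[1]
  if (dim(coords)[2] != nrow(atoms))
    stop("coords atom dimension (", dim(coords)[2], ") != atoms rows (", nrow(atoms), ")")
  if (length(times) != n_frames)
    stop("times length != number of frames")
  if (n_frames > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates")
  if (is.matrix(box)) {
    if (nrow(box) != n_frames || ncol(box) != 3L)
      stop("box matrix must be n_frames x 3")
  } else {
    if (length(box) != 3L) stop("box must be length-3 or n_frames x 3")
    box <- matrix(box, nrow = n_frames, ncol = 3L, byrow = TRUE)
  }
  if (any(box <= 0)) stop("box edge lengths must be positive")
  dimnames(coords) <- NULL
  dimnames(box) <- NULL
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times),
                 box = box, axis_convention = "pore axis = z, outward = +z"),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, %d atoms, t = [%g, %g] ns\n",
              n_frames(x), nrow(x$atoms), x$times[1], x$times[n_frames(x)]))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$atoms$role)),
                                as.integer(table(x$atoms$role))), collapse = " "), "\n")
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory object
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#'
#' @param traj trajectory object
#' @param i frame index (1-based)
#' @return An object of class \code{md_frame}: list with \code{time} (ns),
#'   \code{box} (length-3 Angstrom vector) and \code{atoms} (data.frame with
#'   atom_id, element, role, molecule_id, x, y, z).
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"), i >= 1, i <= n_frames(traj))
  at <- traj$atoms
  at$x <- traj$coords[i, , 1]
  at$y <- traj$coords[i, , 2]
  at$z <- traj$coords[i, , 3]
  structure(list(time = traj$times[i], box = traj$box[i, ], atoms = at),
            class = "md_frame")
}

#' Build a single-frame object directly
#'
#' @param atoms data.frame with atom_id, element, role, molecule_id, x, y, z.
#' @param box length-3 box vector (Angstrom); may be NULL for isolated
#'   (non-periodic) systems such as cluster models.
#' @param time frame time in ns.
#' @return An \code{md_frame} object.
#' @export
new_frame <- function(atoms, box = NULL, time = 0) {
  atoms <- as.data.frame(atoms)
  req <- c("atom_id", "element", "role", "molecule_id", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("frame atoms lack columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(box)) {
    stopifnot(length(box) == 3L)
    if (any(box <= 0)) stop("box edge lengths must be positive")
  }
  structure(list(time = time, box = box, atoms = atoms), class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms, t = %g ns%s\n", nrow(x$atoms), x$time,
              if (is.null(x$box)) ", no box" else
                sprintf(", box %.2f x %.2f x %.2f A", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Select atom indices by role
#'
#' @param traj trajectory or md_frame
#' @param roles character vector of roles, or "all"
#' @param elements optional element filter
#' @return integer vector of row indices into the atom table
#' @export
select_atoms <- function(traj, roles = "all", elements = NULL) {
  at <- traj$atoms
  keep <- if (identical(roles, "all")) rep(TRUE, nrow(at)) else at$role %in% roles
  if (!is.null(elements)) keep <- keep & at$element %in% elements
  which(keep)
}

# minimum-image displacement for orthorhombic box (vectorized over rows)
.min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# minimum-image distances from one point to a matrix of points
.mi_dist <- function(p, pts, box = NULL) {
  d <- sweep(pts, 2, p)
  if (!is.null(box)) d <- .min_image(d, box)
  sqrt(rowSums(d * d))
}
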