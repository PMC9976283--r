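#' Assign localized-orbital centers to water molecules and classify them
#'
#' Each center is attached to the molecule of its nearest oxygen (within
#' \code{assign_radius}); centers farther from every oxygen are kept with
#' kind "unassigned" and a warning. A center is an O-H bond center when the
#' angle between the O->center and O->H directions is below
#' \code{bond_cone} degrees for either hydrogen of the molecule; otherwise
#' it is an oxygen lone pair. For water, two centers of each kind are
#' expected (4 per molecule, each carrying charge -2 e in the valence
#' picture).
#'
#' @param centers n x 3 matrix of center positions (Angstrom), e.g. from
#'   [read_wannier_centers()] or [boys_centers()]
#' @param frame md_frame holding the molecular geometry
#' @param assign_radius maximal center-oxygen distance (Angstrom, default 1.2)
#' @param bond_cone bond-classification half-angle in degrees (default 35)
#' @return object of class \code{wannier_set}: list with \code{centers}
#'   (data.frame center_id, x, y, z, molecule_id, kind, h_atom_id) and
#'   \code{frame}
#' @export
assign_and_classify_centers <- function(centers, frame, assign_radius = 1.2,
                                        bond_cone = 35) {
  stopifnot(inherits(frame, "md_frame"))
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must be an n x 3 matrix")
  at <- frame$atoms
  o_rows <- which(at$element == "O")
  if (!length(o_rows)) stop("frame contains no oxygen atoms")
  O <- cbind(at$x[o_rows], at$y[o_rows], at$z[o_rows])
  n <- nrow(centers)
  mol <- rep(NA_integer_, n)
  kind <- rep("unassigned", n)
  h_id <- rep(NA_integer_, n)
  cos_cone <- cos(bond_cone * pi / 180)
  for (i in seq_len(n)) {
    d <- .mi_dist(centers[i, ], O, frame$box)
    j <- which.min(d)
    if (d[j] > assign_radius) next
    orow <- o_rows[j]
    mol[i] <- at$molecule_id[orow]
    hs <- which(at$molecule_id == mol[i] & at$element == "H")
    v_c <- centers[i, ] - c(at$x[orow], at$y[orow], at$z[orow])
    nc <- sqrt(sum(v_c^2))
    kind[i] <- "lone_pair"
    if (nc > 1e-12) for (h in hs) {
      v_h <- c(at$x[h] - at$x[orow], at$y[h] - at$y[orow], at$z[h] - at$z[orow])
      ca <- sum(v_c * v_h) / (nc * sqrt(sum(v_h^2)))
      if (ca >= cos_cone) { kind[i] <- "OH_bond"; h_id[i] <- at$atom_id[h]; break }
    }
  }
  if (anyNA(mol))
    warning(sum(is.na(mol)), " center(s) farther than ", assign_radius,
            " A from any oxygen left unassigned")
  structure(list(centers = data.frame(center_id = seq_len(n),
                                      x = centers[, 1], y = centers[, 2],
                                      z = centers[, 3], molecule_id = mol,
                                      kind = kind, h_atom_id = h_id),
                 frame = frame), class = "wannier_set")
}

#' @export
print.wannier_set <- function(x, ...) {
  tb <- table(x$centers$kind)
  cat(sprintf("wannier_set: %d centers (%s) on %d molecules\n",
              nrow(x$centers),
              paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
              length(unique(stats::na.omit(x$centers$molecule_id)))))
  invisible(x)
}

# optimal pairing of two small point sets (<= 4 points): minimizes total
# squared distance over permutations
.match_points <- function(A, B) {
  n <- nrow(A)
  if (n != nrow(B)) return(NULL)
  if (n == 1L) return(1L)
  perms <- .permutations(n)
  cost <- apply(perms, 1, function(p) sum((A - B[p, , drop = FALSE])^2))
  perms[which.min(cost), ]
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(sub >= k, sub + 1L, sub))))
}

#' Mean localized-center displacement between two states
#'
#' Compares matched centers of the same molecules between a reference set
#' (\code{set_a}, e.g. the ion-free computation) and a perturbed set
#' (\code{set_b}, e.g. with the coordinating ion present), assuming the same
#' internal water geometry. Displacements (b - a) are projected on physically
#' meaningful directions:
#' \itemize{
#'   \item lone pairs: onto the unit vector from the molecule's oxygen toward
#'     \code{direction_ref} (the ion position) - positive = toward the ion;
#'   \item bond centers: onto the unit vector from the bond hydrogen toward
#'     the oxygen - positive = toward the oxygen.
#' }
#' Within each (molecule, kind) group, centers are paired by
#' minimum-total-distance matching.
#'
#' @param set_a,set_b \code{wannier_set} objects over the same molecules
#' @param direction_ref length-3 ion position (Angstrom)
#' @return list with lone_pair (mean, sd, n) and OH_bond (mean, sd, n)
#'   projected shifts in Angstrom
#' @export
center_shift <- function(set_a, set_b, direction_ref) {
  stopifnot(inherits(set_a, "wannier_set"), inherits(set_b, "wannier_set"))
  direction_ref <- as.numeric(direction_ref)
  ca <- set_a$centers; cb <- set_b$centers
  at <- set_b$frame$atoms
  mols <- sort(unique(stats::na.omit(ca$molecule_id)))
  mism <- setdiff(mols, unique(stats::na.omit(cb$molecule_id)))
  if (length(mism))
    stop("unmatched molecules between center sets: ",
         paste(mism, collapse = ", "))
  proj <- list(lone_pair = numeric(0), OH_bond = numeric(0))
  for (m in mols) {
    orow <- which(at$molecule_id == m & at$element == "O")
    if (!length(orow)) next
    o_pos <- c(at$x[orow[1]], at$y[orow[1]], at$z[orow[1]])
    for (k in c("lone_pair", "OH_bond")) {
      ia <- which(ca$molecule_id == m & ca$kind == k)
      ib <- which(cb$molecule_id == m & cb$kind == k)
      if (!length(ia) && !length(ib)) next
      if (length(ia) != length(ib))
        stop("molecule ", m, ": ", length(ia), " vs ", length(ib), " centers of kind ", k)
      A <- as.matrix(ca[ia, c("x", "y", "z")])
      B <- as.matrix(cb[ib, c("x", "y", "z")])
      p <- .match_points(A, B)
      for (q in seq_along(ia)) {
        dvec <- B[p[q], ] - A[q, ]
        if (k == "lone_pair") {
          u <- direction_ref - o_pos
        } else {
          hid <- cb$h_atom_id[ib[p[q]]]
          if (is.na(hid)) hid <- ca$h_atom_id[ia[q]]
          hrow <- match(hid, at$atom_id)
          u <- o_pos - c(at$x[hrow], at$y[hrow], at$z[hrow])
        }
        u <- u / sqrt(sum(u^2))
        proj[[k]] <- c(proj[[k]], sum(dvec * u))
      }
    }
  }
  summarize <- function(v) list(
    mean = if (length(v)) mean(v) else NA_real_,
    sd = if (length(v) > 1) stats::sd(v) else NA_real_,
    n = length(v))
  list(lone_pair = summarize(proj$lone_pair),
       OH_bond = summarize(proj$OH_bond))
}

#' Molecular dipole from localized-orbital centers
#'
#' Valence point-charge dipole of one water molecule:
#' mu = 6 e r_O + 1 e r_H1 + 1 e r_H2 - 2 e sum(r_center) over its four
#' localized centers (pseudopotential valence charges O +6, H +1; each
#' doubly occupied localized orbital carries -2 e). The molecule is neutral
#' in this accounting, so the dipole is origin-independent. Magnitude is
#' reported in Debye (1 e*A = 4.80320 D).
#'
#' @param set \code{wannier_set}
#' @param molecule_id which molecule
#' @return list(molecule_id, dipole_eA (length-3 vector), magnitude_D)
#' @export
molecular_dipole <- function(set, molecule_id) {
  stopifnot(inherits(set, "wannier_set"))
  at <- set$frame$atoms
  rows <- which(at$molecule_id == molecule_id)
  o <- rows[at$element[rows] == "O"]
  h <- rows[at$element[rows] == "H"]
  if (length(o) != 1L || length(h) != 2L)
    stop("molecule ", molecule_id, " is not a water (need O,H,H; found ",
         paste(at$element[rows], collapse = ","), ")")
  cc <- set$centers[!is.na(set$centers$molecule_id) &
                      set$centers$molecule_id == molecule_id, ]
  if (nrow(cc) != 4L)
    stop("molecule ", molecule_id, " has ", nrow(cc),
         " assigned centers; exactly 4 required")
  mu <- 6 * c(at$x[o], at$y[o], at$z[o]) +
    c(sum(at$x[h]), sum(at$y[h]), sum(at$z[h])) -
    2 * c(sum(cc$x), sum(cc$y), sum(cc$z))
  list(molecule_id = molecule_id, dipole_eA = mu,
       magnitude_D = sqrt(sum(mu^2)) * permeonics_constants()$debye_per_eA)
}
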