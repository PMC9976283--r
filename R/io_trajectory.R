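#' Default rules mapping atoms to analysis roles
#'
#' Roles are assigned from element symbols and (for PDB/GRO input) residue
#' names. The defaults cover common water models, monatomic ions and the
#' standard amino acids; anything else becomes role \code{other}.
#'
#' @return list of rule vectors; pass a modified copy to [read_trajectory()].
#' @export
default_role_map <- function() {
  list(
    water_residues = c("SOL", "HOH", "TIP3", "TIP3P", "TIP4", "TIP4P",
                       "SPC", "SPCE", "WAT", "T3P"),
    ion_elements = c("Ca", "Na", "K", "Mg", "Zn", "Cl", "Rb", "Cs", "Ba",
                     "Li", "Sr"),
    ion_residues = c("CA", "CAL", "CA2", "NA", "SOD", "K", "POT", "CL",
                     "CLA", "MG", "ZN", "RB", "CS", "BA", "LI", "SR"),
    protein_residues = AMINO3
  )
}

.norm_element <- function(sym) {
  sym <- sub("[^A-Za-z].*$", "", sym)
  paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym))))
}

.check_elements <- function(elements, where = "input") {
  bad <- setdiff(unique(elements), ELEMENTS)
  if (length(bad))
    stop("unknown element symbol(s) in ", where, ": ", paste(bad, collapse = ", "))
}

# element guessed from an atom name (PDB/GRO style): two-letter symbols only
# accepted when the name matches them case-insensitively (CA in a protein
# residue is carbon; CA in residue CAL/CA is calcium - handled by role rules).
.element_from_name <- function(name, resname, role_map) {
  name <- sub("^[0-9]+", "", trimws(name))
  two <- .norm_element(substr(name, 1, 2))
  one <- .norm_element(substr(name, 1, 1))
  res <- trimws(resname)
  if (res %in% role_map$ion_residues && two %in% role_map$ion_elements) return(two)
  if (two %in% c("Cl", "Br", "Rb", "Cs", "Ba", "Mg", "Zn", "Sr", "Li", "Na") &&
      !(res %in% AMINO3)) return(two)
  if (one %in% ELEMENTS) return(one)
  two
}

# assign roles + molecule ids given per-atom element, residue name and
# residue serial; returns list(role, molecule_id)
.assign_roles <- function(element, resname, res_serial, role_map) {
  n <- length(element)
  role <- rep("other", n)
  resname <- toupper(trimws(resname))
  is_wat <- resname %in% role_map$water_residues
  role[is_wat & element == "O"] <- "water_O"
  role[is_wat & element == "H"] <- "water_H"
  role[resname %in% role_map$protein_residues] <- "protein"
  role[resname %in% role_map$ion_residues & element %in% role_map$ion_elements] <- "ion"
  list(role = role, molecule_id = as.integer(factor(res_serial,
                                                    levels = unique(res_serial))))
}

# element-only role assignment for XYZ input: waters are consecutive O,H,H
# triplets; listed ion elements become ions; the rest is "other"
.assign_roles_xyz <- function(element, role_map) {
  n <- length(element)
  role <- rep("other", n)
  molecule <- integer(n)
  mid <- 0L
  i <- 1L
  while (i <= n) {
    if (element[i] %in% role_map$ion_elements) {
      mid <- mid + 1L
      role[i] <- "ion"; molecule[i] <- mid
      i <- i + 1L
    } else if (element[i] == "O" && i + 2L <= n &&
               element[i + 1L] == "H" && element[i + 2L] == "H") {
      mid <- mid + 1L
      role[i] <- "water_O"; role[i + 1L] <- "water_H"; role[i + 2L] <- "water_H"
      molecule[i:(i + 2L)] <- mid
      i <- i + 3L
    } else {
      mid <- mid + 1L
      molecule[i] <- mid
      i <- i + 1L
    }
  }
  list(role = role, molecule_id = molecule)
}

#' Read a coordinate trajectory
#'
#' Reads XYZ (multi-frame), PDB (MODEL records via bio3d) or GRO (multi-frame)
#' files into a [new_trajectory()] object. Coordinates are returned in
#' Angstrom (GRO nm values are converted). Roles are assigned from element
#' and residue-name rules; XYZ input, which carries no residue information,
#' uses element rules with consecutive O,H,H triplets grouped as waters.
#'
#' XYZ comment lines of the form \code{time=<ns> box=<a> <b> <c>} (written by
#' [write_xyz()]) restore times and box; otherwise frame index is used as
#' time and \code{box} must be supplied.
#'
#' @param path file path
#' @param format one of "xyz", "pdb", "gro", "auto" (by file extension)
#' @param role_map rule list, see [default_role_map()]
#' @param box fallback orthorhombic box (Angstrom, length 3) when the file
#'   has none
#' @param dt fallback frame spacing in ns when the file has no times
#' @return A \code{trajectory}
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "pdb", "gro"),
                            role_map = default_role_map(), box = NULL, dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", gro = "gro",
                     stop("cannot infer trajectory format from extension '",
                          ext, "'"))
  }
  switch(format,
         xyz = .read_xyz(path, role_map, box, dt),
         pdb = .read_pdb(path, role_map, box, dt),
         gro = .read_gro(path, role_map, box, dt))
}

.read_xyz <- function(path, role_map, box, dt) {
  lines <- readLines(path)
  frames_coords <- list()
  times <- c(); boxes <- list()
  atoms0 <- NULL
  i <- 1L; fi <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("XYZ parse error at line ", i, ": truncated frame (need ", nat,
           " atom lines)")
    comment <- lines[i + 1L]
    block <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    nt <- lengths(toks)
    if (any(nt < 4))
      stop("XYZ parse error at line ", i + 1L + which(nt < 4)[1],
           ": expected 'element x y z'")
    el <- .norm_element(vapply(toks, `[`, "", 1L))
    .check_elements(el, paste0(path, " line ", i + 2L))
    xyz <- cbind(as.numeric(vapply(toks, `[`, "", 2L)),
                 as.numeric(vapply(toks, `[`, "", 3L)),
                 as.numeric(vapply(toks, `[`, "", 4L)))
    if (anyNA(xyz))
      stop("XYZ parse error near line ", i + 2L, ": non-numeric coordinate")
    fi <- fi + 1L
    t_m <- regmatches(comment, regexec("time=\\s*([0-9eE.+-]+)", comment))[[1]]
    b_m <- regmatches(comment, regexec(
      "box=\\s*([0-9eE.+-]+)\\s+([0-9eE.+-]+)\\s+([0-9eE.+-]+)", comment))[[1]]
    times <- c(times, if (length(t_m)) as.numeric(t_m[2]) else (fi - 1) * dt)
    boxes[[fi]] <- if (length(b_m)) as.numeric(b_m[2:4]) else box
    if (is.null(atoms0)) {
      rl <- .assign_roles_xyz(el, role_map)
      atoms0 <- data.frame(atom_id = seq_len(nat), element = el,
                           role = rl$role, molecule_id = rl$molecule_id,
                           stringsAsFactors = FALSE)
    } else if (nat != nrow(atoms0) || !identical(el, atoms0$element)) {
      stop("XYZ frame ", fi, " has inconsistent atoms")
    }
    frames_coords[[fi]] <- xyz
    i <- i + 2L + nat
  }
  if (fi == 0L) stop("no frames found in ", path)
  if (any(vapply(boxes, is.null, TRUE)))
    stop("no box information in XYZ comments; supply box=")
  coords <- aperm(simplify2array(frames_coords), c(3, 1, 2))
  new_trajectory(atoms0, coords, times, do.call(rbind, boxes))
}

.read_pdb <- function(path, role_map, box, dt) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nat <- nrow(at)
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(!nzchar(trimws(el)))) el <- rep("", nat)
  el <- ifelse(is.na(el) | !nzchar(trimws(el)),
               mapply(.element_from_name, at$elety, at$resid,
                      MoreArgs = list(role_map = role_map)),
               .norm_element(el))
  .check_elements(el, path)
  res_serial <- paste(at$chain, at$resno, at$insert, sep = "_")
  rl <- .assign_roles(el, at$resid, res_serial, role_map)
  atoms0 <- data.frame(atom_id = seq_len(nat), element = el, role = rl$role,
                       molecule_id = rl$molecule_id, stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(0, c(nf, nat, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cl)) {
    b <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33)))
    ang <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                        substr(cl[1], 48, 54)))
    if (any(abs(ang - 90) > 1e-3))
      stop("non-orthorhombic box (angles ", paste(ang, collapse = ", "),
           "); only orthorhombic boxes are supported")
    box <- b
  }
  if (is.null(box)) stop("no CRYST1 record in ", path, "; supply box=")
  new_trajectory(atoms0, coords, (seq_len(nf) - 1) * dt, box)
}

.read_gro <- function(path, role_map, box, dt) {
  lines <- readLines(path)
  i <- 1L; fi <- 0L
  frames_coords <- list(); times <- c(); boxes <- list(); atoms0 <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat <= 0)
      stop("GRO parse error at line ", i + 1L, ": expected atom count")
    if (i + 2L + nat > length(lines))
      stop("GRO parse error: truncated frame starting line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    resno <- as.integer(substr(block, 1, 5))
    resname <- trimws(substr(block, 6, 10))
    atname <- trimws(substr(block, 11, 15))
    x <- as.numeric(substr(block, 21, 28)) * 10
    y <- as.numeric(substr(block, 29, 36)) * 10
    z <- as.numeric(substr(block, 37, 44)) * 10
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("GRO parse error: non-numeric coordinate near line ", i + 2L)
    bline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                 "[[:space:]]+")[[1]])
    if (length(bline) < 3)
      stop("GRO parse error: bad box line ", i + 2L + nat)
    if (length(bline) > 3 && any(abs(bline[4:length(bline)]) > 1e-9))
      stop("triclinic GRO box; only orthorhombic boxes are supported")
    fi <- fi + 1L
    boxes[[fi]] <- bline[1:3] * 10
    t_m <- regmatches(title, regexec("t=\\s*([0-9eE.+-]+)", title))[[1]]
    times <- c(times, if (length(t_m)) as.numeric(t_m[2]) / 1000 else (fi - 1) * dt)
    if (is.null(atoms0)) {
      el <- mapply(.element_from_name, atname, resname,
                   MoreArgs = list(role_map = role_map))
      .check_elements(el, path)
      rl <- .assign_roles(el, resname, resno, role_map)
      atoms0 <- data.frame(atom_id = seq_len(nat), element = el,
                           role = rl$role, molecule_id = rl$molecule_id,
                           stringsAsFactors = FALSE)
    }
    frames_coords[[fi]] <- cbind(x, y, z)
    i <- i + 3L + nat
  }
  if (fi == 0L) stop("no frames found in ", path)
  coords <- aperm(simplify2array(frames_coords), c(3, 1, 2))
  new_trajectory(atoms0, coords, times, do.call(rbind, boxes))
}

#' Write a trajectory (or single frame) as multi-frame XYZ
#'
#' Comment lines carry \code{time=} and \code{box=} metadata so that
#' [read_trajectory()] round-trips times and boxes.
#'
#' @param traj trajectory or md_frame
#' @param path output path
#' @return invisibly, the path
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(traj, "md_frame")) {
    frames <- list(traj)
    get <- function(i) frames[[i]]
    nf <- 1L
  } else {
    nf <- n_frames(traj)
    get <- function(i) get_frame(traj, i)
  }
  for (i in seq_len(nf)) {
    fr <- get(i)
    writeLines(as.character(nrow(fr$atoms)), con)
    meta <- sprintf("time=%.10g", fr$time)
    if (!is.null(fr$box))
      meta <- paste(meta, sprintf("box=%.10g %.10g %.10g",
                                  fr$box[1], fr$box[2], fr$box[3]))
    writeLines(meta, con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", fr$atoms$element,
                       fr$atoms$x, fr$atoms$y, fr$atoms$z), con)
  }
  invisible(path)
}

#' Read localized-orbital (Wannier) center positions
#'
#' Accepts XYZ-style point lists: centers are rows whose element field is one
#' of X, W or XX (any other element rows are ignored, so a combined
#' geometry+centers file also works).
#'
#' @param path XYZ-style file
#' @return numeric matrix (n x 3) of center positions in Angstrom
#' @export
read_wannier_centers <- function(path) {
  lines <- readLines(path)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("not an XYZ-style file: ", path)
  block <- lines[3:(2 + nat)]
  toks <- strsplit(trimws(block), "[[:space:]]+")
  el <- toupper(vapply(toks, `[`, "", 1L))
  keep <- el %in% c("X", "W", "XX")
  if (!any(keep)) stop("no center rows (element X/W) found in ", path)
  m <- t(vapply(toks[keep], function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(m)) stop("non-numeric center coordinates in ", path)
  unname(m)
}

#' Write center positions as an XYZ-style point list
#' @param centers n x 3 matrix (Angstrom)
#' @param path output path
#' @param symbol element tag for the rows (default "X")
#' @return invisibly, the path
#' @export
write_wannier_centers <- function(centers, path, symbol = "X") {
  centers <- as.matrix(centers)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(centers)), "localized orbital centers"), con)
  writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", symbol,
                     centers[, 1], centers[, 2], centers[, 3]), con)
  invisible(path)
}
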