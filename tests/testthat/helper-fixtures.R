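# shared fixture builders (everything generated in code; no stored data)

# single-ion trajectory following a prescribed z(t); x = y = 0
ion_traj <- function(z, box = c(40, 40, 70), element = "Ca") {
  n <- length(z)
  coords <- array(0, c(n, 1, 3))
  coords[, 1, 3] <- z
  new_trajectory(
    atoms = data.frame(atom_id = 1L, element = element, role = "ion",
                       molecule_id = 1L, stringsAsFactors = FALSE),
    coords = coords, times = seq_len(n) - 1, box = box)
}

# multi-atom static frame trajectory: same frame repeated n_frames times
static_traj <- function(atoms, n_frames, box = c(40, 40, 70)) {
  coords <- array(0, c(n_frames, nrow(atoms), 3))
  for (f in seq_len(n_frames)) {
    coords[f, , 1] <- atoms$x
    coords[f, , 2] <- atoms$y
    coords[f, , 3] <- atoms$z
  }
  new_trajectory(atoms[, c("atom_id", "element", "role", "molecule_id")],
                 coords, seq_len(n_frames) - 1, box)
}

# water atom rows helper
water_rows <- function(mol_id, o, h1, h2, first_atom_id) {
  data.frame(atom_id = first_atom_id + 0:2,
             element = c("O", "H", "H"),
             role = c("water_O", "water_H", "water_H"),
             molecule_id = mol_id,
             x = c(o[1], h1[1], h2[1]),
             y = c(o[2], h1[2], h2[2]),
             z = c(o[3], h1[3], h2[3]), stringsAsFactors = FALSE)
}

expect_events <- function(ev, n_out, n_in) {
  expect_equal(sum(ev$direction == "outward"), n_out)
  expect_equal(sum(ev$direction == "inward"), n_in)
}
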