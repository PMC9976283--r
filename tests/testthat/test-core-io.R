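test_that("XYZ trajectories round-trip through write_xyz/read_trajectory", {
  model <- pore_model(n_ions = 2, seed = 3)
  traj <- gen_pore_trajectory(model, 25, 5e-4)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 25)
  expect_equal(back$atoms$role, traj$atoms$role)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  expect_equal(back$times, traj$times, tolerance = 1e-9)
  expect_equal(back$box, traj$box, tolerance = 1e-9)
})

test_that("XYZ reader groups O,H,H triplets into waters and flags ions", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("4", "time=0 box=20 20 20",
               "Ca 0 0 0",
               "O  3 0 0", "H  3.6 0.6 0", "H  3.6 -0.6 0"), f)
  tr <- read_trajectory(f)
  expect_equal(tr$atoms$role, c("ion", "water_O", "water_H", "water_H"))
  expect_equal(tr$atoms$molecule_id, c(1L, 2L, 2L, 2L))
})

test_that("malformed coordinate files produce parse errors with location", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "comment", "O 0 0 0"), f)  # truncated
  expect_error(read_trajectory(f), "truncated")
  writeLines(c("2", "c", "O 0 0 0", "H 1 bad 0"), f)
  suppressWarnings(expect_error(read_trajectory(f), "non-numeric"))
  writeLines(c("1", "c", "Qq 0 0 0"), f)
  expect_error(read_trajectory(f), "Qq")
})

test_that("PDB water residues group O,H,H by residue and parse the box", {
  f <- withr::local_tempfile(fileext = ".pdb")
  pdb_atom <- function(serial, name, resn, resno, x, y, z, ele)
    sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resn, "A", resno, x, y, z, 1, 0, ele)
  writeLines(c(
    "CRYST1   30.000   30.000   40.000  90.00  90.00  90.00 P 1           1",
    pdb_atom(1, "OH2", "TIP3", 1, 1.0, 2.0, 3.0, "O"),
    pdb_atom(2, "H1", "TIP3", 1, 1.6, 2.6, 3.0, "H"),
    pdb_atom(3, "H2", "TIP3", 1, 1.6, 1.4, 3.0, "H"),
    pdb_atom(4, "CA", "CAL", 2, 5.0, 5.0, 5.0, "CA"),
    "END"), f)
  tr <- read_trajectory(f)
  expect_equal(tr$atoms$role, c("water_O", "water_H", "water_H", "ion"))
  expect_equal(tr$atoms$molecule_id[1:3], rep(1L, 3))
  expect_equal(tr$box[1, ], c(30, 30, 40))
  expect_equal(tr$coords[1, 1, ], c(1, 2, 3))
})

test_that("GRO files parse with nm -> Angstrom conversion", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "demo t= 0.0",
    "    2",
    "    1SOL     OW    1   0.100   0.200   0.300",
    "    1SOL    HW1    2   0.160   0.260   0.300",
    "   3.00000   3.00000   4.00000"), f)
  tr <- read_trajectory(f)
  expect_equal(tr$coords[1, 1, ], c(1, 2, 3))
  expect_equal(tr$box[1, ], c(30, 30, 40))
  expect_equal(tr$atoms$role[1:2], c("water_O", "water_H"))
  # triclinic box rejected
  writeLines(c("demo", "    1",
               "    1SOL     OW    1   0.100   0.200   0.300",
               "   3.0   3.0   4.0  0.0 0.0 0.5 0.0 0.0 0.0"), f)
  expect_error(read_trajectory(f), "triclinic")
})

test_that("cube of an analytic Gaussian integrates to its electron count", {
  g <- gen_gaussian_density(list(list(center = c(0, 0, 0), n_electrons = 1,
                                      sigma = 0.8)),
                            origin = c(-8, -8, -8), voxel = 0.25,
                            shape = c(65, 65, 65))
  expect_equal(grid_integral(g), 1.0, tolerance = 1e-6)
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, f)
  back <- read_cube(f)
  expect_equal(grid_integral(back), 1.0, tolerance = 1e-6)
  expect_equal(back$values, g$values, tolerance = 1e-9)
  expect_equal(voxel_volume(back), voxel_volume(g), tolerance = 1e-9)
  expect_equal(back$origin, g$origin, tolerance = 1e-7)
})

test_that("cube atom block round-trips and Bohr convention is honored", {
  cl <- gen_cluster_geometry(2)
  g <- gen_gaussian_density(list(list(center = c(0, 0, 0), n_electrons = 8,
                                      sigma = 0.6)),
                            origin = c(-5, -5, -5), voxel = 0.5,
                            shape = c(21, 21, 21))
  g$atoms <- cl$atoms
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, f)
  lines <- readLines(f)
  n_at <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1])
  expect_equal(n_at, 7)  # Ca + 2 waters; positive count = Bohr convention
  # voxel count line: positive integers signal Bohr; value in Bohr
  v1 <- as.numeric(strsplit(trimws(lines[4]), "\\s+")[[1]])
  expect_equal(v1[1], 21)
  expect_equal(v1[2] * 0.529177210903, 0.5, tolerance = 1e-7)
  back <- read_cube(f)
  expect_equal(back$atoms$element, g$atoms$element)
  expect_equal(back$atoms$x, g$atoms$x, tolerance = 1e-7)
  # zero-atom cube is valid
  g$atoms <- g$atoms[0, ]
  write_cube(g, f)
  expect_equal(nrow(read_cube(f)$atoms), 0)
})

test_that("cube layout matches a hand-written reference grid", {
  # 2x2x2 grid with known values; z varies fastest in the data block
  vals <- array(1:8, c(2, 2, 2))  # [x, y, z]
  g <- new_density_grid(c(0, 0, 0), c(1, 1, 1), vals)
  f <- withr::local_tempfile(fileext = ".cube")
  write_cube(g, f)
  lines <- readLines(f)
  expect_equal(length(lines), 6 + 2)  # 6 header lines (0 atoms) + 2 data lines
  row1 <- as.numeric(strsplit(trimws(lines[7]), "\\s+")[[1]])
  b3 <- 0.529177210903^3
  # cube order: (x1,y1,z1),(x1,y1,z2),(x1,y2,z1),(x1,y2,z2),(x2,y1,z1),...
  expect_equal(row1 / b3, c(vals[1, 1, 1], vals[1, 1, 2], vals[1, 2, 1],
                            vals[1, 2, 2], vals[2, 1, 1], vals[2, 1, 2]),
               tolerance = 1e-10)
  expect_error(read_cube(withr::local_tempfile(fileext = ".cube")),
               "not found")
})

test_that("non-axis-aligned cubes are rejected", {
  f <- withr::local_tempfile(fileext = ".cube")
  writeLines(c("t", "t",
               "    0    0.0 0.0 0.0",
               "    2    1.0 0.1 0.0",
               "    2    0.0 1.0 0.0",
               "    2    0.0 0.0 1.0",
               paste(rep("1.0", 8), collapse = " ")), f)
  expect_error(read_cube(f), "axis-aligned")
})

test_that("Wannier center XYZ point lists round-trip", {
  centers <- matrix(rnorm(12), 4, 3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_wannier_centers(centers, f)
  expect_equal(read_wannier_centers(f), centers, tolerance = 1e-9)
})

test_that("trajectory invariants are enforced", {
  at <- data.frame(atom_id = c(1L, 1L), element = "Ca", role = "ion",
                   molecule_id = 1:2)
  expect_error(new_trajectory(at, array(0, c(1, 2, 3)), 0, c(10, 10, 10)),
               "unique")
  at$atom_id <- 1:2
  expect_error(new_trajectory(at, array(0, c(2, 2, 3)), c(1, 1), c(10, 10, 10)),
               "strictly increasing")
  expect_error(new_trajectory(at, array(0, c(1, 2, 3)), 0, c(10, -1, 10)),
               "positive")
  expect_error(new_trajectory(at, array(Inf, c(1, 2, 3)), 0, c(10, 10, 10)),
               "finite")
})
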