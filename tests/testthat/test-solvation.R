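test_that("occupancy counts, density and concentration are exact on fixtures", {
  # one ion fixed at z = 0 over 10 frames, one bin
  at <- data.frame(atom_id = 1L, element = "Ca", role = "ion",
                   molecule_id = 1L, x = 0, y = 0, z = 0)
  traj <- static_traj(at, 10, box = c(10, 10, 10))
  occ <- occupancy(traj, z_edges = c(-5, 5))
  expect_equal(as.numeric(occ$counts), 10)
  expect_equal(as.numeric(occ$relative), 1.0)
  # concentration of 1 ion in a 10x10x10 A box: 1/(6.02214e23 * 1e-27 L)
  expect_equal(as.numeric(occ$concentration), 1.66054, tolerance = 1e-4)
  expect_equal(as.numeric(occ$density), 1e-3, tolerance = 1e-12)
})

test_that("uniform ideal-gas occupancy is flat within Monte-Carlo error", {
  traj <- gen_ideal_gas(50, c(20, 20, 40), 200, seed = 5)
  occ <- occupancy(traj, ion_selection = seq_len(50),
                   z_edges = seq(-20, 20, by = 4))
  n <- sum(occ$counts)
  p <- 4 / 40
  # binomial 3 sigma around expected count per bin
  expect_true(all(abs(occ$counts - n * p) < 3 * sqrt(n * p * (1 - p)) + 1))
  # total counts = n_frames x n_ions for a fully covered region
  expect_equal(n, 200 * 50)
})

test_that("Boltzmann inversion recovers the generating potential", {
  # uniform density -> F identically zero
  at <- data.frame(atom_id = 1L, element = "Ca", role = "ion",
                   molecule_id = 1L, x = 0, y = 0, z = 0)
  traj <- gen_ideal_gas(100, c(20, 20, 40), 100, seed = 2)
  occ <- boltzmann_invert(occupancy(traj, ion_selection = 1:100,
                                    z_edges = seq(-20, 20, by = 8)))
  expect_true(all(abs(occ$free_energy_kT) < 0.15))  # sampling noise only
  # analytic Gaussian density -> harmonic free energy, max error < 0.02 kT
  sigma <- 2
  edges <- seq(-4, 4, by = 0.5)
  centers <- edges[-length(edges)] + 0.25
  counts <- 1e6 * (pnorm(edges[-1], 0, sigma) - pnorm(edges[-length(edges)], 0, sigma))
  prof <- structure(list(z_edges = edges, r_edges = NULL, counts = counts,
                         n_frames = 1, density = counts / diff(edges),
                         z_centers = centers, temperature = 303),
                    class = "occupancy_profile")
  prof <- boltzmann_invert(prof)
  # exact bin-averaged reference via the same integrals
  f_ref <- -log(counts / max(counts))
  expect_equal(prof$free_energy_kT, f_ref, tolerance = 1e-12)
  # against the analytic z^2/(2 sigma^2) at bin centers
  expect_lt(max(abs(prof$free_energy_kT - (centers^2 / (2 * sigma^2) -
                                             min(centers^2 / (2 * sigma^2))))),
            0.02)
  # a bin at ratio e^-1 of the max sits exactly 1 kT up
  prof2 <- prof
  prof2$density <- c(1, exp(-1))
  prof2$counts <- prof2$density
  prof2 <- boltzmann_invert(prof2)
  expect_equal(prof2$free_energy_kT[2], 1, tolerance = 1e-12)
  # kJ/mol conversion at 303 K
  expect_equal(prof2$free_energy_kJmol[2], 0.0083144626 * 303,
               tolerance = 1e-6)
  prof2$density <- c(0, 0)
  expect_error(boltzmann_invert(prof2), "all-empty")
})

test_that("2D axial-radial occupancy uses annular bin volumes", {
  at <- data.frame(atom_id = 1L, element = "Ca", role = "ion",
                   molecule_id = 1L, x = 3, y = 0, z = 0)
  traj <- static_traj(at, 5, box = c(20, 20, 20))
  occ <- occupancy(traj, z_edges = c(-1, 1), r_edges = c(0, 2, 4))
  expect_equal(occ$counts[1, ], c(0, 5))
  vol <- pi * (16 - 4) * 2
  expect_equal(occ$density[1, 2], 5 / (5 * vol), tolerance = 1e-12)
})

test_that("rdf resolves a delta pair and normalizes an ideal gas to 1", {
  # single center + single partner at 2.4 A -> only that bin nonzero
  at <- rbind(
    data.frame(atom_id = 1L, element = "Ca", role = "ion", molecule_id = 1L,
               x = 0, y = 0, z = 0),
    data.frame(atom_id = 2L, element = "O", role = "water_O", molecule_id = 2L,
               x = 2.4, y = 0, z = 0))
  traj <- static_traj(at, 3, box = c(20, 20, 20))
  r <- rdf(traj, r_max = 5, dr = 0.2)
  hit <- which(r$g > 0)
  expect_length(hit, 1)
  expect_true(r$r_edges[hit] <= 2.4 && 2.4 <= r$r_edges[hit + 1])
  expect_equal(r$n_running[length(r$n_running)], 1)
  # ideal gas: mean |g - 1| below 0.05 for 2 < r < 8
  gas <- gen_ideal_gas(1000, c(30, 30, 30), 50, seed = 9)
  rg <- rdf(gas, center_selection = 1:20, partner_selection = 21:1000,
            r_max = 10, dr = 0.25)
  sel <- rg$r_centers > 2 & rg$r_centers < 8
  expect_lt(mean(abs(rg$g[sel] - 1)), 0.05)
  # n_running at r_max equals the direct average count within r_max
  direct <- mean(vapply(seq_len(n_frames(gas)), function(f) {
    fr <- get_frame(gas, f)
    mean(vapply(1:20, function(ci) coordination_count(
      fr, center = ci, partner_selection = 21:1000, cutoff = 10), numeric(1)))
  }, numeric(1)))
  expect_equal(rg$n_running[length(rg$n_running)], direct, tolerance = 1e-12)
})

test_that("rdf preconditions are enforced", {
  gas <- gen_ideal_gas(10, c(20, 20, 20), 2, seed = 1)
  expect_error(rdf(gas, center_selection = 1, partner_selection = 2:10,
                   r_max = 15, dr = 0.5), "half the smallest box")
  expect_error(rdf(gas, center_selection = 1, partner_selection = 2:10,
                   r_max = 8, dr = 0.5, condition_window = c(100, 110)),
               "conditioning window")
})

test_that("coordination_count handles the first-shell fixture and boundaries", {
  cl <- gen_cluster_geometry(7, ca_o_distance = 2.4)
  expect_equal(coordination_count(cl, center = 1, cutoff = 3.2), 7)
  expect_equal(coordination_count(cl, center = 1, cutoff = 2.0), 0)
  # closed boundary: partner exactly at the cutoff counts (brute force check)
  at <- rbind(
    data.frame(atom_id = 1L, element = "Ca", role = "ion", molecule_id = 1L,
               x = 0, y = 0, z = 0),
    data.frame(atom_id = 2L, element = "O", role = "water_O", molecule_id = 2L,
               x = 3.2, y = 0, z = 0))
  fr <- new_frame(at)
  d_brute <- sqrt(sum((c(3.2, 0, 0) - c(0, 0, 0))^2))
  expect_equal(coordination_count(fr, 1, cutoff = 3.2), sum(d_brute <= 3.2))
  # minimum image: partner across the periodic boundary
  at$x[2] <- 19.5
  fr2 <- new_frame(at, box = c(20, 20, 20))
  expect_equal(coordination_count(fr2, 1, cutoff = 1.0), 1)
})

test_that("hydration profile reports per-bin means, sds and residue counts", {
  # ion with a fixed 6-water shell at every z -> flat profile, sd 0
  shell <- gen_cluster_geometry(6, ca_o_distance = 2.4)$atoms
  zs <- seq(-8, 8, by = 2)
  coords <- array(0, c(length(zs), nrow(shell), 3))
  for (f in seq_along(zs)) {
    coords[f, , 1] <- shell$x
    coords[f, , 2] <- shell$y
    coords[f, , 3] <- shell$z + zs[f]
  }
  traj <- new_trajectory(shell[, 1:4], coords, seq_along(zs) - 1, c(40, 40, 40))
  hp <- hydration_profile(traj, z_edges = seq(-10, 10, by = 5))
  expect_true(all(hp$water_mean[hp$n > 0] == 6))
  # a protein residue with two oxygens in range counts as one residue
  prot <- data.frame(atom_id = 8:9, element = "O", role = "protein",
                     molecule_id = 99L, x = c(2.5, -2.5), y = 0, z = 0)
  at <- rbind(data.frame(atom_id = 1L, element = "Ca", role = "ion",
                         molecule_id = 1L, x = 0, y = 0, z = 0), prot)
  traj2 <- static_traj(at, 4, box = c(30, 30, 30))
  hp2 <- hydration_profile(traj2, z_edges = c(-5, 5), protein_cutoff = 3.2)
  expect_equal(hp2$protein_mean[1], 1)
  expect_equal(hp2$protein_sd[1], 0)
  # constructed shell switching 7 -> 6 waters at z = 0 gives a step profile
  sh7 <- gen_cluster_geometry(7)$atoms
  sh6 <- gen_cluster_geometry(6)$atoms
  sh6b <- rbind(sh6, transform(sh6[sh6$atom_id %in% 2:4, ],
                               atom_id = 20:22, molecule_id = 8L,
                               x = x + 15))  # park one water far away
  coords <- array(0, c(2, nrow(sh7), 3))
  coords[1, , ] <- as.matrix(sh7[, c("x", "y", "z")]) +
    matrix(c(0, 0, -5), nrow(sh7), 3, byrow = TRUE)
  coords[2, , ] <- as.matrix(sh6b[, c("x", "y", "z")]) +
    matrix(c(0, 0, 5), nrow(sh6b), 3, byrow = TRUE)
  traj3 <- new_trajectory(sh7[, 1:4], coords, 0:1, c(60, 60, 60))
  hp3 <- hydration_profile(traj3, z_edges = c(-10, 0, 10))
  expect_equal(hp3$water_mean, c(7, 6))
})
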