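grid_spec <- list(origin = c(-6, -6, -6), voxel = 0.25, shape = c(49, 49, 49))

gauss_grid <- function(components) {
  gen_gaussian_density(components, grid_spec$origin, grid_spec$voxel,
                       grid_spec$shape)
}

test_that("density_difference cancels exactly and conserves electrons", {
  ligand <- gauss_grid(list(list(center = c(0, 0, 0), n_electrons = 18,
                                 sigma = 0.7)))
  rest <- gauss_grid(list(list(center = c(2.4, 0, 0), n_electrons = 10,
                               sigma = 0.8)))
  complex <- ligand
  complex$values <- ligand$values + rest$values
  dd <- density_difference(complex, ligand, rest)
  expect_lt(max(abs(dd$values)), 1e-12)
  # electron counts 28 = 18 + 10: integral of the difference vanishes
  complex2 <- gauss_grid(list(
    list(center = c(0, 0, 0), n_electrons = 18, sigma = 0.7),
    list(center = c(2.4, 0, 0), n_electrons = 10, sigma = 0.8)))
  expect_equal(grid_integral(density_difference(complex2, ligand, rest)), 0,
               tolerance = 1e-6)
})

test_that("grid mismatches are reported by field", {
  a <- gauss_grid(list(list(center = c(0, 0, 0), n_electrons = 1, sigma = 1)))
  b <- a
  b$values <- array(0, c(25, 25, 25)); b$shape <- c(25, 25, 25)
  expect_error(density_difference(a, a, b), "shape of rest")
  d <- a; d$origin <- a$origin + 0.1
  expect_error(density_difference(a, d, a), "origin of ligand")
  e <- a; e$voxel <- a$voxel * 1.001
  expect_error(density_difference(a, a, e), "voxel")
})

test_that("Voronoi integration partitions space exactly", {
  g <- gauss_grid(list(list(center = c(0.3, -0.2, 0.1), n_electrons = 5,
                            sigma = 1.1)))
  # single site captures the whole integral
  expect_equal(voronoi_integrate(g, matrix(c(1, 2, 3), 1)), grid_integral(g),
               tolerance = 1e-12)
  # symmetric density, two mirror sites -> equal halves; the mirror plane
  # (x = 0.125) lies between grid planes so no voxel is tied
  g2 <- gauss_grid(list(list(center = c(0.125, 0, 0), n_electrons = 4,
                             sigma = 0.8)))
  v <- voronoi_integrate(g2, rbind(c(-1.5, 0, 0), c(1.75, 0, 0)))
  expect_equal(v[1], v[2], tolerance = 1e-9)
  expect_equal(sum(v), grid_integral(g2), tolerance = 1e-12)
  expect_error(voronoi_integrate(g2, matrix(0, 0, 3)), "empty site")
})

test_that("Voronoi integrals match a Monte-Carlo nearest-site quadrature", {
  set.seed(31)
  sites <- matrix(runif(15, -2, 2), 5, 3)
  comps <- list(list(center = c(0.5, 0, -0.5), n_electrons = 3, sigma = 1.2),
                list(center = c(-1, 1, 0), n_electrons = 2, sigma = 0.9))
  g <- gauss_grid(comps)
  v <- voronoi_integrate(g, sites)
  # Monte-Carlo oracle over the grid's bounding box
  n_mc <- 2e5
  lo <- grid_spec$origin
  hi <- grid_spec$origin + (grid_spec$shape - 1) * grid_spec$voxel
  pts <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]),
               runif(n_mc, lo[3], hi[3]))
  rho <- rep(0, n_mc)
  for (cm in comps)
    rho <- rho + cm$n_electrons / ((2 * pi)^1.5 * cm$sigma^3) *
      exp(-rowSums(sweep(pts, 2, cm$center)^2) / (2 * cm$sigma^2))
  d2 <- vapply(seq_len(5), function(s) rowSums(sweep(pts, 2, sites[s, ])^2),
               numeric(n_mc))
  nearest <- max.col(-d2)
  vol <- prod(hi - lo)
  for (s in 1:5) {
    sel <- nearest == s
    est <- vol * mean(rho * sel)
    se <- vol * sd(rho * sel) / sqrt(n_mc)
    expect_lt(abs(est - v[s]), 3 * se + 1e-3)
  }
})

test_that("charge transfer recovers a constructed donation pattern", {
  cl <- gen_cluster_geometry(7, ca_o_distance = 2.4)
  o_pos <- cl$atoms[cl$atoms$role == "water_O", c("x", "y", "z")]
  comps <- list(list(center = c(0, 0, 0), n_electrons = 0.21, sigma = 0.4))
  for (i in seq_len(7))
    comps[[i + 1]] <- list(center = as.numeric(o_pos[i, ]),
                           n_electrons = -0.03, sigma = 0.3)
  dd <- gen_gaussian_density(comps, c(-6.4, -6.4, -6.4), 0.2, c(65, 65, 65))
  dd$atoms <- cl$atoms
  ct <- charge_transfer(dd, ion_id = 1, nominal_charge = 2)
  expect_lt(abs(ct$effective_ion_charge - 1.79), 0.005)
  expect_lt(abs(ct$water_loss - 0.03), 0.001)
  expect_equal(sum(ct$per_atom$dn_e), grid_integral(dd), tolerance = 1e-9)
  # zero difference density -> effective charge equals the nominal charge
  dd0 <- dd; dd0$values <- array(0, dd$shape)
  ct0 <- charge_transfer(dd0, ion_id = 1)
  expect_equal(ct0$effective_ion_charge, 2.0)
  expect_error(charge_transfer(dd, ion_id = 99), "not found")
})

test_that("multi-snapshot charge transfer averages with a sample sd", {
  cl <- gen_cluster_geometry(2)
  mk <- function(loss) {
    o_pos <- cl$atoms[cl$atoms$role == "water_O", c("x", "y", "z")]
    comps <- list(list(center = c(0, 0, 0), n_electrons = 2 * loss,
                       sigma = 0.4))
    for (i in 1:2)
      comps[[i + 1]] <- list(center = as.numeric(o_pos[i, ]),
                             n_electrons = -loss, sigma = 0.3)
    g <- gen_gaussian_density(comps, c(-6.4, -6.4, -6.4), 0.2, c(65, 65, 65))
    g$atoms <- cl$atoms
    g
  }
  ct <- charge_transfer(list(mk(0.02), mk(0.04)), ion_id = 1)
  expect_lt(abs(ct$water_loss - 0.03), 0.001)
  expect_lt(abs(ct$water_loss_sd - sd(c(0.02, 0.04))), 0.001)
  expect_equal(ct$n_snapshots, 2)
  ca_row <- ct$per_element$element == "Ca"
  expect_lt(abs(ct$per_element$mean[ca_row] - 0.06), 0.002)
  expect_false(is.na(ct$per_element$sd[ca_row]))
})
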